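test_that("a monomorphic alignment yields no loci", {
  aln <- aligned_set(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                     c(a = "g1", b = "g1", c = "g2"))
  expect_equal(nrow(call_variants(aln)), 0)
})

test_that("calls agree with the brute-force column scanner on random alignments", {
  for (seed in 1:12) {
    aln <- random_alignment(n_taxa = 6, n_cols = 200, seed = seed)
    got <- call_variants(aln)
    want <- brute_force_scan(aln)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    expect_equal(got$start, want$start, info = paste("seed", seed))
    expect_equal(got$end, want$end, info = paste("seed", seed))
    expect_equal(got$class, want$class, info = paste("seed", seed))
  }
})

test_that("indel runs merge on identical gap patterns only", {
  #            0123456789
  aln <- aligned_set(c(a = "AC--GTACGT",
                       b = "ACGTGTA--T",
                       c = "AC--GT-CGT"),
                     c(a = "g1", b = "g2", c = "g3"))
  got <- call_variants(aln)
  # a+c share a 2-column gap run; b has its own; c a del1
  expect_equal(got$class, c("indel_multi", "del1", "indel_multi"))
  expect_equal(got$start, c(2L, 6L, 7L))
  expect_equal(got$end, c(4L, 7L, 9L))
})

test_that("a column with both substitution and gaps yields two flagged records", {
  aln <- aligned_set(c(a = "AAG", b = "A-G", c = "ACG", d = "AAG"),
                     c(a = "g1", b = "g1", c = "g2", d = "g2"))
  got <- call_variants(aln)
  expect_setequal(got$class, c("del1", "snp"))
  expect_true(all(got$overlaps))
  snp <- got[got$class == "snp", ]
  expect_equal(snp$start, 1L)
})

test_that("calling the variants of a reconstructed alignment is idempotent", {
  sim <- generate_alignment(festuca_profile(seed = 3))
  loci <- call_variants(sim$alignment)
  # rebuild an alignment holding only the called spans plus monomorphic
  # filler between them, then re-call
  taxa <- sim$alignment$taxa
  pieces <- lapply(seq_len(nrow(loci)), function(i) {
    vapply(taxa, function(tx) loci$alleles[[i]][[tx]], character(1))
  })
  filler <- matrix("A", length(taxa), 1, dimnames = list(taxa, NULL))
  cols <- list()
  for (i in seq_along(pieces)) {
    block <- do.call(rbind, strsplit(pieces[[i]], ""))
    rownames(block) <- taxa
    cols <- c(cols, list(block, filler))
  }
  mat2 <- do.call(cbind, cols)
  re <- call_variants(aligned_set(mat2, sim$alignment$groups))
  expect_equal(nrow(re), nrow(loci))
  expect_equal(table(re$class), table(loci$class))
})

test_that("N never creates a between-group difference", {
  aln <- aligned_set(c(a = "ANA", b = "ANA", c = "ACA", d = "AGA"),
                     c(a = "g1", b = "g1", c = "g2", d = "g2"))
  loci <- call_variants(aln)
  expect_equal(nrow(loci), 1)  # c vs d substitution only
  # allele sets of g1 at this locus are empty after N exclusion
  expect_equal(count_between_group(loci, aln$groups, "g1", "g2"), 0)
})

test_that("between-group counting follows the disjoint-allele rule", {
  sim <- generate_alignment(festuca_profile(seed = 20180))
  loci <- call_variants(sim$alignment)
  g <- sim$alignment$groups
  # direct count from the truth table: carriers on exactly one side
  truth_count <- function(ga, gb) {
    sum(purrr::map_lgl(sim$truth$carrier_groups,
                       ~ xor(ga %in% .x, gb %in% .x)))
  }
  pairs <- utils::combn(unique(unname(g)), 2)
  for (k in seq_len(ncol(pairs))) {
    expect_equal(
      count_between_group(loci, g, pairs[1, k], pairs[2, k]),
      truth_count(pairs[1, k], pairs[2, k]),
      info = paste(pairs[, k], collapse = "/"))
  }
  # a group against itself shares every allele
  expect_equal(count_between_group(loci, g, "mairei", "mairei"), 0)
  expect_error(count_between_group(loci, g, "nope", "mairei"), "unknown group")
})

test_that("similarity index bounds, rounding and errors", {
  expect_equal(similarity_index(0, 42), 1)
  expect_equal(similarity_index(42, 42), 0)
  expect_error(similarity_index(1, 0), "undefined")
  expect_error(similarity_index(5, 4), "n_between")
  # full precision on request; half-up rounding otherwise
  expect_equal(similarity_index(117, 167, digits = NULL), 1 - 117 / 167)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.985, 2), 0.99)
})

test_that("the comparison table is symmetric with a constant denominator", {
  sim <- generate_alignment(festuca_profile(seed = 5))
  loci <- call_variants(sim$alignment)
  g <- sim$alignment$groups
  tab <- comparison_table(loci, g)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$n_total == nrow(loci)))
  expect_true(all(tab$similarity >= 0 & tab$similarity <= 1))
  expect_equal(tab$similarity, 1 - tab$n_polymorphic / tab$n_total)
  swapped <- comparison_table(loci, g,
                              pairs = data.frame(a = tab$group_b,
                                                 b = tab$group_a))
  expect_equal(swapped$n_polymorphic, tab$n_polymorphic)
})

test_that("class counts always sum to the locus total", {
  for (seed in c(2, 9)) {
    aln <- random_alignment(n_taxa = 8, n_cols = 300, seed = seed)
    loci <- call_variants(aln)
    expect_equal(sum(table(loci$class)), nrow(loci))
  }
})
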