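test_that("in-silico PCR product lengths follow direct construction", {
  p <- primer_pair("p1", "ACGGTTACAGGTCCAATGCA", "TGCCATTGACCGGATATCGA", 400)
  rc <- revcomp(p$reverse)
  set.seed(31)
  for (k in c(0, 1, 13, 200)) {
    filler <- paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = "")
    tpl <- paste0("TT", p$forward, filler, rc, "AAC")
    res <- in_silico_pcr(tpl, p)
    expect_equal(res$product_length, nchar(p$forward) + k + nchar(p$reverse))
    expect_equal(res$forward_start, 2L)
  }
})

test_that("missing or ambiguous primer sites are handled", {
  p <- primer_pair("p1", "ACGGTTACAGGTCCAATGCA", "TGCCATTGACCGGATATCGA", 400)
  rc <- revcomp(p$reverse)
  # no forward site: absent product
  res <- in_silico_pcr(paste0("TTTT", rc), p)
  expect_true(is.na(res$product_length))
  # reverse site upstream of forward: absent
  res2 <- in_silico_pcr(paste0(rc, "ACGT", p$forward), p)
  expect_true(is.na(res2$product_length))
  # duplicated site: ambiguous
  expect_error(
    in_silico_pcr(paste0(p$forward, "AC", p$forward, "GT", rc), p),
    "ambiguous")
  # gapped template rejected
  expect_error(in_silico_pcr("AC-GT", p), "gap-free")
})

test_that("the four planted diagnostic indels are found, strictly and symmetrically", {
  sim <- generate_alignment(festuca_profile(seed = 20180))
  loci <- call_variants(sim$alignment)
  g <- sim$alignment$groups
  found <- find_diagnostic_indels(loci, g, "Continental", "Mediterranean",
                                  min_length = 3)
  expect_equal(nrow(found), 4)
  expect_setequal(found$length, c(32L, 3L, 47L, 8L))
  # symmetry in the group arguments
  swapped <- find_diagnostic_indels(loci, g, "Mediterranean", "Continental",
                                    min_length = 3)
  expect_setequal(found$locus_id, swapped$locus_id)
  # truth lookup: the diagnostic loci are exactly the multi-base indels
  # whose carrier split separates the two morphotypes
  want <- sim$truth |>
    dplyr::filter(class == "indel_multi",
                  purrr::map_lgl(carrier_groups,
                                 ~ xor("Continental" %in% .x,
                                       "Mediterranean" %in% .x)))
  expect_setequal(found$start, want$start)
  # no indel loci at all: empty result
  empty <- find_diagnostic_indels(loci[loci$class == "snp", ], g,
                                  "Continental", "Mediterranean")
  expect_equal(nrow(empty), 0)
})

test_that("one discordant sample disqualifies a locus at tolerance 0 but not 1", {
  # g1 = {a, b, e}, g2 = {c, d}; deletion fixed in g1 except discordant b
  aln <- aligned_set(c(a = "A-T", b = "AGT", c = "AGT", d = "AGT",
                       e = "A-T"),
                     c(a = "g1", b = "g1", c = "g2", d = "g2", e = "g1"))
  loci <- call_variants(aln)
  strict <- find_diagnostic_indels(loci, aln$groups, "g1", "g2")
  expect_equal(nrow(strict), 0)
  loose <- find_diagnostic_indels(loci, aln$groups, "g1", "g2",
                                  tolerance = 1)
  expect_equal(nrow(loose), 1)
  expect_equal(loose$n_violations, 1L)
})

test_that("size genotyping respects windows and rejects overlaps", {
  fx <- nftchl45_fixture()
  preds <- in_silico_pcr(fx$templates, fx$primer)
  rule <- setNames(c(750, 703), c("Mediterranean", "Continental"))
  calls <- genotype_by_size(preds, rule, tolerance = 5)
  expect_equal(calls$call[calls$template == "Mediterranean"], "Mediterranean")
  expect_equal(calls$call[calls$template == "Continental"], "Continental")
  # product between the windows
  mid <- tibble::tibble(primer = "x", template = "odd",
                        product_length = 726L,
                        forward_start = 0L, reverse_start = 700L)
  expect_equal(genotype_by_size(mid, rule, tolerance = 5)$call, "unknown")
  absent <- dplyr::mutate(mid, product_length = NA_integer_)
  expect_equal(genotype_by_size(absent, rule, tolerance = 5)$call, "unknown")
  expect_error(genotype_by_size(preds, rule, tolerance = 30), "overlapping")
})

test_that("SSR scoring matches the exhaustive scan and honours tolerance", {
  groups <- setNames(rep(c("Continental", "Mediterranean", "other"),
                         times = c(2, 3, 2)), sprintf("a%d", 1:7))
  gen <- generate_ssr_table(30, c(1, 12), 6, groups,
                            c("Continental", "Mediterranean"), seed = 9)
  rep0 <- score_ssr_discrimination(gen$table, groups, "Continental",
                                   "Mediterranean")
  expect_setequal(rep0$primer[rep0$discriminating],
                  brute_force_ssr(gen$table, groups, "Continental",
                                  "Mediterranean"))
  expect_setequal(rep0$primer[rep0$discriminating], gen$truth$primer)
  # fragment-count conservation
  expect_equal(sum(rep0$n_fragments),
               nrow(dplyr::distinct(gen$table, primer, fragment_id)))

  # a planted primer with one violating sample survives tolerance 1
  tab <- gen$table
  pk <- gen$truth$primer[1]
  fk <- gen$truth$fragment_ids[[1]][1]
  i <- which(tab$primer == pk & tab$fragment_id == fk &
               tab$accession == "a1")[1]
  tab$present[i] <- 1L - tab$present[i]
  rep_t0 <- score_ssr_discrimination(tab, groups, "Continental",
                                     "Mediterranean")
  rep_t1 <- score_ssr_discrimination(tab, groups, "Continental",
                                     "Mediterranean", tolerance = 1)
  expect_true(rep_t1$discriminating[rep_t1$primer == pk])
  expect_setequal(rep_t1$primer[rep_t1$discriminating],
                  brute_force_ssr(tab, groups, "Continental",
                                  "Mediterranean", tolerance = 1))
  # missing presence calls are reported with their cells
  tab$present[i] <- NA
  expect_error(score_ssr_discrimination(tab, groups, "Continental",
                                        "Mediterranean"),
               "missing presence")
})
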