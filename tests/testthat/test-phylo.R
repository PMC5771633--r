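test_that("binary encoding follows the one-column-per-allele rules", {
  sim <- generate_alignment(festuca_profile(seed = 20180))
  loci <- call_variants(sim$alignment)
  # all planted loci are biallelic: one reference column each
  ref <- encode_binary(loci, reference_taxon = "KY-31")
  expect_equal(ncol(ref), nrow(loci))
  # encoding conservation: ones per column equal carrier counts relative
  # to the reference taxon
  truth <- sim$truth
  set.seed(1)
  for (r in sample(nrow(truth), 20)) {
    carriers <- truth$carriers[[r]]
    id <- loci$locus_id[loci$start == truth$start[r]][1]
    col <- ref[, startsWith(colnames(ref), paste0(id, ":")), drop = FALSE]
    expect_equal(ncol(col), 1)
    n_ones <- sum(col)
    expected <- if ("KY-31" %in% carriers) 12 - length(carriers)
                else length(carriers)
    expect_equal(n_ones, expected)
  }
  # band encoding: one presence column per allele, two per biallelic locus
  band <- encode_binary(loci, encoding = "band")
  expect_equal(ncol(band), 2 * nrow(loci))
  expect_true(all(rowSums(band) == nrow(loci)))

  # a triallelic SNP contributes two reference columns
  aln3 <- aligned_set(c(a = "AAT", b = "ACT", c = "AGT"),
                      c(a = "g1", b = "g2", c = "g3"))
  tri <- call_variants(aln3)
  expect_equal(ncol(encode_binary(tri, reference_taxon = "a")), 2)
  # monomorphic input: zero columns
  empty <- call_variants(aligned_set(c(a = "AAA", b = "AAA"),
                                     c(a = "g1", b = "g2")))
  expect_equal(ncol(encode_binary(empty, reference_taxon = "a")), 0)
})

test_that("Dice distances match hand arithmetic and vegan", {
  m <- rbind(r1 = c(1, 1, 1, 0, 0), r2 = c(1, 1, 0, 1, 0),
             r3 = c(0, 0, 0, 1, 1), r4 = c(1, 1, 1, 0, 0))
  d <- as.matrix(dice_distance(m))
  expect_equal(d["r1", "r4"], 0)              # identical rows
  expect_equal(d["r1", "r2"], 1 - 2 * 2 / (2 * 2 + 1 + 1))  # a=2,b=1,c=1
  expect_equal(d["r1", "r3"], 1)              # disjoint presences
  skip_if_not_installed("vegan")
  ref <- as.matrix(vegan::designdist(m, "(A+B-2*J)/(A+B)", terms = "binary"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)
  # rows with no presences at all are defined as identical
  z <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(as.matrix(dice_distance(z))["a", "b"], 0)
})

test_that("TN93 distances are exact on trivial cases and match ape", {
  aln <- aligned_set(c(a = "ACGTACGTAC", b = "ACGTACGTAC"),
                     c(a = "g1", b = "g2"))
  expect_equal(as.matrix(tamura_nei_distance(aln))[1, 2], 0)
  # pairs differing only at gap columns are identical after pairwise deletion
  aln_gap <- aligned_set(c(a = "ACGTAC-TAC", b = "ACGTACG-AC"),
                         c(a = "g1", b = "g2"))
  expect_equal(as.matrix(tamura_nei_distance(aln_gap))[1, 2], 0)
  # cross-check against ape on a diverged pair
  set.seed(5)
  x <- sample(c("A", "C", "G", "T"), 4000, TRUE,
              prob = c(0.35, 0.15, 0.3, 0.2))
  y <- x
  mut <- sample(4000, 260)
  for (i in mut) y[i] <- sample(setdiff(c("A", "C", "G", "T"), y[i]), 1)
  aln2 <- aligned_set(c(a = paste(x, collapse = ""),
                        b = paste(y, collapse = "")),
                      c(a = "g1", b = "g2"))
  mine <- as.matrix(tamura_nei_distance(aln2))[1, 2]
  bin <- ape::as.DNAbin(matrix(c(x, y), nrow = 2, byrow = TRUE,
                               dimnames = list(c("a", "b"), NULL)))
  expect_equal(mine, as.matrix(ape::dist.dna(bin, model = "TN93"))[1, 2],
               tolerance = 1e-10)
})

test_that("TN93 estimates recover a known simulated distance", {
  # explicit TN93 rate matrix; sites drawn iid, one lineage evolved for
  # the target expected number of substitutions
  pi <- c(A = 0.3, C = 0.2, G = 0.25, T = 0.25)
  a1 <- 4; a2 <- 3; b <- 1   # A<->G, C<->T transitions vs transversions
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (i in names(pi)) for (j in names(pi)) {
    if (i == j) next
    rate <- if (paste0(sort(c(i, j)), collapse = "") == "AG") a1
            else if (paste0(sort(c(i, j)), collapse = "") == "CT") a2
            else b
    Q[i, j] <- rate * pi[[j]]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  d_true <- 0.12
  P <- as.matrix(Matrix::expm(Q * d_true))
  set.seed(42)
  n_sites <- 100000
  x <- sample(names(pi), n_sites, TRUE, prob = pi)
  y <- vapply(x, function(s) sample(names(pi), 1, prob = P[s, ]),
              character(1))
  aln <- aligned_set(c(a = paste(x, collapse = ""),
                       b = paste(y, collapse = "")),
                     c(a = "g1", b = "g2"))
  est <- as.matrix(tamura_nei_distance(aln))[1, 2]
  expect_lt(abs(est - d_true) / d_true, 0.05)
})

test_that("TN93 reports saturation naming the offending pair", {
  aln <- aligned_set(c(s1 = "ACACACACAC", s2 = "CACACACACA"),
                     c(s1 = "g1", s2 = "g2"))
  expect_error(tamura_nei_distance(aln), "s1 vs s2")
})

test_that("UPGMA reproduces the hand-computed three-taxon tree", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(sort(tree_clades(tree)), sort(c("A,B", "A,B,C")))
  depth <- fescuephylo:::node_depths(tree)
  h <- max(depth) - depth
  n_tip <- ape::Ntip(tree)
  expect_equal(sort(h[(n_tip + 1):(n_tip + tree$Nnode)]), c(1, 3))
  # two taxa: a single cherry with half the distance on each branch
  d2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$edge.length), c(2.5, 2.5))
})

test_that("UPGMA is ultrametric and recovers planted ultrametric trees", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:9, 1)
    D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 2)
    D <- D + t(D)
    tree <- upgma(D)
    depth <- fescuephylo:::node_depths(tree)
    tip_depth <- depth[seq_len(ape::Ntip(tree))]
    expect_lt(diff(range(tip_depth)) / max(tip_depth), 1e-9)
  }
  for (seed in 1:6) {
    D <- random_ultrametric(n = 7, seed = seed)
    tree <- upgma(D)
    # recovered pairwise cophenetic distances equal the planted matrix
    coph <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
    expect_equal(coph, D, tolerance = 1e-9)
  }
})

test_that("UPGMA agrees with hclust average linkage on tie-free matrices", {
  skip_if_not_installed("phangorn")
  for (seed in 20:24) {
    set.seed(seed)
    n <- 8
    D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 3)
    D <- D + t(D)
    mine <- upgma(D)
    ref <- phangorn::upgma(as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(ref))), 0)
    expect_equal(sort(fescuephylo:::node_depths(mine)),
                 sort(fescuephylo:::node_depths(ref)), tolerance = 1e-9)
  }
})

test_that("bootstrap support is 100 for clean splits and order-invariant", {
  # perfectly clean split duplicated across columns
  m <- cbind(matrix(rep(c(1, 1, 1, 0, 0, 0), 10), 6),
             matrix(rep(c(1, 1, 0, 0, 0, 0), 6), 6))
  rownames(m) <- letters[1:6]
  tree <- bootstrap_support(m, "dice", n_replicates = 100, seed = 2)
  tt <- tidy(tree)
  expect_equal(tt$support[tt$tips == "a,b,c"], 100)
  expect_equal(tt$support[tt$n_tips == 6], 100)  # trivial split
  # permuting taxon input order does not change supports
  perm <- m[c(4, 2, 6, 1, 3, 5), ]
  tree_p <- bootstrap_support(perm, "dice", n_replicates = 100, seed = 2)
  tp <- tidy(tree_p)
  shared <- intersect(tt$tips, tp$tips)
  expect_equal(length(shared), length(tt$tips))
  expect_equal(tt$support[match(shared, tt$tips)],
               tp$support[match(shared, tp$tips)])
})
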