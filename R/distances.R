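#' Nei-Li/Dice distance on a binary marker matrix
#'
#' Pairwise similarity `2a / (2a + b + c)` where `a` counts markers present
#' in both rows and `b`, `c` count presences unique to each row; shared
#' absences are ignored by definition of the coefficient. The returned
#' distance is `1 - similarity`. A pair with no presences at all
#' (`a = b = c = 0`) is defined as similarity 1. `NA` cells are excluded
#' pairwise. Dice is non-metric: triangle-inequality violations are
#' possible and expected.
#'
#' @param x Binary matrix (taxa x markers), e.g. from [encode_binary()].
#' @returns A [stats::dist] object.
#' @examples
#' m <- rbind(s1 = c(1, 1, 0, 1), s2 = c(1, 0, 1, 1), s3 = c(0, 0, 1, 0))
#' dice_distance(m)
#' @export
dice_distance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      a <- sum(x[i, ok] == 1 & x[j, ok] == 1)
      b <- sum(x[i, ok] == 1 & x[j, ok] == 0)
      cc <- sum(x[i, ok] == 0 & x[j, ok] == 1)
      s <- if (a + b + cc == 0) 1 else 2 * a / (2 * a + b + cc)
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  as.dist(d)
}

#' Tamura-Nei (TN93) pairwise distance
#'
#' Estimates the TN93 distance for every pair of sequences, using only the
#' columns where both taxa carry unambiguous bases (pairwise deletion of
#' gap and `N` columns) and base frequencies estimated empirically from
#' each pair's shared columns. The model distinguishes the two transition
#' types (A<->G, C<->T) from transversions:
#' `d = -k1 log(1 - P1/k1 - Q/(2 gR)) - k2 log(1 - P2/k2 - Q/(2 gY))
#'     - k3 log(1 - Q/(2 gR gY))`
#' with `k1 = 2 gA gG / gR`, `k2 = 2 gC gT / gY`,
#' `k3 = 2 (gR gY - gA gG gY/gR - gC gT gR/gY)`, purine/pyrimidine sums
#' `gR`, `gY`, observed transition proportions `P1`, `P2` and transversion
#' proportion `Q`.
#'
#' @param aln An [aligned_set()] with at least two sequences.
#' @returns A [stats::dist] object.
#' @export
tamura_nei_distance <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  mat <- aln$mat
  n <- nrow(mat)
  if (n < 2L) abort("need at least two sequences")
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- tn93_pair(mat[i, ], mat[j, ],
                                      paste(aln$taxa[i], aln$taxa[j],
                                            sep = " vs "))
    }
  }
  as.dist(d)
}

tn93_pair <- function(x, y, label) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  m <- length(x)
  if (m == 0L) abort(sprintf("no shared ungapped columns for pair %s", label))
  if (all(x == y)) return(0)
  f <- table(factor(c(x, y), levels = c("A", "C", "G", "T"))) / (2 * m)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  if (gR == 0 || gY == 0) {
    abort(sprintf("degenerate base composition for pair %s", label))
  }
  diff <- x != y
  p1 <- sum(diff & ((x == "A" & y == "G") | (x == "G" & y == "A"))) / m
  p2 <- sum(diff & ((x == "C" & y == "T") | (x == "T" & y == "C"))) / m
  q <- sum(diff) / m - p1 - p2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- if (k1 > 0) 1 - p1 / k1 - q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - p2 / k2 - q / (2 * gY) else 1
  w3 <- 1 - q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    abort(sprintf("saturated distance (log argument <= 0) for pair %s", label))
  }
  unname(-(if (k1 > 0) k1 * log(w1) else 0) -
           (if (k2 > 0) k2 * log(w2) else 0) - k3 * log(w3))
}
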