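#' Simulate a star genealogy with Poisson mutation counts
#'
#' Oracle for rho-statistic recovery: each of `n_tips` lineages radiates
#' independently from a common ancestor and accumulates a
#' Poisson(`expected_mutations`) number of private derived characters (one
#' binary column per mutation). The ancestor is the all-ancestral
#' haplotype and is included as the last row, so the truth (every tip's
#' exact mutation count) is known.
#'
#' @param n_tips Number of descendant lineages (>= 2).
#' @param expected_mutations Poisson mean of private mutations per tip.
#' @param seed Integer seed.
#' @param mutations Optional integer vector of length `n_tips` forcing the
#'   exact per-tip mutation counts (overrides the Poisson draw).
#' @returns A list with `haplotypes` (binary matrix, tips plus an
#'   `"ancestor"` row), `ancestor` (its row name) and `counts` (the true
#'   per-tip mutation counts).
#' @examples
#' sim <- simulate_star_genealogy(5, 3, seed = 1)
#' rowSums(sim$haplotypes)
#' @export
simulate_star_genealogy <- function(n_tips, expected_mutations, seed = 1L,
                                    mutations = NULL) {
  if (n_tips < 2L) abort("n_tips must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  counts <- if (is.null(mutations)) {
    rpois(n_tips, expected_mutations)
  } else {
    stopifnot(length(mutations) == n_tips)
    as.integer(mutations)
  }
  total <- sum(counts)
  tips <- sprintf("tip%03d", seq_len(n_tips))
  mat <- matrix(0L, nrow = n_tips + 1L, ncol = max(total, 1L),
                dimnames = list(c(tips, "ancestor"),
                                sprintf("m%04d", seq_len(max(total, 1L)))))
  if (total == 0L) mat <- mat[, 0L, drop = FALSE]
  stop_at <- cumsum(counts)
  start_at <- stop_at - counts + 1L
  for (i in seq_len(n_tips)) {
    if (counts[i] > 0L) mat[i, start_at[i]:stop_at[i]] <- 1L
  }
  list(haplotypes = mat, ancestor = "ancestor",
       counts = setNames(counts, tips))
}
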