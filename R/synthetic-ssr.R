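#' Generate an SSR presence/absence genotype table with planted
#' discriminating primers
#'
#' Simulates the fragment table of an SSR survey: each primer amplifies a
#' number of fragments drawn from `fragments_per_primer`, each fragment is
#' present/absent per accession, and exactly `n_discriminating_primers`
#' primers carry at least two fragments that are fixed-present in one
#' target group and fixed-absent in the other. All remaining primers are
#' repaired so that they carry at most one such fragment, making the
#' scorer's strict count exact. Deterministic per seed.
#'
#' @param n_primers Number of SSR primers.
#' @param fragments_per_primer Integer range (length-2 vector) of fragments
#'   per primer.
#' @param n_discriminating_primers Number of primers planted with >= 2
#'   discriminating fragments between the two target groups.
#' @param groups Named character vector mapping accessions to groups.
#' @param target_groups Length-2 character vector: the pair of groups the
#'   planted fragments discriminate.
#' @param presence_prob Background presence probability per fragment call.
#' @param total_fragments Optional exact total fragment count across all
#'   primers (fragment counts are nudged within range to hit it).
#' @param seed Integer seed.
#' @returns A list with `table` (long tibble: `primer`, `accession`,
#'   `fragment_id`, `size_bp`, `present`) and `truth` (tibble of planted
#'   discriminating primers with their fragment ids).
#' @export
generate_ssr_table <- function(n_primers, fragments_per_primer = c(1L, 24L),
                               n_discriminating_primers, groups,
                               target_groups, presence_prob = 0.55,
                               total_fragments = NULL, seed = 1L) {
  if (n_discriminating_primers > n_primers) {
    abort("n_discriminating_primers cannot exceed n_primers")
  }
  stopifnot(length(target_groups) == 2L,
            all(target_groups %in% groups))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  accessions <- names(groups)
  taxa_a <- accessions[groups == target_groups[1L]]
  taxa_b <- accessions[groups == target_groups[2L]]
  lo <- fragments_per_primer[1L]; hi <- fragments_per_primer[2L]

  disc_idx <- sort(sample.int(n_primers, n_discriminating_primers))
  per_min <- rep(lo, n_primers)
  per_min[disc_idx] <- pmax(lo, 2L)  # planted primers need >= 2 fragments
  n_frag <- pmax(sample(lo:hi, n_primers, replace = TRUE), per_min)
  if (!is.null(total_fragments)) {
    if (total_fragments < sum(per_min) || total_fragments > n_primers * hi) {
      abort("total_fragments infeasible for the given range")
    }
    while (sum(n_frag) != total_fragments) {
      i <- sample.int(n_primers, 1L)
      step <- sign(total_fragments - sum(n_frag))
      cand <- n_frag[i] + step
      if (cand >= per_min[i] && cand <= hi) n_frag[i] <- cand
    }
  }

  primers <- sprintf("nffa%03d", seq_len(n_primers))
  rows <- vector("list", n_primers)
  truth_rows <- list()
  n_ab <- length(taxa_a) + length(taxa_b)
  for (i in seq_len(n_primers)) {
    k <- n_frag[i]
    sizes <- sort(sample(80:400, k))
    pres <- matrix(rbinom(k * length(accessions), 1L, presence_prob),
                   nrow = k, dimnames = list(NULL, accessions))
    is_disc_fragment <- function(p) {
      all(p[taxa_a] == 1) && all(p[taxa_b] == 0) ||
        all(p[taxa_a] == 0) && all(p[taxa_b] == 1)
    }
    if (i %in% disc_idx) {
      n_plant <- min(k, sample(2:4, 1L))
      plant <- sample.int(k, n_plant)
      for (f in plant) {
        dir_a <- runif(1) < 0.5
        pres[f, taxa_a] <- as.integer(dir_a)
        pres[f, taxa_b] <- as.integer(!dir_a)
      }
      # non-planted fragments of a planted primer may discriminate by
      # chance; harmless (the primer is already planted) but repair keeps
      # the truth's fragment list exact
      for (f in setdiff(seq_len(k), plant)) {
        if (is_disc_fragment(pres[f, ])) {
          flip <- sample(c(taxa_a, taxa_b), 1L)
          pres[f, flip] <- 1L - pres[f, flip]
        }
      }
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        primer = primers[i], fragment_ids = list(sort(plant)))
    } else {
      # repair: leave at most one accidentally discriminating fragment
      disc_f <- which(apply(pres, 1L, is_disc_fragment))
      if (length(disc_f) > 1L) {
        for (f in disc_f[-1L]) {
          flip <- sample(c(taxa_a, taxa_b), 1L)
          pres[f, flip] <- 1L - pres[f, flip]
        }
      }
    }
    rows[[i]] <- tibble(
      primer = primers[i],
      accession = rep(accessions, each = k),
      fragment_id = rep(seq_len(k), times = length(accessions)),
      size_bp = rep(sizes, times = length(accessions)),
      present = as.integer(pres[cbind(rep(seq_len(k), length(accessions)),
                                      rep(seq_along(accessions), each = k))])
    )
  }
  list(table = bind_rows(rows), truth = bind_rows(truth_rows))
}

#' Packaged SSR survey preset
#'
#' The SSR fixture emulating the study's survey: 144 primers over the 12
#' Festuca accessions, 1-24 fragments per primer with exactly 1,212
#' fragments in total, and 26 primers planted with at least two fragments
#' discriminating the Continental and Mediterranean morphotypes.
#'
#' @param seed Integer seed.
#' @returns As [generate_ssr_table()].
#' @export
festuca_ssr_table <- function(seed = 20180L) {
  prof <- festuca_profile()
  generate_ssr_table(
    n_primers = 144L, fragments_per_primer = c(1L, 24L),
    n_discriminating_primers = 26L, groups = prof$groups,
    target_groups = c("Continental", "Mediterranean"),
    total_fragments = 1212L, seed = seed)
}
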