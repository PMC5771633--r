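#' Tidy a haplotype network
#'
#' @param x A [median_joining()] network.
#' @param ... Unused.
#' @returns A tibble of edges with node annotations (`from`, `to`,
#'   `mutations`, `from_is_median`, `to_is_median`).
#' @method tidy haplotype_network
#' @export
tidy.haplotype_network <- function(x, ...) {
  med <- setNames(x$nodes$is_median, x$nodes$node)
  x$edges |>
    mutate(from_is_median = unname(med[.data$from]),
           to_is_median = unname(med[.data$to]))
}

#' @rdname tidy.haplotype_network
#' @method glance haplotype_network
#' @export
glance.haplotype_network <- function(x, ...) {
  tibble(n_observed = sum(!x$nodes$is_median),
         n_median = sum(x$nodes$is_median),
         n_edges = nrow(x$edges),
         total_mutations = sum(x$edges$mutations),
         epsilon = x$parameters$epsilon %||% NA_real_)
}

#' Tidy an age estimate
#'
#' @param x An [rho_age()] result.
#' @param ... Unused.
#' @returns One-row tibble with rho, its standard deviation, and the
#'   scaled ages.
#' @method tidy age_estimate
#' @export
tidy.age_estimate <- function(x, ...) {
  tibble(ancestral = x$ancestral, n_descendants = x$n,
         rho = x$rho, sd_rho = x$sd_rho,
         mutation_rate = x$mutation_rate,
         age_years = x$age_years, sd_years = x$sd_years,
         age_my = x$age_my, sd_my = x$sd_my)
}

#' @rdname tidy.age_estimate
#' @method glance age_estimate
#' @export
glance.age_estimate <- function(x, ...) tidy.age_estimate(x)

#' Tidy a supported UPGMA tree
#'
#' @param x An `upgma_tree`.
#' @param ... Unused.
#' @returns A tibble with one row per internal node: the clade's tips and
#'   bootstrap support (if annotated).
#' @method tidy upgma_tree
#' @export
tidy.upgma_tree <- function(x, ...) {
  clades <- clade_sets(x)
  tibble(
    node = seq_along(clades) + ape::Ntip(x),
    n_tips = lengths(clades),
    tips = map_chr(clades, paste, collapse = ","),
    support = if (!is.null(x$node.label)) {
      suppressWarnings(as.numeric(x$node.label))
    } else NA_real_
  )
}
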