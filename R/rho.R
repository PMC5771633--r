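#' Date a clade with the rho statistic
#'
#' Computes rho - the mean number of mutations separating a designated
#' ancestral network node from a set of descendant haplotypes, weighted by
#' taxon multiplicity - and scales it by a mutation rate (years per
#' mutation) into an age. Distances are shortest-path mutation counts over
#' the network; ties among equal-length shortest paths are broken toward
#' the path through the smallest node index, so the shortest-path tree is
#' deterministic. The standard deviation of rho is computed on that tree
#' as `sd_rho = (1/n) * sqrt(sum_e l_e * n_e^2)`, where `l_e` is an edge's
#' mutation count and `n_e` the number of descendant lineages traversing
#' it. For a star of `n` lineages each `d` mutations from the ancestor
#' this reduces to `rho = d`, `sd_rho = sqrt(d/n)`.
#'
#' @param net A [median_joining()] network.
#' @param ancestral Node id of the assumed ancestor (e.g. `"mv1"` or an
#'   observed node id).
#' @param descendants Character vector of taxon labels (sample names)
#'   forming the dated clade.
#' @param mutation_rate Years per mutation (the conventional chloroplast
#'   calibration used here is 20,180 years per mutation).
#' @returns An object of class `age_estimate`: rho, `sd_rho`, `age_years`,
#'   `sd_years`, `age_my`, `sd_my`, plus the inputs. `age_my` values print
#'   rounded to 2 decimals; stored values are unrounded.
#' @examples
#' sim <- simulate_star_genealogy(4, 2, seed = 1, mutations = rep(3, 4))
#' net <- median_joining(sim$haplotypes)
#' rho_age(net, "ancestor", names(sim$counts))
#' @export
rho_age <- function(net, ancestral, descendants,
                    mutation_rate = 20180) {
  stopifnot(inherits(net, "haplotype_network"))
  nodes <- net$nodes$node
  # an observed taxon name is also accepted as the ancestor spec
  if (!ancestral %in% nodes) {
    hit <- which(map_lgl(net$nodes$taxa, ~ ancestral %in% .x))
    if (length(hit) == 1L) ancestral <- nodes[hit]
    else abort(sprintf("ancestral node '%s' not in the network", ancestral))
  }
  if (length(descendants) == 0) abort("descendants must be non-empty")
  taxon_node <- unlist(map2(net$nodes$node, net$nodes$taxa,
                            function(nm, tx) setNames(rep(nm, length(tx)), tx)))
  missing <- setdiff(descendants, names(taxon_node))
  if (length(missing) > 0) {
    abort(sprintf("descendant taxa not in the network: %s",
                  paste(missing, collapse = ", ")))
  }
  n_nodes <- length(nodes)
  idx <- setNames(seq_len(n_nodes), nodes)
  ei <- idx[net$edges$from]; ej <- idx[net$edges$to]
  len <- net$edges$mutations

  # Dijkstra from the ancestor with smallest-index tie-breaks
  src <- idx[[ancestral]]
  dist <- rep(Inf, n_nodes); dist[src] <- 0
  pred <- rep(NA_integer_, n_nodes)
  done <- rep(FALSE, n_nodes)
  nbr <- vector("list", n_nodes)
  for (e in seq_along(ei)) {
    nbr[[ei[e]]] <- rbind(nbr[[ei[e]]], c(ej[e], len[e]))
    nbr[[ej[e]]] <- rbind(nbr[[ej[e]]], c(ei[e], len[e]))
  }
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0) break
    u <- open[which.min(dist[open])]  # which.min takes the first = smallest id
    done[u] <- TRUE
    for (r in seq_len(NROW(nbr[[u]]))) {
      v <- nbr[[u]][r, 1L]; l <- nbr[[u]][r, 2L]
      alt <- dist[u] + l
      if (alt < dist[v] - 1e-9 ||
          (abs(alt - dist[v]) <= 1e-9 && !is.na(pred[v]) && u < pred[v])) {
        dist[v] <- min(alt, dist[v]); pred[v] <- u
      }
    }
  }

  dnode <- idx[taxon_node[descendants]]
  if (any(!is.finite(dist[dnode]))) {
    abort("unreachable descendant: the network is not connected to the ancestor")
  }
  n <- length(descendants)
  rho <- sum(dist[dnode]) / n

  # lineage counts per shortest-path-tree edge
  n_e <- numeric(0)
  l_e <- numeric(0)
  for (v0 in dnode) {
    v <- v0
    while (v != src) {
      u <- pred[v]
      if (is.na(u)) break
      keyp <- paste(min(u, v), max(u, v))
      if (is.na(n_e[keyp])) {
        n_e[keyp] <- 0
        l_e[keyp] <- dist[v] - dist[u]
      }
      n_e[keyp] <- n_e[keyp] + 1
      v <- u
    }
  }
  sd_rho <- sqrt(sum(l_e * n_e^2)) / n

  # reticulation: some node on a descendant path admits more than one
  # equal-length shortest path back to the ancestor
  ties <- vapply(seq_len(n_nodes), function(v) {
    if (!is.finite(dist[v]) || v == src || NROW(nbr[[v]]) == 0) return(0L)
    sum(abs(dist[nbr[[v]][, 1L]] + nbr[[v]][, 2L] - dist[v]) <= 1e-9)
  }, integer(1))
  if (any(ties[dnode] > 1L) || any(ties[pred[dnode][!is.na(pred[dnode])]] > 1L)) {
    warn(paste("reticulation on a shortest path: equal-length alternatives",
               "exist; ties were broken toward smaller node indices"))
  }
  structure(
    list(ancestral = ancestral, descendants = descendants,
         n = n, rho = rho, sd_rho = sd_rho,
         mutation_rate = mutation_rate,
         age_years = rho * mutation_rate,
         sd_years = sd_rho * mutation_rate,
         age_my = rho * mutation_rate / 1e6,
         sd_my = sd_rho * mutation_rate / 1e6),
    class = "age_estimate"
  )
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(
    "<age_estimate> rho = %.2f (sd %.2f), rate %s yr/mutation\n  age = %.2f My +/- %.3f My (%d descendant lineage(s), ancestor %s)\n",
    x$rho, x$sd_rho, format(x$mutation_rate, big.mark = ","),
    round_half_up(x$age_my, 2), round_half_up(x$sd_my, 3),
    x$n, x$ancestral))
  invisible(x)
}
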