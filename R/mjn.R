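#' Median-joining haplotype network
#'
#' Constructs a median-joining network from a character matrix of
#' haplotypes (rows = samples). Binary 0/1 input is used as-is; DNA input
#' is binarised internally, one indicator column per non-reference
#' segregating state. Identical rows collapse into one observed node with
#' multiplicity. The construction iterates:
#'
#' 1. the epsilon-relaxed minimum spanning network (MSN) over the current
#'    nodes under weighted Hamming distance - an edge `(u, v)` is kept when
#'    its weighted distance is at most `epsilon` above the level at which
#'    `u` and `v` first become connected;
#' 2. for feasible triplets (three nodes mutually connected, or two nodes
#'    sharing an MSN neighbour), the per-character majority consensus
#'    (quasi-median) is added as a median vector when it strictly reduces
#'    the cost of connecting the triplet (the star through the median
#'    beats the triplet's own minimum spanning tree);
#' 3. obsolete median vectors (degree <= 2 and lying on no shortest
#'    observed-to-observed path) are removed;
#'
#' until stable. A final repair pass restores any direct MSN link between
#' observed haplotypes whose shortest network path exceeds their Hamming
#' distance, so the network displays every minimum spanning tree of the
#' input. Edge weights in the result are unweighted mutation counts;
#' character weights (and `epsilon`) act on the construction only, so
#' scaling all weights by a constant changes nothing.
#'
#' @param x Matrix of haplotype states: 0/1 integers, or single characters
#'   over `A`, `C`, `G`, `T`, `-`. Row names identify samples.
#' @param epsilon Non-negative relaxation of the MSN in weighted distance
#'   units; 0 reproduces the strict construction.
#' @param weight Per-character positive weight vector (recycled; the
#'   conventional default is a uniform weight of 10).
#' @returns An object of class `haplotype_network`: a list with `nodes` (a
#'   tibble: `node`, `is_median`, `multiplicity`, `taxa` list-column),
#'   `edges` (a tibble: `from`, `to`, `mutations`), `haplotypes` (binary
#'   node-by-character matrix) and `parameters`.
#' @examples
#' h <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
#' median_joining(h)  # one median vector (0,0,0) with three unit edges
#' @export
median_joining <- function(x, epsilon = 0, weight = 10) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) abort("need at least one haplotype")
  if (is.null(rownames(x))) rownames(x) <- paste0("h", seq_len(nrow(x)))
  bin <- binarize_haplotypes(x)
  keep <- colSums(bin) > 0L & colSums(bin) < nrow(bin)  # drop constants
  bin <- bin[, keep, drop = FALSE]
  w <- rep_len(as.numeric(weight), ncol(bin))
  if (any(w <= 0)) abort("character weights must be positive")

  # collapse identical rows into observed nodes
  sig <- apply(bin, 1L, paste, collapse = "")
  first <- !duplicated(sig)
  H <- bin[first, , drop = FALSE]
  node_names <- paste0("H", seq_len(nrow(H)))
  rownames(H) <- node_names
  taxa_of <- split(rownames(bin), factor(sig, levels = sig[first]))
  names(taxa_of) <- node_names
  observed <- rep(TRUE, nrow(H))
  n_mv <- 0L
  banned <- character()  # removed medians never return

  repeat {
    Dw <- weighted_hamming(H, w)
    msn <- msn_edges_from(Dw, epsilon)

    # obsolete medians first
    if (any(!observed)) {
      deg <- tabulate(c(msn$i, msn$j), nbins = nrow(H))
      sp <- sp_matrix(nrow(H), msn, Dw[cbind(msn$i, msn$j)])
      obs_idx <- which(observed)
      drop_m <- NA_integer_
      for (m in which(!observed)) {
        if (deg[m] > 2L) next
        via <- outer(sp[obs_idx, m], sp[m, obs_idx], "+")
        if (!any(abs(via - sp[obs_idx, obs_idx]) < 1e-9 &
                 is.finite(sp[obs_idx, obs_idx]))) {
          drop_m <- m; break
        }
      }
      if (!is.na(drop_m)) {
        banned <- c(banned, paste(H[drop_m, ], collapse = ""))
        H <- H[-drop_m, , drop = FALSE]
        observed <- observed[-drop_m]
        next
      }
    }

    # quasi-median candidates from feasible triplets
    adj <- matrix(FALSE, nrow(H), nrow(H))
    adj[cbind(msn$i, msn$j)] <- TRUE
    adj <- adj | t(adj)
    sigs <- apply(H, 1L, paste, collapse = "")
    new_rows <- list()
    for (z in seq_len(nrow(H))) {
      nb <- which(adj[z, ])
      if (length(nb) < 2L) next
      # median(u, v, z) differs from z only where u and v both differ
      # from z, so screen pairs by the inner product of difference masks
      Y <- abs(H[nb, , drop = FALSE] -
                 matrix(H[z, ], length(nb), ncol(H), byrow = TRUE))
      G <- Y %*% t(Y)
      hits <- which(G > 0 & upper.tri(G), arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        u <- nb[hits[r, 1L]]; v <- nb[hits[r, 2L]]
        med <- as.integer(H[u, ] + H[v, ] + H[z, ] >= 2L)
        msig <- paste(med, collapse = "")
        if (msig %in% sigs || msig %in% banned) next
        per <- Dw[u, v] + Dw[u, z] + Dw[v, z]
        if (per / 2 < per - max(Dw[u, v], Dw[u, z], Dw[v, z])) {
          new_rows[[msig]] <- med
          sigs <- c(sigs, msig)
        }
      }
    }
    if (length(new_rows) == 0) break
    add <- do.call(rbind, unname(new_rows))
    rownames(add) <- paste0("mv", seq.int(n_mv + 1L, n_mv + nrow(add)))
    n_mv <- n_mv + nrow(add)
    H <- rbind(H, add)
    observed <- c(observed, rep(FALSE, nrow(add)))
  }

  Dw <- weighted_hamming(H, w)
  msn <- msn_edges_from(Dw, epsilon)
  # repair pass: keep the MST display exact for observed pairs
  obs <- which(observed)
  if (length(obs) > 1L && any(!observed)) {
    sp <- sp_matrix(nrow(H), msn, Dw[cbind(msn$i, msn$j)])
    omsn <- msn_edges_from(Dw[obs, obs, drop = FALSE], epsilon)
    have <- paste(msn$i, msn$j)
    for (e in seq_along(omsn$i)) {
      a <- obs[omsn$i[e]]; b <- obs[omsn$j[e]]
      if (sp[a, b] > Dw[a, b] + 1e-9 &&
          !(paste(min(a, b), max(a, b)) %in% have)) {
        msn$i <- c(msn$i, min(a, b)); msn$j <- c(msn$j, max(a, b))
      }
    }
  }

  Du <- unweighted_hamming(H)
  nodes <- tibble(
    node = rownames(H),
    is_median = !observed,
    multiplicity = map_int(rownames(H), function(nm) {
      if (nm %in% names(taxa_of)) length(taxa_of[[nm]]) else 0L
    }),
    taxa = map(rownames(H), function(nm) {
      if (nm %in% names(taxa_of)) taxa_of[[nm]] else character()
    })
  )
  edges <- tibble(from = rownames(H)[msn$i], to = rownames(H)[msn$j],
                  mutations = Du[cbind(msn$i, msn$j)])
  structure(
    list(nodes = nodes, edges = edges, haplotypes = H,
         parameters = list(epsilon = epsilon, weight = weight)),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf(
    "<haplotype_network> %d observed haplotype(s), %d median vector(s), %d edge(s)\n",
    sum(!x$nodes$is_median), sum(x$nodes$is_median), nrow(x$edges)))
  invisible(x)
}

binarize_haplotypes <- function(x) {
  if (is.numeric(x)) {
    m <- matrix(as.integer(x), nrow(x), ncol(x), dimnames = dimnames(x))
    if (!all(m %in% c(0L, 1L))) abort("numeric haplotypes must be 0/1")
    return(m)
  }
  if (all(x %in% c("0", "1"))) {
    m <- matrix(as.integer(x), nrow(x), ncol(x), dimnames = dimnames(x))
    return(m)
  }
  cols <- list()
  for (j in seq_len(ncol(x))) {
    states <- unique(x[, j])
    if (length(states) < 2L) next
    for (s in states[-1L]) {
      cols[[paste0("c", j, ":", s)]] <- as.integer(x[, j] == s)
    }
  }
  if (length(cols) == 0) {
    return(matrix(integer(), nrow(x), 0L, dimnames = list(rownames(x), NULL)))
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(x)
  m
}

# pairwise weighted Hamming distances for a binary matrix, via the
# identity |x - y| = x + y - 2xy per character
weighted_hamming <- function(H, w) {
  n <- nrow(H)
  if (ncol(H) == 0) return(matrix(0, n, n))
  Hw <- H * rep(w, each = n)
  rs <- rowSums(Hw)
  d <- outer(rs, rs, "+") - 2 * tcrossprod(Hw, H)
  diag(d) <- 0
  pmax(d, 0)
}

unweighted_hamming <- function(H) {
  d <- weighted_hamming(H, rep(1, ncol(H)))
  round(d)
}

# epsilon-relaxed minimum spanning network from a distance matrix:
# edge (u,v) kept iff d(u,v) <= connection_level(u,v) + epsilon, where the
# connection level is the smallest level at which u and v join one
# component when all edges are added level by level.
msn_edges_from <- function(D, epsilon) {
  n <- nrow(D)
  if (n < 2L) return(list(i = integer(), j = integer()))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[pairs]
  levels <- sort(unique(dv))
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  conn <- matrix(Inf, n, n)
  for (lv in levels) {
    for (e in which(dv == lv)) {
      i <- find(pairs[e, 1L]); j <- find(pairs[e, 2L])
      if (i != j) parent[i] <- j
    }
    roots <- vapply(seq_len(n), find, integer(1))
    same <- outer(roots, roots, "==")
    conn[same & !is.finite(conn)] <- lv
  }
  keep <- which(dv <= conn[pairs] + epsilon + 1e-9)
  list(i = pairs[keep, 1L], j = pairs[keep, 2L])
}

# all-pairs shortest path lengths over the network (Floyd-Warshall; node
# sets stay small once identical haplotypes are collapsed)
sp_matrix <- function(n, msn, len) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (e in seq_along(msn$i)) {
    d[msn$i[e], msn$j[e]] <- d[msn$j[e], msn$i[e]] <-
      min(d[msn$i[e], msn$j[e]], len[e])
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}
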