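#' UPGMA clustering with deterministic tie-breaking
#'
#' Average-linkage agglomerative clustering: the closest pair of clusters
#' is merged at a node of height half their distance, and distances to the
#' merged cluster are size-weighted arithmetic means. Ties on the minimum
#' distance are broken by the lexicographically smallest merged member
#' label set, so the topology is identical across platforms. The result is
#' a rooted ultrametric tree.
#'
#' @param d A [stats::dist] object or symmetric distance matrix with
#'   labels.
#' @returns An [ape::phylo] tree with branch lengths (class
#'   `c("upgma_tree", "phylo")`).
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  labels <- rownames(m)
  if (is.null(labels)) abort("distance matrix must carry labels")
  n <- length(labels)
  if (n < 2L) abort("need at least two taxa")
  stopifnot(isTRUE(all.equal(m, t(m))), all(diag(m) == 0))

  members <- as.list(labels)           # taxon labels per active cluster
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  newick <- labels                     # subtree string per active cluster
  active <- rep(TRUE, n)
  key <- labels                        # sorted-member key for tie-breaks
  D <- m

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- D[i, j]
        pair_key <- paste(sort(c(key[i], key[j])), collapse = "\r")
        if (dij < best_d - 1e-12 ||
            (abs(dij - best_d) <= 1e-12 && !is.null(best_key) &&
             pair_key < best_key)) {
          best <- c(i, j); best_d <- dij; best_key <- pair_key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    h <- best_d / 2
    bl_i <- h - heights[i]; bl_j <- h - heights[j]
    new_members <- c(members[[i]], members[[j]])
    # order children deterministically by key
    ch <- if (key[i] <= key[j]) c(i, j) else c(j, i)
    bl <- c(bl_i, bl_j)[match(ch, c(i, j))]
    sub <- sprintf("(%s:%.10g,%s:%.10g)", newick[ch[1L]], bl[1L],
                   newick[ch[2L]], bl[2L])
    # merged cluster replaces i
    for (k in which(active)) {
      if (k != i && k != j) {
        D[i, k] <- D[k, i] <-
          (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
      }
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    newick[i] <- sub
    key[i] <- paste(sort(new_members), collapse = "\r")
    active[j] <- FALSE
  }
  root <- which(active)
  tree <- ape::read.tree(text = paste0(newick[root], ";"))
  class(tree) <- c("upgma_tree", "phylo")
  tree
}

#' Node heights of a rooted tree
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @returns Numeric vector of root-to-node path lengths, indexed by node
#'   number.
#' @keywords internal
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  root <- ape::Ntip(tree) + 1L
  # edges in preorder
  ord <- reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    depth[ord$edge[e, 2L]] <- depth[ord$edge[e, 1L]] + ord$edge.length[e]
  }
  depth
}

#' Tip sets of every internal node
#' @keywords internal
clade_sets <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  lapply(seq_len(tree$Nnode) + n_tip, function(node) {
    sort(tips[unlist(phangorn_free_descendants(tree, node))])
  })
}

# tip indices below a node (small trees; plain recursion)
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, phangorn_free_descendants, tree = tree))
}

#' Bootstrap support for a UPGMA tree
#'
#' Builds the tree from the full data, then resamples columns with
#' replacement `n_replicates` times, rebuilds a tree per replicate, and
#' annotates each internal node of the original tree with the percentage
#' of replicate trees containing the same tip-set bipartition (the clade or
#' its complement). Deterministic per seed.
#'
#' @param x A binary marker matrix (`builder = "dice"`) or an
#'   [aligned_set()] (`builder = "tn93"`).
#' @param builder Distance used for tree building.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @returns The original `upgma_tree` with `node.label` set to integer
#'   support percentages (0-100).
#' @export
bootstrap_support <- function(x, builder = c("dice", "tn93"),
                              n_replicates = 1000L, seed = 1L) {
  builder <- match.arg(builder)
  if (n_replicates < 1L) abort("n_replicates must be >= 1")
  build <- function(dat) {
    d <- if (builder == "dice") dice_distance(dat) else tamura_nei_distance(dat)
    upgma(d)
  }
  resample <- function(dat, idx) {
    if (builder == "dice") dat[, idx, drop = FALSE] else
      aligned_set(dat$mat[, idx, drop = FALSE], dat$groups)
  }
  n_col <- if (builder == "dice") ncol(x) else x$length
  tree <- build(x)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ref_clades <- clade_sets(tree)
  all_tips <- sort(tree$tip.label)
  as_bipart <- function(clade) {
    other <- setdiff(all_tips, clade)
    min(paste(clade, collapse = "\r"), paste(other, collapse = "\r"))
  }
  ref_keys <- vapply(ref_clades, as_bipart, character(1))
  hits <- numeric(length(ref_keys))
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n_col, n_col, replace = TRUE)
    rep_tree <- build(resample(x, idx))
    rep_keys <- vapply(clade_sets(rep_tree), as_bipart, character(1))
    hits <- hits + (ref_keys %in% rep_keys)
  }
  tree$node.label <- as.character(round(100 * hits / n_replicates))
  tree
}
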