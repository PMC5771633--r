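# Independent oracles and fixture builders used across the suite.
# Deliberately written as straight-line brute force, separate from the
# package's own algorithms.

# random gapped alignment (taxon-level variation, not group-structured)
random_alignment <- function(n_taxa = 6, n_cols = 200, seed = 1,
                             p_gap = 0.05, p_n = 0.01) {
  set.seed(seed)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  mat <- matrix("", n_taxa, n_cols, dimnames = list(taxa, NULL))
  for (j in seq_len(n_cols)) {
    repeat {
      base <- sample(c("A", "C", "G", "T"), 1)
      col <- vapply(seq_len(n_taxa), function(i) {
        r <- runif(1)
        if (r < p_gap) "-"
        else if (r < p_gap + p_n) "N"
        else if (r < p_gap + p_n + 0.1) sample(c("A", "C", "G", "T"), 1)
        else base
      }, character(1))
      if (!all(col == "-")) break
    }
    mat[, j] <- col
  }
  groups <- setNames(rep(c("g1", "g2"), length.out = n_taxa), taxa)
  aligned_set(mat, groups)
}

# brute-force variant scanner: per-column classification then a single
# left-to-right pass merging adjacent identical gap patterns
brute_force_scan <- function(aln) {
  mat <- aln$mat
  n <- nrow(mat)
  L <- ncol(mat)
  out <- list()
  # gap runs
  j <- 1
  while (j <= L) {
    gp <- mat[, j] == "-"
    if (any(gp) && !all(gp)) {
      k <- j
      while (k < L && identical(mat[, k + 1] == "-", gp)) k <- k + 1
      out[[length(out) + 1]] <- list(
        start = j - 1L, end = k,
        class = if (k == j) "del1" else "indel_multi")
      j <- k + 1
    } else {
      j <- j + 1
    }
  }
  # snp columns
  for (j in seq_len(L)) {
    col <- mat[, j]
    b <- col[!(col %in% c("-", "N"))]
    if (length(unique(b)) >= 2) {
      out[[length(out) + 1]] <- list(start = j - 1L, end = j, class = "snp")
    }
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  if (is.null(df)) {
    return(data.frame(start = integer(), end = integer(),
                      class = character()))
  }
  df[order(df$start, df$class), , drop = FALSE]
}

# exhaustive SSR discrimination scan (independent of the dplyr pipeline)
brute_force_ssr <- function(tab, groups, ga, gb, min_fragments = 2,
                            tolerance = 0) {
  acc_a <- names(groups)[groups == ga]
  acc_b <- names(groups)[groups == gb]
  primers <- unique(tab$primer)
  hits <- character()
  for (p in primers) {
    sub <- tab[tab$primer == p, ]
    n_disc <- 0
    for (f in unique(sub$fragment_id)) {
      pa <- sub$present[sub$accession %in% acc_a & sub$fragment_id == f]
      pb <- sub$present[sub$accession %in% acc_b & sub$fragment_id == f]
      v1 <- sum(pa == 0) + sum(pb == 1)
      v2 <- sum(pa == 1) + sum(pb == 0)
      if (min(v1, v2) <= tolerance) n_disc <- n_disc + 1
    }
    if (n_disc >= min_fragments) hits <- c(hits, p)
  }
  hits
}

# all minimum spanning trees of a complete weighted graph by Prufer
# enumeration (n <= 7)
all_msts <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 2, n <= 7)
  if (n == 2) return(list(cbind(1L, 2L)))
  decode_prufer <- function(seq) {
    n_nodes <- length(seq) + 2L
    degree <- rep(1L, n_nodes)
    for (s in seq) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n_nodes - 1L, 2L)
    ptr <- 1L
    for (s in seq) {
      leaf <- which(degree == 1L)[1L]
      edges[ptr, ] <- c(leaf, s); ptr <- ptr + 1L
      degree[leaf] <- 0L
      degree[s] <- degree[s] - 1L
    }
    left <- which(degree == 1L)
    edges[ptr, ] <- left
    edges
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  keep <- list()
  for (r in seq_len(nrow(grid))) {
    ed <- decode_prufer(grid[r, ])
    w <- sum(D[ed])
    if (w < best - 1e-9) {
      best <- w
      keep <- list(ed)
    } else if (abs(w - best) <= 1e-9) {
      keep[[length(keep) + 1]] <- ed
    }
  }
  keep
}

# shortest-path matrix over a haplotype_network's mutation-count edges
network_sp <- function(net) {
  nodes <- net$nodes$node
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$from[e]; j <- net$edges$to[e]
    d[i, j] <- d[j, i] <- min(d[i, j], net$edges$mutations[e])
  }
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# a random ultrametric distance matrix built from explicit merge heights
random_ultrametric <- function(n = 6, seed = 1) {
  set.seed(seed)
  labels <- sprintf("u%02d", seq_len(n))
  clusters <- as.list(labels)
  height <- 0
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    height <- height + runif(1, 0.5, 2)
    pick <- sample(length(clusters), 2)
    for (x in clusters[[pick[1]]]) for (y in clusters[[pick[2]]]) {
      D[x, y] <- D[y, x] <- 2 * height
    }
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  D
}

# clade tip-sets of a rooted phylo, as sorted label strings
tree_clades <- function(tree) {
  n_tip <- ape::Ntip(tree)
  sapply((n_tip + 1):(n_tip + tree$Nnode), function(node) {
    paste(sort(ape::extract.clade(tree, node)$tip.label), collapse = ",")
  })
}
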