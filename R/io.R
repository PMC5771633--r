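#' Newick input/output
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that
#' preserve branch lengths and integer node-support labels.
#'
#' @param tree A `phylo` (or `upgma_tree`) object.
#' @param path Output/input file path.
#' @returns `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Convert a haplotype network to an igraph graph
#'
#' Nodes carry `name`, `is_median` and `multiplicity` attributes; edges
#' carry `mutations`.
#'
#' @param net A [median_joining()] network.
#' @returns An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$node,
                          is_median = as.integer(net$nodes$is_median),
                          multiplicity = net$nodes$multiplicity)
  )
}

#' GML and edge-list export of a haplotype network
#'
#' `write_network_gml()` writes the network as GML with `is_median` and
#' `multiplicity` node attributes and `mutations` edge weights;
#' `read_network_gml()` reads it back as a `haplotype_network` skeleton
#' (nodes and edges; haplotype state vectors are not stored in GML).
#' `write_network_edges()` writes a plain edge-list TSV.
#'
#' @param net A [median_joining()] network.
#' @param path File path.
#' @returns The path, invisibly (writers); a `haplotype_network` (reader).
#' @export
write_network_gml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "gml")
  # normalise the creator banner so identical networks give identical files
  lines <- readLines(path)
  if (length(lines) > 0 && startsWith(lines[1], "Creator")) {
    lines[1] <- "Creator \"fescuephylo\""
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_network_gml
#' @export
read_network_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  vs <- igraph::vertex_attr(g)
  nm <- vs$name %||% as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  nodes <- tibble(node = nm,
                  is_median = as.logical(vs$ismedian %||% vs$is_median),
                  multiplicity = as.integer(vs$multiplicity),
                  taxa = rep(list(character()), length(nm)))
  edges <- tibble(from = nm[el[, 1L]], to = nm[el[, 2L]],
                  mutations = as.numeric(igraph::edge_attr(g, "mutations")))
  structure(list(nodes = nodes, edges = edges, haplotypes = NULL,
                 parameters = list()),
            class = "haplotype_network")
}

#' @rdname write_network_gml
#' @export
write_network_edges <- function(net, path) {
  med <- setNames(net$nodes$is_median, net$nodes$node)
  readr::write_tsv(
    net$edges |>
      mutate(from_is_median = med[.data$from],
             to_is_median = med[.data$to]),
    path)
  invisible(path)
}

#' Write a variant table as TSV
#'
#' Flattens the list-columns of a [call_variants()] table: one allele
#' column per taxon.
#'
#' @param loci Variant table.
#' @param path File path.
#' @returns `path`, invisibly.
#' @export
write_variant_tsv <- function(loci, path) {
  if (nrow(loci) == 0) {
    readr::write_tsv(tibble(locus_id = character(), start = integer(),
                            end = integer(), class = character()), path)
    return(invisible(path))
  }
  taxa <- names(loci$alleles[[1L]])
  flat <- loci |>
    select("locus_id", "start", "end", "class", "length") |>
    dplyr::bind_cols(
      purrr::map_dfr(loci$alleles, ~ as_tibble(as.list(.x[taxa])))
    )
  readr::write_tsv(flat, path)
  invisible(path)
}
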