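#' Construct a group-annotated multiple alignment
#'
#' An `aligned_set` holds equal-length gapped sequences for a set of taxa
#' together with a taxon-to-group map (e.g. morphotype or species labels).
#' It is the input container for variant calling, Tamura-Nei distances and
#' the pipeline.
#'
#' @param sequences Named character vector of equal-length strings over
#'   `A`, `C`, `G`, `T`, `-`, `N` (case-insensitive), or a character matrix
#'   with one row per taxon and one single-character column per alignment
#'   column.
#' @param groups Named character vector mapping every taxon to a group
#'   label.
#'
#' @returns An object of class `aligned_set`: a list with elements `mat`
#'   (character matrix, taxa x columns), `taxa`, `groups` and `length`.
#' @examples
#' aln <- aligned_set(
#'   c(s1 = "ACGT-A", s2 = "ACGTTA", s3 = "ACCTTA"),
#'   groups = c(s1 = "g1", s2 = "g1", s3 = "g2")
#' )
#' aln
#' @export
aligned_set <- function(sequences, groups) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
      abort("`sequences` must carry unique taxon names.")
    }
    widths <- nchar(sequences)
    if (length(unique(widths)) != 1L) {
      bad <- names(sequences)[widths != widths[1L]][1L]
      abort(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                    bad, nchar(sequences[[bad]]), widths[1L]))
    }
    mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
    rownames(mat) <- names(sequences)
  }
  mat[] <- toupper(mat)
  ok <- mat %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    abort(sprintf("unknown alignment symbol(s): %s",
                  paste(bad, collapse = ", ")))
  }
  taxa <- rownames(mat)
  if (is.null(taxa)) abort("`sequences` must carry taxon names.")
  missing_group <- setdiff(taxa, names(groups))
  if (length(missing_group) > 0) {
    abort(sprintf("no group label for taxa: %s",
                  paste(missing_group, collapse = ", ")))
  }
  all_gap <- colSums(mat == "-") == nrow(mat)
  if (any(all_gap)) {
    abort(sprintf("column(s) gapped in all taxa: %s",
                  paste(head(which(all_gap), 5L), collapse = ", ")))
  }
  structure(
    list(mat = mat, taxa = taxa,
         groups = as.character(groups[taxa]) |> setNames(taxa),
         length = ncol(mat)),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d taxa x %d columns\n",
              length(x$taxa), x$length))
  grp <- split(x$taxa, x$groups)
  for (g in names(grp)) {
    cat(sprintf("  %s: %s\n", g, paste(grp[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.character.aligned_set <- function(x, ...) {
  apply(x$mat, 1L, paste, collapse = "")
}

#' Read and write gapped alignment FASTA
#'
#' `read_alignment_fasta()` reads an aligned FASTA plus a two-column
#' taxon/group map into an [aligned_set()]; `write_alignment_fasta()` is its
#' inverse. The group map is a TSV with columns `taxon` and `group`.
#'
#' @param path FASTA file path.
#' @param groups Either a named character vector (taxon -> group) or the
#'   path to a group-map TSV.
#' @param aln An `aligned_set`.
#' @returns `read_alignment_fasta()` returns an `aligned_set`;
#'   `write_alignment_fasta()` returns `path` invisibly.
#' @export
read_alignment_fasta <- function(path, groups) {
  seqs <- Biostrings::readBStringSet(path)
  if (is.character(groups) && is.null(names(groups)) && length(groups) == 1L) {
    groups <- read_group_map(groups)
  }
  aligned_set(setNames(as.character(seqs), names(seqs)), groups)
}

#' @rdname read_alignment_fasta
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- Biostrings::BStringSet(as.character.aligned_set(aln))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname read_alignment_fasta
#' @export
read_group_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("taxon", "group") %in% names(tab))) {
    abort("group map must have columns 'taxon' and 'group'")
  }
  setNames(tab$group, tab$taxon)
}

#' @rdname read_alignment_fasta
#' @export
write_group_map <- function(aln, path) {
  readr::write_tsv(tibble(taxon = aln$taxa, group = unname(aln$groups)), path)
  invisible(path)
}
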