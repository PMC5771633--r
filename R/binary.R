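#' Encode a variant table as a binary marker matrix
#'
#' Two encodings are supported:
#' * `"reference"`: each biallelic locus becomes one column scoring 1 for
#'   the non-reference state; a multiallelic SNP contributes one column per
#'   non-reference allele; an indel locus contributes one column (1 = state
#'   differing from the reference taxon's gap pattern). Hamming distances
#'   between rows equal per-locus difference counts, independent of the
#'   reference choice, which suits haplotype-network construction.
#' * `"band"`: each distinct allele of each locus becomes one
#'   presence/absence column, the natural coding of alleles as
#'   electrophoretic bands for Nei-Li/Dice similarity. Every taxon carries
#'   exactly one band per locus, so for group-monomorphic data the Dice
#'   similarity between two taxa equals the fraction of loci at which they
#'   share an allele.
#'
#' States containing `N` are scored `NA`. Constant columns (possible with
#' missing data) are dropped.
#'
#' @param loci Variant table from [call_variants()].
#' @param reference_taxon Taxon defining the reference state
#'   (`"reference"` encoding only).
#' @param encoding `"reference"` or `"band"`.
#' @returns Integer matrix (taxa x markers) with column names
#'   `<locus_id>:<state>`.
#' @export
encode_binary <- function(loci, reference_taxon = NULL,
                          encoding = c("reference", "band")) {
  encoding <- match.arg(encoding)
  if (nrow(loci) == 0) {
    return(matrix(integer(), nrow = 0L, ncol = 0L))
  }
  taxa <- names(loci$alleles[[1L]])
  cols <- list()
  for (i in seq_len(nrow(loci))) {
    al <- loci$alleles[[i]][taxa]
    has_n <- grepl("N", al, fixed = TRUE)
    states <- unique(al[!has_n])
    if (encoding == "reference") {
      if (is.null(reference_taxon)) abort("reference_taxon is required")
      if (!reference_taxon %in% taxa) {
        abort(sprintf("reference taxon '%s' not present", reference_taxon))
      }
      ref_state <- al[[reference_taxon]]
      for (s in setdiff(states, ref_state)) {
        v <- as.integer(al == s)
        v[has_n] <- NA_integer_
        cols[[paste0(loci$locus_id[i], ":", s)]] <- v
      }
    } else {
      for (s in states) {
        v <- as.integer(al == s)
        v[has_n] <- NA_integer_
        cols[[paste0(loci$locus_id[i], ":", s)]] <- v
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  keep <- apply(m, 2L, function(v) length(unique(v[!is.na(v)])) > 1L)
  m[, keep, drop = FALSE]
}
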