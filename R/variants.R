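#' Call and classify polymorphic loci from a gapped alignment
#'
#' Scans every column of the alignment and returns one record per
#' polymorphic locus:
#' * `snp` - a single column with two or more distinct bases among the
#'   non-gap, non-`N` taxa;
#' * `del1` - a single column gapped in some but not all taxa;
#' * `indel_multi` - a maximal run of two or more adjacent columns sharing
#'   one identical gap presence/absence pattern, merged into one locus.
#'
#' A column can host both a base substitution and a gap pattern; it then
#' yields a `snp` record (computed over the non-gap taxa) *and* belongs to
#' the enclosing gap locus, and both records are flagged in the `overlaps`
#' column. Spans are 0-based half-open; loci are sorted by span start.
#'
#' @param aln An [aligned_set()].
#' @returns A tibble with columns `locus_id`, `start`, `end`, `class`,
#'   `length`, `alleles` (list-column of named per-taxon state strings;
#'   gaps are `-`), `states` (list-column mapping each observed state to
#'   the groups carrying it) and `overlaps` (logical: locus shares columns
#'   with a locus of the other kind).
#' @examples
#' aln <- aligned_set(
#'   c(a = "ACGT--T", b = "ACATAAT", c = "ACATAAT"),
#'   c(a = "g1", b = "g2", c = "g2")
#' )
#' call_variants(aln)
#' @export
call_variants <- function(aln) {
  stopifnot(inherits(aln, "aligned_set"))
  mat <- aln$mat
  n <- nrow(mat)
  L <- ncol(mat)
  gap <- mat == "-"
  gap_count <- colSums(gap)
  poly_gap <- gap_count > 0L & gap_count < n

  # indel loci: maximal runs of identical gap patterns
  pattern_id <- integer(L)
  if (any(poly_gap)) {
    pats <- apply(gap[, poly_gap, drop = FALSE], 2L, paste, collapse = "")
    pattern_id[poly_gap] <- as.integer(factor(pats, levels = unique(pats)))
  }
  r <- rle(pattern_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  indel_rows <- which(r$values != 0L)

  rows <- list()
  for (i in indel_rows) {
    s <- starts[i]; e <- ends[i]
    width <- e - s + 1L
    allele <- apply(mat[, s:e, drop = FALSE], 1L, paste, collapse = "")
    rows[[length(rows) + 1L]] <- tibble(
      start = s - 1L, end = e, class = if (width == 1L) "del1" else "indel_multi",
      length = width, alleles = list(setNames(allele, aln$taxa))
    )
  }

  # snp loci: per-column base polymorphism among non-gap, non-N taxa
  for (j in seq_len(L)) {
    col <- mat[, j]
    bases <- col[col != "-" & col != "N"]
    if (length(unique(bases)) >= 2L) {
      rows[[length(rows) + 1L]] <- tibble(
        start = j - 1L, end = j, class = "snp", length = 1L,
        alleles = list(setNames(col, aln$taxa))
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(locus_id = character(), start = integer(), end = integer(),
                  class = character(), length = integer(), alleles = list(),
                  states = list(), overlaps = logical()))
  }
  loci <- bind_rows(rows) |> arrange(.data$start, .data$class)

  # overlap flags: snp columns inside indel spans
  loci$overlaps <- FALSE
  is_snp <- loci$class == "snp"
  if (any(is_snp) && any(!is_snp)) {
    for (i in which(is_snp)) {
      hit <- !is_snp & loci$start < loci$end[i] & loci$end > loci$start[i]
      if (any(hit)) {
        loci$overlaps[i] <- TRUE
        loci$overlaps[hit] <- TRUE
      }
    }
  }
  loci |>
    mutate(
      states = map(.data$alleles, function(al) {
        al <- al[al != "N" & !grepl("N", al, fixed = TRUE)]
        split(unname(aln$groups[names(al)]), al) |> map(unique)
      }),
      locus_id = sprintf("L%03d", dplyr::row_number())
    ) |>
    select("locus_id", "start", "end", "class", "length", "alleles",
           "states", "overlaps")
}

#' Count fixed differences between two groups
#'
#' A locus counts as polymorphic between two groups when the allele sets of
#' the groups' taxa are disjoint (a fixed difference). Loci at which the
#' groups share any allele do not count; `N` states are excluded from the
#' allele sets, so missing data never creates a difference.
#'
#' @param loci Variant table from [call_variants()].
#' @param groups Named character vector mapping taxa to group labels.
#' @param group_a,group_b Group labels to compare.
#' @returns Integer count of fixed differences.
#' @export
count_between_group <- function(loci, groups, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) abort(sprintf("unknown group label '%s'", g))
  }
  if (nrow(loci) == 0) return(0L)
  taxa_a <- names(groups)[groups == group_a]
  taxa_b <- names(groups)[groups == group_b]
  drop_n <- function(x) {
    x <- x[!is.na(x)]
    x[x != "N" & !grepl("N", x, fixed = TRUE)]
  }
  sum(map_lgl(loci$alleles, function(al) {
    a <- unique(drop_n(al[intersect(names(al), taxa_a)]))
    b <- unique(drop_n(al[intersect(names(al), taxa_b)]))
    length(a) > 0 && length(b) > 0 && length(intersect(a, b)) == 0
  }))
}

#' Between-group similarity index
#'
#' The similarity index between two groups is one minus the fraction of all
#' polymorphic loci that are fixed differences between them:
#' `1 - n_between / n_total`. Values are reported rounded half-up to two
#' decimals (use `digits = NULL` for full precision).
#'
#' @param n_between Number of polymorphic loci between the two groups.
#' @param n_total Total number of polymorphic loci among all groups.
#' @param digits Decimal places for half-up rounding, or `NULL` to skip.
#' @returns Numeric similarity in `[0, 1]`.
#' @examples
#' similarity_index(117, 167)  # 0.30
#' similarity_index(2, 167)    # 0.99
#' @export
similarity_index <- function(n_between, n_total, digits = 2) {
  if (any(n_total <= 0)) abort("similarity index undefined: n_total must be > 0")
  if (any(n_between < 0) || any(n_between > n_total)) {
    abort("need 0 <= n_between <= n_total")
  }
  s <- 1 - n_between / n_total
  if (is.null(digits)) s else round_half_up(s, digits)
}

#' Round half away from zero
#'
#' Fixed-precision reporting rule used for similarity indices and ages;
#' unlike [round()], halves always round up in magnitude.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @returns Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Pairwise polymorphism and similarity table
#'
#' Builds the group-comparison table: for each pair of groups, the number
#' of fixed differences and the similarity index against the total locus
#' count. The denominator `n_total` is the same for every row.
#'
#' @inheritParams count_between_group
#' @param pairs Optional two-column data frame (or list of length-2
#'   character vectors) of group pairs; defaults to all unordered pairs.
#' @returns A tibble with columns `group_a`, `group_b`, `n_polymorphic`,
#'   `n_total`, `similarity` (full precision) and `similarity_2dp`.
#' @export
comparison_table <- function(loci, groups, pairs = NULL) {
  all_groups <- unique(unname(groups))
  if (is.null(pairs)) {
    pairs <- t(combn(all_groups, 2L))
  } else if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  } else {
    pairs <- as.matrix(as.data.frame(pairs))
  }
  n_total <- nrow(loci)
  purrr::map2(pairs[, 1L], pairs[, 2L], function(a, b) {
    nb <- count_between_group(loci, groups, a, b)
    tibble(group_a = a, group_b = b, n_polymorphic = nb, n_total = n_total,
           similarity = similarity_index(nb, n_total, digits = NULL),
           similarity_2dp = similarity_index(nb, n_total))
  }) |> bind_rows()
}
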