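#' Primer pair
#'
#' @param name Primer label.
#' @param forward,reverse Primer sequences over `A`, `C`, `G`, `T`. The
#'   reverse primer is given 5'->3' on the opposite strand, as synthesised.
#' @param expected_size Expected product size in bp (informational).
#' @returns An object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_size = NA_integer_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) == 0 || nchar(reverse) == 0) {
    abort("both primers must be non-empty")
  }
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    abort("primers must be plain A/C/G/T sequences")
  }
  if (!is.na(expected_size) &&
      expected_size <= max(nchar(forward), nchar(reverse))) {
    abort("expected_size must exceed the primer lengths")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_size = as.integer(expected_size)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s: %s / %s (expected %s bp)\n",
              x$name, x$forward, x$reverse,
              ifelse(is.na(x$expected_size), "?", x$expected_size)))
  invisible(x)
}

#' Reverse complement of a plain A/C/G/T sequence
#'
#' @param x Character vector of sequences.
#' @returns Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGT", "TGCA", sapply(strsplit(toupper(x), "", fixed = TRUE),
                                function(s) paste(rev(s), collapse = "")))
}

#' Predict PCR products by exact primer matching
#'
#' Locates the forward primer on the given strand and the reverse primer as
#' its reverse complement downstream, both by exact match. The product
#' spans the first base of the forward site through the last base of the
#' reverse site inclusive. The product is absent (`NA` length) when either
#' site is missing; a primer matching more than once raises an
#' ambiguous-amplification error.
#'
#' @param templates Named character vector of gap-free template sequences
#'   (a single unnamed template is also accepted).
#' @param primer A [primer_pair()].
#' @returns A tibble with one row per template: `primer`, `template`,
#'   `product_length` (bp or `NA`), `forward_start` and `reverse_start`
#'   (0-based site starts, `NA` when absent).
#' @examples
#' p <- primer_pair("demo", "ACGTACGTAC", "TTTTGGGGCC", 30)
#' tpl <- paste0("AA", p$forward, strrep("A", 8), revcomp(p$reverse), "GG")
#' in_silico_pcr(tpl, p)
#' @export
in_silico_pcr <- function(templates, primer) {
  stopifnot(inherits(primer, "primer_pair"))
  templates <- toupper(templates)
  if (is.null(names(templates))) {
    names(templates) <- if (length(templates) == 1L) "template" else
      paste0("template", seq_along(templates))
  }
  if (any(grepl("-", templates, fixed = TRUE))) {
    abort("templates must be gap-free; remove alignment gaps first")
  }
  rc <- revcomp(primer$reverse)
  purrr::imap(templates, function(tpl, nm) {
    f_hits <- find_exact(tpl, primer$forward)
    r_hits <- find_exact(tpl, rc)
    if (length(f_hits) > 1L || length(r_hits) > 1L) {
      abort(sprintf(
        "ambiguous amplification: primer '%s' matches template '%s' more than once",
        primer$name, nm))
    }
    if (length(f_hits) == 1L && length(r_hits) == 1L) {
      f <- f_hits[1L]
      r_end <- r_hits[1L] + nchar(rc) - 1L
      if (r_end > f + nchar(primer$forward) - 1L) {
        return(tibble(primer = primer$name, template = nm,
                      product_length = r_end - f + 1L,
                      forward_start = f - 1L, reverse_start = r_hits[1L] - 1L))
      }
    }
    tibble(primer = primer$name, template = nm,
           product_length = NA_integer_,
           forward_start = NA_integer_, reverse_start = NA_integer_)
  }) |> bind_rows()
}

find_exact <- function(text, pattern) {
  hits <- gregexpr(pattern, text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}

#' Find morphotype-diagnostic indel loci
#'
#' Returns the indel loci (`del1` or `indel_multi` of at least
#' `min_length` bp) at which the two groups carry fixed, different states.
#' A locus tolerates up to `tolerance` samples deviating from their group's
#' majority state; with the default `tolerance = 0` the rule is strict.
#' Swapping `group_a` and `group_b` returns the same loci.
#'
#' @inheritParams count_between_group
#' @param min_length Minimum indel length in bp (1 admits single-base
#'   deletions).
#' @param tolerance Maximum number of group-inconsistent samples.
#' @returns A tibble with columns `locus_id`, `start`, `end`, `class`,
#'   `length`, `state_a`, `state_b` (the groups' majority states),
#'   `n_violations` and `discriminating`.
#' @export
find_diagnostic_indels <- function(loci, groups, group_a, group_b,
                                   min_length = 1L, tolerance = 0L) {
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) abort(sprintf("unknown group label '%s'", g))
  }
  cand <- loci |>
    filter(.data$class %in% c("del1", "indel_multi"),
           .data$length >= min_length)
  if (nrow(cand) == 0) {
    return(tibble(locus_id = character(), start = integer(), end = integer(),
                  class = character(), length = integer(),
                  state_a = character(), state_b = character(),
                  n_violations = integer(), discriminating = logical()))
  }
  taxa_a <- names(groups)[groups == group_a]
  taxa_b <- names(groups)[groups == group_b]
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
  cand |>
    mutate(
      state_a = map_chr(.data$alleles, ~ majority(.x[taxa_a])),
      state_b = map_chr(.data$alleles, ~ majority(.x[taxa_b])),
      n_violations = purrr::pmap_int(
        list(.data$alleles, .data$state_a, .data$state_b),
        function(al, sa, sb) {
          sum(al[taxa_a] != sa) + sum(al[taxa_b] != sb)
        }),
      discriminating = .data$state_a != .data$state_b &
        .data$n_violations <= tolerance
    ) |>
    filter(.data$discriminating) |>
    select("locus_id", "start", "end", "class", "length",
           "state_a", "state_b", "n_violations", "discriminating")
}

#' Genotype templates by diagnostic product size
#'
#' Assigns each PCR product to the group whose rule size lies within
#' `tolerance` bp of the predicted product length. Templates with an absent
#' product or a product outside every window are called `"unknown"`.
#'
#' @param predictions Tibble from [in_silico_pcr()].
#' @param rule Named numeric vector mapping product size (bp) to group
#'   label, e.g. `c("750" = "Mediterranean", "703" = "Continental")` given
#'   as `setNames(c(750, 703), c("Mediterranean", "Continental"))`.
#'   Sizes must be separated by more than `2 * tolerance`.
#' @param tolerance Half-width of each size window in bp.
#' @returns `predictions` with an added `call` column.
#' @export
genotype_by_size <- function(predictions, rule, tolerance = 0) {
  sizes <- unname(rule)
  if (length(sizes) > 1L && min(dist(sizes)) <= 2 * tolerance) {
    abort("overlapping size windows: rule sizes must be separated by more than 2 * tolerance")
  }
  predictions |>
    mutate(call = map_chr(.data$product_length, function(len) {
      if (is.na(len)) return("unknown")
      hit <- which(abs(sizes - len) <= tolerance)
      if (length(hit) == 1L) names(rule)[hit] else "unknown"
    }))
}

#' Score SSR primers for group-discriminating fragments
#'
#' A fragment discriminates the two groups when it is present in all
#' samples of one group and absent in all samples of the other, allowing up
#' to `tolerance` violating samples (counted across both groups). A primer
#' is reported as discriminating when it carries at least `min_fragments`
#' such fragments.
#'
#' @param ssr A long-format SSR table with columns `primer`, `accession`,
#'   `fragment_id`, and `present` (0/1), as produced by
#'   [generate_ssr_table()].
#' @inheritParams count_between_group
#' @param min_fragments Minimum number of discriminating fragments per
#'   reported primer.
#' @param tolerance Maximum violating samples per fragment.
#' @returns A tibble with one row per primer: `primer`, `n_fragments`,
#'   `n_discriminating`, `n_violations` (largest violation count among its
#'   discriminating fragments) and `discriminating` flag.
#' @export
score_ssr_discrimination <- function(ssr, groups, group_a, group_b,
                                     min_fragments = 2L, tolerance = 0L) {
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) abort(sprintf("unknown group label '%s'", g))
  }
  taxa_a <- names(groups)[groups == group_a]
  taxa_b <- names(groups)[groups == group_b]
  sub <- ssr |> filter(.data$accession %in% c(taxa_a, taxa_b))
  if (anyNA(sub$present)) {
    bad <- sub |> filter(is.na(.data$present))
    abort(sprintf(
      "missing presence calls: %s",
      paste(sprintf("%s/%s/%s", bad$primer, bad$accession, bad$fragment_id),
            collapse = ", ")))
  }
  complete <- sub |>
    dplyr::count(.data$primer, .data$fragment_id) |>
    filter(.data$n < length(taxa_a) + length(taxa_b))
  if (nrow(complete) > 0) {
    abort(sprintf("incomplete SSR table: no call for some samples at %s",
                  paste(sprintf("%s/%s", complete$primer,
                                complete$fragment_id), collapse = ", ")))
  }
  frag <- sub |>
    group_by(.data$primer, .data$fragment_id) |>
    summarise(
      viol_ab = sum(.data$present[.data$accession %in% taxa_a] == 0) +
        sum(.data$present[.data$accession %in% taxa_b] == 1),
      viol_ba = sum(.data$present[.data$accession %in% taxa_a] == 1) +
        sum(.data$present[.data$accession %in% taxa_b] == 0),
      .groups = "drop") |>
    mutate(viol = pmin(.data$viol_ab, .data$viol_ba),
           disc = .data$viol <= tolerance)
  frag |>
    group_by(.data$primer) |>
    summarise(n_fragments = n(),
              n_discriminating = sum(.data$disc),
              n_violations = if (any(.data$disc)) max(.data$viol[.data$disc])
                             else NA_integer_,
              .groups = "drop") |>
    mutate(discriminating = .data$n_discriminating >= min_fragments)
}
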