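#' Specify a synthetic alignment with planted variants
#'
#' A plant profile describes a group-structured alignment to simulate: the
#' taxa and their groups, one row per planted polymorphic locus (class,
#' carrier groups, indel length), the alignment length and the seed. Carrier
#' groups receive the derived state (alternate base, or a gap run for
#' indels); everything else is a monomorphic uniform-random background.
#'
#' @param taxa Character vector of taxon labels.
#' @param groups Named character vector mapping each taxon to its group.
#' @param loci A data frame with one row per planted locus and columns
#'   `class` (one of `"snp"`, `"del1"`, `"indel_multi"`), `carriers` (a
#'   list-column of character vectors of carrier *group* labels) and
#'   `length` (indel length in bp; ignored for `snp`/`del1`, which have
#'   width 1).
#' @param alignment_length Number of alignment columns.
#' @param seed Integer seed; every random draw in [generate_alignment()]
#'   flows from it.
#' @returns An object of class `plant_profile`.
#' @seealso [festuca_profile()] for the packaged 12-taxon preset,
#'   [generate_alignment()] to realise a profile.
#' @export
plant_profile <- function(taxa, groups, loci, alignment_length, seed = 1L) {
  loci <- as_tibble(loci)
  stopifnot(all(c("class", "carriers") %in% names(loci)))
  if (!"length" %in% names(loci)) loci$length <- NA_integer_
  bad_class <- setdiff(unique(loci$class), c("snp", "del1", "indel_multi"))
  if (length(bad_class) > 0) {
    abort(sprintf("unknown locus class: %s", paste(bad_class, collapse = ", ")))
  }
  loci$length <- ifelse(loci$class == "indel_multi", as.integer(loci$length), 1L)
  if (any(loci$class == "indel_multi" & (is.na(loci$length) | loci$length < 2L))) {
    abort("indel_multi loci need `length` >= 2")
  }
  all_groups <- unique(unname(groups[taxa]))
  for (cs in loci$carriers) {
    if (length(cs) == 0 || !all(cs %in% all_groups) ||
        length(setdiff(all_groups, cs)) == 0) {
      abort("`carriers` must be a non-empty proper subset of the group labels")
    }
  }
  structure(
    list(taxa = taxa, groups = setNames(as.character(groups[taxa]), taxa),
         loci = loci, alignment_length = as.integer(alignment_length),
         seed = as.integer(seed)),
    class = "plant_profile"
  )
}

#' @export
print.plant_profile <- function(x, ...) {
  tab <- table(x$loci$class)
  cat(sprintf("<plant_profile> %d taxa, %d columns, %d loci (%s), seed %d\n",
              length(x$taxa), x$alignment_length, nrow(x$loci),
              paste(names(tab), tab, sep = ":", collapse = ", "), x$seed))
  invisible(x)
}

#' The packaged 12-taxon Festuca study preset
#'
#' Returns the plant profile emulating the study conditions of the tall
#' fescue chloroplast comparison: 12 varieties/accessions in six groups
#' (2 Continental, 3 Mediterranean, 1 Rhizomatous, 2 *F. pratensis*,
#' 2 *F. mairei*, 2 *F. glaucescens*), a 20,056-column alignment, and
#' 167 planted loci split 129 SNPs / 25 single-base deletions / 13
#' multi-base indels (3-47 bp). The carrier-group splits are an integer
#' solution chosen so that the planted pairwise fixed-difference counts
#' match the published comparison table on 11 of 15 group pairs, including
#' every pair the similarity-index worked examples use (117, 103, 42, 2,
#' ...); the remaining four pairs cannot be matched simultaneously by any
#' within-group-monomorphic configuration (see the package vignette).
#' Exactly four multi-base indels (32, 3, 47 and 8 bp, mirroring the four
#' diagnostic chloroplast amplicons) separate the Continental and
#' Mediterranean groups.
#'
#' @param seed Integer seed for the realisation.
#' @returns A [plant_profile()].
#' @examples
#' prof <- festuca_profile()
#' sim <- generate_alignment(prof)
#' nrow(sim$truth)  # 167
#' @export
festuca_profile <- function(seed = 20180L) {
  taxa <- c("Ensign", "Rita", "PI283312", "PI283313", "PI289651", "PI289654",
            "Torpedo", "Prosper", "Resolute", "FlechaMaxQ", "TexomaMaxQII",
            "KY-31")
  groups <- setNames(c("pratensis", "pratensis", "mairei", "mairei",
                       "glaucescens", "glaucescens", "Rhizomatous",
                       "Mediterranean", "Mediterranean", "Mediterranean",
                       "Continental", "Continental"), taxa)
  spl <- function(...) list(c(...))
  n_of <- function(n, class, carriers, length = NA_integer_) {
    tibble(class = rep(class, n), carriers = rep(carriers, n),
           length = rep(length, n))
  }
  P <- "pratensis"; M <- "mairei"; G <- "glaucescens"
  R <- "Rhizomatous"; C <- "Continental"; D <- "Mediterranean"
  loci <- bind_rows(
    # multi-base indels: the four Continental/Mediterranean diagnostics
    tibble(class = "indel_multi", carriers = spl(M, D), length = 32L),
    tibble(class = "indel_multi", carriers = spl(M, D), length = 3L),
    tibble(class = "indel_multi", carriers = spl(M, D), length = 47L),
    tibble(class = "indel_multi", carriers = spl(M, D), length = 8L),
    # remaining multi-base indels on splits keeping Continental and
    # Mediterranean on the same side
    tibble(class = "indel_multi", carriers = spl(P), length = 5L),
    tibble(class = "indel_multi", carriers = spl(P), length = 12L),
    tibble(class = "indel_multi", carriers = spl(P), length = 20L),
    tibble(class = "indel_multi", carriers = spl(P, M), length = 6L),
    tibble(class = "indel_multi", carriers = spl(P, M), length = 15L),
    tibble(class = "indel_multi", carriers = spl(M), length = 3L),
    tibble(class = "indel_multi", carriers = spl(M), length = 9L),
    tibble(class = "indel_multi", carriers = spl(M), length = 24L),
    tibble(class = "indel_multi", carriers = spl(M), length = 35L),
    # single-base deletions
    n_of(8, "del1", spl(P)),
    n_of(2, "del1", spl(P, M)),
    n_of(1, "del1", spl(G, R)),
    n_of(1, "del1", spl(R)),
    n_of(13, "del1", spl(M)),
    # SNPs, completing each split to its solved count
    n_of(12, "snp", spl(P)),
    n_of(1, "snp", spl(P, M)),
    n_of(2, "snp", spl(P, C)),
    n_of(13, "snp", spl(P, M, D)),
    n_of(1, "snp", spl(G, D)),
    n_of(43, "snp", spl(M, D)),
    n_of(39, "snp", spl(D)),
    n_of(1, "snp", spl(C)),
    n_of(17, "snp", spl(M))
  )
  plant_profile(taxa, groups, loci, alignment_length = 20056L, seed = seed)
}

#' Realise a plant profile as an alignment plus truth table
#'
#' Generates the alignment described by a [plant_profile()]: an i.i.d.
#' uniform A/C/G/T monomorphic background with every planted locus realised
#' exactly (derived allele fixed in the carrier groups, ancestral
#' elsewhere). Planted loci occupy non-overlapping column spans separated
#' by at least one monomorphic column, so adjacent gap runs never merge.
#' Deterministic for a fixed profile (the seed lives in the profile).
#'
#' @param profile A [plant_profile()].
#' @returns A list with elements `alignment` (an [aligned_set()]) and
#'   `truth` (a tibble with one row per planted locus: `locus_id`, `start`
#'   and `end` as 0-based half-open column spans, `class`, `length`,
#'   `carrier_groups` and `carriers` list-columns, `ancestral` and
#'   `derived` state strings).
#' @export
generate_alignment <- function(profile) {
  stopifnot(inherits(profile, "plant_profile"))
  loci <- profile$loci
  k <- nrow(loci)
  L <- profile$alignment_length
  widths <- ifelse(loci$class == "indel_multi", loci$length, 1L)
  need <- sum(widths) + max(k - 1L, 0L)
  if (need > L) {
    abort(sprintf(
      "alignment_length %d cannot host %d loci needing %d columns",
      L, k, need))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(profile$seed)

  taxa <- profile$taxa
  n <- length(taxa)
  mat <- matrix(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                nrow = n, ncol = L, byrow = TRUE)
  rownames(mat) <- taxa

  truth <- tibble()
  if (k > 0) {
    ord <- sample.int(k)
    w <- widths[ord]
    # distribute spare columns into k+1 gaps; interior gaps get >= 1
    spare <- L - sum(w) - (k - 1L)
    extra <- if (spare > 0) {
      tabulate(sample.int(k + 1L, spare, replace = TRUE), nbins = k + 1L)
    } else rep(0L, k + 1L)
    gaps <- extra + c(0L, rep(1L, max(k - 1L, 0L)), 0L)
    starts0 <- cumsum(c(0L, w[-k] + gaps[2:k])) + gaps[1L]  # 0-based
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      li <- loci[ord[i], ]
      span <- seq.int(starts0[i] + 1L, starts0[i] + w[i])  # 1-based cols
      carrier_groups <- li$carriers[[1L]]
      carrier_taxa <- taxa[profile$groups %in% carrier_groups]
      anc <- mat[1L, span, drop = TRUE]
      if (li$class == "snp") {
        derived <- sample(setdiff(c("A", "C", "G", "T"), anc), 1L)
        mat[carrier_taxa, span] <- derived
      } else {
        derived <- paste(rep("-", w[i]), collapse = "")
        mat[carrier_taxa, span] <- "-"
      }
      rows[[i]] <- tibble(
        start = starts0[i], end = starts0[i] + w[i],
        class = li$class, length = w[i],
        carrier_groups = list(carrier_groups),
        carriers = list(carrier_taxa),
        ancestral = paste(anc, collapse = ""),
        derived = if (li$class == "snp") derived else
          paste(rep("-", w[i]), collapse = "")
      )
    }
    truth <- bind_rows(rows) |>
      arrange(.data$start) |>
      mutate(locus_id = sprintf("L%03d", dplyr::row_number()), .before = 1)
  }
  list(alignment = aligned_set(mat, profile$groups), truth = truth)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
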