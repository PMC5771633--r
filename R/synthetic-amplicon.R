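#' Generate a pair of amplicon templates differing by one indel
#'
#' Builds two gap-free templates that are identical except that the first
#' group's template carries an insertion of `indel_length` bp strictly
#' between the primer binding sites. Both templates contain exactly one
#' occurrence of each primer site, so [in_silico_pcr()] product sizes
#' differ by exactly `indel_length`.
#'
#' @param primer A [primer_pair()]. `expected_size` (when set) is the
#'   product size of the *second* (shorter) template.
#' @param indel_length Insertion length in bp (>= 0).
#' @param group_labels Character vector of two labels naming the templates;
#'   the first label's template carries the insertion.
#' @param flank Number of background bases outside each primer site.
#' @param seed Integer seed.
#' @returns Named character vector of two templates.
#' @export
generate_amplicon_templates <- function(primer, indel_length,
                                        group_labels = c("Mediterranean",
                                                         "Continental"),
                                        flank = 30L, seed = 1L) {
  stopifnot(inherits(primer, "primer_pair"), indel_length >= 0,
            length(group_labels) == 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rc <- revcomp(primer$reverse)
  core_len <- if (!is.na(primer$expected_size)) {
    primer$expected_size - nchar(primer$forward) - nchar(primer$reverse)
  } else 100L
  if (core_len < 0L) abort("expected_size smaller than the primer footprints")
  draw <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                            collapse = "")
  unique_sites <- function(tpl) {
    length(find_exact(tpl, primer$forward)) == 1L &&
      length(find_exact(tpl, rc)) == 1L
  }
  for (try in 1:100) {
    core <- draw(core_len)
    insert <- draw(indel_length)
    left <- draw(flank); right <- draw(flank)
    short <- paste0(left, primer$forward, core, rc, right)
    long <- paste0(left, primer$forward,
                   substr(core, 1L, core_len %/% 2L), insert,
                   substr(core, core_len %/% 2L + 1L, core_len), rc, right)
    if (unique_sites(short) && unique_sites(long)) {
      return(setNames(c(long, short), group_labels))
    }
  }
  abort("could not place unique primer sites; use longer primers")
}

#' Packaged synthetic NFTCHL45-style fixture
#'
#' A synthetic stand-in for the NFTCHL45 morphotype-diagnostic assay: a
#' 20-mer primer pair with invented sequences (the real primer sequences
#' are not shipped) whose templates yield a 703 bp product on the
#' Continental-type template and a 750 bp product on the
#' Mediterranean-type template - the 47 bp diagnostic chloroplast indel,
#' the largest of the four marker indels.
#'
#' @param seed Integer seed for the template backgrounds.
#' @returns A list with elements `primer` (a [primer_pair()]) and
#'   `templates` (named character vector, `Mediterranean` and
#'   `Continental`).
#' @examples
#' fx <- nftchl45_fixture()
#' in_silico_pcr(fx$templates, fx$primer)
#' @export
nftchl45_fixture <- function(seed = 45L) {
  primer <- primer_pair(
    name = "NFTCHL45_synthetic",
    forward = "ATGGCTAGCTTGACCGTACA",
    reverse = "CAGTTCGGATAACGCTTGCA",
    expected_size = 703L
  )
  list(primer = primer,
       templates = generate_amplicon_templates(
         primer, indel_length = 47L,
         group_labels = c("Mediterranean", "Continental"), seed = seed))
}
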