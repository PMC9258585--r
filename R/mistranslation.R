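#' Filter PSM records at a q-value cutoff
#'
#' Retains peptide-spectrum matches at or below the given false-discovery
#' rate at the PSM level (default 1%).
#'
#' @param psms Annotated PSM tibble (see [read_psm_table()]).
#' @param fdr PSM-level q-value cutoff, default 0.01.
#' @return The retained records.
#' @export
filter_psms <- function(psms, fdr = 0.01) {
  assert_cols(psms, c("peptide", "q", "count"), "PSM table")
  if (!is.numeric(fdr) || length(fdr) != 1 || fdr < 0 || fdr > 1) {
    abort_bad_input("fdr must be a single value in [0, 1]")
  }
  dplyr::filter(psms, .data$q <= fdr)
}

#' Qualify mistranslated peptides by the sibling rule
#'
#' A mistranslated peptide observation only counts when the unmodified
#' ("sibling") form of the same reference sequence was also observed among
#' the retained records; mistranslated peptides without an observed sibling
#' are excluded from both numerator and denominator of the frequency.
#'
#' @param psms FDR-filtered annotated PSM tibble.
#' @return The records minus unqualified mistranslated peptides. The number
#'   of excluded unique mistranslated peptides is in
#'   `attr(, "excluded_no_sibling")`.
#' @export
qualify_siblings <- function(psms) {
  assert_cols(psms, c("peptide", "count", "is_mistranslated"), "PSM table")
  unmod_peps <- unique(psms$peptide[!psms$is_mistranslated])
  drop <- psms$is_mistranslated & !(psms$peptide %in% unmod_peps)
  out <- psms[!drop, ]
  attr(out, "excluded_no_sibling") <-
    length(unique(psms$peptide[drop]))
  out
}

#' Mistranslation frequency from a PSM table
#'
#' Estimates the amino-acid substitution frequency (by default
#' proline-to-serine) as the counts of qualified mistranslated peptides
#' divided by the counts of all retained peptides whose reference sequence
#' contains the substituted residue, expressed as a percentage. Records are
#' first filtered to the PSM-level FDR and mistranslated peptides qualified
#' by the sibling rule (see [qualify_siblings()]).
#'
#' Counting modes:
#' * `"spectral"` (default): spectral counts weight every observation.
#' * `"unique"`: each distinct peptide form counts once.
#'
#' A peptide carrying two substitution sites still counts as one
#' mistranslated observation (the counting unit is the mistranslated
#' peptide); `per_site = TRUE` switches the numerator to substitution sites.
#'
#' @param psms Annotated PSM tibble (see [read_psm_table()]); an optional
#'   `sample` column yields one result row per sample.
#' @param fdr PSM-level q-value cutoff (default 0.01).
#' @param counting `"spectral"` or `"unique"`.
#' @param per_site Count substitution sites rather than mistranslated
#'   peptides in the numerator (default `FALSE`).
#' @param residue One-letter code of the genetically encoded residue being
#'   substituted (default `"P"`).
#' @return Tibble with one row (per sample): `n_mistranslated`,
#'   `n_pro_total`, `frequency_pct`, `n_qualified_unique_peptides`,
#'   `excluded_no_sibling`.
#' @export
mistranslation_frequency <- function(psms, fdr = 0.01,
                                     counting = c("spectral", "unique"),
                                     per_site = FALSE, residue = "P") {
  counting <- match.arg(counting)
  if ("sample" %in% names(psms)) {
    return(
      psms |>
        dplyr::group_by(.data$sample) |>
        dplyr::group_modify(~ mistranslation_frequency(
          .x,
          fdr = fdr, counting = counting,
          per_site = per_site, residue = residue
        )) |>
        dplyr::ungroup()
    )
  }

  kept <- filter_psms(psms, fdr = fdr)
  kept <- qualify_siblings(kept)
  excluded <- attr(kept, "excluded_no_sibling")

  work <- tibble::tibble(
    peptide = kept$peptide,
    is_mis = kept$is_mistranslated,
    n_sub = kept$n_sub,
    count = kept$count,
    form = paste(
      kept$peptide,
      vapply(
        kept$mods,
        function(m) paste(m$position, m$name, sep = ":", collapse = ";"),
        character(1)
      )
    )
  )
  if (counting == "unique") {
    # one vote per distinct peptide form, regardless of spectral depth
    work <- work |>
      dplyr::distinct(.data$form, .keep_all = TRUE) |>
      dplyr::mutate(count = 1L)
  }

  denom_rows <- stringr::str_detect(work$peptide, stringr::fixed(residue)) |
    work$is_mis
  num_weight <- if (per_site) work$count * work$n_sub else work$count

  n_mis <- sum(num_weight[work$is_mis])
  n_tot <- sum(work$count[denom_rows])
  if (n_tot == 0) {
    abort_bad_input(
      "no retained peptides containing '", residue,
      "': frequency undefined"
    )
  }
  tibble::tibble(
    n_mistranslated = n_mis,
    n_pro_total = n_tot,
    frequency_pct = 100 * n_mis / n_tot,
    n_qualified_unique_peptides =
      length(unique(kept$peptide[kept$is_mistranslated])),
    excluded_no_sibling = excluded
  )
}
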