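#' Expected double-mutant fitness under the multiplicative model
#'
#' @param w_a,w_b Single-mutant fitness values (non-negative, vectorized).
#' @return The product `w_a * w_b`.
#' @export
expected_double <- function(w_a, w_b) {
  assert_nonneg(w_a, "fitness")
  assert_nonneg(w_b, "fitness")
  w_a * w_b
}

#' Validate screen hits from spot-assay intensities
#'
#' Screen hits are validated by remaking each double mutant and spotting it
#' alongside the two single mutants and a control strain. Fitness of each
#' genotype is its mean spot intensity relative to the mean control
#' intensity; the expected double-mutant fitness is the product of the two
#' single-mutant fitnesses, and a hit is validated when the observed double
#' mutant grows more slowly than expected: observed/expected < `theta`.
#'
#' @param spots Tibble with columns `strain` (hit identifier, e.g. the
#'   temperature-sensitive allele), `role` (one of `"double"`, `"single_ts"`,
#'   `"single_trna"`, `"control"`), `replicate` and `intensity`
#'   (net, background-subtracted; non-negative).
#' @param theta Validation margin on the observed/expected ratio (default
#'   0.9; the strict multiplicative rule is `theta = 1`).
#' @return Tibble with one row per strain: `w_single_ts`, `w_single_trna`,
#'   `w_double_obs`, `w_double_expected`, `ratio_obs_over_exp`, `validated`.
#' @export
validate_hits <- function(spots, theta = 0.9) {
  assert_cols(spots, c("strain", "role", "replicate", "intensity"),
    "validation spot table"
  )
  assert_nonneg(spots$intensity, "spot intensity")
  roles <- c("double", "single_ts", "single_trna", "control")
  if (!all(spots$role %in% roles)) {
    abort_bad_input(
      "role must be one of ", paste(roles, collapse = ", ")
    )
  }
  if (!is.numeric(theta) || theta <= 0) {
    abort_bad_input("theta must be positive")
  }

  means <- spots |>
    dplyr::group_by(.data$strain, .data$role) |>
    dplyr::summarise(mi = mean(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "mi")
  missing_roles <- setdiff(roles, names(means))
  if (length(missing_roles) > 0) {
    abort_bad_input(
      "spot table lacks role(s): ", paste(missing_roles, collapse = ", ")
    )
  }
  if (any(is.na(dplyr::select(means, dplyr::all_of(roles))))) {
    abort_bad_input("every strain needs intensities for all four roles")
  }
  if (any(means$control <= 0)) {
    abort_bad_input(
      "zero mean control intensity for strain(s): ",
      paste(means$strain[means$control <= 0], collapse = ", ")
    )
  }

  means |>
    dplyr::mutate(
      w_single_ts = .data$single_ts / .data$control,
      w_single_trna = .data$single_trna / .data$control,
      w_double_obs = .data$double / .data$control,
      w_double_expected = expected_double(.data$w_single_ts, .data$w_single_trna),
      ratio_obs_over_exp = ifelse(
        .data$w_double_expected > 0,
        .data$w_double_obs / .data$w_double_expected,
        NA_real_
      ),
      validated = !is.na(.data$ratio_obs_over_exp) &
        .data$ratio_obs_over_exp < theta
    ) |>
    dplyr::select(
      "strain", "w_single_ts", "w_single_trna", "w_double_obs",
      "w_double_expected", "ratio_obs_over_exp", "validated"
    )
}
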