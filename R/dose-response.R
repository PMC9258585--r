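#' Regulated mistranslation levels of the tRNA constructs
#'
#' The four centromeric constructs place a `GAL1` promoter sequence up- or
#' downstream of the mistranslating tRNA gene (or carry the wild-type tRNA),
#' yielding graded proline-to-serine mistranslation in galactose: background
#' with the wild-type tRNA, low with the downstream (3') promoter,
#' intermediate with the upstream (5') promoter, and the highest level with
#' the unregulated variant.
#'
#' @return Tibble mapping `construct` to `level`
#'   (`reference`/`low`/`medium`/`high`) and nominal `frequency_pct`
#'   (0.3, 0.9, 3.5, 5.6).
#' @export
mistranslation_levels <- function() {
  tibble::tibble(
    construct = c("WT-tS", "3'-tS(UGG)", "5'-tS(UGG)", "tS(UGG)"),
    level = c("reference", "low", "medium", "high"),
    frequency_pct = c(0.3, 0.9, 3.5, 5.6)
  )
}

dose_levels <- c("low", "medium", "high")

#' Per-strain growth normalized to the wild-type tRNA construct
#'
#' For each strain and mistranslating construct, the mean spot intensity is
#' divided by the mean intensity of the same strain carrying the wild-type
#' tRNA-Ser construct and expressed as a percentage. Replicate-level ratios
#' (each replicate against the wild-type-construct mean) are retained for
#' dispersion, and a seeded bootstrap over replicates gives the uncertainty
#' of each percentage.
#'
#' @param spots Spot tibble with columns `strain`, `construct`, `replicate`,
#'   `intensity` (see [read_spot_table()]); constructs must follow
#'   [mistranslation_levels()] naming and include `WT-tS`.
#' @param n_boot Bootstrap draws for the percentage's uncertainty (default
#'   1000; 0 disables).
#' @param seed Seed for the bootstrap (default 1729).
#' @param min_reps Minimum replicates required per construct (default 3).
#' @return Tibble with one row per strain and level: `construct`, `pct`
#'   (mean normalized growth, percent), `pct_sd` and `pct_lo`/`pct_hi`
#'   (bootstrap sd and 95% interval), `n_reps`, and a `rep_pct` list-column
#'   of replicate-level percentages.
#' @export
normalized_growth <- function(spots, n_boot = 1000, seed = 1729, min_reps = 3) {
  assert_cols(spots, c("strain", "construct", "replicate", "intensity"),
    "spot table"
  )
  assert_nonneg(spots$intensity, "spot intensity")
  lv <- mistranslation_levels()
  if (!all(spots$construct %in% lv$construct)) {
    abort_bad_input(
      "unknown construct(s): ",
      paste(setdiff(unique(spots$construct), lv$construct), collapse = ", ")
    )
  }
  counts <- dplyr::count(spots, .data$strain, .data$construct)
  if (any(counts$n < min_reps)) {
    bad <- counts[counts$n < min_reps, ]
    abort_bad_input(
      "fewer than ", min_reps, " replicates for: ",
      paste0(bad$strain, "/", bad$construct, collapse = ", ")
    )
  }
  has_wt <- spots |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(wt = any(.data$construct == "WT-tS"), .groups = "drop")
  if (any(!has_wt$wt)) {
    abort_bad_input(
      "missing WT-tS construct for strain(s): ",
      paste(has_wt$strain[!has_wt$wt], collapse = ", ")
    )
  }

  boot_stats <- function(x, wt) {
    # ratio-of-means bootstrap over replicates of both construct and reference
    if (n_boot <= 0) {
      return(c(sd = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    draws <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        100 * mean(sample(x, replace = TRUE)) /
          mean(sample(wt, replace = TRUE))
      }, numeric(1))
    })
    c(
      sd = stats::sd(draws),
      lo = unname(stats::quantile(draws, 0.025)),
      hi = unname(stats::quantile(draws, 0.975))
    )
  }

  spots |>
    dplyr::inner_join(lv, by = "construct") |>
    dplyr::group_by(.data$strain) |>
    dplyr::group_modify(function(df, g) {
      wt <- df$intensity[df$level == "reference"]
      if (mean(wt) <= 0) {
        abort_bad_input("zero mean WT-tS intensity for a strain")
      }
      df |>
        dplyr::filter(.data$level != "reference") |>
        dplyr::group_by(.data$construct, .data$level) |>
        dplyr::summarise(
          pct = 100 * mean(.data$intensity) / mean(wt),
          rep_pct = list(100 * .data$intensity / mean(wt)),
          n_reps = dplyr::n(),
          boot = list(boot_stats(.data$intensity, wt)),
          .groups = "drop"
        )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      pct_sd = purrr::map_dbl(.data$boot, "sd"),
      pct_lo = purrr::map_dbl(.data$boot, "lo"),
      pct_hi = purrr::map_dbl(.data$boot, "hi"),
      level = factor(.data$level, levels = dose_levels)
    ) |>
    dplyr::select(
      "strain", "construct", "level", "pct", "pct_sd", "pct_lo", "pct_hi",
      "n_reps", "rep_pct"
    ) |>
    dplyr::arrange(.data$strain, .data$level)
}

#' Synthetic-interaction strength relative to the wild-type strain
#'
#' Expresses each strain's normalized growth at every mistranslation level
#' as a percentage of the wild-type strain's normalized growth at the same
#' level. 100% means no synthetic interaction beyond the general cost of
#' mistranslation (not the absence of a mistranslation effect).
#'
#' @param profiles Output of [normalized_growth()] covering the wild-type
#'   strain and at least one other strain.
#' @param wt_strain Identifier of the wild-type strain (default `"BY4742"`).
#' @return Tibble with `strain`, `level`, `rel_pct` (percent of wild-type
#'   normalized growth; `NA` with a warning where the wild-type value is 0)
#'   and the underlying `pct`/`wt_pct`.
#' @export
relative_synthetic_effect <- function(profiles, wt_strain = "BY4742") {
  assert_cols(profiles, c("strain", "level", "pct"), "profile table")
  wt <- profiles |>
    dplyr::filter(.data$strain == wt_strain) |>
    dplyr::select("level", wt_pct = "pct")
  if (nrow(wt) == 0) {
    abort_bad_input("wild-type strain '", wt_strain, "' absent from profiles")
  }
  out <- profiles |>
    dplyr::filter(.data$strain != wt_strain) |>
    dplyr::inner_join(wt, by = "level") |>
    dplyr::mutate(
      rel_pct = ifelse(
        .data$wt_pct > 0, 100 * .data$pct / .data$wt_pct, NA_real_
      )
    ) |>
    dplyr::select("strain", "level", "rel_pct", "pct", "wt_pct") |>
    dplyr::arrange(.data$strain, .data$level)
  if (any(is.na(out$rel_pct))) {
    rlang::warn("wild-type normalized growth is 0 at some level; rel_pct = NA")
  }
  out
}

#' Dose-response classification constants
#'
#' The numeric operationalization of the four qualitative response
#' categories; all constants are tunable. See [classify_triple()] for the
#' rules.
#'
#' @param uniform_span Maximum spread (points) for a `uniform` profile.
#' @param prop_low_min Minimum `low` value (percent) for `proportional`.
#' @param thresh_low_min Minimum `low` value for `threshold`.
#' @param thresh_cap Value both `medium` and `high` must fall below for
#'   `threshold`.
#' @param plateau_span Maximum |medium - high| for the `threshold` plateau.
#' @param low_sens_ratio Minimum ratio of the `low` deficit to the `high`
#'   deficit for `low_sensitive`.
#' @return Named list of constants.
#' @export
dose_response_constants <- function(uniform_span = 10,
                                    prop_low_min = 90,
                                    thresh_low_min = 75,
                                    thresh_cap = 75,
                                    plateau_span = 10,
                                    low_sens_ratio = 0.6) {
  list(
    uniform_span = uniform_span,
    prop_low_min = prop_low_min,
    thresh_low_min = thresh_low_min,
    thresh_cap = thresh_cap,
    plateau_span = plateau_span,
    low_sens_ratio = low_sens_ratio
  )
}

#' Classify one dose-response triple
#'
#' Deterministic, total classification of a strain's relative synthetic
#' effect at the three mistranslation levels into the four response
#' categories. With the default constants, rules are evaluated in order:
#'
#' 1. `uniform`: max - min <= 10 points (near-equivalent effect at all
#'    levels).
#' 2. `proportional`: low >= 90 and low > medium > high (interaction grows
#'    with mistranslation, none to speak of at the lowest level).
#' 3. `threshold`: 75 <= low < 90, medium < 75, high < 75 and
#'    |medium - high| <= 10 (modest effect at low, strong plateau at
#'    moderate and high).
#' 4. `low_sensitive`: deficit at low >= 0.6 x deficit at high (relatively
#'    strong impact already at the lowest level).
#' 5. Remaining profiles are assigned by the `low` band: `proportional` when
#'    low >= 90, otherwise `threshold`.
#'
#' The `low >= 90` band is exclusive to `proportional` and excluded from
#' `threshold`, which makes the classification stable under worsening
#' high-level effects: lowering `high` can never turn a `threshold` profile
#' into a `proportional` one.
#'
#' @param low,medium,high Relative synthetic effect (percent of wild type)
#'   at the three levels; vectorized, each in (0, 200].
#' @param constants See [dose_response_constants()].
#' @return Character vector of categories: `proportional`, `threshold`,
#'   `uniform` or `low_sensitive`.
#' @export
classify_triple <- function(low, medium, high,
                            constants = dose_response_constants()) {
  if (any(is.na(low) | is.na(medium) | is.na(high))) {
    abort_bad_input("rel_pct missing at some level; cannot classify")
  }
  k <- constants
  span <- pmax(low, medium, high) - pmin(low, medium, high)
  uniform <- span <= k$uniform_span
  proportional <- low >= k$prop_low_min & low > medium & medium > high
  threshold <- low >= k$thresh_low_min & low < k$prop_low_min &
    medium < k$thresh_cap & high < k$thresh_cap &
    abs(medium - high) <= k$plateau_span
  low_sensitive <- (100 - low) >= k$low_sens_ratio * (100 - high)
  dplyr::case_when(
    uniform ~ "uniform",
    proportional ~ "proportional",
    threshold ~ "threshold",
    low_sensitive ~ "low_sensitive",
    low >= k$prop_low_min ~ "proportional",
    TRUE ~ "threshold"
  )
}

#' Classify dose-response profiles
#'
#' @param rel Output of [relative_synthetic_effect()] (long format with
#'   `strain`, `level`, `rel_pct`); every strain must have exactly the three
#'   levels low/medium/high.
#' @param constants See [dose_response_constants()].
#' @return Tibble with one row per strain: `rel_low`, `rel_medium`,
#'   `rel_high` and `category`.
#' @export
classify_profiles <- function(rel, constants = dose_response_constants()) {
  assert_cols(rel, c("strain", "level", "rel_pct"), "relative-effect table")
  wide <- rel |>
    dplyr::mutate(level = as.character(.data$level)) |>
    dplyr::select("strain", "level", "rel_pct") |>
    tidyr::pivot_wider(names_from = "level", values_from = "rel_pct")
  missing_lv <- setdiff(dose_levels, names(wide))
  if (length(missing_lv) > 0 || anyNA(wide[dose_levels])) {
    abort_bad_input("every strain needs rel_pct at levels low, medium, high")
  }
  wide |>
    dplyr::transmute(
      strain = .data$strain,
      rel_low = .data$low,
      rel_medium = .data$medium,
      rel_high = .data$high,
      category = classify_triple(
        .data$low, .data$medium, .data$high,
        constants = constants
      )
    )
}

#' Welch's t-tests with Bonferroni correction
#'
#' Unequal-variance two-sample comparisons (Welch-Satterthwaite degrees of
#' freedom) between all pairs of groups, with Bonferroni-corrected p-values
#' `min(1, m * p)`. Used for the group comparisons of mistranslation
#' frequency, doubling time and reporter induction between strains.
#'
#' @param data Tibble with one value per row.
#' @param value Name of the numeric value column (default `"value"`).
#' @param group Name of the grouping column (default `"group"`).
#' @param m Number of comparisons for the Bonferroni factor; defaults to the
#'   number of pairs tested.
#' @return Tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference), `t`, `df`, `p_raw`, `p_adj`.
#' @export
welch_bonferroni <- function(data, value = "value", group = "group", m = NULL) {
  assert_cols(data, c(value, group), "comparison table")
  v <- data[[value]]
  g <- as.character(data[[group]])
  lev <- unique(g)
  if (length(lev) < 2) abort_bad_input("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) abort_bad_input("need at least 2 values per group")

  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- m %||% length(pairs)
  purrr::map_dfr(pairs, function(p) {
    x <- v[g == p[1]]
    y <- v[g == p[2]]
    res <- tryCatch(
      stats::t.test(x, y, var.equal = FALSE),
      error = function(e) NULL
    )
    if (is.null(res)) {
      # both groups constant: identical means -> no evidence; else certain
      p_raw <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      tibble::tibble(
        group1 = p[1], group2 = p[2], estimate = mean(x) - mean(y),
        t = NA_real_, df = NA_real_, p_raw = p_raw,
        p_adj = min(1, m * p_raw)
      )
    } else {
      tibble::tibble(
        group1 = p[1], group2 = p[2],
        estimate = unname(res$estimate[1] - res$estimate[2]),
        t = unname(res$statistic), df = unname(res$parameter),
        p_raw = res$p.value, p_adj = min(1, m * res$p.value)
      )
    }
  })
}
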