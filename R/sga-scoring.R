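#' Normalize colony-array plates
#'
#' Corrects systematic variation in colony sizes before fitness estimation.
#' Two corrections are available and can be combined:
#'
#' * `"medpolish"`: removes multiplicative row/column gradients (pinning,
#'   nutrient and incubation artifacts) by median polish of log colony sizes;
#'   the plate-level overall term and the residuals are retained, so the
#'   absolute size scale of the plate is preserved.
#' * `"scale"`: rescales each plate so its median non-missing, non-border
#'   colony size equals a common reference median (the grand median across
#'   plates unless `reference_median` is given), absorbing plate-to-plate
#'   pinning differences.
#' * `"medpolish+scale"` applies both; `"none"` returns the input.
#'
#' Colonies of size zero (dead) and missing positions are excluded from the
#' gradient/median estimates but are carried through unchanged: zero stays
#' zero (multiplicative corrections cannot revive a dead colony) and missing
#' stays missing.
#'
#' @param plates Validated plate table (see [read_plate_table()]).
#' @param mode One of `"medpolish"`, `"scale"`, `"medpolish+scale"`, `"none"`.
#' @param key Optional array key; mapped border/blank positions are then
#'   excluded from all normalization statistics.
#' @param reference_median Target plate median for `"scale"` mode; defaults to
#'   the grand median of non-missing, non-border sizes across plates.
#' @return Plate tibble of the same shape with corrected sizes.
#' @export
normalize_plates <- function(plates,
                             mode = c("medpolish", "scale", "medpolish+scale", "none"),
                             key = NULL,
                             reference_median = NULL) {
  mode <- match.arg(mode)
  plates <- validate_plate_tbl(plates)

  border <- rep(FALSE, nrow(plates))
  if (!is.null(key)) {
    if (!"is_border" %in% names(key)) key <- validate_array_key(key)
    kb <- key |>
      dplyr::select("plate", "row", "col", "is_border")
    plates_k <- dplyr::left_join(plates, kb, by = c("plate", "row", "col"))
    border <- !is.na(plates_k$is_border) & plates_k$is_border
  }
  plates$.border <- border

  usable <- !is.na(plates$size) & !plates$.border
  frac <- plates |>
    dplyr::group_by(.data$plate) |>
    dplyr::summarise(
      f = mean(!is.na(.data$size)),
      any_ok = any(!is.na(.data$size)),
      .groups = "drop"
    )
  if (any(!frac$any_ok)) {
    abort_bad_input(
      "all-missing plate(s): ", paste(frac$plate[!frac$any_ok], collapse = ", ")
    )
  }
  if (any(frac$f < 0.5)) {
    abort_bad_input(
      "plate(s) with < 50% non-missing positions: ",
      paste(frac$plate[frac$f < 0.5], collapse = ", ")
    )
  }

  if (mode %in% c("medpolish", "medpolish+scale")) {
    plates <- plates |>
      dplyr::group_by(.data$plate) |>
      dplyr::group_modify(~ polish_one(.x)) |>
      dplyr::ungroup()
  }
  if (mode %in% c("scale", "medpolish+scale")) {
    use <- !is.na(plates$size) & !plates$.border & plates$size > 0
    ref <- reference_median %||% stats::median(plates$size[use])
    plates <- plates |>
      dplyr::group_by(.data$plate) |>
      dplyr::mutate(size = .data$size * ref /
        stats::median(.data$size[!is.na(.data$size) & !.data$.border &
          .data$size > 0])) |>
      dplyr::ungroup()
  }
  plates$.border <- NULL
  plates
}

# Median polish of log sizes for a single plate; removes row/col effects,
# keeps overall + residual. Zeros and missing are untouched.
polish_one <- function(df) {
  nr <- max(df$row)
  nc <- max(df$col)
  m <- matrix(NA_real_, nr, nc)
  use <- !is.na(df$size) & !df$.border & df$size > 0
  m[cbind(df$row[use], df$col[use])] <- log(df$size[use])
  fit <- stats::medpolish(m, na.rm = TRUE, trace.iter = FALSE, maxiter = 20)
  rowe <- ifelse(is.na(fit$row), 0, fit$row)
  cole <- ifelse(is.na(fit$col), 0, fit$col)
  # centre the effects (mean 0 over informative rows/cols) so the correction
  # only reshapes the plate and leaves its overall size level untouched
  row_has <- rowSums(!is.na(m)) > 0
  col_has <- colSums(!is.na(m)) > 0
  rowe[row_has] <- rowe[row_has] - mean(rowe[row_has])
  cole[col_has] <- cole[col_has] - mean(cole[col_has])
  corr <- exp(rowe[df$row] + cole[df$col])
  out <- df
  pos <- !is.na(df$size) & df$size > 0
  out$size[pos] <- df$size[pos] / corr[pos]
  out
}

#' Replicate fitness values from a quadruplicate block
#'
#' Converts the colony sizes of one allele's replicate block into
#' dimensionless fitness values by dividing by a reference colony size (the
#' size a no-defect strain reaches under the same pinning conditions; wild
#' type = 1 by construction). Missing replicates are dropped; per-replicate
#' resolution is retained (no premature averaging). Zero sizes give fitness
#' zero: lethality is signal, not missing data.
#'
#' @param sizes Numeric vector of replicate colony sizes (`NA` = missing).
#' @param reference Positive reference colony size.
#' @return Numeric vector of replicate fitness values, or `NULL` when fewer
#'   than 2 usable replicates remain (allele unscorable).
#' @export
fitness_from_block <- function(sizes, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0) {
    abort_bad_input("reference colony size must be a single positive number")
  }
  assert_nonneg(sizes, "colony size")
  w <- sizes[!is.na(sizes)] / reference
  if (length(w) < 2) {
    return(NULL)
  }
  w
}

#' Multiplicative-model interaction score
#'
#' The genetic-interaction score is the deviation of the double-mutant
#' fitness from the multiplicative expectation of the two single mutants:
#' epsilon = W_AB - W_A * W_B. Negative values indicate synthetic sickness,
#' positive values alleviation/suppression.
#'
#' @param w_ab Double-mutant fitness (vectorized).
#' @param w_a,w_b Single-mutant fitness values.
#' @return epsilon, `w_ab - w_a * w_b`.
#' @export
epsilon <- function(w_ab, w_a, w_b) {
  assert_nonneg(w_ab, "fitness")
  assert_nonneg(w_a, "fitness")
  assert_nonneg(w_b, "fitness")
  w_ab - w_a * w_b
}

#' Build a per-allele fitness table from normalized plates
#'
#' Joins double-mutant and control (single-mutant) plates to the array key
#' and computes replicate fitness values per allele: `w_a` is the mean
#' replicate fitness of the temperature-sensitive single mutant from the
#' control cross, `w_ab` keeps per-replicate double-mutant fitness.
#'
#' @param double_plates,control_plates Normalized plate tables for the
#'   query cross (double mutants) and the control cross (single mutants).
#'   Both must share the array `key` layout.
#' @param key Array key (see [read_array_key()]).
#' @param reference Reference colony size defining fitness 1 (see
#'   [fitness_from_block()]).
#' @return Tibble with one row per allele: `allele`, `gene`, `w_a`,
#'   `n_rep_a`, list-column `w_ab` of replicate double-mutant fitness,
#'   `n_rep_ab`, and `scorable` (at least 2 usable replicates in each cross).
#' @export
fitness_table <- function(double_plates, control_plates, key, reference) {
  join_sizes <- function(plates, name) {
    out <- key |>
      dplyr::filter(!.data$is_border) |>
      dplyr::left_join(
        dplyr::select(plates, "plate", "row", "col", "size"),
        by = c("plate", "row", "col")
      ) |>
      dplyr::group_by(.data$allele, .data$gene) |>
      dplyr::summarise(
        w = list(fitness_from_block(.data$size, reference)),
        .groups = "drop"
      )
    names(out)[names(out) == "w"] <- name
    out
  }
  ctl <- join_sizes(control_plates, "w_a_rep")
  dbl <- join_sizes(double_plates, "w_ab")
  dplyr::inner_join(ctl, dbl, by = c("allele", "gene")) |>
    dplyr::mutate(
      n_rep_a = purrr::map_int(.data$w_a_rep, length),
      n_rep_ab = purrr::map_int(.data$w_ab, length),
      w_a = purrr::map_dbl(
        .data$w_a_rep,
        ~ if (is.null(.x)) NA_real_ else mean(.x)
      ),
      scorable = !purrr::map_lgl(.data$w_a_rep, is.null) &
        !purrr::map_lgl(.data$w_ab, is.null)
    ) |>
    dplyr::select(
      "allele", "gene", "w_a", "n_rep_a", "w_ab", "n_rep_ab", "scorable"
    )
}

#' Estimate the query-strain fitness from the screen itself
#'
#' The query single-mutant fitness W_B is shared by every double mutant. With
#' genetic interactions sparse, W_AB = W_A * W_B for the large majority of
#' alleles, so the median over scorable alleles of mean(W_AB)/W_A is a robust
#' estimate of W_B (ties/even counts averaged, as by the sample median).
#'
#' @param fit Fitness table from [fitness_table()].
#' @return Estimated W_B (single number).
#' @export
estimate_query_fitness <- function(fit) {
  ok <- dplyr::filter(fit, .data$scorable, .data$w_a > 0)
  if (nrow(ok) == 0) abort_bad_input("no scorable alleles to estimate W_B")
  stats::median(purrr::map_dbl(ok$w_ab, mean) / ok$w_a)
}

# Vectorized one-sample two-sided t-test of replicate values against 0.
# Constant replicates: p = 1 when the mean is (numerically) 0, else 0.
t_one_sample_p <- function(m, s, n) {
  p <- rep(NA_real_, length(m))
  ok <- !is.na(m) & n >= 2
  zero_sd <- ok & (is.na(s) | s < .Machine$double.eps^0.75)
  p[zero_sd] <- ifelse(abs(m[zero_sd]) < 1e-12, 1, 0)
  reg <- ok & !zero_sd
  tstat <- m[reg] / (s[reg] / sqrt(n[reg]))
  p[reg] <- 2 * stats::pt(-abs(tstat), df = n[reg] - 1)
  p
}

#' Score alleles under the multiplicative model
#'
#' Computes per-replicate interaction scores epsilon_i = W_AB,i - W_A * W_B
#' for every scorable allele (the allele's mean single-mutant fitness W_A and
#' the shared query fitness W_B are used for all replicates), their mean, and
#' a raw p-value from a one-sample two-sided t-test of the replicate scores
#' against zero. Unscorable alleles are retained with `call = "none"` and no
#' p-value.
#'
#' @param fit Fitness table from [fitness_table()].
#' @param w_query Query single-mutant fitness W_B; estimated from the screen
#'   via [estimate_query_fitness()] when `NULL`.
#' @return Tibble of interaction records sorted by `eps_mean`: `allele`,
#'   `gene`, `w_a`, `w_b`, list-column `eps_reps`, `eps_mean`, `n_rep`,
#'   `p_raw`, `scorable`, and `call` initialised to `"none"` (see
#'   [call_interactions()]).
#' @export
score_alleles <- function(fit, w_query = NULL) {
  wb <- w_query %||% estimate_query_fitness(fit)
  recs <- fit |>
    dplyr::mutate(
      w_b = wb,
      eps_reps = purrr::map2(
        .data$w_ab, .data$w_a,
        function(w_ab_i, w_a_i) {
          if (is.null(w_ab_i) || is.na(w_a_i)) NULL else epsilon(w_ab_i, w_a_i, wb)
        }
      ),
      eps_mean = purrr::map_dbl(
        .data$eps_reps, ~ if (is.null(.x)) NA_real_ else mean(.x)
      ),
      n_rep = purrr::map_int(.data$eps_reps, length),
      eps_sd = purrr::map_dbl(
        .data$eps_reps, ~ if (is.null(.x)) NA_real_ else stats::sd(.x)
      ),
      p_raw = t_one_sample_p(.data$eps_mean, .data$eps_sd, .data$n_rep),
      call = "none"
    ) |>
    dplyr::select(
      "allele", "gene", "w_a", "w_b", "eps_reps", "eps_mean",
      "n_rep", "p_raw", "scorable", "call"
    ) |>
    dplyr::arrange(.data$eps_mean)
  recs
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values (order of input
#' preserved, monotonicity enforced). Thin, validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (`NA` allowed for
#'   unscorable records and passed through).
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort_bad_input("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Call negative and positive genetic interactions
#'
#' Applies the joint magnitude/FDR rule: an allele is called `negative` when
#' its mean interaction score is below `eps_threshold` (default -0.2) with
#' BH-adjusted p-value below `q_threshold` (default 0.05); `positive` calls
#' mirror the rule at `|eps_threshold|`. Everything else (including
#' unscorable alleles) is `none`.
#'
#' @param records Interaction records from [score_alleles()].
#' @param eps_threshold Negative interaction-score threshold (must be < 0).
#' @param q_threshold BH-adjusted p-value threshold in (0, 1).
#' @return The records with columns `q_bh` and `call` filled in.
#' @export
call_interactions <- function(records, eps_threshold = -0.2, q_threshold = 0.05) {
  if (!is.numeric(eps_threshold) || eps_threshold >= 0) {
    abort_bad_input("eps_threshold must be negative")
  }
  if (q_threshold <= 0 || q_threshold >= 1) {
    abort_bad_input("q_threshold must lie in (0, 1)")
  }
  records |>
    dplyr::mutate(
      q_bh = bh_adjust(.data$p_raw),
      call = dplyr::case_when(
        is.na(.data$eps_mean) | is.na(.data$q_bh) ~ "none",
        .data$eps_mean < eps_threshold & .data$q_bh < q_threshold ~ "negative",
        .data$eps_mean > abs(eps_threshold) & .data$q_bh < q_threshold ~ "positive",
        TRUE ~ "none"
      )
    )
}

#' Score a whole screen from plates to interaction calls
#'
#' Convenience composition of [normalize_plates()], [fitness_table()],
#' [score_alleles()], [bh_adjust()] and [call_interactions()].
#'
#' @inheritParams fitness_table
#' @inheritParams call_interactions
#' @inheritParams normalize_plates
#' @param w_query Optional known query fitness W_B (estimated from the screen
#'   when `NULL`).
#' @return Called interaction records (see [call_interactions()]).
#' @export
score_screen <- function(double_plates, control_plates, key, reference,
                         mode = "medpolish", w_query = NULL,
                         eps_threshold = -0.2, q_threshold = 0.05) {
  dbl <- normalize_plates(double_plates, mode = mode, key = key)
  ctl <- normalize_plates(control_plates, mode = mode, key = key)
  fit <- fitness_table(dbl, ctl, key, reference)
  score_alleles(fit, w_query = w_query) |>
    call_interactions(eps_threshold = eps_threshold, q_threshold = q_threshold)
}

#' Write interaction records to TSV
#'
#' @param records Called interaction records.
#' @param path Output path; the `eps_reps` list-column is serialised as a
#'   comma-separated field.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path) {
  out <- records |>
    dplyr::mutate(
      eps_reps = purrr::map_chr(
        .data$eps_reps,
        ~ paste(formatC(.x, digits = 10, format = "g"), collapse = ",")
      )
    )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}
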