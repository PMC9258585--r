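#' Fit a logistic growth model to one OD600 series
#'
#' Least-squares fit of the three-parameter logistic
#' `N(t) = K / (1 + ((K - N0) / N0) * exp(-r * t))` to an optical-density
#' time series, as used for microplate growth curves. The doubling time is
#' `ln(2) / r` in the time units of the input (minutes for a standard
#' 15-min/24-h plate-reader run). There is no lag-phase term; see the
#' methods vignette for the implications.
#'
#' Starting values follow the standard recipe: `K` from the maximum OD, `N0`
#' from the first reading, and `r` from the slope of log-OD over the
#' steepest 5-point window; all three parameters are bounded positive.
#' Optimisation is Levenberg-Marquardt least squares with a relative
#' tolerance of 1e-8 and at most 500 iterations. Series with no net growth
#' return `converged = FALSE` with the failure reason, never a spurious rate.
#'
#' @param time Numeric vector of strictly increasing times (>= 10 points).
#' @param od Positive OD600 readings, same length as `time`.
#' @param blank Optional scalar blank OD subtracted from all readings.
#' @return An object of class `logistic_fit`: list with `K`, `N0`, `r`,
#'   `doubling_time`, `rss`, `converged`, `reason`, `n` and the input data.
#'   Unconverged fits leave the parameters `NA`.
#' @examples
#' t <- seq(0, 1440, by = 15)
#' od <- 1.4 / (1 + ((1.4 - 0.1) / 0.1) * exp(-log(2) / 90 * t))
#' fit <- fit_logistic(t, od)
#' fit$doubling_time # ~90 minutes
#' @export
fit_logistic <- function(time, od, blank = 0) {
  if (length(time) != length(od)) {
    abort_bad_input("time and od must have the same length")
  }
  if (length(time) < 10) {
    abort_bad_input("need at least 10 time points")
  }
  if (any(diff(time) <= 0)) {
    abort_bad_input("time must be strictly increasing")
  }
  od <- od - blank
  if (any(is.na(od) | od <= 0)) {
    abort_bad_input("OD readings must be positive (after blank subtraction)")
  }

  failed <- function(reason) {
    structure(
      list(
        K = NA_real_, N0 = NA_real_, r = NA_real_,
        doubling_time = NA_real_, rss = NA_real_,
        converged = FALSE, reason = reason, n = length(time),
        data = tibble::tibble(time = time, od = od)
      ),
      class = "logistic_fit"
    )
  }

  # Initial values
  k0 <- max(od)
  n00 <- od[1]
  logod <- log(od)
  slopes <- vapply(seq_len(length(time) - 4), function(i) {
    idx <- i:(i + 4)
    stats::coef(stats::lm.fit(cbind(1, time[idx]), logod[idx]))[2]
  }, numeric(1))
  r0 <- max(slopes)
  if (!is.finite(r0) || r0 <= 0 || (max(od) - min(od)) < 1e-6) {
    return(failed("no net growth in series"))
  }
  if (n00 >= k0) n00 <- 0.99 * k0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ K / (1 + ((K - N0) / N0) * exp(-r * time)),
      data = data.frame(time = time, od = od),
      start = list(K = k0, N0 = n00, r = r0),
      lower = c(K = 1e-8, N0 = 1e-8, r = 1e-8),
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-8, ptol = 1e-8
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(failed(conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  if (cf[["K"]] <= cf[["N0"]] || cf[["r"]] <= 0) {
    return(failed("degenerate parameter estimates (K <= N0 or r <= 0)"))
  }
  structure(
    list(
      K = unname(cf[["K"]]), N0 = unname(cf[["N0"]]), r = unname(cf[["r"]]),
      doubling_time = log(2) / unname(cf[["r"]]),
      rss = sum(stats::resid(fit)^2),
      converged = TRUE, reason = NA_character_, n = length(time),
      data = tibble::tibble(time = time, od = od)
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Logistic fit: K = %.4g, N0 = %.4g, r = %.4g per unit time\n",
      x$K, x$N0, x$r
    ))
    cat(sprintf(
      "Doubling time = %.2f (ln 2 / r), RSS = %.3g, n = %d\n",
      x$doubling_time, x$rss, x$n
    ))
  } else {
    cat("Logistic fit did not converge:", x$reason, "\n")
  }
  invisible(x)
}

#' Tidy a logistic growth fit
#'
#' @param x A `logistic_fit` object.
#' @param ... Unused.
#' @return One row per parameter (`K`, `N0`, `r`, `doubling_time`) with its
#'   estimate, broom-style.
#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K", "N0", "r", "doubling_time"),
    estimate = c(x$K, x$N0, x$r, x$doubling_time)
  )
}

#' One-row summary of a logistic growth fit
#'
#' @param x A `logistic_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `K`, `N0`, `r`, `doubling_time`, `rss`,
#'   `converged`, `nobs`.
#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, N0 = x$N0, r = x$r, doubling_time = x$doubling_time,
    rss = x$rss, converged = x$converged, nobs = x$n
  )
}

#' Plot a logistic growth fit
#'
#' @param object A `logistic_fit` object.
#' @param ... Unused.
#' @return A ggplot of the OD readings with the fitted logistic curve.
#' @exportS3Method ggplot2::autoplot
autoplot.logistic_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$od)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "Time (min)", y = "OD600")
  if (object$converged) {
    grid <- tibble::tibble(
      time = seq(min(object$data$time), max(object$data$time), length.out = 200)
    )
    grid$od <- object$K /
      (1 + ((object$K - object$N0) / object$N0) * exp(-object$r * grid$time))
    p <- p +
      ggplot2::geom_line(data = grid, colour = "steelblue") +
      ggplot2::labs(
        subtitle = sprintf("Doubling time %.1f min", object$doubling_time)
      )
  }
  p
}

#' Fit logistic growth curves for a table of OD series
#'
#' @param od OD tibble with columns `strain`, optional `replicate`,
#'   `time_min`, `od` (see [read_od_table()]).
#' @param blank Optional scalar blank OD subtracted from all readings.
#' @return Tibble with one row per (strain, replicate): fitted `K`, `N0`,
#'   `r` (per minute), `doubling_time` (minutes), `rss`, `converged`.
#' @export
fit_growth_curves <- function(od, blank = 0) {
  if (!"replicate" %in% names(od)) od$replicate <- 1L
  od <- validate_od_tbl(od)
  od |>
    dplyr::group_by(.data$strain, .data$replicate) |>
    dplyr::group_modify(function(df, g) {
      glance(fit_logistic(df$time_min, df$od, blank = blank)) |>
        dplyr::rename(nobs_fit = "nobs")
    }) |>
    dplyr::ungroup()
}
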