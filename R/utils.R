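# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

abort_bad_input <- function(msg, ..., class = "sgamist_input_error") {
  rlang::abort(paste0(msg, ...), class = class)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_bad_input(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

assert_nonneg <- function(x, what) {
  if (any(!is.na(x) & x < 0)) {
    abort_bad_input(what, " must be non-negative")
  }
  invisible(x)
}

assert_prob <- function(x, what) {
  if (any(is.na(x)) || any(x < 0 | x > 1)) {
    abort_bad_input(what, " must lie in [0, 1]")
  }
  invisible(x)
}

# Supported colony-array formats: total positions -> (rows, cols).
plate_formats <- function() {
  tibble::tibble(
    n = c(1536L, 384L, 96L),
    n_rows = c(32L, 16L, 8L),
    n_cols = c(48L, 24L, 12L)
  )
}
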