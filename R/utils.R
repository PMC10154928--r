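# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can distinguish input errors
# from numerical failures.
stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "flightpower_invalid_input")
}

stop_numeric <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "flightpower_numeric_error")
}

stop_data <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "flightpower_data_error")
}

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_invalid("`%s` must be numeric and non-missing.", name)
  }
  bad <- if (allow_zero) any(x < 0) else any(x <= 0)
  if (bad) {
    stop_invalid("`%s` must be %s (got %s).", name,
                 if (allow_zero) "non-negative" else "strictly positive",
                 paste(signif(x[if (allow_zero) x < 0 else x <= 0], 4),
                       collapse = ", "))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_data("%s is missing required column(s): %s.",
              what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Population (n-denominator) standard deviation; the outlier Z-scores in the
# flight filters are defined with it.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# round() ties behaviour is banker's rounding; speed bins use plain rounding
# to the nearest multiple of `width`.
round_to <- function(x, width = 1) width * round(x / width)

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
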