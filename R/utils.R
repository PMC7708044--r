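# Error classes used across the package:
#   nanobeam_validation_error  -- bad arguments / inconsistent design
#   nanobeam_range_error       -- calibration target outside attainable bracket
#   nanobeam_numeric_error     -- singular / ill-posed linear system
#   nanobeam_config_error      -- trajectory lacks a required schedule feature
#   nanobeam_insufficient_data -- too few plateaus to fit

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nanobeam_validation_error")
}

stop_range <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nanobeam_range_error")
}

stop_numeric <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nanobeam_numeric_error")
}

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nanobeam_config_error")
}

stop_insufficient <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "nanobeam_insufficient_data")
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number, not %s.",
                    name, paste(class(x), collapse = "/"))
  }
  if (integer && abs(x - round(x)) > 1e-9) {
    stop_validation("`%s` must be an integer, got %g.", name, x)
  }
  lo_ok <- if (strict) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    stop_validation("`%s` must be in %s%g, %g], got %g.",
                    name, if (strict) "(" else "[", lower, upper, x)
  }
  if (integer) as.integer(round(x)) else x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation("`%s` must be TRUE or FALSE.", name)
  }
  x
}
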