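# internal helpers: typed errors and argument checks

abort_omapr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "omapr_error"), ...)
}

stop_argument <- function(message, ...) abort_omapr(message, "omapr_argument_error", ...)
stop_format <- function(message, ...) abort_omapr(message, "omapr_format_error", ...)
stop_truncation <- function(message, ...) abort_omapr(message, "omapr_truncation_error", ...)
stop_validation <- function(message, ...) abort_omapr(message, "omapr_validation_error", ...)
stop_segmentation <- function(message, ...) abort_omapr(message, "omapr_segmentation_error", ...)
stop_computation <- function(message, ...) abort_omapr(message, "omapr_computation_error", ...)

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_argument(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integer && x != round(x)) {
    stop_argument(sprintf("`%s` must be a whole number.", name))
  }
  if (x < lower || x > upper) {
    stop_argument(sprintf("`%s` must be in [%s, %s], got %s.", name,
                          format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_argument(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# odd-window normalized 1-D gaussian, weights sum to 1
gaussian_kernel_1d <- function(window, sigma) {
  check_number(window, "window", lower = 1, integer = TRUE)
  if (window %% 2L == 0L) stop_argument("`window` must be odd.")
  check_number(sigma, "sigma", lower = 0)
  r <- (window - 1L) / 2L
  x <- seq.int(-r, r)
  w <- if (sigma == 0) as.numeric(x == 0) else exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# indices with reflective boundary (1 2 3 ... n with 2-1-2 style reflection)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j >= n, p - j, j) + 1L
}
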