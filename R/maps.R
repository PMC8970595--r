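new_map <- function(values, kind, units = "", ...) {
  structure(list(values = values, kind = kind, units = units, ...),
            class = "omr_map")
}

#' @export
print.omr_map <- function(x, ...) {
  v <- x$values
  n_def <- sum(!is.na(v))
  cat(sprintf("<omr_map:%s> %dx%d px, %d defined", x$kind, nrow(v), ncol(v), n_def))
  if (is.logical(v)) {
    cat(sprintf(", %d kept\n", sum(v, na.rm = TRUE)))
  } else if (n_def > 0L) {
    cat(sprintf(", range [%.4g, %.4g] %s\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE), x$units))
  } else cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-pixel map into a long table
#'
#' @param x an `omr_map`.
#' @param drop_na drop undefined pixels?
#' @param ... unused.
#' @return Tibble with `row`, `col`, `value`.
#' @method tidy omr_map
#' @export
tidy.omr_map <- function(x, drop_na = TRUE, ...) {
  v <- x$values
  out <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Render a per-pixel map
#'
#' Raster rendering with image orientation (row 1 at the top), as used
#' for activation isochrone, APD, SNR and intensity maps.
#'
#' @param object an `omr_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot omr_map
#' @export
autoplot.omr_map <- function(object, ...) {
  df <- tidy(object, drop_na = FALSE)
  lab <- if (nzchar(object$units)) {
    sprintf("%s (%s)", object$kind, object$units)
  } else object$kind
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = lab)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
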