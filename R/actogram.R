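# Double-plotted actograms: one row per calendar day, time of day on the
# horizontal axis; double plotting repeats each day over 48 h so rhythms
# that cross midnight read as continuous bands.

#' Build an actogram matrix from an ODBA series
#'
#' @param series An `odba_series`.
#' @param bin_min Bin width in minutes (must divide 60, default 10).
#' @param double_plot If TRUE (default) each row spans 48 h: day i followed
#'   by day i+1. The right half of row i equals the left half of row i+1
#'   exactly; the final row's right half is missing.
#' @return An `actogram` object: list with `matrix` (days x bins, mean ODBA
#'   in g, NA = no data), `dates`, `bin_min`, `double_plot`, `animal_id`.
#' @export
build_actogram <- function(series, bin_min = 10, double_plot = TRUE) {
  stopifnot(60 %% bin_min == 0)
  bins <- bin_activity(series, bin_min)
  date <- as.Date(format(bins$time, "%Y-%m-%d"))
  slot <- floor(clock_hours(bins$time) * 60 / bin_min) + 1L
  nbin <- 1440 %/% bin_min
  dates <- seq(min(date), max(date), by = "day")
  m <- matrix(NA_real_, nrow = length(dates), ncol = nbin,
              dimnames = list(format(dates), NULL))
  m[cbind(match(date, dates), slot)] <- bins$activity
  if (double_plot) {
    m2 <- cbind(m, rbind(m[-1, , drop = FALSE],
                         matrix(NA_real_, 1, nbin)))
    m <- m2
  }
  structure(list(matrix = m, dates = dates, bin_min = bin_min,
                 double_plot = double_plot,
                 animal_id = attr(series, "animal_id")),
            class = "actogram")
}

#' @export
print.actogram <- function(x, ...) {
  cat(sprintf("<actogram> animal %s: %d days x %d bins (%d-min bins%s)\n",
              x$animal_id, length(x$dates), ncol(x$matrix), x$bin_min,
              if (x$double_plot) ", double-plotted" else ""))
  invisible(x)
}

#' Plot an actogram
#'
#' Raster plot with days on the vertical axis (top = first day) and time of
#' day across; missing bins render as grey, distinct from zero activity.
#'
#' @param object An `actogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot actogram
#' @export
autoplot.actogram <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(day = seq_along(object$dates),
                           bin = seq_len(ncol(m)))
  df$odba <- as.vector(t(m))
  df$hour <- (df$bin - 1) * object$bin_min / 60
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$day,
                                   fill = .data$odba)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(breaks = scales_days(object$dates)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", name = "ODBA (g)") +
    ggplot2::labs(x = if (object$double_plot) "time of day (h, double-plotted)"
                  else "time of day (h)",
                  y = "day",
                  title = sprintf("Actogram: %s", object$animal_id)) +
    ggplot2::theme_minimal()
}

scales_days <- function(dates) {
  n <- length(dates)
  unique(round(seq(1, n, length.out = min(n, 8))))
}

#' @export
plot.actogram <- function(x, ...) print(autoplot(x, ...))
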