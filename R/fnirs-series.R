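# Lightweight container for multichannel optical timeseries: a samples x
# series matrix behind a tidy accessor, plus acquisition metadata.

new_fnirs_series <- function(values, info, time, rate, montage, events, kind,
                             extra = list()) {
  stopifnot(ncol(values) == nrow(info), nrow(values) == length(time))
  structure(
    c(list(values = values, info = info, time = time, rate = rate,
           montage = montage, events = events, kind = kind), extra),
    class = "fnirs_series"
  )
}

#' @export
print.fnirs_series <- function(x, ...) {
  cat(sprintf("<fnirs_series: %s> %d samples x %d series @ %.3g Hz, %d events\n",
              x$kind, nrow(x$values), ncol(x$values), x$rate,
              nrow(x$events %||% tibble::tibble())))
  invisible(x)
}

#' Tidy method for fNIRS series
#'
#' @param x an `fnirs_series`.
#' @param ... unused.
#' @return Long tibble with `time`, the series descriptors (channel and
#'   wavelength or chromophore) and `value`.
#' @method tidy fnirs_series
#' @export
tidy.fnirs_series <- function(x, ...) {
  info <- x$info
  df <- info[rep(seq_len(nrow(info)), each = nrow(x$values)), ]
  df$time <- rep(x$time, times = nrow(info))
  df$value <- as.vector(x$values)
  tibble::as_tibble(df[, c("time", setdiff(names(df), c("time", "value")), "value")])
}

#' @method autoplot fnirs_series
#' @export
autoplot.fnirs_series <- function(object, channels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(channels)) df <- df[df$channel %in% channels, ]
  colour_var <- if ("chromophore" %in% names(df)) "chromophore" else "wavelength"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = factor(.data[[colour_var]]))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = object$kind, colour = colour_var) +
    ggplot2::theme_minimal()
}

#' Synthetic optode montage
#'
#' Builds a montage in the layout used for frontal inhibitory-control
#' recordings: long channels (30 mm source-detector separation) mapped to
#' the five regions of interest (left/right inferior frontal gyrus;
#' left/middle/right prefrontal cortex) plus 8-mm short channels carrying
#' only scalp/systemic signal. The default sizes mirror a 38-long /
#' 8-short frontal montage.
#'
#' @param long_per_roi named integer vector: long channels per ROI.
#' @param n_short number of short channels.
#' @return Tibble with `channel`, `source`, `detector`, `separation_mm`,
#'   `roi`, `is_short`.
#' @export
default_montage <- function(long_per_roi = c(LIFG = 8, LPFC = 8, MPFC = 6,
                                             RPFC = 8, RIFG = 8),
                            n_short = 8) {
  rois <- names(long_per_roi)
  long <- tibble::tibble(
    roi = rep(rois, times = long_per_roi),
    idx = sequence(long_per_roi)
  ) |>
    dplyr::mutate(
      channel = sprintf("%s_L%02d", .data$roi, .data$idx),
      source = sprintf("S%02d", dplyr::row_number()),
      detector = sprintf("D%02d", dplyr::row_number()),
      separation_mm = 30, is_short = FALSE
    )
  short <- tibble::tibble(
    roi = rep(rois, length.out = n_short),
    channel = sprintf("SHORT%02d", seq_len(n_short)),
    source = sprintf("S%02d", nrow(long) + seq_len(n_short)),
    detector = sprintf("SD%02d", seq_len(n_short)),
    separation_mm = 8, is_short = TRUE
  )
  dplyr::bind_rows(long, short) |>
    dplyr::select("channel", "source", "detector", "separation_mm", "roi",
                  "is_short")
}
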