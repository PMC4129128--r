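# Activity maps: a day x time-of-day grid coloured by the ADL occupying
# each bin, visualising the structure of a resident's routine, plus a
# simple day-to-day regularity score.

#' Build an activity map from an event list
#'
#' The 24 h timeline of each day is divided into fixed bins; each bin
#' takes the label covering the majority of the bin (ties go to the
#' earlier-starting event), or none. A regularity score — the mean
#' fraction of bins that carry the same assignment on consecutive days —
#' is reported alongside: a perfectly repeated schedule scores 1,
#' unstructured behaviour scores lower.
#'
#' @param events Event tibble (classified or ground truth).
#' @param n_days Number of days covered by the grid.
#' @param bin_s Bin width in seconds (default 300, i.e. 5 min).
#' @return An `activity_map`: list with `grid` (`n_days` x bins character
#'   matrix, `NA` = no activity), `bin_s`, `regularity`.
#' @export
build_activity_map <- function(events, n_days, bin_s = 300) {
  stopifnot(86400 %% bin_s == 0, n_days >= 1)
  bins_per_day <- 86400 %/% bin_s
  n_bins <- n_days * bins_per_day
  lab <- rep(NA_character_, n_bins)
  cover <- numeric(n_bins)
  ev <- events[order(events$start), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    lo <- floor(ev$start[i] / bin_s) + 1
    hi <- min(n_bins, ceiling(ev$end[i] / bin_s))
    if (lo > hi || lo > n_bins) next
    for (b in lo:hi) {
      cv <- interval_intersection(ev$start[i], ev$end[i], (b - 1) * bin_s, b * bin_s)
      if (cv > cover[b]) { # strict: ties keep the earlier-starting event
        cover[b] <- cv
        lab[b] <- ev$label[i]
      }
    }
  }
  grid <- matrix(lab, nrow = n_days, ncol = bins_per_day, byrow = TRUE)
  reg <- NA_real_
  if (n_days >= 2) {
    agree <- vapply(seq_len(n_days - 1), function(d) {
      a <- grid[d, ]
      b <- grid[d + 1, ]
      mean((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
    }, numeric(1))
    reg <- mean(agree)
  }
  structure(
    list(grid = grid, bin_s = bin_s, regularity = reg),
    class = "activity_map"
  )
}

#' @export
print.activity_map <- function(x, ...) {
  cat(
    "<activity_map>", nrow(x$grid), "days x", ncol(x$grid), "bins of",
    x$bin_s, "s; regularity =",
    if (is.na(x$regularity)) "NA" else round(x$regularity, 3), "\n"
  )
  occ <- table(x$grid[!is.na(x$grid)])
  if (length(occ)) {
    for (lab in names(sort(occ, decreasing = TRUE))) {
      cat(sprintf(
        "  %-22s %5.1f h/day\n", lab,
        occ[[lab]] * x$bin_s / 3600 / nrow(x$grid)
      ))
    }
  }
  invisible(x)
}

#' Plot an activity map
#'
#' Renders the day x time-of-day grid as coloured tiles (requires
#' ggplot2).
#'
#' @param x An `activity_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.activity_map <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_adlsense("plotting an activity map requires ggplot2")
  }
  grid <- x$grid
  df <- data.frame(
    day = rep(seq_len(nrow(grid)), times = ncol(grid)),
    tod_h = rep((seq_len(ncol(grid)) - 0.5) * x$bin_s / 3600, each = nrow(grid)),
    label = as.vector(grid)
  )
  df <- df[!is.na(df$label), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tod_h, y = .data$day, fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time of day [h]", y = "day", fill = "ADL") +
    ggplot2::theme_minimal()
}
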