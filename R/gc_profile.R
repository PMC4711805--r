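#' Cumulative G+C profile of a genome
#'
#' Computes the running sum `S(p) = sum_{i <= p} u_i` with `u_i = +1` for
#' A/T, `-1` for G/C and `0` for masked bases, sampled every `step` bp, then
#' removes the least-squares linear trend so that genome-average composition
#' maps to a flat curve. Regions of divergent G+C content appear as
#' near-linear segments of non-zero slope bounded by slope breaks — a jump
#' marks an abrupt drop in G+C, a fall an abrupt rise. The curve is a
#' visual companion to the island calls and never feeds back into them.
#'
#' @param genome A `genome_sequence`.
#' @param step Sampling interval in bp (>= 1); default 1,000.
#' @return A `gc_profile` tibble with columns `position` (bp, end of each
#'   sampled stretch), `cumulative_raw` (the running AT-minus-GC sum) and
#'   `cumulative` (after detrending).
#' @export
gc_cumulative <- function(genome, step = 1000L) {
  stopifnot(inherits(genome, "genome_sequence"), step >= 1)
  step <- as.integer(step)
  starts <- seq.int(0L, genome$length - 1L, by = step)
  ends <- pmin(starts + step, genome$length)
  counts <- count_window_bases(genome$sequence, starts, ends)
  raw <- cumsum((counts[, "A"] + counts[, "T"]) - (counts[, "G"] + counts[, "C"]))
  trend <- lm(raw ~ ends)
  out <- tibble::tibble(
    position = as.integer(ends),
    cumulative_raw = as.numeric(raw),
    cumulative = as.numeric(raw - predict_linear(trend, ends))
  )
  class(out) <- c("gc_profile", class(out))
  out
}

predict_linear <- function(fit, x) {
  coef(fit)[[1L]] + coef(fit)[[2L]] * x
}

#' Plot a cumulative G+C profile with island overlays
#'
#' @param profile A [gc_cumulative()] tibble.
#' @param islands Optional island tibble from [call_islands()]; each island
#'   interval is highlighted.
#' @return A ggplot object.
#' @export
plot_gc_profile <- function(profile, islands = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position / 1e6, y = .data$cumulative))
  if (!is.null(islands) && nrow(islands) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = islands,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey20", alpha = 0.25
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Genome position (Mb)",
      y = "Cumulative AT − GC excess (detrended)"
    ) +
    ggplot2::theme_minimal()
}
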