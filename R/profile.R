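#' Sliding-window normalized coverage profile of 5'-end positions
#'
#' The value at reference position p is the mean of per-position 5'-end read
#' counts over a window of `window` nt centred at p (the window is shrunk at
#' the reference edges), divided by the sample's total read count. Sense
#' reads' 5' ends sit at their mapped start; antisense reads' at
#' `start + length - 1`.
#'
#' @param mapped Uniquely mapped reads of one sample ([map_reads()] output;
#'   multi-placement reads are ignored).
#' @param ref_length Reference length in nt.
#' @param window Window width in nt (default 10).
#' @param total_reads Total read count of the sample used as the denominator;
#'   defaults to the tally recorded by [map_reads()].
#' @param strand Optionally restrict to `"sense"` or `"antisense"` reads.
#' @return A tibble `position`, `value` of length `ref_length`.
#' @export
sliding_window_profile <- function(mapped, ref_length, window = 10L,
                                   total_reads = NULL, strand = NULL) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  tal <- attr(mapped, "tallies")
  if (is.null(total_reads)) {
    total_reads <- if (!is.null(tal)) unname(tal["total"]) else
      length(unique(mapped$read_id))
  }
  if (is.null(total_reads) || total_reads <= 0) {
    stop("total read count must be positive", call. = FALSE)
  }
  uniq <- mapped[mapped$n_placements == 1, , drop = FALSE]
  if (!is.null(strand)) uniq <- uniq[uniq$strand == strand, , drop = FALSE]
  fp <- as.integer(five_prime_pos(uniq$start, uniq$length, uniq$strand))
  cnt <- tabulate(fp, nbins = ref_length)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo  # even windows extend one further to 3'
  cs <- c(0, cumsum(cnt))
  pos <- seq_len(ref_length)
  lo <- pmax(1L, pos - half_lo)
  hi <- pmin(ref_length, pos + half_hi)
  win_sum <- cs[hi + 1L] - cs[lo]
  tibble::tibble(position = pos,
                 value = win_sum / (hi - lo + 1L) / total_reads)
}

#' Plot sliding-window coverage profiles
#'
#' @param profiles Tibble of profiles with columns `position`, `value`, and
#'   optionally `sample_id` / `region` for faceting or colour.
#' @param regions Optional region tibble drawn as shaded intervals.
#' @return A ggplot object.
#' @export
plot_coverage_profile <- function(profiles, regions = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(.data$position, .data$value))
  if (!is.null(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE, alpha = 0.12,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$region))
  }
  if ("sample_id" %in% names(profiles)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$sample_id))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "reference position (nt)",
                    y = "normalized 5'-end coverage") +
    ggplot2::theme_minimal()
}
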