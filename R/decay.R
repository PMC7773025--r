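#' Fit an exponential length-decay model to a read-length histogram
#'
#' Random nucleolytic degradation leaves more short fragments than long ones;
#' a read set dominated by degradation therefore shows counts falling off
#' exponentially with read length. The fit is ordinary least squares of
#' natural-log counts on length over the lengths with nonzero counts in
#' `fit_range`; `pearson_r` is the (signed) correlation of log-counts with
#' length, so clean decay gives r close to -1. The correlation on raw counts
#' is also reported, since on narrow windows both are informative.
#'
#' @param counts Either a named numeric vector (names = lengths) or a tibble
#'   with columns `length` and `count`.
#' @param fit_range Lengths eligible for the fit (default `17:29`).
#' @return A `decay_fit` object: `rate` (slope per nt), `intercept`,
#'   `pearson_r` (log counts), `pearson_r_raw` (raw counts), `n_points`,
#'   `excluded_zero_lengths`.
#' @export
#' @examples
#' L <- 17:29
#' fit_length_decay(setNames(round(1000 * exp(-0.3 * (L - 17))), L))
fit_length_decay <- function(counts, fit_range = 17:29) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$length)
  }
  lens <- as.integer(names(counts))
  keep <- lens %in% fit_range
  lens <- lens[keep]; cnt <- as.numeric(counts[keep])
  nz <- cnt > 0
  excluded <- sum(!nz)
  lens_nz <- lens[nz]; cnt_nz <- cnt[nz]
  if (length(lens_nz) < 3) {
    stop("fewer than 3 nonzero lengths in the fit range: insufficient data",
         call. = FALSE)
  }
  lc <- log(cnt_nz)
  if (sd(lc) == 0 || sd(lens_nz) == 0) {
    rate <- 0; intercept <- mean(lc); r <- 0
  } else {
    fit <- lm(lc ~ lens_nz)
    rate <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    r <- cor(lens_nz, lc)
  }
  r_raw <- if (sd(cnt_nz) == 0 || sd(lens_nz) == 0) 0 else cor(lens_nz, cnt_nz)
  structure(list(rate = rate, intercept = intercept, pearson_r = r,
                 pearson_r_raw = r_raw, n_points = length(lens_nz),
                 excluded_zero_lengths = excluded,
                 lengths = lens_nz, log_counts = lc),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> rate = %.4f /nt, |r| = %.4f (log), %.4f (raw), %d points\n",
              x$rate, abs(x$pearson_r), abs(x$pearson_r_raw), x$n_points))
  invisible(x)
}

#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("rate", "intercept"),
                 estimate = c(x$rate, x$intercept))
}

#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, intercept = x$intercept,
                 pearson_r = x$pearson_r, pearson_r_raw = x$pearson_r_raw,
                 n_points = x$n_points,
                 excluded_zero_lengths = x$excluded_zero_lengths)
}

#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- tibble::tibble(length = object$lengths,
                       log_count = object$log_counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$length, .data$log_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$rate,
                         linetype = 2) +
    ggplot2::labs(x = "read length (nt)", y = "log count",
                  title = sprintf("length decay: rate %.3f/nt, r = %.3f",
                                  object$rate, object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Per-sample decay fits from a size-class table
#'
#' @param tbl A `size_class_table` (counts are summed over regions and
#'   strands per length) or a tibble with `sample_id`, `length`, `count`.
#' @param fit_range Lengths eligible for the fit.
#' @return A tibble with one row per sample: the [glance()] columns of each
#'   fit.
#' @export
fit_decay_per_sample <- function(tbl, fit_range = 17:29) {
  df <- if (inherits(tbl, "size_class_table")) tbl$counts else tbl
  df <- dplyr::summarise(dplyr::group_by(df, .data$sample_id, .data$length),
                         count = sum(.data$count), .groups = "drop")
  dplyr::bind_rows(purrr::map(split(df, df$sample_id), function(d) {
    g <- glance(fit_length_decay(d, fit_range))
    dplyr::bind_cols(tibble::tibble(sample_id = d$sample_id[1]), g)
  }))
}
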