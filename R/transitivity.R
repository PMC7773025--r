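#' Detect transitivity from flank antisense read counts
#'
#' Secondary siRNAs produced by RDR6 amplification map antisense to the
#' target outside the sprayed trigger interval; antisense reads in the flanks
#' are therefore the fingerprint of genuine RNAi engagement. The wild-type
#' dsRNA-sprayed samples carry no target transgene and cannot produce
#' transitive reads, so their flank antisense counts estimate the
#' spray-degradation background. The target samples' total flank antisense
#' count is tested against a Poisson with that background rate (one-sided
#' exceedance), and the verdict additionally requires a mean of at least 5
#' antisense flank reads per sample so that 1–2 stray reads can never call
#' transitivity.
#'
#' @param tbl A multi-sample `size_class_table` whose `samples` (or a joined
#'   design) carry a `condition` column, or a tidy counts tibble with
#'   `sample_id`, `condition`, `region`, `strand`, `length`, `count`.
#' @param flank_regions Names of the flank regions (default
#'   `c("flank5", "flank3")`).
#' @param alpha Significance level.
#' @param target_condition,control_condition Condition labels of the
#'   target-carrying sprayed samples and the wild-type sprayed controls.
#' @return A `transitivity_result` list: per-sample flank counts, background
#'   rate, `p_value`, `verdict`.
#' @export
detect_transitivity <- function(tbl, flank_regions = c("flank5", "flank3"),
                                alpha = 0.05,
                                target_condition = "target_ds",
                                control_condition = "wildtype_ds") {
  check_alpha(alpha)
  df <- if (inherits(tbl, "size_class_table")) tidy(tbl) else tbl
  if (!"condition" %in% names(df)) {
    stop("a 'condition' column is required to locate the control samples",
         call. = FALSE)
  }
  if (!any(df$condition == control_condition)) {
    stop("missing control condition '", control_condition,
         "': cannot estimate the degradation background", call. = FALSE)
  }
  fl <- df[df$region %in% flank_regions, , drop = FALSE]
  per_sample <- dplyr::summarise(
    dplyr::group_by(fl, .data$sample_id, .data$condition, .data$strand),
    count = sum(.data$count), .groups = "drop")
  anti <- per_sample[per_sample$strand == "antisense", , drop = FALSE]
  tgt <- anti[anti$condition == target_condition, , drop = FALSE]
  ctl <- anti[anti$condition == control_condition, , drop = FALSE]
  bg_rate <- mean(ctl$count)          # background per sample
  obs_total <- sum(tgt$count)
  n_tgt <- nrow(tgt)
  lambda <- bg_rate * n_tgt
  p <- if (obs_total == 0) 1 else
    ppois(obs_total - 1, lambda, lower.tail = FALSE)
  mean_tgt <- if (n_tgt > 0) obs_total / n_tgt else 0
  verdict <- (p < alpha) && (mean_tgt >= 5)
  sense <- per_sample[per_sample$strand == "sense", , drop = FALSE]
  structure(list(
    antisense_flank_counts = anti, sense_flank_counts = sense,
    background_rate = bg_rate, observed_total = obs_total,
    n_target_samples = n_tgt, mean_target_count = mean_tgt,
    p_value = p, verdict = verdict, alpha = alpha
  ), class = "transitivity_result")
}

#' @export
print.transitivity_result <- function(x, ...) {
  cat(sprintf(paste0("<transitivity_result> verdict: %s\n",
                     "  antisense flank reads: %d over %d target sample(s) ",
                     "(mean %.2f), background rate %.2f/sample, p = %.4g\n"),
              ifelse(x$verdict, "TRANSITIVE", "not transitive"),
              x$observed_total, x$n_target_samples, x$mean_target_count,
              x$background_rate, x$p_value))
  invisible(x)
}

#' @method glance transitivity_result
#' @export
glance.transitivity_result <- function(x, ...) {
  tibble::tibble(observed_total = x$observed_total,
                 mean_target_count = x$mean_target_count,
                 background_rate = x$background_rate,
                 p_value = x$p_value, verdict = x$verdict)
}

#' Phasing score of trigger-mapped reads
#'
#' Processive dicing from a fixed end places siRNA 5' ends on a register of
#' period equal to the siRNA length. The score is the maximal fraction of
#' 5' ends (among reads of exactly `register_length` nt inside the trigger)
#' falling on one of the `register_length` possible phase offsets; its
#' p-value is a one-sided binomial test of that offset's occupancy against
#' the uniform rate `1/register_length`, Bonferroni-corrected for the
#' `register_length` offsets examined. With fewer than 10 eligible reads the
#' score is still reported but the p-value is suppressed as underpowered.
#'
#' @param mapped Uniquely mapped reads ([map_reads()] output).
#' @param trigger One-row trigger region (`start`, `end`).
#' @param register_length Register period in nt (21 or 22).
#' @return A `phasing_result` list: `score`, `p_value` (`NA` if underpowered),
#'   `n_reads`, `best_offset`.
#' @export
phasing_score <- function(mapped, trigger, register_length = 22L) {
  uniq <- mapped[mapped$n_placements == 1, , drop = FALSE]
  fp <- five_prime_pos(uniq$start, uniq$length, uniq$strand)
  in_trig <- fp >= trigger$start & fp <= trigger$end &
    uniq$length == register_length
  fp <- fp[in_trig]
  n <- length(fp)
  if (n == 0) {
    return(structure(list(score = NA_real_, p_value = NA_real_, n_reads = 0L,
                          best_offset = NA_integer_,
                          register_length = register_length),
                     class = "phasing_result"))
  }
  offs <- (fp - trigger$start) %% register_length
  occ <- tabulate(offs + 1L, nbins = register_length)
  best <- which.max(occ)
  score <- occ[best] / n
  p <- if (n < 10) NA_real_ else {
    min(1, register_length *
          binom.test(occ[best], n, p = 1 / register_length,
                     alternative = "greater")$p.value)
  }
  structure(list(score = score, p_value = p, n_reads = n,
                 best_offset = as.integer(best - 1L),
                 register_length = as.integer(register_length)),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat(sprintf("<phasing_result> register %d nt: score %.3f (n = %d), p = %s\n",
              x$register_length, x$score, x$n_reads,
              ifelse(is.na(x$p_value), "NA (underpowered)",
                     format(x$p_value, digits = 4))))
  invisible(x)
}

#' Fisher test of long/short read ratio inside vs outside the trigger
#'
#' Tests whether the ratio of long reads (> 24 nt) to short reads (< 25 nt)
#' differs between the trigger interval and the rest of the reference; a
#' flatter length profile outside the trigger (odds ratio > 1 for outside
#' long reads) indicates that outside reads come from a different decay
#' process than trigger reads. Two-sided Fisher's exact test; the odds
#' ratio is the plain cross-product of cells, not the conditional MLE.
#'
#' @param tbl A `size_class_table` (or tidy counts tibble with `region`,
#'   `length`, `count`).
#' @param inside Region name(s) forming the trigger stratum
#'   (default `"trigger"`).
#' @param outside Region name(s) for the outside stratum; default all other
#'   regions except `"outside"`.
#' @param long_threshold Reads strictly longer than this are "long"
#'   (default 24).
#' @return A list `odds_ratio`, `p_value`, `table` (the 2x2 matrix),
#'   `undefined` (flag when a margin is empty).
#' @export
long_short_ratio_test <- function(tbl, inside = "trigger", outside = NULL,
                                  long_threshold = 24L) {
  df <- if (inherits(tbl, "size_class_table")) tbl$counts else tbl
  if (is.null(outside)) outside <- setdiff(unique(df$region),
                                           c(inside, "outside"))
  m <- matrix(c(
    sum(df$count[df$region %in% inside & df$length > long_threshold]),
    sum(df$count[df$region %in% inside & df$length <= long_threshold]),
    sum(df$count[df$region %in% outside & df$length > long_threshold]),
    sum(df$count[df$region %in% outside & df$length <= long_threshold])
  ), nrow = 2, dimnames = list(c("long", "short"), c("inside", "outside")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, table = m,
                undefined = TRUE))
  }
  # cross-product odds ratio: (outside long / outside short) over inside
  or <- (m["long", "outside"] * m["short", "inside"]) /
    (m["long", "inside"] * m["short", "outside"])
  p <- fisher.test(m)$p.value
  list(odds_ratio = or, p_value = p, table = m, undefined = FALSE)
}
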