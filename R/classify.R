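#' Classify a sample set as DCL-processed or degradation-only
#'
#' Combines the statistical sub-results into a verdict on whether the sprayed
#' dsRNA engaged the RNAi machinery:
#'
#' * `DCL_PROCESSED` if any canonical silencing size (21/22/24 nt) is
#'   significantly *enriched* in the target condition versus the wild-type
#'   sprayed control, or the transitivity verdict is positive, or phasing is
#'   significant.
#' * `DEGRADATION_ONLY` if none of the above holds and the length-decay fits
#'   of the dsRNA-sprayed samples are convincingly exponential: the mean
#'   `|pearson_r|` within each sprayed condition is at least `decay_r_min`.
#'   (The condition-level mean is used because replicate-level correlations
#'   on narrow length windows are noisy even under clean decay.)
#' * `INCONCLUSIVE` otherwise.
#'
#' @param enrichment An `enrichment_result` from [compare_size_classes_raw()]
#'   (target vs wild-type, raw counts).
#' @param decay_fits Per-sample decay fits from [fit_decay_per_sample()],
#'   with a `condition` column (water-sprayed samples are ignored for the
#'   decay criterion).
#' @param transitivity A `transitivity_result`, or `NULL` when flank data are
#'   unavailable (treated as no transitivity evidence, and noted).
#' @param phasing A `phasing_result`, or `NULL`.
#' @param alpha Significance level used for the phasing check.
#' @param silencing_sizes Canonical DCL product sizes (default 21, 22, 24 nt).
#' @param decay_r_min Minimum condition-mean `|pearson_r|` for the
#'   degradation call (default 0.9).
#' @return A `signature_report` list with the verdict, the evidence flags,
#'   all sub-results and the parameters used.
#' @export
classify_signature <- function(enrichment, decay_fits, transitivity = NULL,
                               phasing = NULL, alpha = 0.05,
                               silencing_sizes = c(21L, 22L, 24L),
                               decay_r_min = 0.9) {
  missing <- c(
    if (is.null(enrichment) || nrow(enrichment) == 0) "enrichment",
    if (is.null(decay_fits) || nrow(decay_fits) == 0) "decay_fits"
  )
  if (length(missing)) {
    stop("missing sub-result(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sil <- enrichment[enrichment$length %in% silencing_sizes, , drop = FALSE]
  enriched_sig <- any(sil$significant & sil$direction == "enriched")
  transitive <- !is.null(transitivity) && isTRUE(transitivity$verdict)
  phased <- !is.null(phasing) && !is.na(phasing$p_value) &&
    phasing$p_value < alpha
  df <- decay_fits
  if ("condition" %in% names(df)) {
    # the water control is a normalization denominator, not a decay subject
    df <- df[df$condition != "target_water", , drop = FALSE]
    cond_r <- tapply(abs(df$pearson_r), df$condition, mean)
  } else {
    cond_r <- mean(abs(df$pearson_r))
  }
  decay_ok <- all(cond_r >= decay_r_min)
  classification <- if (enriched_sig || transitive || phased) {
    "DCL_PROCESSED"
  } else if (decay_ok) {
    "DEGRADATION_ONLY"
  } else {
    "INCONCLUSIVE"
  }
  structure(list(
    classification = classification,
    evidence = list(
      silencing_size_enriched = enriched_sig,
      transitivity = transitive,
      phasing_significant = phased,
      decay_consistent = decay_ok,
      condition_mean_abs_r = cond_r
    ),
    enrichment = enrichment,
    decay_fits = decay_fits,
    transitivity_result = transitivity,
    phasing_result = phasing,
    params = list(alpha = alpha, silencing_sizes = silencing_sizes,
                  decay_r_min = decay_r_min),
    notes = c(
      if (is.null(transitivity)) "no flank data: transitivity not assessed",
      if (is.null(phasing)) "no position data: phasing not assessed"
    )
  ), class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("<signature_report> classification:", x$classification, "\n")
  ev <- x$evidence
  cat(sprintf("  silencing-size enrichment: %s | transitivity: %s | phasing: %s\n",
              ev$silencing_size_enriched, ev$transitivity,
              ev$phasing_significant))
  cat(sprintf("  decay consistent (condition mean |r| >= %.2f): %s [%s]\n",
              x$params$decay_r_min, ev$decay_consistent,
              paste(sprintf("%s=%.3f", names(ev$condition_mean_abs_r),
                            ev$condition_mean_abs_r), collapse = ", ")))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @method glance signature_report
#' @export
glance.signature_report <- function(x, ...) {
  tibble::tibble(
    classification = x$classification,
    silencing_size_enriched = x$evidence$silencing_size_enriched,
    transitivity = x$evidence$transitivity,
    phasing_significant = x$evidence$phasing_significant,
    decay_consistent = x$evidence$decay_consistent,
    min_condition_mean_abs_r = min(x$evidence$condition_mean_abs_r)
  )
}

#' @method tidy signature_report
#' @export
tidy.signature_report <- function(x, ...) {
  tibble::as_tibble(x$enrichment)
}
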