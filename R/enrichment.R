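#' Per-length Student t comparison of raw size-class counts
#'
#' Compares two conditions length by length with a two-sided pooled-variance
#' Student t test on raw counts (no multiplicity correction: each length is
#' annotated on its own, as in per-length figure annotations). When both
#' groups have zero variance and equal means the p-value is 1 by convention.
#'
#' @param data Tibble with columns `sample_id`, `condition`, `length`,
#'   `count` (counts already aggregated per sample and length).
#' @param condition_a,condition_b The two condition labels to compare
#'   (direction is reported for A relative to B).
#' @param alpha Significance level (default 0.05).
#' @return An `enrichment_result` tibble: per length, group means, `statistic`,
#'   `p_value`, `significant`, `direction` (`enriched`/`depleted`/`none`).
#' @export
compare_size_classes_raw <- function(data, condition_a = "target_ds",
                                     condition_b = "wildtype_ds",
                                     alpha = 0.05) {
  check_alpha(alpha)
  dat <- data[data$condition %in% c(condition_a, condition_b), , drop = FALSE]
  dat$.grp <- ifelse(dat$condition == condition_a, "a", "b")
  smry <- dplyr::summarise(
    dplyr::group_by(dat, .data$length, .data$.grp),
    n = dplyr::n(), mean = mean(.data$count), var = stats::var(.data$count),
    .groups = "drop")
  wide <- tidyr::pivot_wider(smry, names_from = ".grp",
                             values_from = c("n", "mean", "var"))
  if (!all(c("n_a", "n_b") %in% names(wide)) ||
      any(is.na(wide$n_a)) || any(is.na(wide$n_b)) ||
      any(wide$n_a < 2) || any(wide$n_b < 2)) {
    stop("need >= 2 replicates per group at every length", call. = FALSE)
  }
  sp2 <- ((wide$n_a - 1) * wide$var_a + (wide$n_b - 1) * wide$var_b) /
    (wide$n_a + wide$n_b - 2)
  tstat <- (wide$mean_a - wide$mean_b) /
    sqrt(sp2 * (1 / wide$n_a + 1 / wide$n_b))
  p <- 2 * pt(-abs(tstat), df = wide$n_a + wide$n_b - 2)
  # degenerate strata: zero pooled variance
  zero <- sp2 == 0
  eqm <- zero & (wide$mean_a == wide$mean_b)
  tstat[eqm] <- 0; p[eqm] <- 1
  nem <- zero & !eqm
  tstat[nem] <- Inf * sign(wide$mean_a - wide$mean_b)[nem]; p[nem] <- 0
  res <- tibble::tibble(length = wide$length, mean_a = wide$mean_a,
                        mean_b = wide$mean_b, statistic = tstat, p_value = p)
  res <- res[order(res$length), ]
  res$significant <- res$p_value < alpha
  res$direction <- dplyr::case_when(
    !res$significant & res$mean_a == res$mean_b ~ "none",
    res$mean_a > res$mean_b ~ "enriched",
    res$mean_a < res$mean_b ~ "depleted",
    TRUE ~ "none"
  )
  res$direction[res$mean_a == res$mean_b] <- "none"
  class(res) <- c("enrichment_result", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "mode") <- "raw_t"
  res
}

pooled_t <- function(a, b, L) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(length = L, mean_a = mean(a), mean_b = mean(b),
                            statistic = 0, p_value = 1))
    }
    return(tibble::tibble(length = L, mean_a = mean(a), mean_b = mean(b),
                          statistic = Inf * sign(mean(a) - mean(b)),
                          p_value = 0))
  }
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), df = na + nb - 2)
  tibble::tibble(length = L, mean_a = mean(a), mean_b = mean(b),
                 statistic = tstat, p_value = p)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
}

#' Normalize per-length counts to a control sample
#'
#' Elementwise ratio of counts to the control's counts at the same length
#' (the water-sprayed target line serves as the degradation baseline).
#' Control zeros yield an `NA` ratio flagged in `undefined`, never a silent
#' infinity.
#'
#' @param counts Named numeric vector (names = lengths) or tibble
#'   (`length`, `count`).
#' @param control Control counts in the same form; every length in `counts`
#'   must be present.
#' @return A tibble `length`, `count`, `control`, `ratio`, `undefined`.
#' @export
normalize_to_control <- function(counts, control) {
  cv <- as_length_vector(counts)
  ct <- as_length_vector(control)
  miss <- setdiff(names(cv), names(ct))
  if (length(miss)) {
    stop("control counts missing for length(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ct <- ct[names(cv)]
  if (all(ct == 0)) {
    stop("all control counts are zero: normalization impossible", call. = FALSE)
  }
  tibble::tibble(
    length = as.integer(names(cv)),
    count = as.numeric(cv),
    control = as.numeric(ct),
    ratio = unname(ifelse(ct == 0, NA_real_, cv / ct)),
    undefined = unname(ct == 0)
  )
}

as_length_vector <- function(x) {
  if (is.data.frame(x)) setNames(x$count, x$length) else x
}

#' Functional normalization of per-sample counts
#'
#' Divides each sample's counts by a per-sample functional denominator:
#' either the reads mapping to miR159 (`scheme = "mir159"`) — an endogenous
#' microRNA processed by the same machinery — or the sample's total 24-nt
#' read count (`scheme = "all_24nt"`), a global proxy for RNAi-machinery
#' output. Both denominators scale with depth, making samples comparable.
#'
#' @param counts Numeric vector (or tibble `length`, `count`) for one sample.
#' @param reference_counts The sample's denominator: miR159-mapped read count
#'   or total 24-nt read count, per the scheme.
#' @param scheme `"mir159"` or `"all_24nt"`.
#' @return Normalized counts in the same shape as `counts`.
#' @export
functional_normalize <- function(counts, reference_counts,
                                 scheme = c("mir159", "all_24nt")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(reference_counts) || length(reference_counts) != 1 ||
      reference_counts <= 0) {
    stop("zero or invalid denominator for scheme '", scheme, "'",
         call. = FALSE)
  }
  if (is.data.frame(counts)) {
    counts$count <- counts$count / reference_counts
    counts
  } else {
    counts / reference_counts
  }
}

#' Per-length one-way ANOVA on control-normalized ratios
#'
#' For each length, fits a one-way ANOVA of the normalized values across
#' conditions, then performs all pairwise comparisons at a
#' Bonferroni-adjusted alpha and summarises them as a compact letter display
#' (conditions sharing a letter are not significantly different).
#'
#' @param data Tibble with columns `condition`, `length`, `value`
#'   (the control-normalized ratio per replicate); >= 2 conditions with >= 2
#'   replicates each.
#' @param alpha Family significance level (default 0.05).
#' @return An `enrichment_result` tibble: per length and condition, the group
#'   mean, the ANOVA `p_value`, and `letters` (compact letter display).
#' @export
compare_normalized_anova <- function(data, alpha = 0.05) {
  check_alpha(alpha)
  conds <- unique(data$condition)
  if (length(conds) < 2) {
    stop("at least two conditions are required for ANOVA", call. = FALSE)
  }
  res <- purrr::map_dfr(sort(unique(data$length)), function(L) {
    d <- data[data$length == L, , drop = FALSE]
    d$condition <- factor(d$condition, levels = conds)
    if (any(table(d$condition) < 2)) {
      stop("need >= 2 replicates per condition at length ", L, call. = FALSE)
    }
    p_anova <- if (sd(d$value) == 0) 1 else {
      fit <- aov(value ~ condition, data = d)
      summary(fit)[[1]][["Pr(>F)"]][1]
    }
    sig_pairs <- pairwise_bonferroni(d$value, d$condition, alpha)
    letters <- compact_letters(levels(d$condition), sig_pairs)
    means <- tapply(d$value, d$condition, mean)
    tibble::tibble(length = L, condition = names(means),
                   mean = as.numeric(means),
                   p_value = p_anova,
                   letters = unname(letters[names(means)]))
  })
  class(res) <- c("enrichment_result", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "mode") <- "anova_bonferroni"
  res
}

# pairwise pooled-t comparisons at Bonferroni-adjusted alpha; returns a matrix
# of logical "significantly different" flags
pairwise_bonferroni <- function(value, group, alpha) {
  lev <- levels(group)
  k <- length(lev)
  m <- k * (k - 1) / 2
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- pooled_t(value[group == lev[i]], value[group == lev[j]], 0)$p_value
      sig[i, j] <- sig[j, i] <- (p < alpha / m)
    }
  }
  sig
}

# insert-and-absorb algorithm for a compact letter display: groups sharing a
# letter are not significantly different
compact_letters <- function(groups, sig) {
  sets <- list(groups)  # start with all groups in one letter set
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !sig[groups[i], groups[j]]) next
      for (s in seq_along(sets)) {
        if (all(c(groups[i], groups[j]) %in% sets[[s]])) {
          # split the offending set into two copies, one without each member
          sets <- c(sets, list(setdiff(sets[[s]], groups[j])))
          sets[[s]] <- setdiff(sets[[s]], groups[i])
        }
      }
      # absorb sets contained in another set
      sets <- unique(purrr::map(sets, sort))
      keep <- vapply(seq_along(sets), function(s) {
        !any(vapply(seq_along(sets), function(t)
          t != s && all(sets[[s]] %in% sets[[t]]), logical(1)))
      }, logical(1))
      sets <- sets[keep]
    }
  }
  out <- setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}

#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  mode <- attr(object, "mode")
  if (identical(mode, "raw_t")) {
    df <- tidyr::pivot_longer(object, c("mean_a", "mean_b"),
                              names_to = "group", values_to = "mean")
    ggplot2::ggplot(df, ggplot2::aes(factor(.data$length), .data$mean,
                                     fill = .data$group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "read length (nt)", y = "mean count") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(factor(.data$length), .data$mean,
                                         fill = .data$condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                         position = ggplot2::position_dodge(width = 0.9),
                         vjust = -0.3) +
      ggplot2::labs(x = "read length (nt)", y = "normalized ratio") +
      ggplot2::theme_minimal()
  }
}
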