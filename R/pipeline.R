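#' Load the published seven-sample count-table fixture
#'
#' The package ships the printed per-sample totals and 20–25-nt counts of
#' reads matching the target region of interest (ROI) for the seven-sample
#' spray experiment: three dsRNA-sprayed target-line replicates, three
#' dsRNA-sprayed wild-type replicates and one water-sprayed target-line
#' sample. Strand and within-ROI position were not published, so the counts
#' carry `region = "ROI"` and `strand = "all"`. The published table leaves
#' its "reads matching the ROI" column blank; [tidy()] of the returned table
#' exposes `roi_sum_20_25` (the row sum of the printed size columns) as the
#' package's labelled interpretation.
#'
#' @return A `size_class_table` with a `condition` column in `$samples`.
#' @export
load_published_counts <- function() {
  path <- system.file("extdata", "published_srna_counts.tsv", package = "srnasig")
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  counts <- tidyr::pivot_longer(
    wide, dplyr::starts_with("nt"),
    names_to = "length", names_prefix = "nt", names_transform = as.integer,
    values_to = "count")
  counts <- tibble::tibble(sample_id = counts$sample_id, region = "ROI",
                           strand = "all", length = counts$length,
                           count = counts$count)
  samples <- tibble::tibble(
    sample_id = wide$sample_id, condition = wide$condition,
    total_reads = wide$total_reads,
    mapped_reads = NA_integer_, ambiguous = NA_integer_,
    unmapped = NA_integer_,
    out_of_range = NA_integer_,
    roi_sum_20_25 = as.integer(rowSums(wide[, grep("^nt", names(wide))]))
  )
  new_size_class_table(counts, samples)
}

#' Statistics and classification from a pre-counted size-class table
#'
#' The table-based entry point: runs the statistical battery that does not
#' need positions — per-length Student t on raw counts, control-normalized
#' one-way ANOVA with Bonferroni letters (in both orientations: conditions
#' compared within each length, and lengths within each condition), decay
#' fits per sample, transitivity when strand-resolved flank counts are
#' present — and classifies the result.
#'
#' @param tbl A multi-sample `size_class_table` whose `$samples` carry a
#'   `condition` column (see [load_published_counts()]).
#' @param alpha Significance level (default 0.05).
#' @param fit_range Lengths for the decay fit; defaults to the lengths
#'   present in the table.
#' @param phasing Optional `phasing_result` computed from positional data.
#' @return A `signature_report`; the ANOVA tables ride along in
#'   `$normalized_anova` and `$normalized_anova_flipped`.
#' @export
analyze_counts <- function(tbl, alpha = 0.05, fit_range = NULL,
                           phasing = NULL) {
  df <- tidy(tbl)
  if (!"condition" %in% names(df)) {
    stop("the table's samples need a 'condition' column", call. = FALSE)
  }
  if (nrow(df) == 0 || all(df$count == 0)) {
    stop("empty count table", call. = FALSE)
  }
  per_len <- dplyr::summarise(
    dplyr::group_by(df, .data$sample_id, .data$condition, .data$length),
    count = sum(.data$count), .groups = "drop")
  if (is.null(fit_range)) fit_range <- sort(unique(per_len$length))
  enr <- compare_size_classes_raw(per_len, alpha = alpha)
  # control-normalized ratios: denominator = water-control mean per length
  ctrl <- dplyr::summarise(
    dplyr::group_by(per_len[per_len$condition == "target_water", ], .data$length),
    control = mean(.data$count), .groups = "drop")
  anova_cond <- NULL; anova_len <- NULL; norm <- NULL
  if (nrow(ctrl) > 0 && any(ctrl$control > 0)) {
    norm <- dplyr::inner_join(
      per_len[per_len$condition != "target_water", ], ctrl, by = "length")
    norm$value <- ifelse(norm$control == 0, NA_real_,
                         norm$count / norm$control)
    ok <- !is.na(norm$value)
    anova_cond <- compare_normalized_anova(norm[ok, ], alpha = alpha)
    flipped <- tibble::tibble(condition = paste0("nt", norm$length[ok]),
                              length = match(norm$condition[ok],
                                             unique(norm$condition[ok])),
                              value = norm$value[ok])
    anova_len <- compare_normalized_anova(flipped, alpha = alpha)
    anova_len$condition_label <- unique(norm$condition[ok])[anova_len$length]
  }
  fits <- fit_decay_per_sample(tbl, fit_range = fit_range)
  fits <- dplyr::left_join(fits, tbl$samples[, c("sample_id", "condition")],
                           by = "sample_id")
  trans <- NULL
  has_strands <- any(df$strand %in% c("sense", "antisense")) &&
    any(!df$region %in% c("ROI", "outside"))
  if (has_strands) {
    trans <- detect_transitivity(tbl, alpha = alpha)
  }
  report <- classify_signature(enr, fits, transitivity = trans,
                               phasing = phasing, alpha = alpha)
  report$normalized_anova <- anova_cond
  report$normalized_anova_flipped <- anova_len
  report$normalized_ratios <- norm
  n_water <- sum(tbl$samples$condition == "target_water")
  if (n_water == 1) {
    report$notes <- c(report$notes,
                      "single-replicate water control: normalization denominator is statistically fragile")
  }
  report
}

default_configs <- function(scenario = c("negative", "positive")) {
  scenario <- match.arg(scenario)
  base <- sim_config()
  if (scenario == "negative") {
    list(target_ds = base, wildtype_ds = base,
         target_water = sim_config(strand_mode = "sense_only"))
  } else {
    list(
      target_ds = sim_config(dcl_fraction = 0.3, transitive_fraction = 0.05),
      wildtype_ds = sim_config(dcl_fraction = 0.3),
      target_water = sim_config(strand_mode = "sense_only")
    )
  }
}

#' Run the full pipeline: simulate/read, count, test, classify
#'
#' Orchestrates the end-to-end analysis from one configuration: obtain reads
#' (seeded simulation, or FASTQ files with optional adapter trimming), filter
#' to the 17–29-nt window, map exactly to the reference, count by region,
#' strand and size, run the statistical battery and classify. All
#' intermediate tables are written to `outdir` when given
#' (`report.json`, `enrichment_raw.tsv`, `enrichment_normalized.tsv`,
#' `coverage_profiles.tsv`, `transitivity.tsv`, `qc_lengths.tsv`).
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `mode` (`"simulate"` or `"fastq"`), `seed`, `scenario`
#'   (`"negative"`/`"positive"`, simulate mode), `sim` (per-condition
#'   [sim_config()] overrides), `reads` (named FASTQ paths, fastq mode),
#'   `adapter` (optional 3' adapter), `reference` / `regions` (paths, or
#'   `NULL` for the defaults), `design` (or `NULL` for [default_design()]),
#'   and `params` (`alpha`, `window`, `lengths`, `fit_range`).
#' @param outdir Output directory, or `NULL` to skip file output.
#' @return A `run_report` list: the `signature_report`, QC tibbles, the
#'   count table, profiles and provenance.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "simulate"
  seed <- as.integer(config$seed %||% 0L)
  params <- modifyList(list(alpha = 0.05, window = 10L, lengths = 20:25,
                            fit_range = 17:29), config$params %||% list())
  if (length(params$lengths) == 2 && params$lengths[2] > params$lengths[1] + 1) {
    params$lengths <- params$lengths[1]:params$lengths[2]
  }
  if (length(params$fit_range) == 2) {
    params$fit_range <- params$fit_range[1]:params$fit_range[2]
  }
  digests <- character()
  ref <- if (is.null(config$reference)) default_reference() else {
    digests["reference"] <- unname(tools::md5sum(config$reference))
    read_reference_fasta(config$reference)
  }
  regions <- if (is.null(config$regions)) default_regions(ref$length) else {
    digests["regions"] <- unname(tools::md5sum(config$regions))
    read_regions(config$regions)
  }
  validate_regions(regions, ref$length)
  design <- if (is.null(config$design)) default_design() else {
    des <- config$design
    if (!is.data.frame(des)) des <- dplyr::bind_rows(purrr::map(des, tibble::as_tibble))
    des
  }
  # --- stage: reads -------------------------------------------------------
  reads <- tryCatch({
    if (mode == "simulate") {
      cfgs <- default_configs(config$scenario %||% "negative")
      for (cond in names(config$sim %||% list())) {
        cfgs[[cond]] <- do.call(sim_config, modifyList(
          unclass(cfgs[[cond]]), config$sim[[cond]]))
      }
      simulate_experiment(design, cfgs, ref, regions, seed = seed)
    } else {
      paths <- config$reads
      missing <- paths[!file.exists(unlist(paths))]
      if (length(missing)) {
        stop("FASTQ file(s) not found: ",
             paste(unlist(missing), collapse = ", "), call. = FALSE)
      }
      for (s in names(paths)) digests[[paste0("reads.", s)]] <-
          unname(tools::md5sum(paths[[s]]))
      purrr::map(paths, read_fastq)
    }
  }, error = function(e) stop("stage 'reads': ", conditionMessage(e),
                              call. = FALSE))
  # --- stage: trim + filter ----------------------------------------------
  reads <- tryCatch({
    purrr::map(reads, function(r) {
      if (!is.null(config$adapter)) r <- trim_adapter(r, config$adapter)
      filter_by_length(r)
    })
  }, error = function(e) stop("stage 'trim/filter': ", conditionMessage(e),
                              call. = FALSE))
  # --- stage: map + count -------------------------------------------------
  staged <- tryCatch({
    purrr::imap(reads, function(r, sid) {
      m <- map_reads(r, ref)
      tab <- count_by_size_and_region(m, regions, lengths = params$lengths,
                                      sample_id = sid)
      list(mapped = m, table = tab, reads = r)
    })
  }, error = function(e) stop("stage 'map/count': ", conditionMessage(e),
                              call. = FALSE))
  tbl <- bind_size_tables(purrr::map(staged, "table"))
  tbl$samples <- dplyr::left_join(tbl$samples,
                                  design[, c("sample_id", "condition")],
                                  by = "sample_id")
  # --- stage: statistics --------------------------------------------------
  report <- tryCatch({
    trigger <- regions[regions$region == "trigger", ]
    target_ids <- design$sample_id[design$condition == "target_ds"]
    pooled <- dplyr::bind_rows(purrr::map(staged[target_ids], "mapped"))
    phas <- phasing_best(pooled, trigger)
    mapped_hist <- purrr::imap_dfr(staged, function(x, sid) {
      u <- x$mapped[x$mapped$n_placements == 1, ]
      tibble::tibble(sample_id = sid, length = u$length)
    })
    hist_tbl <- dplyr::count(mapped_hist, .data$sample_id, .data$length,
                             name = "count")
    fits <- fit_decay_per_sample(hist_tbl, fit_range = params$fit_range)
    fits <- dplyr::left_join(fits, design[, c("sample_id", "condition")],
                             by = "sample_id")
    enr_input <- dplyr::summarise(
      dplyr::group_by(tidy(tbl), .data$sample_id, .data$condition,
                      .data$length),
      count = sum(.data$count), .groups = "drop")
    enr <- compare_size_classes_raw(enr_input, alpha = params$alpha)
    trans <- detect_transitivity(tbl, alpha = params$alpha)
    ls_test <- long_short_ratio_test(tbl)
    rep <- classify_signature(enr, fits, transitivity = trans,
                              phasing = phas, alpha = params$alpha)
    rep$long_short <- ls_test
    rep
  }, error = function(e) stop("stage 'stats': ", conditionMessage(e),
                              call. = FALSE))
  # --- QC + profiles ------------------------------------------------------
  qc <- purrr::imap_dfr(reads, function(r, sid) {
    h <- dplyr::count(r, .data$length, name = "count")
    h$sample_id <- sid
    h
  })
  profiles <- purrr::imap_dfr(staged, function(x, sid) {
    purrr::map_dfr(c("sense", "antisense"), function(str) {
      pr <- sliding_window_profile(x$mapped, ref$length,
                                   window = params$window, strand = str)
      pr$strand <- str; pr$sample_id <- sid
      pr
    })
  })
  out <- structure(list(
    report = report, table = tbl, qc_lengths = qc, profiles = profiles,
    provenance = list(package_version = as.character(utils::packageVersion("srnasig")),
                      seed = seed, mode = mode, params = params,
                      input_digests = as.list(digests),
                      config = config)
  ), class = "run_report")
  if (!is.null(outdir)) write_run_report(out, outdir)
  out
}

# evaluate both canonical registers, Bonferroni over the two, keep the best
phasing_best <- function(mapped, trigger, registers = c(21L, 22L)) {
  res <- purrr::map(registers, ~ phasing_score(mapped, trigger, .x))
  ps <- purrr::map_dbl(res, "p_value")
  if (all(is.na(ps))) return(res[[which(registers == 22L)]])
  best <- which.min(ps)
  out <- res[[best]]
  out$p_value <- min(1, out$p_value * length(registers))
  out
}

#' Write a run report and its per-analysis TSVs
#'
#' @param x A `run_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(x, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  rep <- x$report
  readr::write_tsv(tibble::as_tibble(rep$enrichment),
                   file.path(outdir, "enrichment_raw.tsv"))
  if (!is.null(rep$normalized_anova)) {
    readr::write_tsv(tibble::as_tibble(rep$normalized_anova),
                     file.path(outdir, "enrichment_normalized.tsv"))
  }
  readr::write_tsv(x$profiles, file.path(outdir, "coverage_profiles.tsv"))
  if (!is.null(rep$transitivity_result)) {
    readr::write_tsv(glance(rep$transitivity_result),
                     file.path(outdir, "transitivity.tsv"))
  }
  readr::write_tsv(x$qc_lengths, file.path(outdir, "qc_lengths.tsv"))
  write_size_table(x$table, file.path(outdir, "size_class_table.tsv"))
  body <- list(
    classification = rep$classification,
    evidence = rep$evidence,
    params = rep$params,
    decay_fits = rep$decay_fits,
    enrichment = rep$enrichment,
    transitivity = if (!is.null(rep$transitivity_result))
      glance(rep$transitivity_result),
    phasing = if (!is.null(rep$phasing_result))
      rep$phasing_result[c("score", "p_value", "n_reads", "register_length")],
    long_short = if (!is.null(rep$long_short))
      rep$long_short[c("odds_ratio", "p_value", "undefined")],
    notes = rep$notes,
    provenance = x$provenance
  )
  jsonlite::write_json(body, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "mode", x$provenance$mode, "\n")
  print(x$report)
  invisible(x)
}
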