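#' Simulation configuration for one sample condition
#'
#' Bundles the knobs of the synthetic small-RNA read generator. The defaults
#' describe the negative scenario the study observed: the sprayed dsRNA is
#' degraded (exponential read-length decay) but not diced, so `dcl_fraction`
#' and `transitive_fraction` are 0.
#'
#' @param n_reads Reads to generate per sample.
#' @param decay_rate Per-nt exponential rate (lambda >= 0) of the degradation
#'   fragment-length law; counts fall off as `exp(-lambda * (L - min_len))`.
#' @param dcl_fraction Proportion of reads drawn from the DCL (dicing) model.
#' @param size_probs Named probabilities over the canonical siRNA sizes,
#'   e.g. `c("21" = .4, "22" = .4, "24" = .2)`; must sum to 1.
#' @param phase_fraction Proportion of DCL reads placed on the phased register.
#' @param transitive_fraction Proportion of reads that are antisense secondary
#'   siRNAs in the flanks (transitivity); only meaningful for target-carrying
#'   dsRNA-sprayed samples.
#' @param strand_mode `"both"` for dsRNA degradation (either strand) or
#'   `"sense_only"` for mRNA decay.
#' @param length_window Integer `c(min_len, max_len)`; defaults to the 17–29 nt
#'   QC window.
#' @param background_fraction Proportion of reads from the off-target
#'   background pool (including the miR159 spike-in decoy).
#' @param mir159_weight Share of background reads that are exact copies of the
#'   21-nt miR159 decoy.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 20000L,
                       decay_rate = 0.25,
                       dcl_fraction = 0,
                       size_probs = c("21" = 0.4, "22" = 0.4, "24" = 0.2),
                       phase_fraction = 0.7,
                       transitive_fraction = 0,
                       strand_mode = c("both", "sense_only"),
                       length_window = c(17L, 29L),
                       background_fraction = 0.2,
                       mir159_weight = 0.5) {
  strand_mode <- match.arg(strand_mode)
  fr <- c(dcl_fraction, transitive_fraction, background_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("fractions must lie in [0, 1] and jointly sum to <= 1", call. = FALSE)
  }
  if (abs(sum(size_probs) - 1) > 1e-8) {
    stop("size_probs must sum to 1", call. = FALSE)
  }
  if (decay_rate < 0) stop("decay_rate must be >= 0", call. = FALSE)
  if (phase_fraction < 0 || phase_fraction > 1) {
    stop("phase_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(length_window) == 2, length_window[1] <= length_window[2])
  structure(list(
    n_reads = as.integer(n_reads), decay_rate = decay_rate,
    dcl_fraction = dcl_fraction, size_probs = size_probs,
    phase_fraction = phase_fraction, transitive_fraction = transitive_fraction,
    strand_mode = strand_mode, length_window = as.integer(length_window),
    background_fraction = background_fraction, mir159_weight = mir159_weight
  ), class = "sim_config")
}

#' The seven-sample experimental design
#'
#' Three dsRNA-sprayed target-carrying replicates, three dsRNA-sprayed
#' wild-type replicates and one water-sprayed target-carrying sample.
#'
#' @return A tibble with columns `sample_id`, `condition`, `replicate`.
#' @export
default_design <- function() {
  tibble::tibble(
    sample_id = c("16C-ds_1", "16C-ds_2", "16C-ds_3",
                  "WT-ds_1", "WT-ds_2", "WT-ds_3", "16C-w"),
    condition = c(rep("target_ds", 3), rep("wildtype_ds", 3), "target_water"),
    replicate = c(1L, 2L, 3L, 1L, 2L, 3L, 1L)
  )
}

# canonical 21-nt plant miR159 sequence used as the spike-in decoy
MIR159_DECOY <- "TTTGGATTGAAGGGAGCTCTA"

# sample() treats a length-1 x as 1:x; guard against that
sample_from <- function(x, n, prob = NULL) {
  if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE, prob = prob)
}

sample_decay_lengths <- function(n, decay_rate, min_len, max_len) {
  lens <- min_len:max_len
  w <- exp(-decay_rate * (lens - min_len))
  sample_from(lens, n, prob = w / sum(w))
}

extract_read <- function(ref_seq, start, len, strand) {
  s <- substr(rep(ref_seq, length(start)), start, start + len - 1L)
  anti <- strand == "antisense"
  if (any(anti)) s[anti] <- revcomp(s[anti])
  s
}

#' Simulate degradation reads
#'
#' Draws fragment lengths from a truncated exponential (geometric-on-lengths)
#' law, `P(L) proportional to exp(-lambda * (L - min_len))` over the length
#' window, places fragments uniformly over positions fitting inside the
#' region, and emits the sense substring or its reverse complement according
#' to `strand_mode`. This emulates nuclease degradation of the sprayed dsRNA
#' (both strands) or of the endogenous target mRNA (sense only).
#'
#' @param ref One-row reference tibble.
#' @param region A one-row region (columns `start`, `end`), or `NULL` for the
#'   whole reference.
#' @param n Number of reads.
#' @param decay_rate Per-nt exponential rate lambda (>= 0).
#' @param strand_mode `"both"` or `"sense_only"`.
#' @param length_window `c(min_len, max_len)`.
#' @param seed Integer seed.
#' @return A tibble of reads: `read_id`, `sequence`, `length`, plus the
#'   generating truth columns `start` and `strand`.
#' @export
simulate_degradation_reads <- function(ref, region = NULL, n,
                                       decay_rate = 0.25,
                                       strand_mode = c("both", "sense_only"),
                                       length_window = c(17L, 29L),
                                       seed = 0L) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(region)) region <- list(start = 1L, end = ref$length)
  reg_len <- region$end - region$start + 1L
  min_len <- length_window[1]; max_len <- min(length_window[2], reg_len)
  if (reg_len < min_len) {
    stop("region shorter than the minimum read length: infeasible", call. = FALSE)
  }
  if (n == 0) return(empty_reads())
  withr::with_seed(as.integer(seed), {
    len <- sample_decay_lengths(n, decay_rate, min_len, max_len)
    start <- region$start +
      floor(runif(n) * (reg_len - len + 1L))
    strand <- if (strand_mode == "sense_only") rep("sense", n) else
      sample(c("sense", "antisense"), n, replace = TRUE)
    tibble::tibble(
      read_id = sprintf("deg_%06d", seq_len(n)),
      sequence = extract_read(ref$sequence, start, len, strand),
      length = as.integer(len), start = as.integer(start), strand = strand
    )
  })
}

phase_registers <- function(trigger, register_length) {
  k <- 0:(floor((trigger$end - trigger$start + 1L) / register_length) - 1L)
  starts <- trigger$start + k * register_length
  starts[starts + register_length - 1L <= trigger$end]
}

#' Simulate DCL-processed (diced) reads
#'
#' Emulates Dicer-like processing of the trigger dsRNA: read lengths are drawn
#' from `size_probs` (peaks at 21/22/24 nt), a `phase_fraction` of the reads
#' start on the phased register `trigger_start + k * L`, the remainder start
#' uniformly inside the trigger, and strands are assigned with equal
#' probability. Reads never extend past the trigger.
#'
#' @inheritParams simulate_degradation_reads
#' @param trigger One-row trigger region (columns `start`, `end`).
#' @param size_probs Named probabilities over read lengths.
#' @param phase_fraction Proportion of reads on the phased register.
#' @return A read tibble as in [simulate_degradation_reads()].
#' @export
simulate_dcl_reads <- function(ref, trigger, n,
                               size_probs = c("21" = 0.4, "22" = 0.4, "24" = 0.2),
                               phase_fraction = 0.7, seed = 0L) {
  if (abs(sum(size_probs) - 1) > 1e-8) {
    stop("size_probs must sum to 1", call. = FALSE)
  }
  trig_len <- trigger$end - trigger$start + 1L
  if (trig_len < 24) stop("trigger must be at least 24 nt", call. = FALSE)
  if (n == 0) return(empty_reads())
  sizes <- as.integer(names(size_probs))
  withr::with_seed(as.integer(seed), {
    len <- sample_from(sizes, n, prob = size_probs)
    phased <- runif(n) < phase_fraction
    strand <- sample(c("sense", "antisense"), n, replace = TRUE)
    start <- integer(n)
    for (L in unique(len)) {
      reg <- phase_registers(trigger, L)
      # phased reads carry their biological 5' end on the register:
      # sense reads start there, antisense reads end there (and must still
      # fit inside the trigger)
      iph_s <- which(phased & len == L & strand == "sense")
      if (length(iph_s)) start[iph_s] <- sample_from(reg, length(iph_s))
      iph_a <- which(phased & len == L & strand == "antisense")
      if (length(iph_a)) {
        reg_a <- reg[reg - L + 1L >= trigger$start]
        start[iph_a] <- sample_from(reg_a, length(iph_a)) - L + 1L
      }
      iun <- which(!phased & len == L)
      if (length(iun)) {
        start[iun] <- trigger$start +
          floor(runif(length(iun)) * (trig_len - L + 1L))
      }
    }
    tibble::tibble(
      read_id = sprintf("dcl_%06d", seq_len(n)),
      sequence = extract_read(ref$sequence, start, len, strand),
      length = as.integer(len), start = as.integer(start), strand = strand
    )
  })
}

# antisense secondary siRNAs in the flanks: the fingerprint of RDR6-driven
# transitivity, only possible when the target transcript is present
simulate_transitive_reads <- function(ref, flanks, n,
                                      size_probs = c("21" = 0.5, "22" = 0.5),
                                      seed = 0L) {
  if (n == 0) return(empty_reads())
  sizes <- as.integer(names(size_probs))
  withr::with_seed(as.integer(seed), {
    len <- sample_from(sizes, n, prob = size_probs)
    fidx <- sample_from(seq_len(nrow(flanks)), n)
    span <- flanks$end[fidx] - flanks$start[fidx] + 1L
    start <- flanks$start[fidx] + floor(runif(n) * (span - len + 1L))
    tibble::tibble(
      read_id = sprintf("trans_%06d", seq_len(n)),
      sequence = extract_read(ref$sequence, start, len, "antisense"),
      length = as.integer(len), start = as.integer(start),
      strand = "antisense"
    )
  })
}

simulate_background_reads <- function(n, mir159_weight = 0.5,
                                      length_window = c(17L, 29L),
                                      decay_rate = 0.25, seed = 0L) {
  if (n == 0) return(empty_reads())
  withr::with_seed(as.integer(seed) + 104729L, {
    bg_ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                    collapse = "")
    is_mir <- runif(n) < mir159_weight
    n_other <- sum(!is_mir)
    seqs <- character(n)
    seqs[is_mir] <- MIR159_DECOY
    if (n_other > 0) {
      len <- sample_decay_lengths(n_other, decay_rate,
                                  length_window[1], length_window[2])
      start <- 1L + floor(runif(n_other) * (500 - len + 1L))
      seqs[!is_mir] <- substr(rep(bg_ref, n_other), start, start + len - 1L)
    }
    tibble::tibble(
      read_id = sprintf("bg_%06d", seq_len(n)),
      sequence = seqs, length = nchar(seqs),
      start = NA_integer_, strand = NA_character_
    )
  })
}

empty_reads <- function() {
  tibble::tibble(read_id = character(), sequence = character(),
                 length = integer(), start = integer(), strand = character())
}

#' Simulate a full spray experiment
#'
#' Generates one read set per sample of the design, respecting the biology of
#' each condition: `target_ds` samples mix dsRNA degradation (both strands,
#' trigger only), endogenous target-mRNA decay (sense strand, whole
#' reference), optional DCL-processed and transitive reads, and background;
#' `wildtype_ds` samples carry no transgene, so they get no mRNA-decay reads
#' and `transitive_fraction` is forced to 0; `target_water` samples get only
#' sense-strand mRNA decay plus background.
#'
#' @param design Design tibble as from [default_design()].
#' @param configs Named list mapping each condition to a [sim_config()].
#' @param ref Reference tibble.
#' @param regions Region tibble containing a row named `"trigger"`.
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @param outdir If non-`NULL`, a FASTQ file per sample is written there.
#' @return A named list of read tibbles (one per sample), invisibly carrying
#'   the FASTQ paths in `attr(, "fastq")` when `outdir` is given.
#' @export
simulate_experiment <- function(design, configs, ref, regions,
                                seed = 0L, outdir = NULL) {
  validate_regions(regions, ref$length)
  missing <- setdiff(unique(design$condition), names(configs))
  if (length(missing)) {
    stop("no simulation config for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(design$condition),
                 c("target_ds", "wildtype_ds", "target_water"))
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  trigger <- regions[regions$region == "trigger", ]
  flanks <- regions[regions$region != "trigger", ]
  out <- vector("list", nrow(design))
  names(out) <- design$sample_id
  paths <- character(0)
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    cfg <- configs[[cond]]
    s <- (as.integer(seed) %% 100000L) * 10000L + i * 13L
    out[[i]] <- simulate_sample(cond, cfg, ref, trigger, flanks, s)
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      p <- file.path(outdir, paste0(design$sample_id[i], ".fastq"))
      write_fastq(out[[i]], p)
      paths[design$sample_id[i]] <- p
    }
  }
  if (!is.null(outdir)) attr(out, "fastq") <- paths
  out
}

simulate_sample <- function(condition, cfg, ref, trigger, flanks, seed) {
  n <- cfg$n_reads
  trans_frac <- cfg$transitive_fraction
  dcl_frac <- cfg$dcl_fraction
  if (condition != "target_ds" && trans_frac > 0) {
    warning("transitive reads are only possible in target_ds samples; ",
            "forcing transitive_fraction to 0 for ", condition)
    trans_frac <- 0
  }
  if (condition == "target_water") dcl_frac <- 0
  n_bg <- round(n * cfg$background_fraction)
  n_dcl <- round(n * dcl_frac)
  n_trans <- round(n * trans_frac)
  n_deg <- n - n_bg - n_dcl - n_trans
  parts <- list()
  if (condition == "target_ds") {
    # degradation splits between sprayed-dsRNA decay and endogenous mRNA decay
    n_ds <- round(n_deg / 2)
    parts$ds <- simulate_degradation_reads(ref, trigger, n_ds, cfg$decay_rate,
                                           "both", cfg$length_window, seed + 1L)
    parts$mrna <- simulate_degradation_reads(ref, NULL, n_deg - n_ds,
                                             cfg$decay_rate, "sense_only",
                                             cfg$length_window, seed + 2L)
  } else if (condition == "wildtype_ds") {
    parts$ds <- simulate_degradation_reads(ref, trigger, n_deg, cfg$decay_rate,
                                           "both", cfg$length_window, seed + 1L)
  } else { # target_water: only endogenous mRNA decay
    parts$mrna <- simulate_degradation_reads(ref, NULL, n_deg, cfg$decay_rate,
                                             "sense_only", cfg$length_window,
                                             seed + 2L)
  }
  if (n_dcl > 0) {
    parts$dcl <- simulate_dcl_reads(ref, trigger, n_dcl, cfg$size_probs,
                                    cfg$phase_fraction, seed + 3L)
  }
  if (n_trans > 0) {
    parts$trans <- simulate_transitive_reads(ref, flanks, n_trans,
                                             seed = seed + 4L)
  }
  if (n_bg > 0) {
    parts$bg <- simulate_background_reads(n_bg, cfg$mir159_weight,
                                          cfg$length_window, cfg$decay_rate,
                                          seed + 5L)
  }
  reads <- dplyr::bind_rows(parts)
  reads$read_id <- sprintf("r%07d_%s", seq_len(nrow(reads)), reads$read_id)
  reads
}

#' Write reads to a 4-line-record FASTQ file
#'
#' Quality strings are constant `'I'` (Phred+33 Q40): the analysis never uses
#' base qualities.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  con <- file(path, "wb")  # fixed newline bytes regardless of platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a 4-line-record FASTQ file into a read tibble
#' @param path FASTQ file (uncompressed or gzip).
#' @return A tibble with `read_id`, `sequence`, `length`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path,
         call. = FALSE)
  }
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  tibble::tibble(read_id = ids, sequence = seqs, length = nchar(seqs))
}
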