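#' Trim the 3' sequencing adapter from small-RNA reads
#'
#' Small-RNA inserts are shorter than the sequencing cycle count, so the 3'
#' adapter appears inside the read. Each read is truncated at the first
#' occurrence of the adapter's first 8 nt (first occurrence wins). Reads with
#' no adapter hit are kept as-is when shorter than 30 nt (already insert-sized)
#' and discarded otherwise; reads whose insert would be empty are discarded.
#'
#' @param reads Read tibble (`read_id`, `sequence`, ...).
#' @param adapter Adapter sequence, at least 8 nt; only its first 8 nt are
#'   used as the match seed.
#' @return The trimmed read tibble; discarded reads are dropped and tallied in
#'   `attr(, "discarded")` (`no_adapter_long`, `empty_insert`).
#' @export
trim_adapter <- function(reads, adapter) {
  if (nchar(adapter) < 8) {
    stop("adapter must be at least 8 nt long", call. = FALSE)
  }
  seedseq <- toupper(substr(adapter, 1, 8))
  pos <- stringr::str_locate(reads$sequence, stringr::fixed(seedseq))[, "start"]
  keep_untrimmed <- is.na(pos) & nchar(reads$sequence) < 30
  drop_long <- is.na(pos) & !keep_untrimmed
  insert_len <- ifelse(is.na(pos), nchar(reads$sequence), pos - 1L)
  empty <- !is.na(pos) & insert_len == 0
  out <- reads[!(drop_long | empty), , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L,
                         insert_len[!(drop_long | empty)])
  out$length <- nchar(out$sequence)
  attr(out, "discarded") <- c(no_adapter_long = sum(drop_long),
                              empty_insert = sum(empty))
  out
}

#' Filter reads by insert length
#'
#' Retains reads with `min_len <= length <= max_len` (both inclusive); the
#' default window keeps reads longer than 16 nt and shorter than 30 nt.
#'
#' @param reads Read tibble with a `length` column.
#' @param min_len,max_len Inclusive bounds (defaults 17 and 29).
#' @return The retained reads, order preserved, with discard counts per bound
#'   in `attr(, "discarded")` (`too_short`, `too_long`).
#' @export
filter_by_length <- function(reads, min_len = 17L, max_len = 29L) {
  stopifnot(min_len <= max_len)
  short <- reads$length < min_len
  long <- reads$length > max_len
  out <- reads[!short & !long, , drop = FALSE]
  attr(out, "discarded") <- c(too_short = sum(short), too_long = sum(long))
  out
}

#' Exactly map one read to a reference, strand-aware
#'
#' Returns every position where the read matches a substring of the reference
#' on the sense strand, or where its reverse complement matches (antisense).
#' Antisense placements are reported in sense coordinates (the start of the
#' reference window whose reverse complement equals the read). Matching is
#' exact: zero mismatches, overlapping occurrences included.
#'
#' @param read A single ACGT string.
#' @param ref One-row reference tibble.
#' @return A tibble with columns `start`, `strand`; zero rows if unmapped.
#' @export
map_exact <- function(read, ref) {
  stopifnot(nchar(read) >= 1)
  if (grepl("[^ACGT]", read)) {
    return(tibble::tibble(start = integer(), strand = character()))
  }
  subject <- Biostrings::DNAString(ref$sequence)
  hit_s <- Biostrings::start(Biostrings::matchPattern(read, subject))
  hit_a <- Biostrings::start(Biostrings::matchPattern(revcomp(read), subject))
  tibble::tibble(
    start = as.integer(c(hit_s, hit_a)),
    strand = c(rep("sense", length(hit_s)), rep("antisense", length(hit_a)))
  )
}

#' Map a read set to the reference
#'
#' Applies [map_exact()] per unique sequence (deduplicated for speed) and
#' returns one row per (read, placement). Reads containing non-ACGT characters
#' are skipped and tallied, not errored.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `length`).
#' @param ref One-row reference tibble.
#' @return A tibble `read_id`, `sequence`, `length`, `start`, `strand`,
#'   `n_placements` (per read). Unmapped reads are absent; tallies are in
#'   `attr(, "tallies")` (`total`, `mapped`, `ambiguous`, `unmapped`,
#'   `skipped_non_acgt`).
#' @export
map_reads <- function(reads, ref) {
  non_acgt <- grepl("[^ACGT]", reads$sequence)
  clean <- reads[!non_acgt, , drop = FALSE]
  uniq <- unique(clean$sequence)
  # position-indexed dictionary of all reference windows per read length:
  # O(1) per read, exact, overlapping occurrences included
  hits <- purrr::map_dfr(sort(unique(nchar(uniq))), function(L) {
    n_win <- ref$length - L + 1L
    if (n_win < 1) return(NULL)
    windows <- substring(ref$sequence, seq_len(n_win), seq_len(n_win) + L - 1L)
    dict <- tibble::tibble(
      sequence = c(windows, revcomp(windows)),
      start = rep(seq_len(n_win), 2L),
      strand = rep(c("sense", "antisense"), each = n_win)
    )
    dplyr::inner_join(tibble::tibble(sequence = uniq[nchar(uniq) == L]),
                      dict, by = "sequence",
                      relationship = "many-to-many")
  })
  mapped <- dplyr::inner_join(
    clean[, c("read_id", "sequence", "length")], hits,
    by = "sequence", relationship = "many-to-many"
  )
  mapped <- dplyr::add_count(mapped, .data$read_id, name = "n_placements")
  n_per_read <- dplyr::distinct(mapped, .data$read_id, .data$n_placements)
  tallies <- c(
    total = nrow(reads),
    mapped = sum(n_per_read$n_placements == 1),
    ambiguous = sum(n_per_read$n_placements > 1),
    unmapped = nrow(clean) - nrow(n_per_read),
    skipped_non_acgt = sum(non_acgt)
  )
  attr(mapped, "tallies") <- tallies
  mapped
}

# biological 5' end in sense coordinates: sense reads start at their 5' end,
# antisense reads end there
five_prime_pos <- function(start, length, strand) {
  ifelse(strand == "antisense", start + length - 1L, start)
}

assign_region <- function(pos, regions) {
  out <- rep("outside", length(pos))
  for (i in seq_len(nrow(regions))) {
    inr <- pos >= regions$start[i] & pos <= regions$end[i]
    out[inr] <- regions$region[i]
  }
  out
}

#' Count uniquely mapped reads by region, strand and size class
#'
#' Builds the per-sample size-class count table: each uniquely mapped read
#' increments exactly one (region, strand, length) cell. Reads are assigned to
#' the region containing their biological 5' end, multi-placement reads are
#' discarded as ambiguous, and reads outside the length range are tallied but
#' not counted. All (region, strand, length) cells in range are present even
#' when zero.
#'
#' @param mapped Output of [map_reads()].
#' @param regions Region tibble (`region`, `start`, `end`), non-overlapping.
#' @param lengths Size classes to tabulate (default `20:25`).
#' @param sample_id Sample label stored in the table.
#' @param total_reads Total reads in the sample before mapping; defaults to
#'   the tally recorded by [map_reads()].
#' @return A `size_class_table`: list with `counts` (tibble `sample_id`,
#'   `region`, `strand`, `length`, `count`) and `samples` (tibble of
#'   per-sample totals and tallies).
#' @export
count_by_size_and_region <- function(mapped, regions, lengths = 20:25,
                                     sample_id = "sample",
                                     total_reads = NULL) {
  validate_regions(regions)
  tal <- attr(mapped, "tallies")
  if (is.null(total_reads)) {
    total_reads <- if (!is.null(tal)) unname(tal["total"]) else
      length(unique(mapped$read_id))
  }
  uniq <- mapped[mapped$n_placements == 1, , drop = FALSE]
  uniq$fp <- five_prime_pos(uniq$start, uniq$length, uniq$strand)
  uniq$region <- assign_region(uniq$fp, regions)
  in_range <- uniq$length %in% lengths
  counted <- uniq[in_range, , drop = FALSE]
  grid <- tidyr::expand_grid(
    sample_id = sample_id,
    region = c(regions$region, "outside"),
    strand = c("sense", "antisense"),
    length = as.integer(lengths)
  )
  obs <- dplyr::count(counted, .data$region, .data$strand, .data$length,
                      name = "count")
  counts <- dplyr::left_join(grid, obs,
                             by = c("region", "strand", "length"))
  counts$count <- dplyr::coalesce(counts$count, 0L)
  samples <- tibble::tibble(
    sample_id = sample_id,
    total_reads = as.integer(total_reads),
    mapped_reads = if (!is.null(tal)) unname(tal["mapped"]) else nrow(uniq),
    ambiguous = if (!is.null(tal)) unname(tal["ambiguous"]) else
      length(unique(mapped$read_id[mapped$n_placements > 1])),
    unmapped = if (!is.null(tal)) unname(tal["unmapped"]) else NA_integer_,
    out_of_range = sum(!in_range)
  )
  new_size_class_table(counts, samples)
}

new_size_class_table <- function(counts, samples) {
  structure(list(counts = tibble::as_tibble(counts),
                 samples = tibble::as_tibble(samples)),
            class = "size_class_table")
}

#' @export
print.size_class_table <- function(x, ...) {
  cat("<size_class_table> ", nrow(x$samples), " sample(s)\n", sep = "")
  print(x$samples)
  cat("counts:\n")
  print(x$counts, n = 12)
  invisible(x)
}

#' Combine per-sample size-class tables
#' @param ... `size_class_table` objects (or a single list of them).
#' @return One `size_class_table` with all samples.
#' @export
bind_size_tables <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "size_class_table")) xs <- xs[[1]]
  new_size_class_table(
    dplyr::bind_rows(purrr::map(xs, "counts")),
    dplyr::bind_rows(purrr::map(xs, "samples"))
  )
}

#' @method tidy size_class_table
#' @export
tidy.size_class_table <- function(x, ...) {
  dplyr::left_join(x$counts, x$samples, by = "sample_id")
}

#' Write / read a size-class table as TSV
#'
#' The long TSV mirrors the printed count-table layout plus `region` and
#' `strand` columns; per-sample totals travel in companion columns.
#'
#' @param x A `size_class_table`.
#' @param path Output TSV path.
#' @return `path` (write) or a `size_class_table` (read).
#' @export
write_size_table <- function(x, path) {
  readr::write_tsv(tidy.size_class_table(x), path)
  invisible(path)
}

#' @rdname write_size_table
#' @export
read_size_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sample_cols <- intersect(
    c("sample_id", "condition", "total_reads", "mapped_reads", "ambiguous",
      "unmapped", "out_of_range"), names(df))
  samples <- dplyr::distinct(df[, sample_cols])
  counts <- df[, intersect(c("sample_id", "region", "strand", "length",
                             "count"), names(df))]
  new_size_class_table(counts, samples)
}

#' Read regions from a BED-like TSV or YAML file
#'
#' The TSV dialect is 1-based with both ends inclusive and has columns
#' `region`, `start`, `end` (header row required; comment lines start
#' with `#`).
#'
#' @param path TSV (`.tsv`/`.bed`) or YAML (`.yml`/`.yaml`) file.
#' @return A region tibble.
#' @export
read_regions <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    out <- tibble::tibble(
      region = purrr::map_chr(y, "region"),
      start = purrr::map_int(y, ~ as.integer(.x$start)),
      end = purrr::map_int(y, ~ as.integer(.x$end))
    )
  } else {
    out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
    out <- tibble::tibble(region = as.character(out$region),
                          start = as.integer(out$start),
                          end = as.integer(out$end))
  }
  validate_regions(out)
  out
}
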