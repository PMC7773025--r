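#' Build a seeded reference sequence with embedded motifs
#'
#' Generates a pseudorandom ACGT sequence of the requested length and embeds
#' each motif verbatim at its 1-based start position. The shipped default
#' reference ([default_reference()]) stands in for a GFP transgene whose
#' sequence is not distributed with the package: the trigger-amplicon primer
#' cores are embedded at their published coordinates so that all coordinate
#' arithmetic downstream is exercised on realistic anchors.
#'
#' @param length Reference length in nucleotides (>= 1).
#' @param seed Integer seed; the same `(length, seed, motifs)` always yields
#'   the same sequence.
#' @param motifs A list of `list(sequence =, start =)` entries (or a data
#'   frame with columns `sequence`, `start`), each embedded verbatim at its
#'   1-based start. Motifs must fit inside the reference and not overlap.
#'
#' @return A tibble with one row: `name`, `sequence`, `length`.
#' @export
#' @examples
#' ref <- build_reference(100, seed = 1,
#'                        motifs = list(list(sequence = "ACGTACGT", start = 10)))
#' substr(ref$sequence, 10, 17)
build_reference <- function(length, seed = 0L, motifs = list(), name = "reference") {
  stopifnot(is.numeric(length), length >= 1)
  motifs <- normalize_motifs(motifs)
  if (nrow(motifs) > 0) {
    ends <- motifs$start + nchar(motifs$sequence) - 1L
    if (any(motifs$start < 1) || any(ends > length)) {
      stop("motif overruns the reference: coordinates must satisfy 1 <= start, end <= length",
           call. = FALSE)
    }
    ord <- order(motifs$start)
    if (nrow(motifs) > 1 &&
        any(motifs$start[ord][-1] <= ends[ord][-nrow(motifs)])) {
      stop("overlapping motifs are not allowed", call. = FALSE)
    }
  }
  seq <- withr::with_seed(as.integer(seed), {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
  if (nrow(motifs) > 0) {
    for (i in seq_len(nrow(motifs))) {
      m <- toupper(motifs$sequence[i])
      stopifnot(grepl("^[ACGT]+$", m))
      substr(seq, motifs$start[i], motifs$start[i] + nchar(m) - 1L) <- m
    }
  }
  tibble::tibble(name = name, sequence = seq, length = nchar(seq))
}

normalize_motifs <- function(motifs) {
  if (is.data.frame(motifs)) {
    return(tibble::as_tibble(motifs)[, c("sequence", "start")])
  }
  if (length(motifs) == 0) {
    return(tibble::tibble(sequence = character(), start = integer()))
  }
  tibble::tibble(
    sequence = purrr::map_chr(motifs, ~ as.character(.x$sequence %||% .x[[1]])),
    start = purrr::map_int(motifs, ~ as.integer(.x$start %||% .x[[2]]))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Primer cores bounding the two published trigger amplicons (gene-specific
# 3' portions, T7 promoter and restriction tails stripped).
trigger_primer_cores <- function() {
  tibble::tibble(
    amplicon = c("midGFP", "midGFP", "GFP5p", "GFP5p"),
    sequence = c(
      "TATGAAGCGGCACGACTTCT",         # forward core, 5' end of 294..432
      "ACACCCTCGTCAACAGGATC",         # reverse core read on the sense strand
      "ATGAAGACTAATCTTTTTCTCTTT",     # forward core at position 1
      "TCAAGAGCGCCATGCCTGAG"          # reverse core, sense strand, end of 1..322
    ),
    start = c(294L, 413L, 1L, 303L)
  )
}

#' Default synthetic reference emulating the GFP transgene
#'
#' A 720-nt seeded pseudorandom sequence with the published primer cores of
#' the two trigger amplicons embedded at their stated coordinates: the
#' 139-bp "midGFP" trigger spans positions 294..432 and the 322-bp 5' trigger
#' spans 1..322. The sequence between the anchors is synthetic; only the
#' coordinates and primer cores are real.
#'
#' @param length Total reference length (default 720 nt).
#' @param seed Seed for the filler sequence.
#' @return A one-row tibble as from [build_reference()].
#' @export
default_reference <- function(length = 720L, seed = 0L) {
  cores <- trigger_primer_cores()
  # the GFP5p forward core (pos 1) and midGFP forward core (pos 294) overlap
  # the GFP5p reverse core region; keep the non-overlapping anchors
  keep <- cores[c(1, 2, 3), ]
  build_reference(length, seed = seed,
                  motifs = keep[, c("sequence", "start")],
                  name = "GFP_synthetic")
}

#' Trigger and flank regions for a reference
#'
#' Returns the trigger interval (the sprayed dsRNA, positions 294..432 of the
#' default reference) together with the 5' and 3' flanks derived from it:
#' 5' flank = `[1, trigger_start - 1]`, 3' flank = `[trigger_end + 1, ref_length]`.
#' All coordinates are 1-based and inclusive at both ends.
#'
#' @param ref_length Reference length in nt.
#' @param trigger_start,trigger_end Trigger interval (defaults 294 and 432).
#' @return A tibble with columns `region`, `start`, `end`.
#' @export
default_regions <- function(ref_length = 720L, trigger_start = 294L,
                            trigger_end = 432L) {
  stopifnot(trigger_start >= 1, trigger_end >= trigger_start,
            trigger_end <= ref_length)
  out <- tibble::tibble(
    region = c("flank5", "trigger", "flank3"),
    start = c(1L, as.integer(trigger_start), as.integer(trigger_end) + 1L),
    end = c(as.integer(trigger_start) - 1L, as.integer(trigger_end),
            as.integer(ref_length))
  )
  out[out$end >= out$start, ]
}

validate_regions <- function(regions, ref_length = NULL) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  if (anyDuplicated(regions$region)) {
    stop("duplicated region names", call. = FALSE)
  }
  if (any(regions$start < 1) || any(regions$end < regions$start)) {
    stop("regions must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(ref_length) && any(regions$end > ref_length)) {
    stop("region extends past the reference end", call. = FALSE)
  }
  reg <- regions[order(regions$start), ]
  if (nrow(reg) > 1 && any(reg$start[-1] <= reg$end[-nrow(reg)])) {
    stop("regions must be non-overlapping", call. = FALSE)
  }
  invisible(regions)
}

#' Reverse complement of a DNA string
#' @param x Character vector of ACGT(N) strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a reference tibble to FASTA
#' @param ref One-row reference tibble (`name`, `sequence`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  set <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA reference into the package's reference tibble
#' @param path FASTA file; the first record is used.
#' @return A one-row tibble (`name`, `sequence`, `length`).
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble::tibble(name = names(set)[1],
                 sequence = as.character(set[[1]]),
                 length = Biostrings::width(set)[1])
}
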