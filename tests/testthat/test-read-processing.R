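adapter <- "TGGAATTCTCGGGTGCCAAGG"

make_reads <- function(seqs) {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                 sequence = seqs, length = nchar(seqs))
}

test_that("adapter trimming truncates at the first adapter-seed occurrence", {
  insert <- "ACGTACGTACGTACGTACGT"
  r <- make_reads(c(
    paste0(insert, adapter),                     # clean ligation
    strrep("ACGT", 19),                          # 76 nt, no adapter -> drop
    paste0(adapter, "ACGTACGT"),                 # empty insert -> drop
    "ACGTACGTACGTACGTAC",                        # 18 nt, no adapter -> keep
    paste0("AAAC", substr(adapter, 1, 8), insert, adapter) # first hit wins
  ))
  out <- trim_adapter(r, adapter)
  expect_identical(out$sequence, c(insert, "ACGTACGTACGTACGTAC", "AAAC"))
  expect_identical(out$length, c(20L, 18L, 4L))
  expect_equal(unname(attr(out, "discarded")["no_adapter_long"]), 1)
  expect_equal(unname(attr(out, "discarded")["empty_insert"]), 1)
  expect_error(trim_adapter(r, "ACGTACG"), "at least 8")
})

test_that("length filter keeps the 17-29 window with strict bounds", {
  r <- make_reads(c(strrep("A", 16), strrep("C", 17), strrep("G", 29),
                    strrep("T", 30)))
  out <- filter_by_length(r)
  expect_identical(out$length, c(17L, 29L))
  expect_equal(unname(attr(out, "discarded")), c(1, 1))
  empty <- filter_by_length(make_reads(character(0)))
  expect_equal(nrow(empty), 0)
  all_in <- make_reads(c(strrep("A", 20), strrep("C", 22), strrep("G", 21)))
  expect_identical(filter_by_length(all_in)$sequence, all_in$sequence)
})

test_that("map_exact reports sense and antisense placements in sense coordinates", {
  ref <- tiny_ref(400)
  sense_read <- substr(ref$sequence, 100, 120)
  hit <- map_exact(sense_read, ref)
  expect_true(nrow(hit) >= 1)
  expect_true(any(hit$start == 100 & hit$strand == "sense"))
  anti_read <- oracle_revcomp(substr(ref$sequence, 294, 315))
  hit2 <- map_exact(anti_read, ref)
  expect_true(any(hit2$start == 294 & hit2$strand == "antisense"))
  expect_equal(nrow(map_exact(strrep("N", 21), ref)), 0)
})

test_that("mapper agrees with the all-substrings oracle on random cases", {
  set.seed(11)
  for (case in 1:60) {
    len <- sample(60:400, 1)
    ref <- build_reference(len, seed = case)
    rl <- sample(17:30, 1)
    read <- if (runif(1) < 0.7) {
      s <- sample(len - rl + 1, 1)
      w <- substr(ref$sequence, s, s + rl - 1)
      if (runif(1) < 0.5) w else oracle_revcomp(w)
    } else {
      paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE), collapse = "")
    }
    expect_identical(sorted_placements(map_exact(read, ref)),
                     sorted_placements(oracle_map(read, ref$sequence)),
                     info = paste("case", case))
  }
})

test_that("strand symmetry: reverse-complementing a read swaps strand labels", {
  ref <- tiny_ref(300, seed = 5)
  set.seed(21)
  for (i in 1:20) {
    s <- sample(270, 1)
    read <- substr(ref$sequence, s, s + 21)
    a <- sorted_placements(map_exact(read, ref))
    b <- sorted_placements(map_exact(oracle_revcomp(read), ref))
    flipped <- b
    flipped$strand <- ifelse(b$strand == "sense", "antisense", "sense")
    expect_identical(a, sorted_placements(flipped))
  }
})

test_that("ambiguous reads (duplicated block) are excluded from counts", {
  block <- strrep("ACGTC", 5)  # 25 nt
  ref <- build_reference(300, seed = 3,
                         motifs = list(list(sequence = block, start = 10),
                                       list(sequence = block, start = 200)))
  reads <- make_reads(block)
  m <- map_reads(reads, ref)
  expect_gte(unique(m$n_placements), 2)
  regions <- tibble::tibble(region = "whole", start = 1L, end = 300L)
  tab <- count_by_size_and_region(m, regions, lengths = 25)
  expect_equal(sum(tab$counts$count), 0)
  expect_equal(tab$samples$ambiguous, 1)
})

test_that("counting assigns by biological 5' end and keeps zero cells", {
  ref <- tiny_ref(400)
  regions <- tibble::tibble(region = c("left", "right"),
                            start = c(1L, 201L), end = c(200L, 400L))
  # antisense read straddling the boundary: start 195, length 22 -> 5' end 216
  seqs <- c(oracle_revcomp(substr(ref$sequence, 195, 216)),
            substr(ref$sequence, 50, 71))
  m <- map_reads(make_reads(seqs), ref)
  tab <- count_by_size_and_region(m, regions, lengths = 20:25)
  cnt <- tab$counts
  expect_equal(cnt$count[cnt$region == "right" & cnt$strand == "antisense" &
                           cnt$length == 22], 1)
  expect_equal(cnt$count[cnt$region == "left" & cnt$strand == "sense" &
                           cnt$length == 22], 1)
  expect_equal(sum(cnt$count), 2)
  expect_equal(nrow(cnt), 3 * 2 * 6)  # left/right/outside x strand x lengths
})

test_that("count conservation: cells + ambiguous + unmapped + out-of-range = total", {
  ref <- default_reference()
  regs <- default_regions()
  for (seed in 1:4) {
    trig <- regs[regs$region == "trigger", ]
    r1 <- simulate_degradation_reads(ref, trig, 300, seed = seed)
    r2 <- simulate_dcl_reads(ref, trig, 200, seed = seed)
    bg <- tibble::tibble(read_id = "alien", length = 21L,
                         sequence = paste0(strrep("AC", 10), "A"))
    reads <- dplyr::bind_rows(r1, r2, bg[, c("read_id", "sequence", "length")])
    reads$read_id <- sprintf("u%04d", seq_len(nrow(reads)))
    m <- map_reads(reads, ref)
    tab <- count_by_size_and_region(m, regs, lengths = 20:25)
    tal <- attr(m, "tallies")
    expect_equal(sum(tab$counts$count) + tab$samples$ambiguous +
                   unname(tal["unmapped"]) + tab$samples$out_of_range,
                 tab$samples$total_reads)
  }
})

test_that("size-class tables round-trip through TSV", {
  tab <- load_published_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_size_table(tab, path)
  back <- read_size_table(path)
  expect_equal(as.data.frame(back$counts[, c("sample_id", "length", "count")]),
               as.data.frame(tab$counts[, c("sample_id", "length", "count")]))
  expect_equal(back$samples$total_reads, tab$samples$total_reads)
})
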