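ref <- default_reference()
regs <- default_regions()
trigger <- regs[regs$region == "trigger", ]

# build a size_class_table-like counts object directly from truth columns
table_from_counts <- function(...) {
  rows <- list(...)
  counts <- dplyr::bind_rows(rows)
  samples <- dplyr::distinct(counts[, c("sample_id", "condition")])
  samples$total_reads <- NA_integer_
  counts$condition <- NULL
  structure(list(counts = counts, samples = samples),
            class = "size_class_table")
}

flank_row <- function(sample_id, condition, strand, count,
                      region = "flank5", length = 21L) {
  tibble::tibble(sample_id = sample_id, condition = condition,
                 region = region, strand = strand, length = length,
                 count = count)
}

test_that("zero antisense flank reads give verdict false with p = 1", {
  tbl <- table_from_counts(
    flank_row(c("t1", "t2"), "target_ds", "antisense", 0L),
    flank_row(c("w1", "w2"), "wildtype_ds", "antisense", 0L)
  )
  res <- detect_transitivity(tbl)
  expect_false(res$verdict)
  expect_equal(res$p_value, 1)
})

test_that("sense-only flank reads (mRNA decay) never trigger the verdict", {
  tbl <- table_from_counts(
    flank_row(c("t1", "t2"), "target_ds", "sense", 500L),
    flank_row(c("t1", "t2"), "target_ds", "antisense", 0L),
    flank_row(c("w1", "w2"), "wildtype_ds", "antisense", 0L)
  )
  res <- detect_transitivity(tbl)
  expect_false(res$verdict)
})

test_that("the minimum-signal floor suppresses 1-2 stray antisense reads", {
  tbl <- table_from_counts(
    flank_row(c("t1", "t2"), "target_ds", "antisense", c(2L, 1L)),
    flank_row(c("w1", "w2"), "wildtype_ds", "antisense", 0L)
  )
  res <- detect_transitivity(tbl)
  expect_false(res$verdict)   # p may be small but the mean is below 5
  expect_lt(res$mean_target_count, 5)
})

test_that("a missing wild-type control is an error", {
  tbl <- table_from_counts(flank_row("t1", "target_ds", "antisense", 10L))
  expect_error(detect_transitivity(tbl), "control")
})

test_that("simulated transitive signal is recovered end-to-end", {
  design <- default_design()
  cfgs <- list(
    target_ds = sim_config(n_reads = 5000, transitive_fraction = 0.05),
    wildtype_ds = sim_config(n_reads = 5000),
    target_water = sim_config(n_reads = 5000, strand_mode = "sense_only")
  )
  reads <- simulate_experiment(design, cfgs, ref, regs, seed = 17)
  tabs <- purrr::imap(reads, function(r, sid) {
    count_by_size_and_region(map_reads(r, ref), regs, lengths = 17:29,
                             sample_id = sid)
  })
  tbl <- bind_size_tables(tabs)
  tbl$samples <- dplyr::left_join(tbl$samples,
                                  design[, c("sample_id", "condition")],
                                  by = "sample_id")
  res <- detect_transitivity(tbl)
  expect_true(res$verdict)
  expect_lt(res$p_value, 0.05)
})

test_that("phasing score is 1 on a single register and calibrated under uniformity", {
  mk <- function(start, len = 22L) {
    tibble::tibble(read_id = sprintf("r%d", seq_along(start)), sequence = "x",
                   length = len, start = as.integer(start), strand = "sense",
                   n_placements = 1L)
  }
  reg <- 294 + 22 * (0:5)
  res <- phasing_score(mk(rep(reg, 3)), trigger, 22L)
  expect_equal(res$score, 1)
  expect_lt(res$p_value, 0.05)
  # generator at phase_fraction = 1 forces score 1
  d <- simulate_dcl_reads(ref, trigger, 300, size_probs = c("22" = 1),
                          phase_fraction = 1, seed = 2)
  d$n_placements <- 1L
  expect_equal(phasing_score(d, trigger, 22L)$score, 1)
  # uniform offsets: score near 1/22, not significant
  set.seed(99)
  offs <- sample(0:21, 10000, replace = TRUE)
  k <- vapply(offs, function(o) sample(0:floor((117 - o) / 22), 1), 1)
  unif <- mk(294L + offs + 22L * k)
  res_u <- phasing_score(unif, trigger, 22L)
  expect_equal(res_u$score, 1 / 22, tolerance = 0.25)
  expect_gt(res_u$p_value, 0.05)
  # underpowered: score reported, p suppressed
  small <- phasing_score(mk(reg), trigger, 22L)
  expect_equal(small$score, 1)
  expect_true(is.na(small$p_value))
})

test_that("phasing test keeps approximately its nominal size under the null", {
  set.seed(7)
  rejections <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    offs <- sample(0:21, 60, replace = TRUE)
    k <- vapply(offs, function(o) sample(0:floor((117 - o) / 22), 1), 1)
    m <- tibble::tibble(read_id = as.character(1:60), sequence = "x",
                        length = 22L,
                        start = 294L + offs + 22L * as.integer(k),
                        strand = "sense", n_placements = 1L)
    p <- phasing_score(m, trigger, 22L)$p_value
    if (!is.na(p) && p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / reps, 0.08)  # Bonferroni makes the test conservative
})

test_that("Fisher long/short test matches the trivial and oracle cases", {
  mk_tbl <- function(long_in, short_in, long_out, short_out) {
    tibble::tibble(
      region = c("trigger", "trigger", "flank5", "flank5"),
      length = c(25L, 20L, 25L, 20L),
      count = c(long_in, short_in, long_out, short_out))
  }
  even <- long_short_ratio_test(mk_tbl(10, 10, 10, 10))
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p_value, 1)
  skew <- long_short_ratio_test(mk_tbl(1, 9, 9, 1))
  expect_equal(skew$p_value, oracle_fisher_p(1, 9, 9, 1), tolerance = 1e-10)
  degenerate <- long_short_ratio_test(mk_tbl(0, 10, 0, 10))
  expect_true(degenerate$undefined)
  expect_equal(degenerate$p_value, 1)
})

test_that("flatter decay outside the trigger drives the odds ratio above 1", {
  flank5 <- regs[regs$region == "flank5", ]
  inside <- simulate_degradation_reads(ref, trigger, 25000, decay_rate = 0.5,
                                       seed = 4)
  outside <- simulate_degradation_reads(ref, flank5, 25000, decay_rate = 0.1,
                                        strand_mode = "sense_only", seed = 5)
  outside$read_id <- paste0("o", outside$read_id)
  m <- map_reads(dplyr::bind_rows(inside, outside), ref)
  tab <- count_by_size_and_region(m, regs, lengths = 17:29)
  res <- long_short_ratio_test(tab)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.05)
})
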