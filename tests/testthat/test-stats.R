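test_that("decay fit recovers an exact log-linear histogram", {
  L <- 17:29
  counts <- setNames(round(1000 * exp(-0.3 * (L - 17))), L)
  fit <- fit_length_decay(counts)
  expect_equal(fit$rate, -0.3, tolerance = 0.01)
  expect_gte(abs(fit$pearson_r), 0.999)
  expect_equal(fit$excluded_zero_lengths, 0)
})

test_that("decay fit degenerates gracefully", {
  const <- setNames(rep(100, 13), 17:29)
  fit <- fit_length_decay(const)
  expect_equal(fit$rate, 0)
  expect_equal(fit$pearson_r, 0)
  expect_error(fit_length_decay(setNames(c(5, 7, 0, 0), 17:20)),
               "insufficient")
  # zero-count lengths are excluded and reported
  counts <- setNames(c(100, 80, 0, 50, 40, 30), 20:25)
  fit2 <- fit_length_decay(counts, fit_range = 20:25)
  expect_equal(fit2$excluded_zero_lengths, 1)
  expect_equal(fit2$n_points, 5)
})

test_that("pooled t-test handles identical and degenerate groups", {
  d <- tidyr::expand_grid(condition = c("target_ds", "wildtype_ds"),
                          sample_id = 1:3, length = 20:22)
  d$count <- rep(c(10, 20, 30), 6)
  res <- compare_size_classes_raw(d)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$direction == "none"))
  # zero variance in both groups with equal means -> p = 1
  d2 <- d; d2$count <- 7
  res2 <- compare_size_classes_raw(d2)
  expect_true(all(res2$p_value == 1))
})

test_that("published 22-nt counts compare as non-significant depletion", {
  d <- tibble::tibble(
    condition = rep(c("target_ds", "wildtype_ds"), each = 3),
    sample_id = 1:6, length = 22,
    count = c(186, 276, 202, 275, 246, 209))
  res <- compare_size_classes_raw(d)
  expect_false(res$significant)
  expect_identical(res$direction, "depleted")
})

test_that("control normalization divides elementwise and flags control zeros", {
  out <- normalize_to_control(setNames(186, 22), setNames(37, 22))
  expect_equal(out$ratio, 5.027, tolerance = 1e-3)
  eq <- normalize_to_control(setNames(c(5, 9), 21:22), setNames(c(5, 9), 21:22))
  expect_true(all(eq$ratio == 1))
  z <- normalize_to_control(setNames(c(5, 9), 21:22), setNames(c(0, 3), 21:22))
  expect_true(is.na(z$ratio[1]) && z$undefined[1])
  expect_equal(z$ratio[2], 3)
  expect_error(normalize_to_control(setNames(5, 21), setNames(0, 21)),
               "impossible")
})

test_that("functional normalization is depth-invariant and scheme-consistent", {
  x <- c(10, 20, 30)
  expect_equal(functional_normalize(x, 1), x)
  # doubling depth doubles both counts and the denominator
  expect_equal(functional_normalize(2 * x, 2 * 50),
               functional_normalize(x, 50))
  expect_error(functional_normalize(x, 0), "mir159")
  # condition ordering identical under both depth-proportional schemes
  counts22 <- c(a = 120, b = 80, c = 200)
  depth <- c(a = 1e6, b = 5e5, c = 2e6)
  norm_mir <- counts22 / (depth * 0.001)   # miR159 pool proportional to depth
  norm_24 <- counts22 / (depth * 0.02)     # 24-nt pool proportional to depth
  expect_identical(order(norm_mir), order(norm_24))
})

test_that("ANOVA letters separate a strongly shifted group and merge identical ones", {
  d <- tibble::tibble(
    condition = rep(c("g1", "g2"), each = 3), length = 22,
    value = c(1, 2, 3, 1, 2, 3))
  res <- compare_normalized_anova(d)
  expect_equal(res$letters[1], res$letters[2])
  set.seed(8)
  d3 <- tibble::tibble(
    condition = rep(c("g1", "g2", "g3"), each = 3), length = 21,
    value = c(rnorm(3), rnorm(3), rnorm(3) + 10))
  res3 <- compare_normalized_anova(d3)
  lg3 <- res3$letters[res3$condition == "g3"]
  expect_false(lg3 %in% res3$letters[res3$condition != "g3"])
  expect_error(compare_normalized_anova(d3[d3$condition == "g1", ]),
               "two conditions")
})

test_that("sliding-window profile matches the explicit-loop oracle", {
  ref_len <- 300L
  mk_mapped <- function(start, length, strand) {
    m <- tibble::tibble(read_id = sprintf("r%d", seq_along(start)),
                        sequence = "x", length = length, start = start,
                        strand = strand, n_placements = 1L)
    m
  }
  # single read, total 1, window 10: ten positions at 0.1
  m1 <- mk_mapped(100L, 22L, "sense")
  p1 <- sliding_window_profile(m1, ref_len, window = 10, total_reads = 1)
  expect_equal(sum(p1$value > 0), 10)
  expect_equal(unique(p1$value[p1$value > 0]), 0.1)
  # uniform 5'-end counts give a constant interior profile
  m2 <- mk_mapped(rep(seq_len(ref_len - 21L), each = 2), 22L, "sense")
  p2 <- sliding_window_profile(m2, ref_len, window = 10,
                               total_reads = nrow(m2))
  interior <- p2$value[10:(ref_len - 30)]
  expect_equal(max(interior) - min(interior), 0)
  # random sample vs oracle, to within 1e-12
  set.seed(31)
  starts <- sample(ref_len - 25L, 400, replace = TRUE)
  strands <- sample(c("sense", "antisense"), 400, replace = TRUE)
  m3 <- mk_mapped(as.integer(starts), 20L, strands)
  p3 <- sliding_window_profile(m3, ref_len, window = 10, total_reads = 500)
  fp <- ifelse(strands == "antisense", starts + 19L, starts)
  expect_equal(p3$value, oracle_profile(fp, ref_len, 10, 500),
               tolerance = 1e-12)
  expect_error(sliding_window_profile(m3, ref_len, total_reads = 0),
               "positive")
})

test_that("profile accounting identity holds with edge shrinkage", {
  ref_len <- 120L
  set.seed(13)
  starts <- sample(ref_len - 20L, 200, replace = TRUE)
  m <- tibble::tibble(read_id = sprintf("r%d", 1:200), sequence = "x",
                      length = 21L, start = as.integer(starts),
                      strand = "sense", n_placements = 1L)
  w <- 10L
  p <- sliding_window_profile(m, ref_len, window = w, total_reads = 300)
  # each 5'-end count contributes 1/|window(p)| for every window covering it
  half_lo <- floor((w - 1) / 2); half_hi <- w - 1 - half_lo
  weight <- vapply(seq_len(ref_len), function(q) {
    covering <- max(1, q - half_hi):min(ref_len, q + half_lo)
    sum(1 / (pmin(ref_len, covering + half_hi) -
               pmax(1, covering - half_lo) + 1))
  }, numeric(1))
  cnt <- tabulate(starts, nbins = ref_len)
  expect_equal(sum(p$value) * 300, sum(cnt * weight), tolerance = 1e-9)
})

test_that("more dicing never lowers the mean silencing-size enrichment statistic", {
  ref <- default_reference()
  regs <- default_regions()
  design <- default_design()[1:6, ]  # dsRNA-sprayed conditions only
  stat_for <- function(dcl, seed) {
    cfgs <- list(
      target_ds = sim_config(n_reads = 1200, dcl_fraction = dcl),
      wildtype_ds = sim_config(n_reads = 1200)
    )
    reads <- simulate_experiment(design, cfgs, ref, regs, seed = seed)
    counts <- purrr::imap_dfr(reads, function(r, sid) {
      on_target <- r[!is.na(r$start), ]
      d <- dplyr::count(on_target, .data$length, name = "count")
      d$sample_id <- sid
      d
    })
    counts <- dplyr::left_join(counts, design, by = "sample_id")
    grid <- tidyr::expand_grid(sample_id = design$sample_id,
                               length = c(21L, 22L, 24L))
    counts <- dplyr::left_join(grid, counts, by = c("sample_id", "length"))
    counts$count <- dplyr::coalesce(counts$count, 0L)
    counts$condition <- design$condition[match(counts$sample_id,
                                               design$sample_id)]
    res <- compare_size_classes_raw(counts)
    mean(res$statistic)
  }
  means <- vapply(c(0, 0.15, 0.3), function(dcl) {
    mean(vapply(1:20, function(s) stat_for(dcl, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
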