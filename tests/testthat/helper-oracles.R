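# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (explicit loops, no shared code with
# the package internals beyond exported entry points under test).

# manual complement, independent of Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all-substrings scan: every placement of `read` on `refseq`, both strands
oracle_map <- function(read, refseq) {
  L <- nchar(read)
  out <- list()
  rc <- oracle_revcomp(read)
  for (s in seq_len(nchar(refseq) - L + 1)) {
    win <- substr(refseq, s, s + L - 1)
    if (win == read) out[[length(out) + 1]] <- list(s, "sense")
    if (win == rc) out[[length(out) + 1]] <- list(s, "antisense")
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character()))
  }
  data.frame(start = vapply(out, function(x) x[[1]], 1),
             strand = vapply(out, function(x) x[[2]], ""))
}

# explicit-loop sliding-window profile over 5'-end counts
oracle_profile <- function(fp, ref_length, window, total) {
  cnt <- numeric(ref_length)
  for (p in fp) cnt[p] <- cnt[p] + 1
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  out <- numeric(ref_length)
  for (p in seq_len(ref_length)) {
    lo <- max(1, p - half_lo); hi <- min(ref_length, p + half_hi)
    out[p] <- mean(cnt[lo:hi]) / total
  }
  out
}

# two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, probabilities from choose() arithmetic
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  kk <- max(0, k - n):min(k, m)
  probs <- choose(m, kk) * choose(n, k - kk) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a tiny fixed reference for cheap deterministic tests
tiny_ref <- function(len = 200L, seed = 42L) {
  build_reference(len, seed = seed)
}

sorted_placements <- function(df) {
  df <- data.frame(start = as.integer(df$start),
                   strand = as.character(df$strand))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
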