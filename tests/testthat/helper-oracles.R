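# Independent oracles used by the property and acceptance tests.
#
# oracle_intervals() enumerates every candidate window [i..j] of probes
# directly (exhaustive window scan) instead of the package's run-length
# grouping: a window qualifies if all probes share the same non-zero
# state, successive starts are within max_gap, it has >= min_run probes
# and a tile-union span >= min_span. Probes covered by any qualifying
# window are merged into maximal same-sign intervals.
oracle_intervals <- function(chrom, start, value, state, tile_width,
                             max_gap, min_run, min_span) {
  n <- length(start)
  covered <- integer(n)
  for (i in seq_len(n)) {
    if (state[i] == 0L) next
    j <- i
    repeat {
      span <- start[j] + tile_width - start[i]
      if ((j - i + 1) >= min_run && span >= min_span) covered[i:j] <- state[i]
      if (j == n) break
      ok_next <- state[j + 1] == state[i] &&
        chrom[j + 1] == chrom[j] &&
        (start[j + 1] - start[j]) <= max_gap
      if (!ok_next) break
      j <- j + 1
    }
  }
  # merge covered probes into maximal intervals
  rows <- list()
  i <- 1
  while (i <= n) {
    if (covered[i] == 0L) { i <- i + 1; next }
    j <- i
    while (j < n && covered[j + 1] == covered[i] &&
           chrom[j + 1] == chrom[j] &&
           (start[j + 1] - start[j]) <= max_gap) {
      j <- j + 1
    }
    iv_start <- start[i]
    iv_end <- start[j] + tile_width
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = chrom[i], start = iv_start, end = iv_end,
      sign = as.numeric(covered[i]), score = mean(value[i:j]),
      n_probes = j - i + 1L)
    i <- j + 1
  }
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), sign = numeric(),
                          score = numeric(), n_probes = integer()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, chrom, start)
}

# Random sparse probe track: regular grid with randomly dropped probes
# and a mix of background and elevated scores, to exercise gap handling.
random_track <- function(n_probes, tile_width = 35, elevated_prob = 0.3,
                         drop_prob = 0.1, chroms = c("chr2L", "chr3R")) {
  chrom <- sort(sample(chroms, n_probes, replace = TRUE))
  start <- unlist(tapply(seq_len(n_probes), chrom, function(ix) {
    (seq_along(ix) - 1) * tile_width
  }, simplify = FALSE), use.names = FALSE)
  keep <- stats::runif(n_probes) >= drop_prob
  elevated <- stats::runif(n_probes) < elevated_prob
  score <- stats::rnorm(n_probes, ifelse(elevated, 4, 0), 1)
  polystate::probe_track(
    tibble::tibble(chrom = chrom, start = start, score = score)[keep, ],
    tile_width)
}

# Direct run-counting change-call rate on one pure-null delta vector
# (regular grid, no gaps): thresholds from the vector's own median/sd,
# rle over the per-probe state, probes inside runs of >= min_run.
direct_null_call_rate <- function(delta, k_sd = 2, min_run = 3) {
  thr_up <- stats::median(delta) + k_sd * stats::sd(delta)
  thr_dn <- stats::median(delta) - k_sd * stats::sd(delta)
  state <- ifelse(delta >= thr_up, 1L, ifelse(delta <= thr_dn, -1L, 0L))
  r <- rle(state)
  inside <- r$values != 0L & r$lengths >= min_run
  sum(r$lengths[inside]) / length(delta)
}

# Same counting, split by sign, returning interval counts.
direct_null_run_counts <- function(delta, k_sd = 2, min_run = 3) {
  thr_up <- stats::median(delta) + k_sd * stats::sd(delta)
  thr_dn <- stats::median(delta) - k_sd * stats::sd(delta)
  state <- ifelse(delta >= thr_up, 1L, ifelse(delta <= thr_dn, -1L, 0L))
  r <- rle(state)
  c(up = sum(r$values == 1L & r$lengths >= min_run),
    down = sum(r$values == -1L & r$lengths >= min_run))
}

# Small gene set laid out on one chromosome for region tests.
toy_genes <- function() {
  polystate::gene_models(tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr2L",
    strand = c("+", "-"),
    tx_start = c(1000, 6000),
    tx_end = c(3000, 9000)))
}

make_track_scores <- function(start, score, chrom = "chr2L", tw = 35) {
  polystate::probe_track(
    tibble::tibble(chrom = chrom, start = start, score = score), tw)
}
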