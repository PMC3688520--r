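make_track <- function(start, score, chrom = "chr2L", tw = 35) {
  probe_track(tibble::tibble(chrom = chrom, start = start, score = score), tw)
}

test_that("bound intervals require a threshold run of sufficient span", {
  tr <- make_track(c(0, 35, 70), c(5, 5, 5))
  iv <- call_bound_intervals(tr, tau = 3)
  expect_equal(iv[, c("start", "end")], tibble::tibble(start = 0, end = 105))
  expect_equal(iv$score, 5)

  # all below threshold -> empty
  expect_equal(nrow(call_bound_intervals(make_track(c(0, 35, 70), c(1, 2, 1)),
                                         tau = 3)), 0)
  # run of 2 with min_run 3 -> empty
  expect_equal(nrow(call_bound_intervals(make_track(c(0, 35), c(5, 5)),
                                         tau = 3)), 0)
})

test_that("a below-threshold probe breaks a run; a missing probe may not", {
  # missing grid position at 70: default merge_gap (one tile) bridges it
  tr <- make_track(c(0, 35, 105), c(5, 5, 5))
  iv <- call_bound_intervals(tr, tau = 3)
  expect_equal(iv$end - iv$start, 140)
  # with merge_gap = 0 the gap splits the run and neither piece survives
  expect_equal(nrow(call_bound_intervals(tr, tau = 3, merge_gap = 0)), 0)

  # probe present but below threshold always breaks the run
  tr2 <- make_track(c(0, 35, 70, 105, 140, 175, 210),
                    c(5, 5, 5, 1, 5, 5, 5))
  iv2 <- call_bound_intervals(tr2, tau = 3)
  expect_equal(nrow(iv2), 2)
  expect_true(all(iv2$end - iv2$start == 105))
})

test_that("bound caller matches the exhaustive window-scan oracle", {
  withr::local_seed(101)
  for (rep in 1:60) {
    tr <- random_track(sample(50:400, 1))
    tau <- runif(1, 1, 3)
    got <- call_bound_intervals(tr, tau = tau)
    state <- ifelse(tr$score >= tau, 1L, 0L)
    want <- oracle_intervals(tr$chrom, tr$start, tr$score, state,
                             35, max_gap = 70, min_run = 3, min_span = 105)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$score, want$score)
    # emitted intervals are sorted, non-overlapping, all probes >= tau
    if (nrow(got) > 1) {
      by_chr <- split(got, got$chrom)
      for (g in by_chr) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("gene binding needs >= 1 bp overlap with the transcription unit", {
  genes <- gene_models(tibble::tibble(
    gene_id = "g1", chrom = "chr2L", strand = "+",
    tx_start = 150, tx_end = 500))
  iv <- tibble::tibble(chrom = "chr2L", start = 100, end = 200, sign = 0,
                       score = 1)
  expect_equal(assign_gene_binding(iv, genes)$bound, 1L)
  # half-open: abutting interval does not overlap
  iv$end <- 150
  expect_equal(assign_gene_binding(iv, genes)$bound, 0L)
  expect_equal(assign_gene_binding(iv[0, ], genes)$bound, 0L)
})

test_that("overlap counts enumerate every factor combination exactly", {
  m <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      A = c(1, 1, 0), B = c(1, 0, 0))
  v <- overlap_counts(m, c("A", "B"))
  expect_equal(v$n_genes[v$combination == "A&B"], 1L)
  expect_equal(v$n_genes[v$combination == "A"], 1L)
  expect_equal(v$n_genes[v$combination == "B"], 0L)
  # counts sum to genes bound by >= 1 factor
  expect_equal(sum(v$n_genes), 2L)

  # single factor: counts equal column sums
  v1 <- overlap_counts(m, "A")
  expect_equal(v1$n_genes, 2L)

  # 3 factors on 8 genes covering all patterns -> each non-empty region 1
  pats <- expand.grid(A = 0:1, B = 0:1, C = 0:1)
  m8 <- tibble::as_tibble(pats) |>
    dplyr::mutate(gene_id = paste0("g", 1:8), .before = 1)
  v8 <- overlap_counts(m8, c("A", "B", "C"))
  expect_equal(nrow(v8), 7)
  expect_true(all(v8$n_genes == 1L))

  expect_error(overlap_counts(m, c("A", "Z")), "Z")
})

test_that("genome-wide correlation is Pearson r over shared probes", {
  a <- make_track(c(0, 35, 70), c(1, 2, 3))
  expect_equal(genomewide_correlation(a, a)$r, 1.0)
  neg <- make_track(c(0, 35, 70), -c(1, 2, 3))
  expect_equal(genomewide_correlation(a, neg)$r, -1.0)

  # textbook formula oracle on a hand example
  b <- make_track(c(0, 35, 70), c(1, 2, 4))
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(genomewide_correlation(a, b)$r, r_hand)
  expect_equal(genomewide_correlation(a, b)$n_probes, 3L)

  # invariance under positive-slope affine transforms
  withr::local_seed(5)
  t1 <- make_track((0:99) * 35, rnorm(100))
  t2 <- make_track((0:99) * 35, rnorm(100))
  r0 <- genomewide_correlation(t1, t2)$r
  t1b <- make_track(t1$start, 3.7 * t1$score + 11)
  expect_equal(genomewide_correlation(t1b, t2)$r, r0)

  one <- make_track(0, 1)
  expect_error(genomewide_correlation(one, one), "fewer than 2")
  flat <- make_track(c(0, 35), c(1, 1))
  expect_error(genomewide_correlation(flat, flat), "zero variance")
})
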