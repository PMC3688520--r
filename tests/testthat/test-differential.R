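fake_null <- function(median = 0, sd = 1) {
  structure(list(median = median, mean = median, sd = sd, n = 1000L),
            class = "null_stats")
}

make_delta <- function(start, delta, chrom = "chr2L", tw = 35) {
  out <- dplyr::arrange(tibble::tibble(chrom = chrom, start = start,
                                       delta = delta), chrom, start)
  attr(out, "tile_width") <- tw
  class(out) <- unique(c("delta_track", "probe_track", class(out)))
  out
}

test_that("null statistics summarise the delta distribution", {
  d <- make_delta(c(0, 35, 70), c(-1, 0, 1))
  ns <- null_stats(d)
  expect_equal(ns$median, 0)
  expect_equal(ns$mean, 0)
  expect_equal(ns$sd, 1)  # sample SD
  expect_equal(tidy(ns)$n, 3L)

  expect_error(null_stats(make_delta(c(0, 35, 70), c(2, 2, 2))),
               "degenerate")
  expect_warning(null_stats(make_delta((0:99) * 35, c(rnorm(99, 5, 1), -40))),
                 "shifted")

  # recovers the generating SD on a seeded Monte-Carlo draw
  withr::local_seed(21)
  d2 <- make_delta((0:9999) * 35, rnorm(10000, 0, 0.8))
  expect_lt(abs(null_stats(d2)$sd - 0.8) / 0.8, 0.05)
})

test_that("change intervals need k-sd runs of three probes over 105 bp", {
  ns <- fake_null()
  expect_equal(nrow(call_change_intervals(
    make_delta(c(0, 35, 70, 105), c(0, 0, 0, 0)), ns)), 0)

  up <- call_change_intervals(make_delta(c(0, 35, 70), c(2.5, 2.5, 2.5)), ns)
  expect_equal(up[, c("start", "end")], tibble::tibble(start = 0, end = 105),
               ignore_attr = TRUE)
  expect_equal(up$sign, 1)

  # two probes beyond threshold: too short
  expect_equal(nrow(call_change_intervals(
    make_delta(c(0, 35), c(3, 3)), ns)), 0)

  # decreases are called with sign -1; opposite signs never merge
  mix <- call_change_intervals(
    make_delta((0:5) * 35, c(-3, -3, -3, 3, 3, 3)), ns)
  expect_equal(mix$sign, c(-1, 1))
  expect_equal(mix$start, c(0, 105))
  expect_equal(glance(mix)$n_increase, 1L)
  expect_equal(glance(mix)$n_decrease, 1L)
})

test_that("change caller matches the exhaustive window-scan oracle", {
  withr::local_seed(202)
  ns <- fake_null(median = 0.1, sd = 1)
  for (rep in 1:60) {
    tr <- random_track(sample(50:400, 1), elevated_prob = 0)
    # inject symmetric up/down stretches
    delta <- tr$score + sample(c(-4, 0, 0, 4), nrow(tr), replace = TRUE)
    d <- make_delta(tr$start, delta, chrom = tr$chrom)
    got <- call_change_intervals(d, ns)
    state <- ifelse(delta >= ns$median + 2, 1L,
                    ifelse(delta <= ns$median - 2, -1L, 0L))
    want <- oracle_intervals(tr$chrom, tr$start, delta, state,
                             35, max_gap = 70, min_run = 3, min_span = 105)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$sign, want$sign)
    expect_equal(got$score, want$score)
  }
})

test_that("raising k_sd or min_run never increases the number of calls", {
  withr::local_seed(303)
  d <- make_delta((0:1999) * 35, rnorm(2000, 0, 1) +
                    rep(sample(c(-2.5, 0, 2.5), 200, replace = TRUE),
                        each = 10))
  ns <- null_stats(d)
  n_prev <- Inf
  for (k in c(1, 1.5, 2, 2.5, 3)) {
    n_k <- nrow(call_change_intervals(d, ns, change_call_params(k_sd = k)))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
  n_prev <- Inf
  for (mr in c(1, 2, 3, 5, 8)) {
    n_mr <- nrow(call_change_intervals(
      d, ns, change_call_params(min_run = mr, min_span = 35)))
    expect_lte(n_mr, n_prev)
    n_prev <- n_mr
  }
})

test_that("integrated gene deltas sum shared probes within regions", {
  ctrl <- make_track_scores(c(1000, 1035), c(1, 2))
  depl <- make_track_scores(c(1000, 1035), c(2, 4))
  region <- tibble::tibble(gene_id = "g1", chrom = "chr2L",
                           start = 900, end = 1200)
  out <- integrated_gene_delta(ctrl, depl, region)
  expect_equal(out$delta_total, 3)
  expect_false(out$no_data)

  expect_equal(integrated_gene_delta(ctrl, ctrl, region)$delta_total, 0)

  far <- tibble::tibble(gene_id = "g2", chrom = "chr2L",
                        start = 5000, end = 6000)
  out2 <- integrated_gene_delta(ctrl, depl, far)
  expect_true(out2$no_data)
  expect_true(is.na(out2$delta_total))
})

test_that("pause index is the promoter/body median ratio", {
  g <- gene_models(tibble::tibble(gene_id = "g1", chrom = "chr2L",
                                  strand = "+", tx_start = 1000,
                                  tx_end = 3000))
  # promoter window [800, 1200); body [1200, 3000)
  tr <- make_track_scores(c(850, 950, 1050, 1300, 1400, 1500),
                          c(2, 2, 2, 1, 1, 1))
  expect_equal(pause_index(tr, g)$pause_index, 2)

  # uniform track -> PI 1
  expect_equal(pause_index(make_track_scores(seq(800, 2900, 35),
                                             rep(2, 61)), g)$pause_index, 1)

  # hand medians: promoter (1,3,5), body (1,2,2,4) -> 3 / 2
  tr3 <- make_track_scores(c(850, 950, 1050, 1300, 1400, 1500, 1600),
                           c(1, 3, 5, 1, 2, 2, 4))
  expect_equal(pause_index(tr3, g)$pause_index, 1.5)

  # scale invariance: PI unchanged under score * c, c > 0
  tr3b <- probe_track(dplyr::mutate(tibble::as_tibble(tr3),
                                    score = score * 7.3), 35)
  expect_equal(pause_index(tr3b, g)$pause_index, 1.5)

  # flags: no probes -> no_data; non-positive body median -> undefined
  expect_equal(pause_index(make_track_scores(c(850, 950, 1050), c(1, 1, 1)),
                           g)$flag, "no_data")
  neg <- make_track_scores(c(850, 950, 1050, 1300, 1400, 1500),
                           c(2, 2, 2, -1, -1, -1))
  expect_equal(pause_index(neg, g)$flag, "undefined")

  # minus-strand gene: promoter centred at tx_end - 1
  gm <- gene_models(tibble::tibble(gene_id = "gm", chrom = "chr2L",
                                   strand = "-", tx_start = 1000,
                                   tx_end = 3000))
  trm <- make_track_scores(c(2810, 2900, 1300, 1400, 1500), c(4, 4, 2, 2, 2))
  expect_equal(pause_index(trm, gm)$pause_index, 2)
})

test_that("elongation ratio divides body medians of shared probes", {
  g <- gene_models(tibble::tibble(gene_id = "g1", chrom = "chr2L",
                                  strand = "+", tx_start = 1000,
                                  tx_end = 3000))
  ser2p <- make_track_scores(c(1300, 1400), c(4, 4))
  rpb3 <- make_track_scores(c(1300, 1400), c(2, 2))
  expect_equal(elongation_ratio(ser2p, rpb3, g)$ratio, 2)
  expect_equal(elongation_ratio(rpb3, rpb3, g)$ratio, 1)
  zero <- make_track_scores(c(1300, 1400), c(0, 0))
  expect_equal(elongation_ratio(ser2p, zero, g)$flag, "undefined")
})

test_that("gene change classes follow the region overlap rules", {
  g <- gene_models(tibble::tibble(gene_id = "g1", chrom = "chr2L",
                                  strand = "+", tx_start = 1000,
                                  tx_end = 3000))
  up_body <- tibble::tibble(chrom = "chr2L", start = 1500, end = 1605,
                            sign = 1, score = 2)
  cls <- classify_gene_changes(up_body, g)
  expect_equal(cls$class[cls$region == "body"], "UP")
  expect_equal(cls$resolved_class[cls$region == "body"], "UP")
  expect_equal(cls$class[cls$region == "promoter"], "NONE")

  none <- classify_gene_changes(up_body[0, ], g)
  expect_true(all(none$class == "NONE"))

  # ambiguous: increase span 105 vs decrease span 210, equal |mean delta|
  # -> weighted-area rule resolves DOWN
  both <- tibble::tibble(chrom = "chr2L", start = c(1500, 2000),
                         end = c(1605, 2210), sign = c(1, -1),
                         score = c(2, -2))
  cls2 <- classify_gene_changes(both, g)
  body <- cls2[cls2$region == "body", ]
  expect_equal(body$class, "AMBIGUOUS")
  expect_equal(body$resolved_class, "DOWN")
  expect_equal(body$weight_up, 2 * 105)
  expect_equal(body$weight_down, 2 * 210)

  # exact tie stays unresolved
  tie <- tibble::tibble(chrom = "chr2L", start = c(1500, 2000),
                        end = c(1605, 2105), sign = c(1, -1),
                        score = c(2, -2))
  expect_true(is.na(classify_gene_changes(tie, g) |>
                      dplyr::filter(region == "body") |>
                      dplyr::pull(resolved_class)))
})

test_that("category percentages use resolved classes and flag empty groups", {
  classes <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    class = c(rep("UP", 3), rep("DOWN", 2), "AMBIGUOUS", rep("NONE", 4)),
    resolved_class = c(rep("UP", 3), rep("DOWN", 2), "UP",
                       rep(NA_character_, 4)))
  groups <- tibble::tibble(gene_id = paste0("g", 1:10), group = "cohesin")
  pct <- category_percentages(classes, groups)
  expect_equal(pct$pct_up, 40)
  expect_equal(pct$pct_down, 20)
  expect_equal(pct$pct_ambiguous, 10)

  # 4 genes, 2 DOWN -> 50% DOWN
  cl4 <- tibble::tibble(gene_id = paste0("h", 1:4),
                        class = c("DOWN", "DOWN", "NONE", "NONE"),
                        resolved_class = c("DOWN", "DOWN", NA, NA))
  g4 <- tibble::tibble(gene_id = paste0("h", 1:4), group = "bound")
  expect_equal(category_percentages(cl4, g4)$pct_down, 50)

  # empty factor level is flagged, not reported as 0%
  g4f <- dplyr::mutate(g4, group = factor("bound", levels = c("bound", "free")))
  pctf <- category_percentages(cl4, g4f)
  empty <- pctf[pctf$group == "free", ]
  expect_true(empty$empty_group)
  expect_true(is.na(empty$pct_down))
})
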