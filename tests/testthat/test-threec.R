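test_that("BAC normalization divides replicate means by primer efficiency", {
  qpcr <- tibble::tibble(anchor_id = "a", fragment_id = c("f1", "f1"),
                         quantity = c(8, 8))
  bac <- tibble::tibble(anchor_id = "a", fragment_id = "f1", bac_quantity = 4)
  out <- normalize_interactions(qpcr, bac)
  expect_equal(out$interaction, 2)
  expect_equal(out$se, 0)

  # hand SE: quantities (4, 8) / bac 4 -> (1, 2); SE = sd/sqrt(2) = 0.5
  qpcr2 <- tibble::tibble(anchor_id = "a", fragment_id = c("f1", "f1"),
                          quantity = c(4, 8))
  out2 <- normalize_interactions(qpcr2, bac)
  expect_equal(out2$interaction, 1.5)
  expect_equal(out2$se, 0.5)

  expect_error(normalize_interactions(
    qpcr, dplyr::mutate(bac, bac_quantity = 0)), "BAC control")

  # single replicate: SE undefined, flagged
  out3 <- normalize_interactions(qpcr[1, ], bac)
  expect_true(is.na(out3$se))
  expect_equal(out3$flag, "single_replicate")

  # biological-replicate SE reported alongside the pooled SE
  qpcr4 <- tibble::tibble(anchor_id = "a", fragment_id = "f1",
                          biological = c("b1", "b1", "b2", "b2"),
                          quantity = c(4, 8, 6, 6))
  out4 <- normalize_interactions(qpcr4, bac)
  expect_equal(out4$n_reps, 4L)
  expect_false(is.na(out4$se_biological))
})

test_that("normalization is invariant to primer-efficiency scaling", {
  withr::local_seed(31)
  for (i in 1:20) {
    q <- runif(4, 1, 10)
    b <- runif(1, 0.5, 5)
    f <- runif(1, 0.1, 20)  # shared scaling factor
    base <- normalize_interactions(
      tibble::tibble(anchor_id = "a", fragment_id = "f1", quantity = q),
      tibble::tibble(anchor_id = "a", fragment_id = "f1", bac_quantity = b))
    scaled <- normalize_interactions(
      tibble::tibble(anchor_id = "a", fragment_id = "f1", quantity = q * f),
      tibble::tibble(anchor_id = "a", fragment_id = "f1",
                     bac_quantity = b * f))
    expect_equal(scaled$interaction, base$interaction)
    expect_equal(scaled$se, base$se)
  }
})

test_that("profiles order fragments by coordinate and flag self-ligation", {
  pts <- tibble::tibble(anchor_id = "b",
                        fragment_id = c("f3", "b", "f1"),
                        interaction = c(1, 9, 3), se = c(0.1, 0.5, 0.2))
  frags <- tibble::tibble(fragment_id = c("f1", "b", "f3"),
                          chrom = "chr2R",
                          start = c(0, 5000, 20000),
                          end = c(4000, 9000, 24000))
  pr <- interaction_profile(pts, "b", frags)
  expect_equal(pr$fragment_id, c("f1", "b", "f3"))
  expect_equal(pr$self_ligation, c(FALSE, TRUE, FALSE))

  expect_equal(nrow(interaction_profile(pts[0, ], "b", frags)), 0)
  expect_error(interaction_profile(
    dplyr::mutate(pts, fragment_id = c("f3", "b", "zz")), "b", frags), "zz")
})

test_that("condition comparison flags decreased loops with propagated SE", {
  frags <- tibble::tibble(fragment_id = c("f1", "f2", "f3"), chrom = "chr2R",
                          start = c(0, 5000, 10000), end = c(4000, 9000, 14000))
  mk <- function(i, se = 0) {
    interaction_profile(tibble::tibble(anchor_id = "b",
                                       fragment_id = frags$fragment_id,
                                       interaction = i, se = se), "b", frags)
  }
  ctrl <- mk(c(2, 1, 0))
  depl <- mk(c(1, 1, 1))
  cmp <- compare_conditions(ctrl, depl)
  expect_equal(cmp$ratio[cmp$fragment_id == "f1"], 0.5)
  expect_true(cmp$decreased[cmp$fragment_id == "f1"])
  expect_false(cmp$decreased[cmp$fragment_id == "f2"])
  expect_equal(cmp$flag[cmp$fragment_id == "f3"], "undefined")

  # identical profiles: all ratios 1, nothing flagged
  same <- compare_conditions(mk(c(2, 1, 3)), mk(c(2, 1, 3)))
  expect_true(all(same$ratio == 1))
  expect_false(any(same$decreased))

  # a large SE suppresses the decreased flag
  noisy <- compare_conditions(mk(c(2, 1, 3), se = 1), mk(c(1.8, 1, 3), se = 1))
  expect_false(any(noisy$decreased))

  expect_error(compare_conditions(ctrl, mk(c(1, 1, 1))[1:2, ]),
               "different fragment sets")
})

test_that("simulated qPCR tables recover the generating interactions", {
  loops <- tibble::tibble(anchor_id = "b",
                          fragment_id = c("f1", "f2", "f3"),
                          true_I = c(2, 0.5, 0))
  # noise-free: exact recovery including the zero-strength pair
  sim0 <- simulate_3c(loops, cv = 0, seed = 4)
  out0 <- normalize_interactions(sim0$qpcr, sim0$bac)
  expect_equal(out0$interaction[match(loops$fragment_id, out0$fragment_id)],
               loops$true_I)

  # with noise: recovered means within 2 SE of truth (Monte-Carlo)
  simn <- simulate_3c(loops[1:2, ], cv = 0.1, n_biological = 2,
                      n_reactions = 2, seed = 8)
  outn <- normalize_interactions(simn$qpcr, simn$bac)
  outn <- outn[match(loops$fragment_id[1:2], outn$fragment_id), ]
  expect_true(all(abs(outn$interaction - loops$true_I[1:2]) <= 2 * outn$se))

  expect_error(simulate_3c(dplyr::mutate(loops, true_I = -1)), ">= 0")
})
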