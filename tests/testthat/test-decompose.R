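test_that("rates are enumerated directly from paired misses", {
  r <- compute_rates(tiny_paired_session())
  expect_equal(r$P1, 0.5)
  expect_equal(r$P2, 0.25)
  expect_equal(r$P12, 0.25)
  expect_equal(r$n_pairs, 4L)

  all_hits <- tiny_paired_session()
  all_hits$response <- "present"
  r0 <- compute_rates(all_hits)
  expect_equal(c(r0$P1, r0$P2, r0$P12), c(0, 0, 0))
})

test_that("compute_rates demands complete pairs", {
  broken <- tiny_paired_session()[-1, ]
  expect_error(compute_rates(broken), "complete pairs")
  absent_only <- tiny_paired_session()
  absent_only$target_present <- FALSE
  expect_error(compute_rates(absent_only), "target-present")
})

test_that("the no-cue solver inverts the composition equations", {
  # stochastic limit: P12 = P1 * P2 forces d = 0
  est <- solve_nocue(tibble::tibble(P1 = 0.1, P2 = 0.1, P12 = 0.01))
  expect_equal(c(est$d, est$s1, est$s2), c(0, 0.1, 0.1), tolerance = 1e-12)

  # deterministic limit: P12 = min forces s = 0
  est2 <- solve_nocue(tibble::tibble(P1 = 0.2, P2 = 0.2, P12 = 0.2))
  expect_equal(c(est2$d, est2$s1, est2$s2), c(0.2, 0, 0), tolerance = 1e-12)

  # the worked mixed case
  est3 <- solve_nocue(tibble::tibble(P1 = 0.164, P2 = 0.126, P12 = 0.05912))
  expect_equal(c(est3$d, est3$s1, est3$s2), c(0.05, 0.12, 0.08),
               tolerance = 1e-12)
})

test_that("slightly negative d is rounded to zero and flagged", {
  est <- solve_nocue(tibble::tibble(P1 = 0.1, P2 = 0.1, P12 = 0.0098))
  # raw value: (0.0098 - 0.01) / (1 - 0.2 + 0.0098) = -2.47e-4
  expect_equal(est$d, 0)
  expect_true(est$rounded_d)
  expect_false(est$excluded)

  # below the -0.002 threshold the participant is excluded
  est2 <- solve_nocue(tibble::tibble(P1 = 0.2, P2 = 0.2, P12 = 0.03))
  expect_lt((0.03 - 0.04) / (1 - 0.4 + 0.03), -0.002)
  expect_true(est2$excluded)
  expect_equal(est2$exclusion_reason, "d_below_threshold")
})

test_that("degenerate denominators are excluded, not infinite", {
  est <- solve_nocue(tibble::tibble(P1 = 1, P2 = 0.5, P12 = 0.5))
  expect_true(est$excluded)
  expect_equal(est$exclusion_reason, "degenerate_denominator")
  expect_true(is.na(est$d))
})

test_that("the cue solver recovers all four parameters from composed rates", {
  r <- compose_rates(d1 = 0.10, d2 = 0.04, s1 = 0.12, s2 = 0.08)
  expect_equal(unlist(r), c(P1 = 0.208, P2 = 0.1168, P12 = 0.05344),
               tolerance = 1e-12)
  est <- solve_cue(r, d1_ref = 0.10)
  expect_equal(c(est$d2, est$s1, est$s2), c(0.04, 0.12, 0.08),
               tolerance = 1e-12)

  # model nesting: with d1 = d2 the cue solver reproduces the no-cue one
  r2 <- compose_rates(d1 = 0.07, s1 = 0.1, s2 = 0.06)
  nocue <- solve_nocue(r2)
  cue <- solve_cue(r2, d1_ref = nocue$d)
  expect_equal(cue$d2, nocue$d, tolerance = 1e-10)
  expect_equal(cue$s1, nocue$s1, tolerance = 1e-10)
  expect_equal(cue$s2, nocue$s2, tolerance = 1e-10)

  # negative s1 exclusion when the borrowed d1 exceeds P1
  est3 <- solve_cue(tibble::tibble(P1 = 0.05, P2 = 0.1, P12 = 0.02),
                    d1_ref = 0.10)
  expect_true(est3$excluded)
  expect_equal(est3$exclusion_reason, "negative_s1")
})

test_that("round trip is exact over random parameter draws", {
  set.seed(101)
  n <- 2000
  d <- runif(n, 0, 0.9)
  s1 <- runif(n, 0, 0.9)
  s2 <- runif(n, 0, 0.9)
  est <- solve_nocue(compose_rates(d1 = d, s1 = s1, s2 = s2))
  expect_lt(max(abs(est$d - d)), 1e-12)
  expect_lt(max(abs(est$s1 - s1)), 1e-12)
  expect_lt(max(abs(est$s2 - s2)), 1e-12)

  d1 <- runif(n, 0, 0.9)
  d2 <- d1 * runif(n)
  est2 <- solve_cue(compose_rates(d1 = d1, d2 = d2, s1 = s1, s2 = s2),
                    d1_ref = d1)
  expect_lt(max(abs(est2$d2 - d2)), 1e-12)
  expect_lt(max(abs(est2$s1 - s1)), 1e-12)
  expect_lt(max(abs(est2$s2 - s2)), 1e-12)
})

test_that("composed rates always respect the mixture ordering", {
  set.seed(202)
  n <- 5000
  d1 <- runif(n)
  r <- compose_rates(d1 = d1, d2 = d1 * runif(n), s1 = runif(n),
                     s2 = runif(n))
  expect_true(all(r$P12 >= r$P1 * r$P2 - 1e-12))
  expect_true(all(r$P12 <= pmin(r$P1, r$P2) + 1e-12))
  p <- predictions(r)
  expect_true(all(p$stoch_pred <= p$det_pred + 1e-12))
})

test_that("prediction bounds are plain arithmetic on the rates", {
  p <- predictions(tibble::tibble(P1 = c(0.3, 0, 1), P2 = c(0.2, 0.4, 1)))
  expect_equal(p$stoch_pred, c(0.06, 0, 1))
  expect_equal(p$det_pred, c(0.2, 0, 1))
})

test_that("contrast stratification splits the discrete levels correctly", {
  levels <- c(-105, -75, -45, -15, 15, 45, 75, 105)
  des <- pair_design(400, 0, tb_contrast = levels, seed = 9)
  lt <- latent_params(d1 = 0.3, d2 = 0.3, s1 = 0.05, s2 = 0.05, fa_rate = 0,
                      contrast_link = c(threshold = 40, slope = 15))
  tr <- simulate_participant(des, lt, seed = 30)
  strat <- split_by_contrast(tr, threshold = 30)
  expect_setequal(strat$contrast_stratum, c("low", "high"))
  n_low <- strat$n_pairs[strat$contrast_stratum == "low"]
  expect_equal(n_low, 100L)  # the +/-15 levels are a quarter of the pairs

  # a single stratum reproduces compute_rates
  one <- split_by_contrast(tr, threshold = 1000)
  base <- compute_rates(tr)
  expect_equal(one$P1, base$P1)
  expect_equal(one$P12, base$P12)
})

test_that("low-contrast targets yield larger solved d under a contrast link", {
  levels <- c(-105, -75, -45, -15, 15, 45, 75, 105)
  des <- pair_design(4000, 0, tb_contrast = levels, seed = 10)
  lt <- latent_params(d1 = 0.3, d2 = 0.3, s1 = 0.08, s2 = 0.08, fa_rate = 0,
                      contrast_link = c(threshold = 40, slope = 15))
  tr <- simulate_participant(des, lt, seed = 31)
  est <- solve_nocue(split_by_contrast(tr, threshold = 30))
  expect_gt(est$d[est$contrast_stratum == "low"],
            est$d[est$contrast_stratum == "high"])
})

test_that("decompose_cohort handles cued and uncued conditions together", {
  des <- build_design("exp3", seed = 12)
  lt <- latent_params(d1 = 0.10, d2 = 0.04, s1 = 0.12, s2 = 0.08)
  coh <- simulate_cohort(6, des, lt, seed = 40)
  est <- decompose_cohort(coh)
  expect_setequal(unique(est$condition), c("noCue-Cue", "noCue-noCue"))
  expect_equal(nrow(est), 12)
  # the cued rows borrow each participant's own uncued d
  nn <- est[est$condition == "noCue-noCue", ]
  nc <- est[est$condition == "noCue-Cue", ]
  expect_equal(nc$d1, nn$d[match(nc$participant_id, nn$participant_id)])
  # uncued data produce a single "all" condition
  des0 <- pair_design(100, 100, seed = 13)
  est0 <- decompose_cohort(simulate_cohort(3, des0, seed = 41))
  expect_true(all(est0$condition == "all"))
  expect_true(all(c("stoch_pred", "det_pred") %in% names(est0)))
})
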