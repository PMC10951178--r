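test_that("one-sample t matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  res <- one_sample_t(x)
  expect_equal(res$statistic, mean(x) / (sd(x) / sqrt(5)), tolerance = 1e-10)
  expect_equal(res$statistic, 4.242641, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(res$statistic), 4),
               tolerance = 1e-10)
  expect_equal(res$cohens_d, mean(x) / sd(x), tolerance = 1e-10)

  sym <- c(-2, -1, 0, 1, 2)
  res0 <- one_sample_t(sym)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(one_sample_t(c(1)), "at least 2")
  expect_error(one_sample_t(rep(3, 10)), "Zero standard deviation")
})

test_that("paired t is the one-sample t on differences", {
  y <- rep(0, 4)
  x <- c(1, 1, 1, -1)
  res <- paired_t(x, y)
  expect_equal(res$statistic, 1.0, tolerance = 1e-12)  # mean .5, sd 1, n 4
  expect_equal(res$df, 3)
  expect_equal(res$kind, "paired_t")

  # identical vectors: no difference at all, t = 0 by convention
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "equal length")
  # constant nonzero difference still has an undefined t
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "Zero standard deviation")
})

test_that("miss_rate_diff compares P2 - P1 across cue conditions", {
  est <- tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:5), each = 2),
    condition = rep(c("noCue-Cue", "noCue-noCue"), 5),
    P1 = rep(0.2, 10),
    P2 = c(0.10, 0.18, 0.12, 0.20, 0.08, 0.16, 0.11, 0.19, 0.09, 0.21)
  )
  mrd <- miss_rate_diff(est)
  td <- tidy(mrd)
  expect_equal(nrow(td), 10)
  gl <- glance(mrd)
  expect_equal(gl$kind, "paired_t")
  expect_lt(gl$p_value, 0.05)  # cue consistently lowers P2

  # identical conditions give t = 0 (needs nonzero SD across participants)
  est2 <- est
  est2$P2 <- rep(c(0.10, 0.12, 0.08, 0.11, 0.09), each = 2)
  gl2 <- glance(miss_rate_diff(est2))
  expect_equal(gl2$statistic, 0)

  # participants missing a condition are dropped with a warning
  expect_warning(miss_rate_diff(est[-1, ]), "dropped")
  # a single participant cannot be tested
  expect_error(suppressWarnings(miss_rate_diff(est[1:2, ])), "at least 2")
})

test_that("cued simulations show a larger second-pass miss drop", {
  des <- build_design("exp3", seed = 14)
  lt <- latent_params(d1 = 0.15, d2 = 0.03, s1 = 0.10, s2 = 0.10)
  coh <- simulate_cohort(12, des, lt, seed = 50)
  est <- decompose_cohort(coh)
  mrd <- miss_rate_diff(est)
  diffs <- tidy(mrd) |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(p2_minus_p1))
  expect_lt(diffs$m[diffs$condition == "noCue-Cue"],
            diffs$m[diffs$condition == "noCue-noCue"])
})

test_that("binned hit rates are correct and order-invariant", {
  lvls <- c(-105, -75, -45, -15, 15, 45, 75, 105)
  des <- pair_design(160, 0, tb_contrast = lvls, seed = 15)
  coh <- simulate_cohort(4, des, latent_params(d1 = 0, d2 = 0, s1 = 0,
                                               s2 = 0, fa_rate = 0),
                         seed = 60)
  bh <- bin_hit_rates(coh)
  expect_equal(nrow(bh), 8)          # discrete levels, no binning
  expect_true(all(bh$hit_rate == 1)) # error-free cohort
  expect_true(all(bh$sem == 0))

  shuffled <- coh[sample(nrow(coh)), ]
  expect_equal(tibble::as_tibble(bin_hit_rates(shuffled)),
               tibble::as_tibble(bh))
})

test_that("continuous contrasts are binned at the requested width", {
  tr <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 100),
    target_present = TRUE,
    tb_contrast = rep(seq(-99.5, 99.5, length.out = 100), 2),
    response = rep(c("present", "absent"), 100)
  )
  bh <- bin_hit_rates(tr, bin_width = 50, discrete = FALSE)
  expect_equal(bh$tb_center, c(-75, -25, 25, 75))
  expect_true(all(abs(bh$hit_rate - 0.5) < 0.25))
})

test_that("hit rate rises with contrast under a contrast link", {
  lvls <- c(-105, -75, -45, -15, 15, 45, 75, 105)
  des <- pair_design(2000, 0, tb_contrast = lvls, seed = 16)
  lt <- latent_params(d1 = 0.4, d2 = 0.4, s1 = 0.05, s2 = 0.05, fa_rate = 0,
                      contrast_link = c(threshold = 40, slope = 15))
  coh <- simulate_cohort(3, des, lt, seed = 61)
  bh <- bin_hit_rates(coh)
  by_abs <- tapply(bh$hit_rate, abs(bh$tb_center), mean)
  rates <- by_abs[order(as.numeric(names(by_abs)))]
  expect_gt(rates[length(rates)], rates[1])
})

test_that("the P12 table pairs observations with both predictions", {
  # pure stochastic cohort: observed P12 hugs the stochastic prediction
  des <- pair_design(3000, 0, seed = 17)
  lt <- latent_params(d1 = 0, d2 = 0, s1 = 0.15, s2 = 0.12, fa_rate = 0)
  est <- decompose_cohort(simulate_cohort(5, des, lt, seed = 70))
  p12 <- scatter_p12(est)
  se <- sqrt(p12$stoch_pred * (1 - p12$stoch_pred) / 3000)
  expect_true(all(abs(p12$P12 - p12$stoch_pred) < 4 * se))

  # pure deterministic cohort: observed P12 equals the deterministic bound
  ltd <- latent_params(d1 = 0.2, d2 = 0.2, s1 = 0, s2 = 0, fa_rate = 0)
  estd <- decompose_cohort(simulate_cohort(3, des, ltd, seed = 71))
  p12d <- scatter_p12(estd)
  expect_equal(p12d$P12, p12d$det_pred, tolerance = 1e-12)

  # mixed cohort: observed strictly between the bounds on average
  ltm <- latent_params(d1 = 0.1, d2 = 0.1, s1 = 0.15, s2 = 0.15,
                       fa_rate = 0)
  estm <- decompose_cohort(simulate_cohort(5, des, ltm, seed = 72))
  p12m <- scatter_p12(estm)
  expect_gt(mean(p12m$P12 - p12m$stoch_pred), 0)
  expect_lt(mean(p12m$P12 - p12m$det_pred), 0)
})

test_that("plot builders return ggplot objects", {
  des <- pair_design(200, 200, tb_contrast = c(-50, 50), seed = 18)
  est <- decompose_cohort(simulate_cohort(3, des, seed = 80))
  expect_s3_class(ggplot2::autoplot(scatter_p12(est)), "ggplot")
  expect_s3_class(plot_estimates(est), "ggplot")
  coh <- simulate_cohort(3, des, seed = 81)
  expect_s3_class(ggplot2::autoplot(bin_hit_rates(coh)), "ggplot")
})

test_that("RT summaries are descriptive per-cell means", {
  des <- pair_design(100, 100, seed = 19)
  coh <- simulate_cohort(4, des, seed = 90)
  rs <- rt_summary(coh)
  expect_true(all(c("mean_rt_ms", "sem") %in% names(rs)))
  expect_true(all(rs$mean_rt_ms > 0))
  # absent trials slower on average
  m <- tapply(rs$mean_rt_ms, rs$target_present, mean)
  expect_gt(m["FALSE"], m["TRUE"])
})

test_that("trial logs round-trip through CSV with latent sidecar", {
  des <- pair_design(20, 20, seed = 20)
  coh <- simulate_cohort(2, des, seed = 91)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(coh, path)
  expect_true(file.exists(paste0(path, ".latent.json")))
  back <- read_trials(path)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$response, coh$response)
  expect_equal(latent_truth(back)$d1, latent_truth(coh)$d1)
})
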