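test_that("rescale01 maps to the unit interval and is affine-invariant", {
  expect_equal(rescale01(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.2, 0.77, 1)
  expect_equal(rescale01(v), v)
  set.seed(61)
  x <- rnorm(50)
  expect_equal(rescale01(3.7 * x + 11), rescale01(x), tolerance = 1e-12)
  expect_error(rescale01(rep(1, 5)), "constant")
})

test_that("rank_p follows the (k+1)/(n+1) convention and is uniform under exchangeability", {
  null <- 1:100
  expect_equal(rank_p(1000, null), 1)
  expect_equal(rank_p(-5, null), 1 / 101)
  expect_equal(rank_p(50.5, null), 51 / 101)

  set.seed(62)
  ps <- replicate(2000, rank_p(rnorm(1), rnorm(100)))
  lo <- mean(ps < 0.05); hi <- mean(ps > 0.95)
  expect_gte(lo, 0.02); expect_lte(lo, 0.10)
  expect_gte(hi, 0.02); expect_lte(hi, 0.10)
})

test_that("trend regression recovers a monotone synthetic rate profile", {
  tr <- small_bd_tree(seed = 18)
  ctx <- rr_context(tr)
  # rate magnitudes constructed as exp(age): the log pipeline must see a
  # positive slope
  synth <- structure(list(rates = setNames(exp(unname(ctx$branch_age)),
                                           colnames(ctx$L)),
                          context = ctx), class = "rr_fit")
  reg <- trend_regression(synth)
  expect_gt(reg$slope, 0)
  expect_equal(nrow(reg$data), length(synth$rates))

  # age-shuffled rates carry no trend: permutation-null slope centred on zero
  lr <- reg$data$log_rescaled_rate
  ages <- reg$data$age
  set.seed(64)
  null_slopes <- replicate(500, {
    s <- sample(lr)
    cov(ages, s) / var(ages)
  })
  expect_lt(abs(mean(null_slopes)), 2 * sd(null_slopes) / sqrt(500) * 4)
})

test_that("drift regression flags a perfectly linear phenotype", {
  tr <- small_bd_tree(seed = 19)
  ages <- element_ages(tr)[seq_len(ape::Ntip(tr))]
  y <- setNames(2 + 0.8 * ages, tr$tip.label)   # exact linear signal, no noise
  rep <- search_trend(tr, y + rnorm(length(y), sd = 1e-3), n_null = 100, seed = 65)
  expect_gt(rep$drift_p, 0.95)
  expect_identical(rep$drift_verdict, "+")
})

test_that("null slope families are reproducible and need not centre on zero", {
  tr <- small_bd_tree(seed = 20)
  f1 <- bm_null_slopes(tr, "trend", n = 50, seed = 66)
  f2 <- bm_null_slopes(tr, "trend", n = 50, seed = 66)
  expect_identical(f1, f2)
  expect_length(f1, 50)
  # BM rate magnitudes grow towards the present: the null trend slopes sit
  # mostly above zero (the test is rank-based, not zero-based)
  expect_gt(mean(f1 > 0), 0.5)
})

test_that("SD-halves statistic is 1 for mirrored rate magnitudes", {
  tr <- small_bd_tree(seed = 26)
  ctx <- rr_context(tr)
  old <- ctx$branch_mid_age <= ctx$height / 2
  rates <- numeric(length(ctx$branch_age))
  rates[old] <- seq_len(sum(old))
  # give the recent half the same standard deviation as the old half
  rates[!old] <- seq_len(sum(!old)) * sd(seq_len(sum(old))) / sd(seq_len(sum(!old)))
  fit <- structure(list(rates = rates, context = ctx), class = "rr_fit")
  chk <- sd_halves_check(fit, null_sd_ratios = c(0.5, 0.9, 1.1, 2))
  expect_equal(chk$statistic, 1, tolerance = 1e-12)
  expect_equal(chk$p, 3 / 5)
})

test_that("search_trend reports are reproducible bit-for-bit given a seed", {
  tr <- small_bd_tree(seed = 27)
  y <- simulate_bm(tr, sigma2 = 4, root_value = 2, seed = 67)
  r1 <- search_trend(tr, y, n_null = 60, seed = 68)
  r2 <- search_trend(tr, y, n_null = 60, seed = 68)
  for (f in c("trend_slope", "trend_p", "drift_slope", "drift_p",
              "sd_ratio", "sd_ratio_p", "trend_verdict", "drift_verdict")) {
    expect_identical(r1[[f]], r2[[f]])
  }
  expect_identical(r1$elements, r2$elements)
})

test_that("strong transforms drive the verdicts in the matching direction", {
  tr <- small_bd_tree(seed = 28, n_extant = 40, min_tips = 30)
  y <- simulate_bm(tr, sigma2 = 1, root_value = 0, seed = 69)
  rep_minus <- search_trend(tr, apply_trend(y, tr, -0.5), n_null = 100, seed = 70)
  expect_identical(rep_minus$trend_verdict, "-")
  sg <- 1
  rep_drift <- search_trend(tr, apply_drift(y, tr, 1.5 * sg), n_null = 100, seed = 71)
  expect_identical(rep_drift$drift_verdict, "+")
})
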