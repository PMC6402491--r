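test_that("Wald ratio reproduces the closed-form per-SNP estimate", {
  wr <- wald_ratio(gamma = 0.1, se_gamma = 0.02, beta = 0.004,
                   se_beta = 0.002)
  expect_equal(wr$alpha, 0.04)
  expect_equal(wr$v, 0.0004)

  # identity instrument: ratio is the outcome effect, variance its se^2
  wr1 <- wald_ratio(gamma = 1, se_gamma = 0.1, beta = 0.123, se_beta = 0.05)
  expect_equal(wr1$alpha, 0.123)
  expect_equal(wr1$v, 0.0025)

  wr2 <- wald_ratio(gamma = 0.2, se_gamma = 0.02, beta = 0.01,
                    se_beta = 0.004)
  expect_equal(wr2$alpha, 0.05)
  expect_equal(wr2$v, 0.0004)

  expect_error(wald_ratio(0, 0.1, 0.01, 0.01), "undefined ratio")
})

test_that("IVW matches hand-evaluated weighted means on the 3-SNP toy", {
  d <- make_mr_data(gamma = rep(0.1, 3), beta = c(0.004, 0.005, 0.002))
  # alpha_i = {0.04, 0.05, 0.02}, all v_i = 0.0004
  f <- mr_fit(d, "ivw_fixed")
  expect_equal(f$alpha, 0.0366667, tolerance = 1e-6)
  expect_equal(f$se_alpha, 0.0115470, tolerance = 1e-6)
  expect_equal(f$heterogeneity$q, 1.1666667, tolerance = 1e-6)
  expect_equal(f$heterogeneity$df, 2)
  expect_equal(f$heterogeneity$i2, 0)  # Q < df

  # Q < df means the multiplicative inflation clamps at 1
  fr <- mr_fit(d, "ivw_random")
  expect_equal(fr$alpha, f$alpha)
  expect_equal(fr$se_alpha, f$se_alpha)
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  d1 <- make_mr_data(gamma = 0.1, beta = 0.004)
  f <- mr_fit(d1, "ivw_fixed")
  expect_equal(f$alpha, 0.04)
  expect_equal(f$se_alpha, 0.02)
  expect_null(f$heterogeneity)            # Q undefined, guarded
  expect_error(cochran_q(d1, 0.04), "at least 2")
  # random mode falls back to fixed with a note
  expect_message(fr <- mr_fit(d1, "ivw_random"), "single instrument")
  expect_equal(fr$se_alpha, f$se_alpha)
  expect_match(fr$note, "fixed")
})

test_that("fixed-effect IVW equals the brute-force oracle on random sets", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(2:300, 1)
    gamma <- abs(rnorm(n, 0.08, 0.03)) + 0.01
    se_gamma <- runif(n, 0.005, 0.02)
    beta <- rnorm(n, 0.04 * gamma, 0.01)
    se_beta <- runif(n, 0.004, 0.02)
    d <- mr_data(sprintf("rs%d", 1:n), gamma, se_gamma, beta, se_beta)
    f <- mr_fit(d, "ivw_fixed")
    o <- oracle_ivw(gamma, se_gamma, beta, se_beta)
    expect_equal(f$alpha, o$alpha, tolerance = 1e-12)
    expect_equal(f$se_alpha, o$se, tolerance = 1e-12)
    expect_equal(f$heterogeneity$q, o$q, tolerance = 1e-10)
  }
})

test_that("Cochran's Q is zero under homogeneity and I2 follows its formula", {
  d <- make_mr_data(gamma = c(0.1, 0.2, 0.4), beta = c(0.004, 0.008, 0.016))
  het <- cochran_q(d, 0.04)   # all alpha_i exactly 0.04
  expect_equal(het$q, 0)
  expect_equal(het$i2, 0)
  expect_equal(het$p_het, 1)

  # i2 invariant: max(0, (q - df)/q) * 100
  d2 <- make_mr_data(gamma = rep(0.1, 4),
                     beta = c(0.001, 0.004, 0.008, 0.012))
  f2 <- mr_fit(d2, "ivw_fixed")
  h2 <- f2$heterogeneity
  expect_equal(h2$i2, max(0, (h2$q - h2$df) / h2$q) * 100)
  expect_equal(h2$p_het, pchisq(h2$q, h2$df, lower.tail = FALSE))
})

test_that("weighted median interpolates the ordered ratios at half weight", {
  # equal weights, ratios {0.02, 0.04, 0.05}: s = (1/6, 1/2, 5/6) and the
  # 0.5 quantile hits the middle ratio exactly
  d <- make_mr_data(gamma = rep(0.1, 3), beta = c(0.004, 0.005, 0.002))
  wm <- mr_fit(d, "weighted_median", n_boot = 200, seed = 4)
  expect_equal(wm$alpha, 0.04)
  expect_gt(wm$se_alpha, 0)

  # all weight on one SNP -> that SNP's ratio
  dcon <- mr_data(c("rs1", "rs2", "rs3"), gamma = c(0.1, 0.1, 0.1),
                  se_gamma = 0.01, beta = c(0.004, 0.005, 0.002),
                  se_beta = c(1e-4, 10, 10))
  wmc <- mr_fit(dcon, "weighted_median", n_boot = 200, seed = 4)
  expect_equal(wmc$alpha, 0.04)

  # equal-weight limit equals the interpolated unweighted median (oracle)
  set.seed(7)
  ratios <- rnorm(8, 0.05, 0.02)
  d8 <- make_mr_data(gamma = rep(0.1, 8), beta = ratios * 0.1)
  wm8 <- mr_fit(d8, "weighted_median", n_boot = 200, seed = 4)
  expect_equal(wm8$alpha, oracle_weighted_median(ratios, rep(1, 8)),
               tolerance = 1e-10)

  # unequal weights against the independent cumulative-weight oracle
  d9 <- mr_data(sprintf("rs%d", 1:6), gamma = rep(0.1, 6), se_gamma = 0.01,
                beta = c(0.004, 0.007, 0.002, 0.005, 0.009, 0.001),
                se_beta = c(0.001, 0.004, 0.002, 0.003, 0.005, 0.002))
  wm9 <- mr_fit(d9, "weighted_median", n_boot = 200, seed = 4)
  w9 <- (0.1 / d9$se_beta)^2
  expect_equal(wm9$alpha, oracle_weighted_median(d9$beta / 0.1, w9),
               tolerance = 1e-10)

  expect_error(mr_fit(make_mr_data(rep(0.1, 2), rep(0.004, 2)),
                      "weighted_median", seed = 1), "at least 3")
  expect_error(mr_fit(d, "weighted_median", n_boot = 200), "seed")
})

test_that("estimators are permutation- and joint-sign-flip invariant, bootstrap is seeded", {
  set.seed(21)
  n <- 40
  d <- mr_data(sprintf("rs%d", 1:n), gamma = abs(rnorm(n, 0.09, 0.02)),
               se_gamma = 0.01, beta = rnorm(n, 0.004, 0.008),
               se_beta = runif(n, 0.006, 0.01))
  perm <- sample(n)
  dp <- d[perm, , drop = FALSE]
  class(dp) <- class(d)

  f <- mr_fit(d, "ivw_random")
  fp <- mr_fit(dp, "ivw_random")
  expect_equal(fp$alpha, f$alpha)
  expect_equal(fp$se_alpha, f$se_alpha)
  expect_equal(fp$heterogeneity$q, f$heterogeneity$q)

  # weighted median point estimate is permutation invariant; same seed
  # reproduces the bootstrap SE exactly
  wm1 <- mr_fit(d, "weighted_median", n_boot = 300, seed = 5)
  wm2 <- mr_fit(d, "weighted_median", n_boot = 300, seed = 5)
  expect_identical(wm1$alpha, wm2$alpha)
  expect_identical(wm1$se_alpha, wm2$se_alpha)
  wmp <- mr_fit(dp, "weighted_median", n_boot = 300, seed = 5)
  expect_equal(wmp$alpha, wm1$alpha)

  # negating both gamma and beta of some SNPs leaves the Wald ratios, and
  # hence every estimate, unchanged (bypassing the orientation constructor)
  dflip <- as.data.frame(d)
  k <- sample(n, 15)
  dflip$gamma[k] <- -dflip$gamma[k]
  dflip$beta[k] <- -dflip$beta[k]
  ff <- mr_fit(dflip, "ivw_random")
  expect_equal(ff$alpha, f$alpha)
  expect_equal(ff$se_alpha, f$se_alpha)
})

test_that("odds-ratio transform exponentiates and preserves ordering", {
  d <- make_mr_data(gamma = rep(0.1, 3), beta = c(0.004, 0.005, 0.002))
  f <- mr_fit(d, "ivw_fixed")
  f$alpha <- 0.0392; f$ci_low <- 0.0198; f$ci_high <- 0.0583
  or <- odds_ratios(f)
  expect_equal(unname(or$rounded), c(1.04, 1.02, 1.06))

  f$alpha <- 0; f$ci_low <- -0.01; f$ci_high <- 0.01
  expect_equal(unname(odds_ratios(f)$rounded["or"]), 1.00)

  f$alpha <- -0.05; f$ci_low <- -0.08; f$ci_high <- -0.02
  or2 <- odds_ratios(f)
  expect_lt(or2$or, 1)
  expect_true(or2$ci_low < or2$or && or2$or < or2$ci_high)
})

test_that("mr_fit accessors behave like a fitted model object", {
  d <- make_mr_data(gamma = rep(0.1, 3), beta = c(0.004, 0.005, 0.002))
  f <- mr_fit(d, "ivw_fixed")
  expect_equal(unname(coef(f)), f$alpha)
  ci <- confint(f)
  expect_equal(unname(ci[1, ]), c(f$ci_low, f$ci_high))
  expect_equal(unname(vcov(f)[1, 1]), f$se_alpha^2)
  r <- residuals(f)
  expect_equal(unname(r), d$beta - f$alpha * d$gamma)
  rs <- residuals(f, "standardized")
  expect_equal(unname(rs), unname(r) / d$se_beta)
  expect_equal(unname(fitted(f) + r), d$beta)
  expect_equal(predict(f, data.frame(gamma = 1)), f$alpha)
  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "mr_data")
  expect_output(print(summary(f)), "Cochran")
})
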