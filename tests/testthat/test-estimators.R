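test_that("Wald ratios reproduce direct arithmetic on the printed pairs", {
  h <- fixture_harmonized()
  r <- wald_ratio(h)
  rec <- r[r$snp == "rs17279437", ]
  expect_equal(rec$theta, -0.067 / 0.059)
  expect_equal(rec$se_theta, 0.023 / 0.059)
  expect_equal(rec$weight, (0.059 / 0.023)^2)

  # zero outcome effect gives a zero ratio under either SE method
  h0 <- harmonized_variants(tibble::tibble(
    snp = "rs1", beta_exp = 0.1, se_exp = 0.01, beta_out = 0, se_out = 0.02))
  expect_equal(wald_ratio(h0)$theta, 0)
  expect_equal(wald_ratio(h0, "second_order")$theta, 0)

  # second-order SE dominates whenever se_exp > 0
  for (seed in 1:5) {
    hr <- random_harmonized(8, seed)
    expect_true(all(wald_ratio(hr, "second_order")$se_theta >=
                      wald_ratio(hr, "first_order")$se_theta))
  }

  hz <- harmonized_variants(tibble::tibble(
    snp = "rs1", beta_exp = 0, se_exp = 0.01, beta_out = 0.1, se_out = 0.02))
  expect_error(wald_ratio(hz), "beta_exp")
})

test_that("IVW equals the inverse-variance weighted mean of ratios", {
  for (seed in 1:10) {
    h <- random_harmonized(6, seed)
    est <- mr_ivw(h)
    # independent weighted-mean oracle
    th <- h$beta_out / h$beta_exp
    w <- (h$beta_exp / h$se_out)^2
    expect_equal(est$beta, sum(w * th) / sum(w), tolerance = 1e-12)
    expect_gte(est$beta, min(th))
    expect_lte(est$beta, max(th))
    # permutation and joint sign-flip invariance
    perm <- h[withr::with_seed(seed, sample(nrow(h))), ]
    expect_equal(mr_ivw(harmonized_variants(perm))$beta, est$beta)
    flipped <- h
    flipped$beta_exp[1] <- -flipped$beta_exp[1]
    flipped$beta_out[1] <- -flipped$beta_out[1]
    expect_equal(mr_ivw(flipped)$beta, est$beta, tolerance = 1e-12)
    # random effects never narrows the interval
    expect_gte(est$se, mr_ivw(h, model = "fixed")$se)
  }
})

test_that("IVW degenerates correctly when all ratios agree", {
  h <- harmonized_variants(tibble::tibble(
    snp = c("rs1", "rs2"), beta_exp = c(0.1, 0.2), se_exp = 0.01,
    beta_out = c(0.05, 0.10), se_out = c(0.02, 0.03)))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(attr(est, "q"), 0)
  expect_equal(est$se, attr(est, "se_fixed"))  # max(1, sqrt(0/1)) = 1
  expect_error(mr_ivw(h[1, ]), "2 variants")
})

test_that("the MRE standard error exceeds fixed only when Q exceeds its df", {
  for (seed in 1:10) {
    h <- random_harmonized(7, seed)
    mre <- mr_ivw(h)
    fixed <- mr_ivw(h, model = "fixed")
    q <- attr(mre, "q")
    if (q > nrow(h) - 1) expect_gt(mre$se, fixed$se)
    else expect_equal(mre$se, fixed$se)
  }
})

test_that("the weighted median matches a grid-search oracle on random instances", {
  # oracle: root of the piecewise-linear quantile curve via approxfun/uniroot
  oracle <- function(theta, w) {
    o <- order(theta)
    th <- theta[o]
    p <- w[o] / sum(w)
    s <- cumsum(p) - p / 2
    if (s[1] >= 0.5) return(th[1])
    if (s[length(s)] <= 0.5) return(th[length(th)])
    # root of the interpolated cumulative-weight curve at s = 0.5
    stats::uniroot(function(z) stats::approx(th, s, xout = z)$y - 0.5,
                   interval = range(th), tol = 1e-12)$root
  }
  for (seed in 1:100) {
    inst <- withr::with_seed(seed, {
      j <- sample(3:12, 1)
      list(theta = rnorm(j), w = runif(j, 0.1, 5))
    })
    # package path exercised through mr_weighted_median's point estimate
    h <- harmonized_variants(tibble::tibble(
      snp = sprintf("rs%02d", seq_along(inst$theta)),
      beta_exp = 1, se_exp = 1e-6,
      beta_out = inst$theta, se_out = 1 / sqrt(inst$w)))
    est <- mr_weighted_median(h, n_boot = 100, seed = 1)
    expect_equal(est$beta, oracle(inst$theta, inst$w), tolerance = 1e-6)
  }
})

test_that("equal weights reduce the weighted median to the interpolated median", {
  h <- harmonized_variants(tibble::tibble(
    snp = sprintf("rs%d", 1:5), beta_exp = 1, se_exp = 1e-6,
    beta_out = c(-0.2, 0.1, 0.4, 0.7, 1.0), se_out = 1))
  est <- mr_weighted_median(h, n_boot = 100, seed = 1)
  # five equal weights: s = (0.1, 0.3, 0.5, 0.7, 0.9); s = 0.5 is the 3rd
  expect_equal(est$beta, 0.4)
})

test_that("weighted-median guards: dominance, minimum variants, bootstrap floor", {
  h <- fixture_harmonized()
  expect_error(mr_weighted_median(h[1:2, ]), "3 variants")
  expect_error(mr_weighted_median(h, n_boot = 50), "100")
  # a ratio carrying nearly all the weight pulls the estimate onto itself
  hc <- harmonized_variants(tibble::tibble(
    snp = c("rs1", "rs2", "rs3"), beta_exp = 1, se_exp = 1e-6,
    beta_out = c(-5, 1, 2), se_out = c(0.01, 10, 10)))
  est <- mr_weighted_median(hc, n_boot = 100, seed = 1)
  expect_equal(est$beta, -5, tolerance = 1e-4)
})

test_that("bootstrap SE is reproducible given a seed and positive when ratios agree", {
  h <- fixture_harmonized()
  a <- mr_weighted_median(h, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h, n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, mr_weighted_median(h, n_boot = 200, seed = 8)$se))

  same <- harmonized_variants(tibble::tibble(
    snp = sprintf("rs%d", 1:4), beta_exp = c(0.1, 0.2, 0.15, 0.12),
    se_exp = 0.005, beta_out = c(0.05, 0.10, 0.075, 0.06), se_out = 0.01))
  est <- mr_weighted_median(same, n_boot = 500, seed = 1)
  expect_equal(est$beta, 0.5)
  expect_gt(est$se, 0)
  expect_lt(est$se, 0.2)
})

test_that("Egger weighted-LS coefficients match a normal-equations oracle", {
  for (seed in 1:10) {
    h <- random_harmonized(8, seed)
    fit <- mr_egger(h)
    v <- orient_to_positive_exposure(h)
    w <- 1 / v$se_out^2
    X <- cbind(1, v$beta_exp)
    cf <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% v$beta_out)
    expect_equal(fit$intercept, cf[1, 1], tolerance = 1e-10)
    expect_equal(fit$slope$beta, cf[2, 1], tolerance = 1e-10)
    expect_equal(fit$df, nrow(h) - 2L)
  }
  expect_error(mr_egger(fixture_harmonized()[1:2, ]), "3 variants")
  degenerate <- harmonized_variants(tibble::tibble(
    snp = sprintf("rs%d", 1:3), beta_exp = c(0.1, -0.1, 0.1), se_exp = 0.01,
    beta_out = rnorm(3), se_out = 0.02))
  expect_error(mr_egger(degenerate), "variance")
})

test_that("the Egger intercept vanishes on strong data simulated without pleiotropy", {
  sims <- vapply(1:50, function(i) {
    cfg <- sim_config(n_snps = 50, theta = -0.3, pleiotropy = "none",
                      seed = 5000L + i)
    mr_egger(sim_harmonized(simulate_mr(cfg)))$intercept
  }, numeric(1))
  expect_lt(abs(mean(sims)), 3 * sd(sims) / sqrt(length(sims)) + 5e-4)
})

test_that("odds-ratio transforms reproduce the printed conversions", {
  # published CI bounds come from unrounded coefficients, so agreement is to
  # one unit in the last printed digit
  expect_true(all(abs(unname(to_odds_ratio(-0.644, 0.213)) -
                        c(0.525, 0.346, 0.798)) < 1e-3))
  expect_true(all(abs(unname(to_odds_ratio(-0.609, 0.244)) -
                        c(0.544, 0.337, 0.878)) < 1e-3))
  null <- to_odds_ratio(0, 0.2)
  expect_equal(unname(null[["or"]]), 1)
  expect_equal(null[["or_lci95"]] * null[["or_uci95"]], 1)  # symmetric on log scale
  expect_error(to_odds_ratio(0.1, 0))
})
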