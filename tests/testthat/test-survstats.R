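# hand-coded Breslow partial log-likelihood for a single covariate
partial_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

test_that("fit_cox matches grid-search maximization of the partial likelihood", {
  # note (1,1,0,0) would be separable (monotone likelihood); alternate the
  # covariate so the partial likelihood has an interior maximum
  x <- c(1, 0, 1, 0)
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, partial_loglik, 0, x = x, time = time, event = event)
  beta_grid <- grid[which.max(ll)]
  fit <- fit_cox(x, time, event, ties = "breslow")
  expect_lt(abs(unname(fit$coef) - beta_grid), 1e-3)
  # refine the oracle locally to 1e-6
  fine <- seq(beta_grid - 2e-4, beta_grid + 2e-4, by = 1e-7)
  llf <- vapply(fine, partial_loglik, 0, x = x, time = time, event = event)
  expect_lt(abs(unname(fit$coef) - fine[which.max(llf)]), 1e-6)
})

test_that("fit_cox error contract: constant covariate, no events, divergence", {
  expect_error(fit_cox(rep(1, 5), 1:5, rep(1, 5)), "zero-variance")
  expect_error(fit_cox(rnorm(5), 1:5, rep(0, 5)), "no events")
  # perfectly separating covariate drives the coefficient to infinity
  x <- c(5, 4, 3, 2, 1, 0)
  expect_error(fit_cox(x, 1:6, rep(1, 6)), "monotone likelihood")
})

test_that("fit_cox recovers the true hazard coefficient in simulation", {
  est <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 500
    x <- rnorm(n)
    t0 <- rexp(n, 0.05 * exp(0.7 * x))
    cens <- runif(n, 0, quantile(t0, 0.9))
    unname(fit_cox(x, pmin(t0, cens), as.numeric(t0 <= cens))$coef)
  }, 0)
  expect_lt(abs(mean(est) - 0.7), 0.1)
})

test_that("breslow equals efron on tie-free data", {
  set.seed(4)
  n <- 40
  x <- rnorm(n)
  time <- sort(rexp(n, 0.1)) + seq_len(n) * 1e-6  # guarantee no ties
  event <- rbinom(n, 1, 0.7); event[1] <- 1
  f1 <- fit_cox(x, time, event, ties = "breslow")
  f2 <- fit_cox(x, time, event, ties = "efron")
  expect_lt(abs(unname(f1$coef) - unname(f2$coef)), 1e-10)
})

test_that("km_estimate follows the product-limit construction", {
  km <- km_estimate(1:10, rep(1, 10))$all
  expect_equal(km$surv, seq(0.9, 0, by = -0.1))
  expect_equal(km$median, 5)
  # hand product-limit with a censor: times 1, 2+, 3
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))$all
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  km3 <- km_estimate(c(2, 4, 6), c(0, 0, 0))$all
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median))
})

test_that("km group sizes sum to the total n", {
  set.seed(5)
  g <- sample(c("a", "b", "c"), 30, replace = TRUE)
  km <- km_estimate(rexp(30), rbinom(30, 1, 0.5), g)
  expect_equal(sum(vapply(km, `[[`, 0, "n")), 30)
})

test_that("logrank statistic is zero for identical survival multisets", {
  time <- c(1, 3, 5, 7, 9, 1, 3, 5, 7, 9)
  event <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(g, time, event)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
})

test_that("logrank p tracks the label-permutation oracle", {
  # the chi-square(1) reference is asymptotic: at n = 30 the exact
  # permutation null is slightly heavier-tailed, so exact agreement is
  # only expected where that approximation error is below Monte-Carlo
  # resolution; elsewhere the deviation stays small and one-sided
  perm_p <- function(g, time, event, B) {
    obs <- logrank_test(g, time, event)
    perm <- vapply(seq_len(B), function(b)
      logrank_test(sample(g), time, event)$statistic, 0)
    c(chi = obs$p, perm = mean(perm >= obs$statistic))
  }
  n <- 30
  g <- rep(c("a", "b"), each = 15)
  # accurate regime (small statistic)
  set.seed(103)
  time <- rexp(n, 0.1); event <- rep(1, n)
  set.seed(200)
  r <- perm_p(g, time, event, 4000)
  expect_lt(abs(r["chi"] - r["perm"]),
            2 * sqrt(r["perm"] * (1 - r["perm"]) / 4000))
  # moderate-p fixture: approximation error bounded
  set.seed(11)
  time <- c(rexp(15, 0.12), rexp(15, 0.08))
  event <- rbinom(n, 1, 0.85)
  set.seed(201)
  r2 <- perm_p(g, time, event, 4000)
  expect_lt(abs(r2["chi"] - r2["perm"]), 0.025)
})

test_that("logrank p is uniform under the null", {
  set.seed(12)
  ps <- vapply(1:200, function(i) {
    g <- rep(c("a", "b"), each = 20)
    logrank_test(g, rexp(40, 0.1), rbinom(40, 1, 0.8))$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("fisher_exact matches enumerated hypergeometric probabilities", {
  fe <- fisher_exact(matrix(c(3, 1, 1, 3), 2))
  expect_equal(fe$p, 34 / 70)
  expect_equal(fe$odds_ratio, 9)
  fe2 <- fisher_exact(matrix(c(10, 10, 10, 10), 2))
  expect_equal(fe2$p, 1)
  expect_equal(fe2$odds_ratio, 1)
  fe3 <- suppressWarnings(fisher_exact(matrix(c(5, 0, 0, 5), 2)))
  expect_equal(fe3$p, 2 * (1 / 252))
  expect_true(fe3$haldane)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("bh_fdr equals the from-definition step-up with monotonicity", {
  # independent oracle: sort, apply p * n / rank, cumulative min from the top
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(13)
  for (i in 1:5) {
    p <- runif(20)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("clinical covariate coding follows the standard cutpoints", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:5),
                   os_months = c(10, 20, 30, 40, 50),
                   event = c(1, 1, 0, 1, 0),
                   age_years = c(64.9, 65, 70, NA, 50),
                   stage = c(3, 4, NA, 3, 4),
                   grade = c(1, 2, 3, NA, 2),
                   debulking = c("optimal", "suboptimal", "unknown",
                                 "optimal", "suboptimal"))
  cov <- prognostic_covariates(cl)
  expect_equal(cov$age_ge65, c(0, 1, 1, NA, 0))
  expect_equal(cov$high_grade, c(0, 1, 1, NA, 1))
  expect_equal(cov$optimal_debulking, c(1, 0, NA, 1, 0))
  # grade 2 counted as low when requested
  cov2 <- prognostic_covariates(cl, low_grade = c(1, 2))
  expect_equal(cov2$high_grade, c(0, 0, 1, NA, 0))
})

test_that("multivariate Cox fits use complete cases and keep the risk term", {
  set.seed(21)
  n <- 120
  z <- rnorm(n)
  age <- rnorm(n, 62, 10)
  t0 <- rexp(n, 0.03 * exp(0.8 * z + 0.02 * (age - 62)))
  cens <- runif(n, 0, quantile(t0, 0.9))
  cl <- data.frame(sample_id = sprintf("s%d", 1:n),
                   os_months = pmin(t0, cens),
                   event = as.numeric(t0 <= cens),
                   age_years = age,
                   stage = sample(c(3, 4), n, TRUE),
                   grade = sample(c(1:3, NA), n, TRUE),
                   debulking = sample(c("optimal", "suboptimal"), n, TRUE))
  cov <- cbind(risk = z, prognostic_covariates(cl))
  fit <- fit_cox(cov, cl$os_months, cl$event)
  expect_lt(fit$p[["risk"]], 0.01)
  expect_equal(fit$n, sum(stats::complete.cases(cov)))
})
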