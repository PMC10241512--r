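sim_glmm_data <- function(S = 10, n = 150, beta = c(0.3, 0.5, -0.4),
                          re_sd = c(0.4, 0.3, 0), family = "binomial",
                          sigma = 0.7, seed = 1) {
  set.seed(seed)
  sess <- rep(sprintf("S%02d", seq_len(S)), each = n)
  x1 <- rnorm(S * n); x2 <- rnorm(S * n)
  b <- vapply(re_sd, function(s) rnorm(S, 0, s), numeric(S))
  i <- as.integer(factor(sess))
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 +
    b[i, 1] + b[i, 2] * x1 + b[i, 3] * x2
  y <- if (family == "binomial") rbinom(S * n, 1, plogis(eta))
  else eta + rnorm(S * n, 0, sigma)
  data.frame(session_id = sess, x1 = x1, x2 = x2, y = y)
}

test_that("fixed effects and variance components match an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  d <- sim_glmm_data(S = 12, n = 200, seed = 5)
  f <- fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)
  g <- lme4::glmer(y ~ x1 + x2 + (1 + x1 + x2 || session_id), d,
                   family = stats::binomial(), nAGQ = 0)
  expect_equal(unname(coef(f)), unname(lme4::fixef(g)), tolerance = 1e-3)
  th_g <- sqrt(unlist(lapply(lme4::VarCorr(g), diag)))
  expect_equal(unname(f$theta), unname(th_g), tolerance = 0.02)
  # gaussian family against lmer (ML)
  dg <- sim_glmm_data(S = 12, n = 200, family = "gaussian", seed = 6)
  fg <- fit_glmm(y ~ x1 + x2, dg, family = "gaussian", zscore = FALSE)
  lg <- lme4::lmer(y ~ x1 + x2 + (1 + x1 + x2 || session_id), dg, REML = FALSE)
  expect_equal(unname(coef(fg)), unname(lme4::fixef(lg)), tolerance = 1e-4)
  expect_equal(fg$sigma, stats::sigma(lg), tolerance = 1e-3)
})

test_that("fixed effects are recovered across replicates within Monte Carlo error", {
  beta <- c(0.3, 0.5, -0.4)
  est <- t(vapply(1:12, function(s) {
    d <- sim_glmm_data(S = 10, n = 150, beta = beta, seed = 100 + s)
    unname(coef(fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)))
  }, numeric(3)))
  mce <- apply(est, 2, sd) / sqrt(nrow(est))
  for (j in 1:3) expect_lt(abs(mean(est[, j]) - beta[j]), 3 * mce[j] + 0.02)
})

test_that("zero random-effect variance reduces to an ordinary GLM", {
  d <- sim_glmm_data(S = 8, n = 200, re_sd = c(0, 0, 0), seed = 9)
  f <- fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)
  g <- glm(y ~ x1 + x2, stats::binomial(), d)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 0.05)
})

test_that("degenerate designs are handled explicitly", {
  d <- sim_glmm_data(S = 6, n = 100, seed = 11)
  d$flat <- 0
  f <- fit_glmm(y ~ x1 + flat, d, family = "binomial", zscore = FALSE)
  expect_equal(unname(coef(f)["flat"]), 0)
  expect_match(paste(f$notes, collapse = " "), "dropped constant")
  # single session: ordinary GLM fallback, flagged in notes
  d1 <- d[d$session_id == "S01", ]
  f1 <- fit_glmm(y ~ x1 + x2, d1, family = "binomial", zscore = FALSE)
  expect_true(f1$glm_fallback)
  expect_match(paste(f1$notes, collapse = " "), "single session")
  g1 <- glm(y ~ x1 + x2, stats::binomial(), d1)
  expect_equal(unname(coef(f1)), unname(coef(g1)), tolerance = 1e-6)
})

test_that("session-wise z-scoring makes fits invariant to per-session predictor offsets", {
  d <- sim_glmm_data(S = 8, n = 150, seed = 13)
  f1 <- fit_glmm(y ~ x1 + x2, d, family = "binomial")
  d2 <- d
  off <- rnorm(8, 0, 5)[as.integer(factor(d$session_id))]
  d2$x1 <- d2$x1 + off
  f2 <- fit_glmm(y ~ x1 + x2, d2, family = "binomial")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("hierarchical bootstrap is deterministic, session-preserving, and sign-equivariant", {
  d <- sim_glmm_data(S = 6, n = 120, seed = 17)
  f <- fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)
  b1 <- hierarchical_bootstrap(f, n_resamples = 80, seed = 3)
  b2 <- hierarchical_bootstrap(f, n_resamples = 80, seed = 3)
  expect_identical(b1$draws, b2$draws)
  b3 <- hierarchical_bootstrap(f, n_resamples = 80, seed = 4)
  expect_false(identical(b1$draws, b3$draws))
  # sign-flip of a predictor negates its draws exactly (same seed)
  d2 <- d; d2$x1 <- -d2$x1
  f2 <- fit_glmm(y ~ x1 + x2, d2, family = "binomial", zscore = FALSE)
  b4 <- hierarchical_bootstrap(f2, n_resamples = 80, seed = 3)
  expect_equal(b4$draws[, "x1"], -b1$draws[, "x1"], tolerance = 1e-6)
  expect_equal(b4$summary$ci_lo[2], -b1$summary$ci_hi[2], tolerance = 1e-6)
  # n_resamples = 1: summary equals that single draw, IQR zero
  b5 <- hierarchical_bootstrap(f, n_resamples = 1, seed = 8)
  expect_equal(b5$summary$median, unname(b5$draws[1, ]))
  expect_equal(b5$summary$q75 - b5$summary$q25, rep(0, 3))
})

test_that("bootstrap summaries are coherent and agree with Wald on sign and significance", {
  beta <- c(0.3, 0.6, -0.5)
  d <- sim_glmm_data(S = 12, n = 250, beta = beta, seed = 19)
  f <- fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)
  b <- hierarchical_bootstrap(f, n_resamples = 400, seed = 21)
  s <- b$summary
  expect_true(all(s$ci_lo <= s$ci_hi))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  # the within-session bootstrap distribution is centered on the full-data fit
  expect_true(all(s$estimate >= s$ci_lo & s$estimate <= s$ci_hi))
  # Wald z from the approximate-likelihood fit: same signs, same calls at 5%
  wald <- summary(f)$coefficients
  for (j in seq_len(nrow(s))) {
    expect_equal(sign(s$estimate[j]), sign(wald[j, "Estimate"]))
    expect_equal(s$p_value[j] < 0.05, wald[j, "Pr(>|z|)"] < 0.05)
  }
})

test_that("outlier filtering removes exactly the aberrant resamples", {
  set.seed(23)
  draws <- matrix(rnorm(500 * 3), 500, 3)
  keep <- filter_outlier_resamples(draws)
  expect_lt(mean(!keep), 0.005) # well-behaved draws: < 0.5% removed
  draws2 <- draws
  draws2[17, 2] <- median(draws[, 2]) +
    100 * median(abs(draws[, 2] - median(draws[, 2])))
  keep2 <- filter_outlier_resamples(draws2)
  expect_identical(which(!keep2 & keep), 17L)
  # identical draws: MAD = 0 imposes no removals
  expect_true(all(filter_outlier_resamples(matrix(1, 50, 2))))
})

test_that("quantile p-values follow the opposite-sign-fraction rule", {
  draws <- cbind(a = c(rep(1, 9), -1), b = rep(2, 10), c = c(rep(1, 5), rep(-1, 5)))
  p <- quantile_pvalue(draws, c(1, 1, 1))
  expect_equal(unname(p), c(0.2, 0, 1))
  # zero draws count as opposite sign (conservative)
  expect_equal(quantile_pvalue(cbind(c(1, 1, 0, 1)), 1), 0.5)
  # zero estimate: p = 1
  expect_equal(quantile_pvalue(cbind(rnorm(10)), 0), 1)
  # and a reported bound of 2/n when no draw opposes
  d <- sim_glmm_data(S = 4, n = 400, beta = c(0, 2, 0), re_sd = c(0.1, 0.1, 0.1),
                     seed = 25)
  f <- fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)
  b <- hierarchical_bootstrap(f, n_resamples = 50, seed = 1)
  expect_equal(b$summary$p_bound[b$summary$term == "x1"], 2 / nrow(b$draws))
})

test_that("re-optimizing variance components per resample gives consistent summaries", {
  d <- sim_glmm_data(S = 6, n = 120, seed = 27)
  f <- fit_glmm(y ~ x1 + x2, d, family = "binomial", zscore = FALSE)
  bf <- hierarchical_bootstrap(f, n_resamples = 60, seed = 5, theta = "fixed")
  br <- hierarchical_bootstrap(f, n_resamples = 60, seed = 5, theta = "refit")
  expect_equal(bf$summary$median, br$summary$median, tolerance = 0.1)
  expect_equal(dim(bf$draws), dim(br$draws))
})
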