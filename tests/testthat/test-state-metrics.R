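test_that("firing rate is count over units and time", {
  # 600 spikes, 60 units, 2 s -> 5 spikes/s
  times <- seq(-2, -1e-6, length.out = 600)
  expect_equal(compute_fr(times, n_units = 60), 5)
  expect_equal(compute_fr(numeric(0), n_units = 10), 0)
  expect_error(compute_fr(times), "n_units")
  expect_error(compute_fr(times, n_units = NA), "n_units")
  # spikes outside the half-open window do not count
  expect_equal(compute_fr(c(-2.5, -1, 0), n_units = 1, window = c(-2, 0)), 0.5)
})

test_that("synchrony is calibrated at 1 for independent Poisson firing", {
  set.seed(201)
  syn <- replicate(150, compute_synch(poisson_baseline(300)))
  expect_lt(abs(mean(syn) - 1), 0.025)
  # and stays near 1 across a range of rates
  set.seed(202)
  for (r in c(60, 600, 2500)) {
    s <- replicate(60, compute_synch(poisson_baseline(r)))
    expect_lt(abs(mean(s) - 1), 0.05)
  }
})

test_that("synchrony is large when all spikes share one bin and NA when empty", {
  set.seed(7)
  times <- runif(200, -1.99, -1.98) # inside a single 20-ms bin
  expect_gt(compute_synch(times), 5)
  expect_true(is.na(compute_synch(numeric(0))))
  expect_true(is.na(compute_cv(numeric(0))))
})

test_that("synchrony is invariant to unit relabeling and common time shift", {
  set.seed(11)
  times <- runif(400, -2, -0.1)
  s_ref <- { set.seed(99); compute_synch(times) }
  # unit labels never enter: pooled times fully determine the statistic
  tp <- sample(times)
  s_perm <- { set.seed(99); compute_synch(tp) }
  expect_identical(s_ref, s_perm)
  # common shift by whole bins inside the window
  s_shift <- { set.seed(99); compute_synch(times + 0.04) }
  expect_equal(s_ref, s_shift, tolerance = 1e-12)
})

test_that("CV follows 1/sqrt(lambda) for Poisson counts and is 0 when constant", {
  # identical count in every bin
  times <- rep(seq(-2, -0.02, by = 0.02), each = 3) + 0.01
  expect_equal(compute_cv(times), 0)
  set.seed(13)
  for (lam in c(2, 8, 32)) {
    cv <- replicate(120, compute_cv(poisson_baseline(lam * 50)))
    expect_lt(abs(mean(cv) - 1 / sqrt(lam)), 0.1 / sqrt(lam))
  }
})

test_that("CV is rate-entangled while synchrony is not", {
  set.seed(17)
  rates <- exp(runif(120, log(50), log(1000)))
  m <- t(vapply(rates, function(r) {
    b <- poisson_baseline(r)
    c(fr = length(b) / 2, cv = compute_cv(b), synch = compute_synch(b))
  }, numeric(3)))
  expect_lt(cor(m[, "cv"], m[, "fr"]), -0.5)
  expect_lt(abs(cor(m[, "synch"], m[, "fr"])), abs(cor(m[, "cv"], m[, "fr"])))
})

test_that("per-trial metrics table is reproducible and handles empty trials", {
  ds <- memo("spk_ds", generate_dataset(
    synth_config(n_sessions = 2, trials_per_session = 40, emit_spikes = TRUE,
                 seed = 55)))
  trials <- ds$trials
  m1 <- compute_state_metrics(ds$spikes, trials, n_units = 60, seed = 4)
  m2 <- compute_state_metrics(ds$spikes, trials, n_units = 60, seed = 4)
  expect_identical(m1, m2)
  m3 <- compute_state_metrics(ds$spikes, trials, n_units = 60, seed = 5)
  expect_false(identical(m1$synch, m3$synch))
  expect_true(all(m1$fr >= 0))
  expect_equal(m1$fr, m1$n_spikes / (60 * 2))
  # a trial without spikes: fr 0, synch/cv missing
  t2 <- rbind(trials[, c("session_id", "trial_number")],
              data.frame(session_id = "S01", trial_number = 9999L))
  m4 <- compute_state_metrics(ds$spikes, t2, n_units = 60, seed = 4)
  last <- m4[m4$trial_number == 9999L, ]
  expect_equal(last$fr, 0)
  expect_true(is.na(last$synch) && is.na(last$cv))
})

test_that("generated synchrony drive is recovered by the measured statistic", {
  # monotonicity of E[Synch] in the emitted synchrony drive
  set.seed(303)
  lam <- 60 * 5 * 0.02
  rho <- exp(-0.02 / 0.15)
  mean_synch <- vapply(c(1.0, 1.3, 1.6), function(S) {
    m0 <- sqrt(max(S^2 - 1, 0) / lam)
    mean(replicate(100, {
      g <- as.numeric(arima.sim(list(ar = rho), 100, sd = sqrt(1 - rho^2)))
      cnt <- rpois(100, pmax(lam * (1 + m0 * g), 0))
      tms <- -2 + (rep.int(1:100, cnt) - 1) * 0.02 + runif(sum(cnt), 0, 0.02)
      compute_synch(tms)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_synch) > 0.1))
})

test_that("multitaper spectrum is unit-normalized, flat for Poisson, peaked when modulated", {
  set.seed(23)
  spec <- multitaper_spectrum(poisson_baseline(300), tw = 10)
  expect_equal(spec$n_tapers, 19)
  expect_equal(mean(spec$power[spec$freq > 10000]), 1) # exact by construction
  specs <- lapply(1:40, function(i) multitaper_spectrum(poisson_baseline(300), tw = 5))
  for (bd in list(c(2, 16), c(50, 500), c(2000, 9000)))
    expect_lt(abs(band_power(specs, bd) - 1), 0.12)
  # 8 Hz sinusoidal rate modulation -> low-frequency peak at ~8 Hz
  gen <- function() {
    tt <- seq(-2, 0, by = 1 / 30000)
    r <- 300 * (1 + 0.8 * sin(2 * pi * 8 * tt))
    tt[runif(length(tt)) < r / 30000]
  }
  sp2 <- lapply(1:30, function(i) multitaper_spectrum(gen(), tw = 5))
  f <- sp2[[1]]$freq
  P <- rowMeans(vapply(sp2, function(s) s$power, numeric(length(f))))
  expect_lt(abs(f[f < 50][which.max(P[f < 50])] - 8), 3)
  expect_gt(band_power(sp2, c(5, 11)), 1.3)
  expect_error(multitaper_spectrum(poisson_baseline(10), tw = 0.5), "tw")
  expect_error(multitaper_spectrum(runif(5, -0.0001, 0), window = c(-1e-4, 0),
                                   tw = 10), "too short")
})

test_that("high-synchrony baselines show elevated 4-16 Hz normalized power", {
  set.seed(29)
  lam <- 60 * 5 * 0.02
  rho <- exp(-0.02 / 0.15)
  one <- function(S) {
    m0 <- sqrt(max(S^2 - 1, 0) / lam)
    g <- as.numeric(arima.sim(list(ar = rho), 100, sd = sqrt(1 - rho^2)))
    cnt <- rpois(100, pmax(lam * (1 + m0 * g), 0))
    -2 + (rep.int(1:100, cnt) - 1) * 0.02 + runif(sum(cnt), 0, 0.02)
  }
  hi <- lapply(1:25, function(i) multitaper_spectrum(one(1.7), tw = 5))
  lo <- lapply(1:25, function(i) multitaper_spectrum(one(1.0), tw = 5))
  expect_gt(band_power(hi, c(4, 16)), band_power(lo, c(4, 16)) + 0.1)
})
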