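make_session_signals <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(session_id = "A", trial_number = seq_len(n),
             opticf = rnorm(n), pupils = rnorm(n), fr = rnorm(n),
             synch = rnorm(n))
}

make_session_trials <- function(n, seed = 2) {
  set.seed(seed)
  data.frame(session_id = "A", trial_number = seq_len(n),
             trial_class = "valid", correct = rbinom(n, 1, 0.7))
}

test_that("history design has 51 predictor columns with outcome history, 41 without", {
  sig <- make_session_signals(60)
  out <- rbinom(60, 1, 0.7)
  d1 <- build_history_design(sig, out, lags = 10, include_outcome = TRUE)
  expect_equal(ncol(d1$X), 51)
  d0 <- build_history_design(sig, out, lags = 10, include_outcome = FALSE)
  expect_equal(ncol(d0$X), 41)
  # 30-trial session, 10 lags -> 20 usable rows
  sig30 <- make_session_signals(30)
  d30 <- build_history_design(sig30, rbinom(30, 1, 0.5), lags = 10)
  expect_equal(sum(d30$mask), 20)
  expect_equal(nrow(d30$X), 20)
  expect_false(any(d30$mask[1:10]))
  expect_error(build_history_design(make_session_signals(12), rbinom(12, 1, 0.5)),
               "too short")
})

test_that("residuals are exactly orthogonal to the design and centered", {
  n <- 200
  sig <- make_session_signals(n, seed = 3)
  tr <- make_session_trials(n, seed = 4)
  res <- compute_innovations(sig, tr)
  des <- build_history_design(sig, as.numeric(tr$correct == 1))
  for (j in c("opticf_i", "fr_i")) {
    r <- res[[j]][des$mask]
    expect_lt(abs(mean(r)), 1e-10 * sd(r))
    ips <- abs(crossprod(des$X, r))
    norms <- sqrt(colSums(des$X^2)) * sqrt(sum(r^2))
    expect_true(all(ips < 1e-8 * norms))
  }
  # masked rows carry NA
  expect_true(all(is.na(res$opticf_i[1:10])))
})

test_that("white-noise input is unpredictable; AR(1) input has R2 near phi^2", {
  n <- 500
  r2w <- replicate(5, {
    sig <- make_session_signals(n, seed = sample.int(1e6, 1))
    tr <- make_session_trials(n)
    r2 <- attr(compute_innovations(sig, tr), "r2")
    mean(r2$r2)
  })
  # in-sample R2 of pure noise on 51 regressors concentrates near p/n
  expect_lt(abs(mean(r2w) - 51 / (n - 10)), 0.06)
  set.seed(8)
  r2a <- replicate(8, {
    sig <- make_session_signals(n, seed = sample.int(1e6, 1))
    sig$opticf <- as.numeric(arima.sim(list(ar = 0.8), n))
    tr <- make_session_trials(n)
    r2 <- attr(compute_innovations(sig, tr), "r2")
    r2$r2[r2$signal == "opticf"]
  })
  expect_lt(abs(mean(r2a) - 0.64), 0.06)
})

test_that("default innovations are orthogonal to previous outcome; outcome-free ones need not be", {
  ds <- small_dataset()
  sig1 <- compute_innovations(ds$signals, ds$trials, include_outcome = TRUE)
  sig0 <- compute_innovations(ds$signals, ds$trials, include_outcome = FALSE)
  for (sid in unique(ds$trials$session_id)) {
    tr <- ds$trials[ds$trials$session_id == sid, ]
    reward <- as.numeric(tr$trial_class == "valid" & !is.na(tr$correct) &
                           tr$correct == 1)
    prev_reward <- c(NA, reward[-length(reward)])
    s1 <- sig1[sig1$session_id == sid, ]
    ok <- !is.na(s1$pupils_i)
    expect_lt(abs(cor(s1$pupils_i[ok], prev_reward[ok])), 1e-8)
  }
  # with the reward->pupil effect injected, outcome-free pupil innovations
  # correlate with previous reward
  s0 <- sig0[!is.na(sig0$pupils_i), ]
  tr_all <- merge(s0, ds$trials, by = c("session_id", "trial_number"))
  prev_rew <- unlist(lapply(split(ds$trials, ds$trials$session_id), function(d) {
    r <- as.numeric(d$trial_class == "valid" & !is.na(d$correct) & d$correct == 1)
    c(NA, r[-length(r)])
  }))
  key <- paste(ds$trials$session_id, ds$trials$trial_number)
  pr <- prev_rew[match(paste(tr_all$session_id, tr_all$trial_number), key)]
  expect_gt(cor(tr_all$pupils_i, pr, use = "complete.obs"), 0.1)
})

test_that("whitening kills the slow-component correlations, raw signals keep them", {
  cfg <- synth_config(n_sessions = 8, trials_per_session = 300, seed = 62,
                      fast_couplings = c(opticf_fr = 0, pupils_synch = 0,
                                         opticf_pupils = 0),
                      gating_effects = list(after_error = c(fr = 0, synch = 0),
                                            after_correct = c(fr = 0, synch = 0)),
                      reward_pupil_gain = 0, scenario = "null")
  ds <- memo("white_ds", generate_dataset(cfg))
  sig <- compute_innovations(ds$signals, ds$trials)
  wi <- whiteness_report(sig)
  expect_gte(mean(wi$inside), 0.95)
  wr <- whiteness_report(sig, cols = c("opticf", "pupils", "fr", "synch"))
  raw_auto <- wr[wr$a == wr$b & wr$lag <= 3, ]
  expect_true(all(!raw_auto$inside))
  raw_cross0 <- wr[wr$a != wr$b & wr$lag == 0, ]
  expect_true(all(abs(raw_cross0$median) > raw_cross0$band))
  # whitening is temporal: innovations at lags >= 1 are inside the band, and
  # the instantaneous cross-correlation is strongly attenuated relative to the
  # raw signals (a residue from the slow drivers' own correlated one-step
  # innovations remains, as in real data)
  wi_lag <- wi[wi$lag >= 1, ]
  expect_gte(mean(wi_lag$inside), 0.95)
  wi_cross0 <- wi[wi$a != wi$b & wi$lag == 0, ]
  expect_true(all(abs(wi_cross0$median) < abs(raw_cross0$median) / 2))
})

test_that("degenerate inputs are flagged, not silently fit", {
  n <- 120
  sig <- make_session_signals(n, seed = 10)
  sig$synch <- 1 # constant signal
  tr <- make_session_trials(n)
  w <- capture_warnings(res <- compute_innovations(sig, tr))
  expect_match(w, "constant signal", all = FALSE)
  expect_match(w, "rank-deficient", all = FALSE)
  wr <- whiteness_report(res, max_lag = 3)
  expect_true(all(is.na(wr$median[wr$a == "synch_i" | wr$b == "synch_i"])))
  expect_false(anyNA(wr$median[wr$a != "synch_i" & wr$b != "synch_i"]))
  # short sessions are skipped with a warning
  sigs <- rbind(make_session_signals(12), transform(make_session_signals(120),
                                                    session_id = "B",
                                                    trial_number = 1:120))
  trs <- rbind(transform(make_session_trials(12), session_id = "A"),
               transform(make_session_trials(120), session_id = "B"))
  sigs$session_id <- rep(c("A", "B"), c(12, 120))
  expect_warning(r2 <- compute_innovations(sigs, trs), "skipped")
  expect_true(all(is.na(r2$fr_i[r2$session_id == "A"])))
  expect_false(all(is.na(r2$fr_i[r2$session_id == "B"])))
})
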