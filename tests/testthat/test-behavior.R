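test_that("trial classes follow the response-timing rules", {
  rt <- c(0.3, NA, 1.0, 0.64, 0.66, 0.7, 1.7, 1.8, 2.5)
  expect_equal(classify_trials(rt),
               c("premature", "skip", "valid", "premature", "other", "valid",
                 "valid", "other", "skip"))
  expect_error(classify_trials(c(0.5, -0.1)), "negative")
})

test_that("session inclusion applies the trial-count and sensitivity rules", {
  mk <- function(sid, n, p_correct) {
    cat <- sample(c("low", "high"), n, replace = TRUE)
    correct <- rbinom(n, 1, p_correct)
    data.frame(session_id = sid, trial_number = seq_len(n),
               trial_class = "valid", stim_category = cat,
               choice = ifelse(correct == 1, cat,
                               ifelse(cat == "high", "low", "high")),
               correct = correct)
  }
  set.seed(33)
  tr <- rbind(mk("good", 200, 0.85), mk("short", 99, 0.9),
              mk("chance", 200, 0.5), mk("perfect", 200, 1.0))
  incl <- session_inclusion(tr)
  keep <- setNames(incl$keep, incl$session_id)
  expect_true(keep[["good"]])
  expect_false(keep[["short"]])   # 99 trials < 100
  expect_false(keep[["chance"]])  # d' near 0
  expect_true(keep[["perfect"]])  # boundary correction keeps d' finite
  expect_true(is.finite(incl$dprime[incl$session_id == "perfect"]))
  expect_lt(abs(incl$dprime[incl$session_id == "chance"]), 0.5)
})

test_that("joint state predictor matches its closed form", {
  expect_equal(joint_state_predictor(1, -1, "after_error"), sqrt(2))
  expect_equal(joint_state_predictor(1, 1, "after_error"), 0)
  expect_equal(joint_state_predictor(1, 1, "after_correct"), sqrt(2))
  # swapping context negates the projection for antisymmetric inputs
  fr <- c(0.5, -1.2); syn <- -fr
  expect_equal(joint_state_predictor(fr, syn, "after_error"),
               -joint_state_predictor(syn, fr, "after_error"))
})

test_that("analysis table applies the exclusion rules and conditioning splits", {
  ds <- small_dataset()
  sig <- compute_innovations(ds$signals, ds$trials)
  # inject an intervention trial to check successor exclusion
  tr <- ds$trials
  tr$intervention_flag[tr$session_id == "S01" & tr$trial_number == 50] <- 1L
  tab <- build_analysis_table(tr, sig, apply_inclusion = FALSE)
  expect_true(all(tab$trial_number > 10))
  expect_false(any(tab$session_id == "S01" & tab$trial_number %in% c(50, 51)))
  # conditioning consistency: after-correct + after-error = valid-after-valid
  v <- tab[tab$trial_class == "valid" & tab$prev_valid, ]
  expect_equal(sum(v$prev_correct == 1) + sum(v$prev_correct == 0), nrow(v))
  # z-scored columns have unit scale per session
  for (sid in unique(tab$session_id)) {
    z <- tab$fr_iz[tab$session_id == sid]
    z <- z[is.finite(z)]
    expect_lt(abs(mean(z)), 1e-8)
    expect_equal(sd(z), 1, tolerance = 1e-8)
  }
})

test_that("discriminability index matches its closed form", {
  expect_equal(dprime_state_by_outcome(rep(c(0, 1), 10), rep(c(0, 1), 10)), 0)
  a <- c(0.8, 1.2, 1, 0.9, 1.1); b <- a - 1
  expect_equal(dprime_state_by_outcome(a, b),
               (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2))
  set.seed(35)
  x <- rnorm(4000, 1); y <- rnorm(4000, 0)
  expect_equal(dprime_state_by_outcome(x, y), 1, tolerance = 0.08)
  expect_true(is.na(dprime_state_by_outcome(rep(1, 6), rep(0, 6))))
  expect_error(dprime_state_by_outcome(1:3, 1:6), "at least 5")
})

test_that("slow-component cross-correlation finds constructed shifts and asymmetries", {
  set.seed(37)
  ses <- rep(c("A", "B", "C"), each = 200)
  a <- as.numeric(sapply(1:3, function(i) arima.sim(list(ar = 0.9), 200)))
  b <- unlist(lapply(split(a, ses), function(x) c(rep(0, 3), x[1:197])))
  xc <- slow_component_xcorr(a, b, ses)
  expect_equal(xc$lag[which.max(xc$median)], 3)
  # independent series: flat near zero
  b2 <- rnorm(600)
  xc2 <- slow_component_xcorr(a, b2, ses)
  expect_lt(max(abs(xc2$median)), 0.25)
  expect_error(slow_component_xcorr(a[1:30], b2[1:30], ses[1:30]), "enough trials")
  # generated reward -> pupil coupling: effect at positive lags only
  ds <- memo("xc_ds", generate_dataset(
    synth_config(n_sessions = 6, trials_per_session = 300,
                 reward_pupil_gain = 1.2, seed = 71)))
  tr <- ds$trials
  outcome <- ifelse(tr$trial_class == "valid" & !is.na(tr$correct),
                    tr$correct, 0)
  xc3 <- slow_component_xcorr(outcome, ds$signals$pupils, tr$session_id)
  pos <- xc3$median[xc3$lag == 1]
  neg <- xc3$median[xc3$lag == -8]
  expect_gt(pos, neg + 0.1)
})

test_that("accuracy models recover gated state effects and their conditioning logic", {
  ds <- memo("gated_ds", generate_dataset(synth_config(
    n_sessions = 12, trials_per_session = 350,
    gating_effects = list(after_error = c(fr = 0.45, synch = -0.45),
                          after_correct = c(fr = 0, synch = 0)), seed = 81)))
  sig <- compute_innovations(ds$signals, ds$trials)
  tab <- memo("gated_tab", build_analysis_table(ds$trials, sig))
  res <- memo("gated_fits",
              run_accuracy_models(tab, n_resamples = 300, seed = 7))
  ae <- res$after_error$summary
  expect_gt(ae$estimate[ae$term == "fr_iz"], 0)
  expect_lt(ae$estimate[ae$term == "synch_iz"], 0)
  expect_lt(ae$p_value[ae$term == "synch_iz"], 0.05)
  ac <- res$after_correct$summary
  expect_gt(ac$p_value[ac$term == "fr_iz"], 0.05)
  expect_gt(ac$p_value[ac$term == "synch_iz"], 0.05)
  # occlusion: unconditional coefficients attenuated toward zero
  un <- res$unconditional$summary
  expect_lt(abs(un$estimate[un$term == "fr_iz"]),
            abs(ae$estimate[ae$term == "fr_iz"]))
  expect_lt(abs(un$estimate[un$term == "synch_iz"]),
            abs(ae$estimate[ae$term == "synch_iz"]))
  # joint predictor variant: positive and significant after errors
  rj <- run_accuracy_models(tab, conditions = "after_error", joint = TRUE,
                            n_resamples = 300, seed = 8)
  js <- rj$after_error$summary
  expect_gt(js$estimate[js$term == "joint_err"], 0)
  expect_lt(js$p_value[js$term == "joint_err"], 0.05)
})

test_that("outcome decoding finds the injected reward-pupil effect and nothing else under the null", {
  ds <- memo("gated_ds", generate_dataset(synth_config(
    n_sessions = 12, trials_per_session = 350,
    gating_effects = list(after_error = c(fr = 0.45, synch = -0.45),
                          after_correct = c(fr = 0, synch = 0)), seed = 81)))
  sig0 <- compute_innovations(ds$signals, ds$trials, include_outcome = FALSE)
  tab0 <- build_analysis_table(ds$trials, sig0)
  attr(tab0, "include_outcome") <- FALSE
  od <- run_outcome_decoding(tab0, n_resamples = 300, seed = 9)
  s <- od$summary
  expect_gt(s$estimate[s$term == "pupils_iz"], 0)
  expect_lt(s$p_value[s$term == "pupils_iz"], 0.05)
  # innovations computed with outcome history cannot be used here
  tab1 <- small_table()
  expect_error(run_outcome_decoding(tab1), "include_outcome = FALSE")
  # null generator: no state coefficient significant
  dsn <- memo("null_ds", generate_dataset(synth_config(
    n_sessions = 8, trials_per_session = 250, scenario = "null",
    reward_pupil_gain = 0, seed = 83)))
  sn <- compute_innovations(dsn$signals, dsn$trials, include_outcome = FALSE)
  tn <- build_analysis_table(dsn$trials, sn)
  attr(tn, "include_outcome") <- FALSE
  odn <- run_outcome_decoding(tn, n_resamples = 300, seed = 10)
  sn2 <- odn$summary
  state <- sn2$term %in% c("opticf_iz", "pupils_iz", "fr_iz", "synch_iz")
  expect_true(all(sn2$p_value[state] > 0.01))
})

test_that("responsivity models recover the injected couplings", {
  ds <- memo("gated_ds", generate_dataset(synth_config(
    n_sessions = 12, trials_per_session = 350,
    gating_effects = list(after_error = c(fr = 0.45, synch = -0.45),
                          after_correct = c(fr = 0, synch = 0)), seed = 81)))
  sig <- compute_innovations(ds$signals, ds$trials)
  tab <- memo("gated_tab", build_analysis_table(ds$trials, sig))
  rv <- memo("resp_fits", run_responsivity_models(tab, n_resamples = 300, seed = 11))
  sk <- rv$skip$summary
  expect_gt(sk$estimate[sk$term == "trn"], 0)        # end-of-session ramp
  expect_lt(sk$p_value[sk$term == "trn"], 0.05)
  expect_gt(sk$estimate[sk$term == "opticf_iz"], 0)  # movement predicts skips
  expect_lt(sk$p_value[sk$term == "opticf_iz"], 0.05)
  pm <- rv$premature$summary
  expect_lt(pm$estimate[pm$term == "trn"], 0)        # decaying premature hazard
  expect_lt(pm$p_value[pm$term == "trn"], 0.05)
  expect_lt(pm$estimate[pm$term == "pupils_iz"], 0)  # constricted pupil
  # RT model runs on valid trials with the gaussian family
  expect_equal(rv$rt$fit$family, "gaussian")
  expect_equal(rv$rt$fit$n, sum(tab$trial_class == "valid"))
})
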