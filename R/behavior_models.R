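#' Classify trials by response timing
#'
#' Assigns each trial a class from its first-lick time relative to stimulus
#' onset: `premature` if the first lick precedes the go signal at 0.65 s,
#' `valid` if it falls inside the response window `[0.7, 1.7]` s, `skip` if no
#' lick occurs within the first 2 s (`rt_s` missing), and `other` (excluded
#' from analysis) for licks in the remaining gray zones.
#'
#' @param rt_s first-lick time in seconds, `NA` when no lick occurred within
#'   2 s of stimulus onset.
#' @param go_s,window,skip_s go-signal time, valid response window, and the
#'   no-lick horizon defining skips.
#' @return character vector of classes.
#' @export
classify_trials <- function(rt_s, go_s = 0.65, window = c(0.7, 1.7),
                            skip_s = 2) {
  if (any(rt_s < 0, na.rm = TRUE)) stop("negative reaction times in input")
  cls <- rep("other", length(rt_s))
  cls[is.na(rt_s) | rt_s > skip_s] <- "skip"
  lick <- !is.na(rt_s) & rt_s <= skip_s
  cls[lick & rt_s < go_s] <- "premature"
  cls[lick & rt_s >= window[1] & rt_s <= window[2]] <- "valid"
  cls
}

#' Session inclusion by trial count and behavioral sensitivity
#'
#' A session is kept when it has at least `min_trials` trials and a
#' signal-detection sensitivity d' of at least `min_dprime`, computed on valid
#' trials from the hit rate (report high | high stimulus) and false-alarm rate
#' (report high | low stimulus) with a 1/(2N) boundary correction so perfect
#' performance yields a finite d'.
#'
#' @param trials trial table (`session_id`, `trial_class`, `choice`,
#'   `stim_category`).
#' @param min_trials,min_dprime inclusion thresholds (defaults 100 and 1).
#' @return data frame per session: `session_id`, `n_trials`, `dprime`, `keep`.
#' @export
session_inclusion <- function(trials, min_trials = 100L, min_dprime = 1) {
  res <- lapply(split(trials, trials$session_id), function(tr) {
    v <- tr[tr$trial_class == "valid", ]
    hi <- v$stim_category == "high"
    rate <- function(x, n) min(max(x / n, 1 / (2 * n)), 1 - 1 / (2 * n))
    dp <- if (sum(hi) > 0 && sum(!hi) > 0) {
      h <- rate(sum(v$choice[hi] == "high"), sum(hi))
      f <- rate(sum(v$choice[!hi] == "high"), sum(!hi))
      stats::qnorm(h) - stats::qnorm(f)
    } else NA_real_
    data.frame(session_id = tr$session_id[1], n_trials = nrow(tr), dprime = dp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$keep <- out$n_trials >= min_trials & !is.na(out$dprime) &
    out$dprime >= min_dprime
  if (any(!out$keep))
    message("dropping ", sum(!out$keep), " session(s): ",
            paste(out$session_id[!out$keep], collapse = ", "))
  out
}

#' Joint baseline-state predictor
#'
#' Projects each z-scored (firing-rate, synchrony) innovation pair onto a unit
#' axis of -45 degrees (after errors: favorable means elevated *and*
#' desynchronized activity, so `(fr - synch)/sqrt(2)`) or +45 degrees (after
#' corrects: `(fr + synch)/sqrt(2)`), giving a single scalar that is large and
#' positive when both components are favorable for accuracy in that context.
#'
#' @param fr_z,synch_z per-session z-scored innovations.
#' @param context `"after_error"` or `"after_correct"`.
#' @return numeric vector of projections.
#' @export
joint_state_predictor <- function(fr_z, synch_z,
                                  context = c("after_error", "after_correct")) {
  context <- match.arg(context)
  if (context == "after_error") (fr_z - synch_z) / sqrt(2)
  else (fr_z + synch_z) / sqrt(2)
}

#' Assemble the trial-level analysis table
#'
#' Merges the trial table with the (innovation-augmented) signal table, applies
#' the standard exclusions — the first `drop_first` trials of each session,
#' free-reward/intervention trials and the trial following each of them —
#' and adds the derived per-trial columns used by every behavioral model:
#' `stim` (absolute evidence strength), `trn` (trial number), previous-trial
#' class indicators (`pcorr`, `pprem`, `pskip`; previous valid error is the
#' reference), previous/next-outcome conditioning columns (`prev_valid`,
#' `prev_correct`, `next_valid`, `next_correct`), per-session z-scored signal
#' and innovation columns (suffix `_z` / `_iz`), and the two joint state
#' predictors (`joint_err`, `joint_corr`).
#'
#' @param trials trial table (one row per trial, ordered within session).
#' @param signals signal table, typically from [compute_innovations()].
#' @param drop_first number of initial trials per session to exclude (10).
#' @param apply_inclusion drop sessions failing [session_inclusion()].
#' @return the analysis table (excluded rows removed), with attribute
#'   `sessions` carrying the inclusion report.
#' @export
build_analysis_table <- function(trials, signals, drop_first = 10L,
                                 apply_inclusion = TRUE) {
  df <- merge(trials, signals, by = c("session_id", "trial_number"),
              sort = FALSE)
  df <- df[order(df$session_id, df$trial_number), ]
  incl <- session_inclusion(trials)
  if (apply_inclusion)
    df <- df[df$session_id %in% incl$session_id[incl$keep], ]
  parts <- lapply(split(df, df$session_id, drop = TRUE), function(d) {
    n <- nrow(d)
    d$trn <- d$trial_number
    d$stim <- abs(d$evidence)
    prev <- function(x) c(NA, x[-n])
    nxt <- function(x) c(x[-1], NA)
    pc <- prev(d$trial_class)
    pcorrect <- prev(d$correct)
    d$prev_valid <- !is.na(pc) & pc == "valid"
    d$prev_correct <- ifelse(d$prev_valid, pcorrect, NA)
    nc <- nxt(d$trial_class)
    d$next_valid <- !is.na(nc) & nc == "valid"
    d$next_correct <- ifelse(d$next_valid, nxt(d$correct), NA)
    d$pcorr <- as.numeric(d$prev_valid & d$prev_correct == 1)
    d$pcorr[is.na(d$pcorr)] <- 0
    d$pprem <- as.numeric(!is.na(pc) & pc == "premature")
    d$pskip <- as.numeric(!is.na(pc) & pc == "skip")
    flagged <- d$free_reward_flag == 1 | d$intervention_flag == 1
    d$excluded <- d$trial_number <= drop_first | flagged | prev(flagged) %in% TRUE
    # z-scores are computed on the analyzed (non-excluded) trials so the
    # within-session standardization matches what the models will see
    zs <- function(x) {
      out <- rep(NA_real_, length(x))
      out[!d$excluded] <- zscore_session(x[!d$excluded])
      out
    }
    for (j in SIGNALS) {
      d[[paste0(j, "_z")]] <- zs(d[[j]])
      ic <- paste0(j, "_i")
      if (ic %in% names(d)) d[[paste0(j, "_iz")]] <- zs(d[[ic]])
    }
    if (all(c("fr_iz", "synch_iz") %in% names(d))) {
      d$joint_err <- joint_state_predictor(d$fr_iz, d$synch_iz, "after_error")
      d$joint_corr <- joint_state_predictor(d$fr_iz, d$synch_iz, "after_correct")
    }
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out <- out[!out$excluded, ]
  attr(out, "sessions") <- incl
  out
}

zscore_session <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

state_terms <- function(predictors = c("innovations", "raw"), joint = FALSE,
                        context = "after_error", quadratic = FALSE) {
  predictors <- match.arg(predictors)
  suf <- if (predictors == "innovations") "_iz" else "_z"
  if (joint) {
    jt <- if (context == "after_correct") "joint_corr" else "joint_err"
    terms <- c(paste0(c("opticf", "pupils"), suf), jt)
  } else {
    terms <- paste0(SIGNALS, suf)
  }
  if (quadratic && !joint)
    terms <- c(terms, paste0("I(", paste0(c("fr", "synch"), suf), "^2)"))
  terms
}

#' Accuracy models conditioned on previous or next outcome
#'
#' Fits the binomial mixed model `correct ~ stim + trn + state terms`
#' (per-session random intercept and slopes for every term) on valid trials,
#' for the requested conditioning variants: `unconditional` (all valid trials
#' with a valid previous trial, adding the previous-outcome indicator `pcorr`
#' as fixed and random term), `after_correct` / `after_error` (subset by the
#' previous valid trial's outcome), and `next_correct` / `next_error` (subset
#' by the *next* trial's outcome, the epoch-hypothesis control). Each fit gets
#' hierarchical-bootstrap uncertainty.
#'
#' @param table analysis table from [build_analysis_table()].
#' @param conditions character vector of variants (see above).
#' @param predictors `"innovations"` (default) or `"raw"` baseline signals.
#' @param joint replace the separate fr/synch terms by the context-appropriate
#'   joint projection ([joint_state_predictor()]).
#' @param quadratic add squared fr and synch terms.
#' @param n_resamples,seed bootstrap settings (see [hierarchical_bootstrap()]).
#' @param boot run the bootstrap (set `FALSE` for point fits only).
#' @return named list of `state_glmm_boot` (or `state_glmm` when
#'   `boot = FALSE`), one per variant; empty variants are skipped with a
#'   warning.
#' @export
run_accuracy_models <- function(table,
                                conditions = c("unconditional", "after_correct",
                                               "after_error"),
                                predictors = c("innovations", "raw"),
                                joint = FALSE, quadratic = FALSE,
                                n_resamples = 5000L, seed = 1L, boot = TRUE) {
  predictors <- match.arg(predictors)
  valid <- table[table$trial_class == "valid", ]
  out <- list()
  for (cond in conditions) {
    sub <- switch(cond,
      unconditional = valid[valid$prev_valid, ],
      after_correct = valid[valid$prev_valid & valid$prev_correct == 1, ],
      after_error = valid[valid$prev_valid & valid$prev_correct == 0, ],
      next_correct = valid[valid$next_valid & valid$next_correct == 1, ],
      next_error = valid[valid$next_valid & valid$next_correct == 0, ],
      stop("unknown condition: ", cond))
    if (nrow(sub) < 30L || length(unique(sub$session_id)) < 2L) {
      warning("condition '", cond, "' skipped: too few trials or sessions")
      next
    }
    ctx <- if (cond %in% c("after_correct", "next_correct"))
      "after_correct" else "after_error"
    terms <- state_terms(predictors, joint, ctx, quadratic)
    rhs <- c("stim", "trn", terms)
    if (cond == "unconditional") rhs <- c(rhs, "pcorr")
    f <- stats::as.formula(paste("correct ~", paste(rhs, collapse = " + ")))
    fit <- fit_glmm(f, sub, family = "binomial")
    out[[cond]] <- if (boot)
      hierarchical_bootstrap(fit, n_resamples = n_resamples,
                             seed = derive_seed(seed, match(cond, conditions)))
    else fit
  }
  out
}

#' Decode the previous trial's outcome from the current baseline
#'
#' Binomial mixed model `pcorr ~ trn + innovations` asking which features of
#' the current baseline carry information about the previous trial's outcome.
#' The innovations must have been computed with `include_outcome = FALSE`
#' (otherwise they are orthogonal to previous outcome by construction and the
#' model is vacuous); this is checked via the attribute set by
#' [compute_innovations()] when present.
#'
#' @param table analysis table whose innovation columns come from an
#'   outcome-free whitening model; only trials with a valid previous trial are
#'   used.
#' @param n_resamples,seed,boot bootstrap settings.
#' @return a `state_glmm_boot` (or `state_glmm` when `boot = FALSE`).
#' @export
run_outcome_decoding <- function(table, n_resamples = 5000L, seed = 1L,
                                 boot = TRUE) {
  io <- attr(table, "include_outcome")
  if (isTRUE(io))
    stop("outcome decoding requires innovations computed with include_outcome = FALSE")
  sub <- table[table$prev_valid, ]
  f <- stats::as.formula(paste("pcorr ~ trn +",
                               paste(paste0(SIGNALS, "_iz"), collapse = " + ")))
  fit <- fit_glmm(f, sub, family = "binomial")
  if (boot) hierarchical_bootstrap(fit, n_resamples = n_resamples, seed = seed)
  else fit
}

#' Responsivity models: premature responding, disengagement, reaction time
#'
#' Binomial mixed models for premature-vs-valid and skip-vs-valid trials with
#' predictors `trn`, previous-class indicators (`pprem`, `pcorr`, `pskip`) and
#' the four baseline terms, plus a Gaussian mixed model for reaction time on
#' valid trials with the same predictors. All models use per-session random
#' intercepts and slopes.
#'
#' @param table analysis table.
#' @param predictors `"innovations"` or `"raw"`.
#' @param n_resamples,seed,boot bootstrap settings.
#' @return named list with elements `premature`, `skip`, `rt`.
#' @export
run_responsivity_models <- function(table,
                                    predictors = c("innovations", "raw"),
                                    n_resamples = 5000L, seed = 1L,
                                    boot = TRUE) {
  predictors <- match.arg(predictors)
  suf <- if (predictors == "innovations") "_iz" else "_z"
  terms <- paste0(SIGNALS, suf)
  rhs <- paste(c("trn", "pprem", "pcorr", "pskip", terms), collapse = " + ")
  out <- list()
  fit_one <- function(f, d, fam, idx) {
    fit <- fit_glmm(f, d, family = fam)
    if (boot) hierarchical_bootstrap(fit, n_resamples = n_resamples,
                                     seed = derive_seed(seed, idx))
    else fit
  }
  pv <- table[table$trial_class %in% c("premature", "valid"), ]
  pv$premature <- as.numeric(pv$trial_class == "premature")
  out$premature <- fit_one(stats::as.formula(paste("premature ~", rhs)),
                           pv, "binomial", 1L)
  sv <- table[table$trial_class %in% c("skip", "valid"), ]
  sv$skip <- as.numeric(sv$trial_class == "skip")
  out$skip <- fit_one(stats::as.formula(paste("skip ~", rhs)),
                      sv, "binomial", 2L)
  v <- table[table$trial_class == "valid", ]
  out$rt <- fit_one(stats::as.formula(paste("rt_s ~", rhs)), v, "gaussian", 3L)
  out
}

#' Signed discriminability index between two outcome-conditioned distributions
#'
#' `d' = (mean(after correct) - mean(after error)) / sqrt((var_c + var_e)/2)`,
#' the pooled-SD separation of a baseline state variable conditioned on the
#' previous trial's outcome.
#'
#' @param after_correct,after_error numeric vectors (at least 5 values each).
#' @return the signed d', or `NA_real_` if the pooled variance is zero.
#' @export
dprime_state_by_outcome <- function(after_correct, after_error) {
  after_correct <- after_correct[is.finite(after_correct)]
  after_error <- after_error[is.finite(after_error)]
  if (length(after_correct) < 5L || length(after_error) < 5L)
    stop("need at least 5 values per outcome group")
  pooled <- (stats::var(after_correct) + stats::var(after_error)) / 2
  if (pooled == 0) return(NA_real_)
  (mean(after_correct) - mean(after_error)) / sqrt(pooled)
}

#' Cross-correlation of the slow components of two trial series
#'
#' Per session: smooth both series with a centered moving average, linearly
#' detrend, z-score, and correlate at trial lags `-max_lag..max_lag`; then
#' aggregate across sessions as median and MAD. Positive lags mean `b` lags
#' behind `a` (`cor(a[t], b[t + lag])`). Used both for the slow components of
#' baseline state vs. accuracy and for the outcome -> pupil relationship,
#' where reward licking shows up at positive lags only.
#'
#' @param a,b numeric vectors (per-trial series across all sessions).
#' @param session session id per trial.
#' @param smooth_width moving-average width in trials (default 5).
#' @param max_lag maximum lag (default 20).
#' @param min_trials minimum finite trials per session (default 50).
#' @return data frame: `lag`, `median`, `mad`, `n_sessions`. Constant series
#'   within a session yield missing correlations for that session.
#' @export
slow_component_xcorr <- function(a, b, session, smooth_width = 5L,
                                 max_lag = 20L, min_trials = 50L) {
  stopifnot(length(a) == length(b), length(a) == length(session))
  lags <- -max_lag:max_lag
  per <- list()
  for (sid in unique(session)) {
    sel <- session == sid
    x <- a[sel]; y <- b[sel]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_trials) next
    xs <- prep_slow(x, smooth_width); ys <- prep_slow(y, smooth_width)
    if (anyNA(c(xs[1], ys[1]))) next
    r <- vapply(lags, function(l) {
      n <- length(xs)
      if (l >= 0) stats::cor(xs[seq_len(n - l)], ys[seq_len(n - l) + l])
      else stats::cor(xs[seq_len(n + l) - l], ys[seq_len(n + l)])
    }, numeric(1))
    per[[length(per) + 1L]] <- r
  }
  if (!length(per)) stop("no session has enough trials")
  m <- do.call(rbind, per)
  data.frame(lag = lags,
             median = apply(m, 2, stats::median, na.rm = TRUE),
             mad = apply(m, 2, stats::mad, constant = 1, na.rm = TRUE),
             n_sessions = nrow(m))
}

prep_slow <- function(x, width) {
  if (stats::sd(x) == 0) return(rep(NA_real_, length(x)))
  k <- rep(1 / width, width)
  sm <- stats::filter(x, k, sides = 2)
  # shrink the window at the edges instead of dropping trials
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1, i - (width %/% 2)); hi <- min(length(x), i + (width %/% 2))
    sm[i] <- mean(x[lo:hi])
  }
  sm <- as.numeric(sm)
  dt <- stats::lm.fit(cbind(1, seq_along(sm)), sm)$residuals
  s <- stats::sd(dt)
  if (s == 0) return(rep(NA_real_, length(x)))
  (dt - mean(dt)) / s
}
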