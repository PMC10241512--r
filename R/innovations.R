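#' Per-session trial-history design matrix
#'
#' Builds the regression design used to cross-whiten the four baseline signals
#' of one session: the reward outcome of the previous `lags` trials (1 =
#' reward, 0 = no reward, with premature and skip trials counting as 0), the
#' values of all four signals in the previous `lags` trials, and the current
#' trial number. With `include_outcome = TRUE` and `lags = 10` the design has
#' exactly 51 predictor columns (10 outcome lags + 4 x 10 signal lags + trial
#' number), plus an intercept added at fit time; without outcome history, 41.
#' Rows lacking a complete lag history (the first `lags` trials) are masked
#' out rather than zero-padded.
#'
#' @param signals one session's signal table with columns `opticf`, `pupils`,
#'   `fr`, `synch` (one row per trial, in trial order).
#' @param outcomes 0/1 reward vector for the same trials (1 = rewarded).
#' @param lags history depth in trials (default 10).
#' @param include_outcome include the outcome-history block (default `TRUE`).
#' @return list with `X` (design matrix, masked-in rows only), `mask` (logical
#'   vector over trials: has full history and finite signal history) and
#'   `colnames` documentation.
#' @export
build_history_design <- function(signals, outcomes, lags = 10L,
                                 include_outcome = TRUE) {
  n <- nrow(signals)
  if (n < lags + 5L)
    stop("session too short for the requested history depth (need >= lags + 5 trials)")
  if (length(outcomes) != n) stop("outcomes must have one value per trial")
  sig <- as.matrix(signals[, SIGNALS])
  cols <- list()
  if (include_outcome) {
    for (l in seq_len(lags)) cols[[paste0("outcome_lag", l)]] <- shift_lag(outcomes, l)
  }
  for (j in SIGNALS) {
    for (l in seq_len(lags)) cols[[paste0(j, "_lag", l)]] <- shift_lag(sig[, j], l)
  }
  cols[["trn"]] <- seq_len(n)
  X <- do.call(cbind, cols)
  mask <- seq_len(n) > lags & apply(X, 1, function(r) all(is.finite(r)))
  list(X = X[mask, , drop = FALSE], mask = mask)
}

shift_lag <- function(x, l) c(rep(NA_real_, l), x[seq_len(length(x) - l)])

#' Cross-whiten baseline signals into innovations
#'
#' For each session, regresses each of the four baseline signals (`opticf`,
#' `pupils`, `fr`, `synch`) on the trial-history design of
#' [build_history_design()] by ordinary least squares and stores the residuals
#' as the signal's "innovation" (columns `opticf_i`, `pupils_i`, `fr_i`,
#' `synch_i`): the temporally white, trial-by-trial component of the signal
#' from which session trends and slow fluctuations spanning many trials have
#' been removed. Masked rows (the first `lags` trials of each session) carry
#' `NA` innovations and are excluded from downstream fits.
#'
#' For the outcome-decoding analysis (does the baseline carry information
#' about the previous trial's outcome?) use `include_outcome = FALSE`:
#' innovations from the default model are orthogonal to previous outcome by
#' construction.
#'
#' @param signals signal table with `session_id`, `trial_number` and the four
#'   signal columns, in trial order within session.
#' @param trials trial table providing the reward history (`trial_class`,
#'   `correct`).
#' @param lags history depth (default 10).
#' @param include_outcome include outcome history in the whitening model.
#' @return the signal table augmented with the four innovation columns and an
#'   attribute `r2`: a data frame of per-session, per-signal in-sample
#'   prediction R-squared values.
#' @export
compute_innovations <- function(signals, trials, lags = 10L,
                                include_outcome = TRUE) {
  stopifnot(all(SIGNALS %in% names(signals)))
  out <- signals
  for (j in SIGNALS) out[[paste0(j, "_i")]] <- NA_real_
  r2 <- list()
  for (sid in unique(signals$session_id)) {
    sel <- which(signals$session_id == sid)
    sig_s <- signals[sel, , drop = FALSE]
    tr_s <- trials[trials$session_id == sid, , drop = FALSE]
    tr_s <- tr_s[match(sig_s$trial_number, tr_s$trial_number), , drop = FALSE]
    reward <- as.numeric(tr_s$trial_class == "valid" &
                           !is.na(tr_s$correct) & tr_s$correct == 1)
    des <- tryCatch(build_history_design(sig_s, reward, lags, include_outcome),
                    error = function(e) {
                      warning("session ", sid, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(des)) next
    for (j in SIGNALS) {
      y <- sig_s[[j]][des$mask]
      ok <- is.finite(y)
      if (sum(ok) > 1L && stats::sd(y[ok]) == 0) {
        warning("session ", sid, ", signal ", j,
                ": constant signal; innovations left as NA")
        next
      }
      if (sum(ok) < ncol(des$X) + 2L) {
        warning("session ", sid, ", signal ", j,
                ": too few finite trials for whitening; left as NA")
        next
      }
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, des$X[ok, , drop = FALSE]), y[ok])
      if (fit$rank < ncol(des$X) + 1L)
        warning("session ", sid, ", signal ", j,
                ": rank-deficient history design; ",
                ncol(des$X) + 1L - fit$rank, " collinear column(s) dropped")
      res <- rep(NA_real_, length(y)); res[ok] <- fit$residuals
      out[[paste0(j, "_i")]][sel][des$mask] <- res
      r2[[length(r2) + 1L]] <- data.frame(
        session_id = sid, signal = j,
        r2 = 1 - sum(fit$residuals^2) / sum((y[ok] - mean(y[ok]))^2))
    }
  }
  attr(out, "r2") <- do.call(rbind, r2)
  attr(out, "include_outcome") <- include_outcome
  attr(out, "lags") <- lags
  out
}

#' Whiteness diagnostics for innovations (or raw signals)
#'
#' Auto- and cross-correlations at trial lags `1..max_lag` (cross-correlations
#' also at lag 0), computed per session and aggregated across sessions as
#' median and MAD, with the approximate +/-2/sqrt(n) white-noise band.
#' Innovations from [compute_innovations()] should be inside the band at
#' essentially all lags; the raw signals, which carry session trends and slow
#' fluctuations, should not.
#'
#' @param signals table with `session_id` and the columns named in `cols`.
#' @param cols character vector of columns to correlate (default the four
#'   innovation columns).
#' @param max_lag maximum trial lag (default 10).
#' @param min_trials sessions with fewer finite trials are skipped.
#' @return data frame with one row per (pair, lag): `a`, `b`, `lag`, `median`,
#'   `mad`, `band` (2/sqrt of the median session length) and `inside`.
#'   Degenerate (constant) series yield `NA` correlations and are flagged
#'   missing.
#' @export
whiteness_report <- function(signals,
                             cols = c("opticf_i", "pupils_i", "fr_i", "synch_i"),
                             max_lag = 10L, min_trials = 30L) {
  stopifnot(all(cols %in% names(signals)))
  sess <- unique(signals$session_id)
  n_used <- integer(0)
  per_sess <- list()
  for (sid in sess) {
    m <- as.matrix(signals[signals$session_id == sid, cols, drop = FALSE])
    n_fin <- max(colSums(is.finite(m)))
    if (n_fin < min_trials) next
    n_used <- c(n_used, n_fin)
    per_sess[[length(per_sess) + 1L]] <- lagged_corrs(m, max_lag)
  }
  if (!length(per_sess)) stop("no session has enough trials for the report")
  all_s <- do.call(rbind, per_sess)
  agg <- stats::aggregate(r ~ a + b + lag, data = all_s, na.action = stats::na.pass,
                          FUN = function(v) c(med = stats::median(v, na.rm = TRUE),
                                              mad = stats::mad(v, constant = 1,
                                                               na.rm = TRUE)))
  out <- data.frame(a = agg$a, b = agg$b, lag = agg$lag,
                    median = agg$r[, "med"], mad = agg$r[, "mad"])
  out$band <- 2 / sqrt(stats::median(n_used))
  out$inside <- !is.na(out$median) & abs(out$median) <= out$band
  out[order(out$a, out$b, out$lag), ]
}

lagged_corrs <- function(m, max_lag) {
  cols <- colnames(m)
  n <- nrow(m)
  res <- list()
  safe_cor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 10L) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(x, y)
  }
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    if (j < i) next
    lags <- if (i == j) seq_len(max_lag) else 0:max_lag
    for (l in lags) {
      x <- m[seq_len(n - l), i]; y <- m[seq_len(n - l) + l, j]
      res[[length(res) + 1L]] <- data.frame(a = cols[i], b = cols[j], lag = l,
                                            r = safe_cor(x, y))
    }
  }
  do.call(rbind, res)
}
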