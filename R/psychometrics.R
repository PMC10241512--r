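#' Fit a four-parameter logistic psychometric function
#'
#' Weighted maximum-likelihood fit of
#' `P(report high | x) = guess + (1 - guess - lapse) * plogis(slope * (x - location))`
#' to binary report-high responses, with box constraints `guess, lapse` in
#' `[0, 0.2]` and `slope >= 0`. For aggregate fits across sessions, each trial
#' is weighted by the proportion of trials its session contributes to the
#' dataset; within a single session unit weights are appropriate.
#'
#' @param x stimulus values (any monotone evidence scale; e.g. octaves
#'   relative to the 14 kHz category boundary).
#' @param response 0/1 report-high responses.
#' @param weights per-trial weights (default 1).
#' @param max_rate upper bound on the guess and lapse rates (default 0.2).
#' @return object of class `psych_fit`: `location` (bias/threshold), `slope`
#'   (core-logistic steepness), `lapse`, `guess`, `logLik`, `proportions`
#'   (weighted per-level response proportions), `converged`.
#' @export
fit_psychometric <- function(x, response, weights = NULL, max_rate = 0.2) {
  ok <- is.finite(x) & !is.na(response)
  x <- x[ok]; y <- as.numeric(response[ok])
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)[ok]
  if (length(unique(x)) < 2L) stop("need at least 2 distinct stimulus levels")
  if (!all(y %in% c(0, 1))) stop("responses must be binary (report high)")
  psy <- function(p, x) p[4] + (1 - p[4] - p[3]) * stats::plogis(p[2] * (x - p[1]))
  nll <- function(p) {
    mu <- pmin(pmax(psy(p, x), 1e-9), 1 - 1e-9)
    -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  # initial values from a plain weighted logistic regression
  g0 <- tryCatch(suppressWarnings(
    stats::glm.fit(cbind(1, x), y, weights = w,
                   family = stats::binomial())$coefficients),
    error = function(e) c(0, 1))
  sl0 <- max(abs(g0[2]), 0.1)
  loc0 <- if (abs(g0[2]) > 1e-6) -g0[1] / g0[2] else stats::median(x)
  loc0 <- min(max(loc0, min(x)), max(x))
  opt <- stats::optim(c(loc0, sl0, 0.02, 0.02), nll, method = "L-BFGS-B",
                      lower = c(min(x) - diff(range(x)), 0, 0, 0),
                      upper = c(max(x) + diff(range(x)), 200 / diff(range(x)),
                                max_rate, max_rate))
  props <- tapply(w * y, x, sum) / tapply(w, x, sum)
  structure(list(location = opt$par[1], slope = opt$par[2],
                 lapse = opt$par[3], guess = opt$par[4],
                 logLik = -opt$value,
                 proportions = data.frame(x = as.numeric(names(props)),
                                          p_high = as.numeric(props)),
                 n = length(x), converged = opt$convergence == 0),
            class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat("Psychometric fit (4-parameter logistic, weighted ML)\n")
  cat(sprintf("  location %.4g  slope %.4g  lapse %.3g  guess %.3g  (n = %d)\n",
              x$location, x$slope, x$lapse, x$guess, x$n))
  invisible(x)
}

#' @export
predict.psych_fit <- function(object, newdata, ...) {
  object$guess + (1 - object$guess - object$lapse) *
    stats::plogis(object$slope * (newdata - object$location))
}

#' @export
coef.psych_fit <- function(object, ...) {
  c(location = object$location, slope = object$slope,
    lapse = object$lapse, guess = object$guess)
}

#' Label trials by favorable/unfavorable baseline state
#'
#' Quadrant rule on the z-scored (firing rate, synchrony) innovations. After
#' an error, the favorable state is elevated *desynchronized* activity
#' (`fr > 0` and `synch < 0`) and the unfavorable state its mirror
#' (`fr < 0` and `synch > 0`). After a correct trial the favorable state is
#' elevated *synchronized* activity (both positive), unfavorable both
#' negative. Off-quadrant trials are labeled `neither`.
#'
#' @param fr_z,synch_z per-session z-scored innovations.
#' @param context `"after_error"` or `"after_correct"`.
#' @return character vector: `"favorable"`, `"unfavorable"`, or `"neither"`.
#' @export
favorable_split <- function(fr_z, synch_z,
                            context = c("after_error", "after_correct")) {
  context <- match.arg(context)
  lab <- rep("neither", length(fr_z))
  if (context == "after_error") {
    lab[fr_z > 0 & synch_z < 0] <- "favorable"
    lab[fr_z < 0 & synch_z > 0] <- "unfavorable"
  } else {
    lab[fr_z > 0 & synch_z > 0] <- "favorable"
    lab[fr_z < 0 & synch_z < 0] <- "unfavorable"
  }
  lab[!is.finite(fr_z) | !is.finite(synch_z)] <- "neither"
  lab
}

#' Permutation test for the psychometric slope difference by baseline state
#'
#' Test statistic: slope of the aggregate psychometric function on trials in a
#' favorable baseline state minus the slope on unfavorable-state trials, with
#' trials weighted by their session's share of the dataset. The null
#' distribution is built by shuffling the favorable/unfavorable labels within
#' each session separately (preserving per-session label counts), and the
#' one-sided p-value is the fraction of surrogates whose statistic is at least
#' as large as the observed one (direction fixed a priori: favorable >
#' unfavorable).
#'
#' @param x stimulus values (evidence scale) per trial.
#' @param response 0/1 report-high responses.
#' @param label output of [favorable_split()]; `neither` trials are ignored.
#' @param session session id per trial.
#' @param n_perm number of label permutations (default 500).
#' @param seed RNG seed for the permutations.
#' @return list: `statistic` (observed slope difference), `p_value`,
#'   `slope_favorable`, `slope_unfavorable`, `n_perm`, plus the per-group fits.
#' @export
slope_permutation_test <- function(x, response, label, session,
                                   n_perm = 500L, seed = 1L) {
  keep <- label %in% c("favorable", "unfavorable")
  x <- x[keep]; y <- response[keep]; lab <- label[keep]; ses <- session[keep]
  tab <- table(ses, lab)
  if (sum(rowSums(tab > 0) == 2) < 2L)
    stop("need both labels present in at least 2 sessions")
  w <- as.numeric(table(ses)[as.character(ses)]) / length(ses)
  slope_diff <- function(lb) {
    f1 <- fit_psychometric(x[lb == "favorable"], y[lb == "favorable"],
                           w[lb == "favorable"])
    f0 <- fit_psychometric(x[lb == "unfavorable"], y[lb == "unfavorable"],
                           w[lb == "unfavorable"])
    c(f1$slope - f0$slope, f1$slope, f0$slope)
  }
  obs <- slope_diff(lab)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  idx_by <- split(seq_along(ses), ses)
  stat_perm <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    lp <- lab
    for (ix in idx_by) lp[ix] <- sample(lab[ix])
    stopifnot(all(table(ses, lp) == tab)) # exchangeability within session
    stat_perm[r] <- slope_diff(lp)[1]
  }
  list(statistic = obs[1],
       p_value = mean(stat_perm >= obs[1]),
       slope_favorable = obs[2], slope_unfavorable = obs[3],
       n_perm = n_perm, null_stats = stat_perm)
}
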