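#' Fit a mixed model with per-session random intercept and slopes
#'
#' Fits a generalized linear mixed model in which every fixed-effect
#' predictor (plus the intercept) also receives a per-session random slope
#' with a *diagonal* random-effect covariance, the convention used throughout
#' this package for trial-based multi-session designs. Estimation maximizes a
#' Laplace-class approximate marginal likelihood: the random-effect modes are
#' found by penalized IRLS and the profiled deviance (including the
#' log-determinant of the conditional precision) is optimized over the
#' random-effect standard deviations.
#'
#' Continuous predictors are z-scored separately within each session before
#' fitting (idempotently, so pre-standardized inputs are unchanged). This
#' prevents session-by-session differences in the marginal statistics of the
#' predictors from contributing to the trial-by-trial associations the model
#' is meant to isolate.
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `correct ~ stim + trn + opticf_i + pupils_i + fr_i + synch_i`. All
#'   fixed-effect terms are automatically given per-session random slopes.
#' @param data a data frame containing the response, the predictors and the
#'   session identifier.
#' @param family `"binomial"` (logit link, 0/1 response) or `"gaussian"`.
#' @param session name of the session identifier column.
#' @param zscore z-score predictors within session (default `TRUE`).
#' @param weights optional prior weights (defaults to 1).
#' @param maxit,tol PIRLS iteration cap and relative deviance tolerance.
#' @param theta_init initial random-effect SD (relative to the residual SD for
#'   the gaussian family) used to start the outer optimizer.
#'
#' @return an object of class `state_glmm` with components `coefficients`
#'   (fixed effects; dropped degenerate columns appear as exact zeros),
#'   `theta` (random-effect SDs, one per design column), `sigma` (residual SD,
#'   gaussian only), `vcov` (approximate covariance of the fixed effects),
#'   `ranef` (per-session random-effect values), `converged`, `notes`
#'   (character log of dropped columns and fallbacks), and the internal
#'   design needed by [hierarchical_bootstrap()].
#'
#' @details With a single session in `data` the random-effect structure is
#'   unidentifiable and the function falls back to an ordinary GLM (recorded
#'   in `notes`). Model-matrix columns that are constant after within-session
#'   z-scoring are dropped from the design and reported with coefficient 0.
#'
#' @seealso [hierarchical_bootstrap()], [quantile_pvalue()]
#' @export
fit_glmm <- function(formula, data, family = c("binomial", "gaussian"),
                     session = "session_id", zscore = TRUE, weights = NULL,
                     maxit = 200L, tol = 1e-9, theta_init = 0.3) {
  family <- match.arg(family)
  if (!session %in% names(data))
    stop("session column '", session, "' not found in data")
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("predictors not found in data: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  df <- data[keep, , drop = FALSE]
  sess <- factor(df[[session]])
  ord <- order(as.integer(sess))
  df <- df[ord, , drop = FALSE]
  sess <- sess[ord]

  X <- stats::model.matrix(formula, df)
  y <- stats::model.response(stats::model.frame(formula, df))
  y <- as.numeric(y)
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a 0/1 response")
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)[keep][ord]

  notes <- character(0)
  icol <- which(colnames(X) == "(Intercept)")
  if (zscore) {
    for (j in setdiff(seq_len(ncol(X)), icol)) {
      X[, j] <- zscore_by(X[, j], sess)
    }
  }
  # drop columns degenerate everywhere (all-zero after z-scoring / constant)
  sds <- apply(X, 2, stats::sd)
  degen <- setdiff(which(sds == 0 | !is.finite(sds)), icol)
  dropped <- colnames(X)[degen]
  if (length(degen)) {
    notes <- c(notes, paste0("dropped constant predictor(s): ",
                             paste(dropped, collapse = ", ")))
    X <- X[, -degen, drop = FALSE]
  }

  out <- list(formula = formula, family = family, session = session,
              session_levels = levels(sess), notes = notes,
              dropped = dropped, n = nrow(X), call = match.call())

  if (nlevels(sess) < 2L) {
    # degenerate single-session data: ordinary GLM
    notes <- c(notes, "single session: fell back to an ordinary GLM")
    g <- stats::glm.fit(X, y, weights = w,
                        family = if (family == "binomial") stats::binomial() else stats::gaussian())
    beta <- g$coefficients
    out$coefficients <- pad_dropped(beta, dropped)
    out$theta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    out$sigma <- if (family == "gaussian")
      sqrt(sum(w * g$residuals^2 * g$weights / w) / g$df.residual) else 1
    qrX <- qr(X * sqrt(g$weights))
    out$vcov <- tryCatch(chol2inv(qr.R(qrX)) * out$sigma^2,
                         error = function(e) matrix(NA, ncol(X), ncol(X)))
    dimnames(out$vcov) <- list(colnames(X), colnames(X))
    out$converged <- g$converged %||% TRUE
    out$notes <- notes
    out$glm_fallback <- TRUE
    out$X <- X; out$Z <- X; out$y <- y; out$w <- w
    out$starts <- c(0L, nrow(X)); out$sess <- sess
    class(out) <- "state_glmm"
    return(out)
  }

  Z <- X # random slopes for every fixed effect, plus random intercept
  starts <- session_starts(sess)
  fam_code <- if (family == "binomial") 0L else 1L
  q <- ncol(Z)

  objective <- function(th) .glmm_profiled_dev(X, Z, y, w, starts, th,
                                               fam_code, maxit, tol)
  opt <- stats::optim(rep(theta_init, q), objective, method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-8))
  if (q == 1L) { # Nelder-Mead is unreliable in 1-D
    opt1 <- stats::optimize(function(t) objective(t), c(0, 10))
    if (opt1$objective < opt$value)
      opt <- list(par = opt1$minimum, value = opt1$objective, convergence = 0L)
  }
  theta <- abs(opt$par)
  sol <- .glmm_solve(X, Z, y, w, starts, theta, fam_code, maxit, tol,
                     rep(0, ncol(X)), matrix(0, q, nlevels(sess)))
  beta <- drop(sol$beta)
  names(beta) <- colnames(X)
  conv <- isTRUE(sol$converged) && opt$convergence %in% c(0L, 1L) &&
    all(is.finite(beta))
  if (!conv) notes <- c(notes, "fit did not fully converge; estimates are flagged")

  out$coefficients <- pad_dropped(beta, dropped)
  out$theta <- stats::setNames(theta * sol$sigma, colnames(Z))
  out$sigma <- sol$sigma
  out$vcov <- structure(sol$vcov_beta, dimnames = list(colnames(X), colnames(X)))
  out$ranef <- structure(t(sol$b * theta) * sol$sigma,
                         dimnames = list(levels(sess), colnames(Z)))
  out$deviance <- sol$deviance
  out$b_spherical <- sol$b
  out$converged <- conv
  out$notes <- notes
  out$glm_fallback <- FALSE
  out$opt <- list(convergence = opt$convergence, value = opt$value)
  out$X <- X; out$Z <- Z; out$y <- y; out$w <- w
  out$starts <- starts; out$sess <- sess
  out$theta_rel <- theta
  class(out) <- "state_glmm"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# first row (0-based) of each session plus terminal n, for the C++ core
session_starts <- function(sess) {
  n_by <- table(sess)
  as.integer(c(0L, cumsum(n_by)))
}

# z-score within groups; groups with zero variance map to 0
zscore_by <- function(x, g) {
  out <- stats::ave(x, g, FUN = function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  })
  out
}

pad_dropped <- function(beta, dropped) {
  if (!length(dropped)) return(beta)
  c(beta, stats::setNames(rep(0, length(dropped)), dropped))
}

#' @export
coef.state_glmm <- function(object, ...) object$coefficients

#' @export
vcov.state_glmm <- function(object, ...) object$vcov

#' @export
print.state_glmm <- function(x, ...) {
  cat("Mixed model (", x$family, ", per-session random intercept + slopes)\n",
      sep = "")
  cat("  sessions:", length(x$session_levels), " trials:", x$n, "\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  cat("Random-effect SDs:\n")
  print(round(x$theta, 4))
  if (x$family == "gaussian") cat("Residual SD:", round(x$sigma, 4), "\n")
  if (!x$converged) cat("** fit flagged as non-converged **\n")
  if (length(x$notes)) cat("Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.state_glmm <- function(object, ...) {
  est <- object$coefficients[colnames(object$X)]
  se <- sqrt(diag(object$vcov))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  res <- list(coefficients = tab, theta = object$theta, sigma = object$sigma,
              family = object$family, converged = object$converged,
              notes = object$notes, n = object$n,
              n_sessions = length(object$session_levels))
  class(res) <- "summary.state_glmm"
  res
}

#' @export
print.summary.state_glmm <- function(x, ...) {
  cat("Mixed model (", x$family, "), ", x$n_sessions, " sessions, ",
      x$n, " trials\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("Random-effect SDs:\n"); print(round(x$theta, 4))
  invisible(x)
}

#' @export
predict.state_glmm <- function(object, type = c("link", "response"),
                               re.form = NULL, ...) {
  type <- match.arg(type)
  eta <- drop(object$X %*% object$coefficients[colnames(object$X)])
  if (!is.null(object$ranef) && !identical(re.form, NA)) {
    idx <- as.integer(object$sess)
    eta <- eta + rowSums(object$Z * object$ranef[idx, , drop = FALSE])
  }
  if (type == "response" && object$family == "binomial") stats::plogis(eta) else eta
}

#' @export
fitted.state_glmm <- function(object, ...) predict(object, type = "response")

#' @export
residuals.state_glmm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$y - mu
  if (type == "pearson" && object$family == "binomial")
    r <- r / sqrt(pmax(mu * (1 - mu), 1e-12))
  r
}

#' Hierarchical bootstrap of a fitted mixed model
#'
#' Resamples trials with replacement *within each session* (the session set is
#' fixed, and the number of trials contributed by each session is preserved),
#' refits the model for every resample, removes aberrant resamples with a
#' robust rule ([filter_outlier_resamples()]), and summarizes the coefficient
#' distributions with median, interquartile range, 95% confidence intervals
#' and quantile p-values.
#'
#' Resampling with replacement within a session is equivalent to reweighting
#' the session's rows by multinomial counts; refits therefore reuse the
#' original design with new case weights and warm starts. By default the
#' random-effect SDs are held at their full-data estimates while the fixed
#' effects and random-effect modes are re-solved per resample
#' (`theta = "fixed"`); `theta = "refit"` re-optimizes the random-effect SDs
#' in every resample at a substantial computational cost.
#'
#' @param object a fitted [fit_glmm()] model.
#' @param n_resamples number of bootstrap resamples (default 5000).
#' @param seed integer seed controlling the resampling.
#' @param theta `"fixed"` or `"refit"` (see Details).
#' @param mad_mult multiplier of the per-coefficient MAD beyond which a
#'   resample is discarded as an outlier (default 7).
#' @param keep_draws store the resampled coefficient matrix (default `TRUE`).
#'
#' @return an object of class `state_glmm_boot` with a `summary` data frame
#'   (one row per coefficient: estimate, median, q25, q75, ci_lo, ci_hi,
#'   p_value, p_bound), the retained `draws` matrix, `n_resamples`,
#'   `n_outliers_removed` and `n_nonconverged`.
#' @export
hierarchical_bootstrap <- function(object, n_resamples = 5000L, seed = NULL,
                                   theta = c("fixed", "refit"), mad_mult = 7,
                                   keep_draws = TRUE) {
  stopifnot(inherits(object, "state_glmm"))
  theta <- match.arg(theta)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(object$X)
  starts <- object$starts
  S <- length(starts) - 1L
  fam_code <- if (object$family == "binomial") 0L else 1L
  # multinomial case weights per session, scaled by any prior weights
  Wmat <- matrix(0, n, n_resamples)
  for (s in seq_len(S)) {
    i0 <- starts[s] + 1L; i1 <- starts[s + 1L]
    ns <- i1 - i0 + 1L
    cnt <- stats::rmultinom(n_resamples, ns, rep(1 / ns, ns))
    Wmat[i0:i1, ] <- cnt * object$w[i0:i1]
  }
  p <- ncol(object$X)
  est <- object$coefficients[colnames(object$X)]
  if (object$glm_fallback || theta == "fixed") {
    th <- if (object$glm_fallback) rep(0, ncol(object$Z)) else object$theta_rel
    bstart <- if (!is.null(object$b_spherical)) object$b_spherical
    else matrix(0, ncol(object$Z), S)
    res <- .glmm_boot_fixed_theta(object$X, object$Z, object$y, Wmat,
                                  starts, th, fam_code, 200L, 1e-7,
                                  unname(est), bstart)
    draws <- res$draws
    conv <- unlist(res$converged)
  } else {
    draws <- matrix(NA_real_, n_resamples, p)
    conv <- logical(n_resamples)
    for (r in seq_len(n_resamples)) {
      fr <- tryCatch({
        obj <- function(t) .glmm_profiled_dev(object$X, object$Z, object$y,
                                              Wmat[, r], starts, t, fam_code,
                                              200L, 1e-8)
        opt <- stats::optim(object$theta_rel, obj, method = "Nelder-Mead",
                            control = list(maxit = 300L, reltol = 1e-6))
        sol <- .glmm_solve(object$X, object$Z, object$y, Wmat[, r], starts,
                           abs(opt$par), fam_code, 200L, 1e-8,
                           unname(est), matrix(0, ncol(object$Z), S))
        list(beta = drop(sol$beta), ok = isTRUE(sol$converged))
      }, error = function(e) list(beta = rep(NA_real_, p), ok = FALSE))
      draws[r, ] <- fr$beta
      conv[r] <- fr$ok && all(is.finite(fr$beta))
    }
  }
  colnames(draws) <- colnames(object$X)
  n_nonconv <- sum(!conv)
  draws <- draws[conv, , drop = FALSE]
  keep <- filter_outlier_resamples(draws, mad_mult = mad_mult)
  n_out <- sum(!keep)
  draws <- draws[keep, , drop = FALSE]

  med <- apply(draws, 2, stats::median)
  q25 <- apply(draws, 2, stats::quantile, 0.25)
  q75 <- apply(draws, 2, stats::quantile, 0.75)
  lo <- apply(draws, 2, stats::quantile, 0.025)
  hi <- apply(draws, 2, stats::quantile, 0.975)
  pv <- quantile_pvalue(draws, est)
  summ <- data.frame(term = colnames(draws), estimate = unname(est),
                     median = unname(med), q25 = unname(q25), q75 = unname(q75),
                     ci_lo = unname(lo), ci_hi = unname(hi),
                     p_value = unname(pv),
                     p_bound = ifelse(pv == 0, 2 / nrow(draws), NA_real_),
                     row.names = NULL)
  out <- list(fit = object, summary = summ,
              draws = if (keep_draws) draws else NULL,
              n_resamples = n_resamples, n_outliers_removed = n_out,
              n_nonconverged = n_nonconv, theta_mode = theta, seed = seed)
  class(out) <- "state_glmm_boot"
  out
}

#' @export
print.state_glmm_boot <- function(x, digits = 4, ...) {
  cat("Hierarchical bootstrap (", nrow(x$draws %||% x$summary), " retained of ",
      x$n_resamples, " resamples; ", x$n_outliers_removed, " outliers, ",
      x$n_nonconverged, " non-converged)\n", sep = "")
  s <- x$summary
  s$p_value <- ifelse(s$p_value == 0, paste0("<", signif(s$p_bound, 2)),
                      signif(s$p_value, 3))
  s$p_bound <- NULL
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' @export
coef.state_glmm_boot <- function(object, ...) {
  stats::setNames(object$summary$estimate, object$summary$term)
}

#' @export
summary.state_glmm_boot <- function(object, ...) object$summary

#' Robust filtering of bootstrap resamples
#'
#' Flags resamples whose distance from the per-coefficient median exceeds
#' `mad_mult` times the per-coefficient median absolute deviation (MAD, no
#' scale constant), in *any* coefficient. Coefficients with zero MAD impose
#' no removals.
#'
#' @param draws numeric matrix of resampled coefficients (resamples x terms).
#' @param mad_mult MAD multiplier (default 7).
#' @return logical vector: `TRUE` for resamples to keep.
#' @export
filter_outlier_resamples <- function(draws, mad_mult = 7) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) return(logical(0))
  keep <- rep(TRUE, nrow(draws))
  for (j in seq_len(ncol(draws))) {
    med <- stats::median(draws[, j])
    m <- stats::median(abs(draws[, j] - med))
    if (is.finite(m) && m > 0)
      keep <- keep & (abs(draws[, j] - med) <= mad_mult * m)
  }
  keep
}

#' Quantile p-values from bootstrap coefficient draws
#'
#' Two-sided p-value for the null hypothesis that a coefficient is zero:
#' twice the fraction of resampled coefficients whose sign opposes the point
#' estimate, clipped to at most 1. Draws exactly equal to zero are counted as
#' opposite-signed (conservative); a zero point estimate yields p = 1. An
#' all-same-sign distribution yields p = 0, to be reported as a bound
#' `< 2/n_draws`.
#'
#' @param draws matrix (resamples x terms) or vector of bootstrap draws.
#' @param estimate point estimate(s) from the original fit.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
quantile_pvalue <- function(draws, estimate) {
  draws <- as.matrix(draws)
  estimate <- rep_len(as.numeric(estimate), ncol(draws))
  vapply(seq_len(ncol(draws)), function(j) {
    e <- estimate[j]
    if (e == 0) return(1)
    opp <- if (e > 0) draws[, j] <= 0 else draws[, j] >= 0
    min(1, 2 * mean(opp))
  }, numeric(1))
}
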