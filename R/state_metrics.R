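#' Baseline firing rate from pooled spike times
#'
#' Average firing rate of the multi-unit activity in a window: total spike
#' count divided by (number of units x window length), i.e. the average over
#' time and over units, in spikes/s per unit.
#'
#' @param times spike times (s) of the pooled multi-unit activity, relative to
#'   stimulus onset.
#' @param n_units number of units pooled into the MUA (required).
#' @param window half-open analysis window `[a, b)` in seconds
#'   (default the 2-s pre-stimulus baseline `c(-2, 0)`).
#' @return firing rate in spikes/s per unit; 0 for empty input.
#' @export
compute_fr <- function(times, n_units, window = c(-2, 0)) {
  if (missing(n_units) || is.null(n_units) || is.na(n_units) || n_units <= 0)
    stop("n_units must be a known positive unit count")
  len <- diff(window)
  if (len <= 0) stop("window length must be positive")
  n <- sum(times >= window[1] & times < window[2])
  n / (n_units * len)
}

#' Shuffle-normalized population synchrony
#'
#' Synchrony of the pooled multi-unit activity in a baseline window: the
#' standard deviation across time bins of the binned population spike count,
#' divided by the mean of the same statistic over surrogates in which the same
#' number of spikes is placed independently and uniformly at random in the
#' window. The statistic is 1 in expectation for statistically uncorrelated
#' units with Poisson-like firing, above 1 for coordinated low-frequency
#' rate fluctuations.
#'
#' Uniform placement is realized by drawing bin indices uniformly (the
#' within-bin position of a spike never enters the statistic). Bins tile the
#' window from the left edge and are half-open (a spike on a boundary belongs
#' to the bin on its right).
#'
#' @param times pooled MUA spike times (s).
#' @param window half-open window `[a, b)`; must contain at least 10 bins.
#' @param bin bin width in seconds (default 0.02).
#' @param n_surrogates number of uniform-placement surrogates (default 100).
#' @return the synchrony value, or `NA_real_` when the window contains no
#'   spikes (never an imputed 0).
#' @export
compute_synch <- function(times, window = c(-2, 0), bin = 0.02,
                          n_surrogates = 100L) {
  nb <- bin_count(window, bin)
  idx <- bin_index(times, window, bin)
  nsp <- length(idx)
  if (nsp == 0L) return(NA_real_)
  counts <- tabulate(idx, nbins = nb)
  num <- stats::sd(counts)
  surr <- matrix(sample.int(nb, nsp * n_surrogates, replace = TRUE),
                 nrow = nsp)
  sds <- apply(surr, 2, function(ix) stats::sd(tabulate(ix, nbins = nb)))
  num / mean(sds)
}

#' Coefficient of variation of the binned population count
#'
#' SD/mean of the pooled MUA spike count across time bins; an older synchrony
#' measure that, unlike [compute_synch()], is negatively correlated with the
#' firing rate.
#'
#' @inheritParams compute_synch
#' @return the CV, or `NA_real_` when the mean binned count is zero.
#' @export
compute_cv <- function(times, window = c(-2, 0), bin = 0.02) {
  nb <- bin_count(window, bin)
  idx <- bin_index(times, window, bin)
  if (length(idx) == 0L) return(NA_real_)
  counts <- tabulate(idx, nbins = nb)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::sd(counts) / m
}

bin_count <- function(window, bin) {
  len <- diff(window)
  nb <- round(len / bin)
  if (nb < 10L || abs(nb * bin - len) > 1e-9)
    stop("window must divide into at least 10 whole bins")
  nb
}

bin_index <- function(times, window, bin) {
  t <- times[times >= window[1] & times < window[2]]
  pmin(floor((t - window[1]) / bin) + 1L, bin_count(window, bin))
}

#' Per-trial baseline state metrics
#'
#' Computes firing rate, shuffle-normalized synchrony and the coefficient of
#' variation for every trial of a spike-event table. The surrogate stream of
#' each trial is seeded deterministically from (master seed, session, trial),
#' so results are reproducible regardless of evaluation order.
#'
#' @param spikes data frame with columns `session_id`, `trial_number`,
#'   `unit_id`, `time_s` (s relative to stimulus onset).
#' @param trials trial table with `session_id` and `trial_number`; every trial
#'   listed here gets a row in the output even if it has no spikes.
#' @param n_units unit count per session: a single number, a named vector by
#'   session id, or `NULL` to use the number of distinct `unit_id`s observed
#'   in each session.
#' @param window,bin,n_surrogates as in [compute_synch()].
#' @param seed master seed for the surrogate streams.
#' @return data frame keyed by (`session_id`, `trial_number`) with columns
#'   `fr`, `synch`, `cv`, `n_spikes`, `n_units`. Zero-spike trials carry `NA`
#'   synchrony and CV (missing, never zero) and `fr = 0`.
#' @export
compute_state_metrics <- function(spikes, trials, n_units = NULL,
                                  window = c(-2, 0), bin = 0.02,
                                  n_surrogates = 100L, seed = 1L) {
  stopifnot(all(c("session_id", "trial_number", "time_s") %in% names(spikes)))
  if (is.null(n_units)) {
    n_units <- tapply(spikes$unit_id, spikes$session_id,
                      function(u) length(unique(u)))
  }
  sess_ids <- unique(trials$session_id)
  units_for <- function(sid) {
    u <- if (length(n_units) == 1L && is.null(names(n_units))) n_units
    else n_units[[as.character(sid)]]
    if (is.null(u) || is.na(u) || u <= 0)
      stop("unknown unit count for session ", sid)
    u
  }
  in_win <- spikes$time_s >= window[1] & spikes$time_s < window[2]
  key_sp <- paste(spikes$session_id[in_win], spikes$trial_number[in_win], sep = "\r")
  sp_by <- split(spikes$time_s[in_win], key_sp)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  len <- diff(window)
  out <- trials[, c("session_id", "trial_number")]
  nr <- nrow(out)
  fr <- synch <- cv <- numeric(nr); nsp <- integer(nr); nu <- integer(nr)
  sess_int <- as.integer(factor(out$session_id, levels = sess_ids))
  for (i in seq_len(nr)) {
    times <- sp_by[[paste(out$session_id[i], out$trial_number[i], sep = "\r")]]
    u <- units_for(out$session_id[i])
    nu[i] <- u
    if (is.null(times)) {
      fr[i] <- 0; synch[i] <- NA_real_; cv[i] <- NA_real_; nsp[i] <- 0L
      next
    }
    nsp[i] <- length(times)
    fr[i] <- nsp[i] / (u * len)
    set.seed(derive_seed(seed, sess_int[i], out$trial_number[i]))
    synch[i] <- compute_synch(times, window, bin, n_surrogates)
    cv[i] <- compute_cv(times, window, bin)
  }
  out$fr <- fr; out$synch <- synch; out$cv <- cv
  out$n_spikes <- nsp; out$n_units <- nu
  out
}

#' Rate-normalized multitaper spectrum of a spike train
#'
#' Multitaper power-spectral estimate of a point process represented on a
#' 30 kHz sample grid, using 2TW-1 discrete prolate spheroidal (DPSS) tapers,
#' normalized by its own mean power above a high-frequency cutoff. Because the
#' high-frequency limit of a point-process spectrum is the firing rate, this
#' normalization makes spectra comparable across baselines of different rate:
#' an uncorrelated Poisson train is flat at 1, and coordinated low-frequency
#' rate fluctuations appear as normalized power above 1 at low frequencies.
#'
#' @param times pooled spike times (s) in the window.
#' @param window half-open analysis window `[a, b)`.
#' @param tw time-bandwidth parameter (10 for single baselines, 5 when
#'   averaging across trials); the number of tapers is `2*tw - 1`.
#' @param fs sample grid rate in Hz (default 30000, the recording resolution).
#' @param cutoff high-frequency normalization cutoff in Hz (default 10000).
#' @return object of class `mt_spectrum`: list with `freq` (Hz, up to
#'   Nyquist), `power` (normalized, unit mean above `cutoff`), `tw`,
#'   `n_tapers`, `n_spikes`.
#' @export
multitaper_spectrum <- function(times, window = c(-2, 0), tw = 10,
                                fs = 30000, cutoff = 10000) {
  if (tw < 1) stop("tw must be at least 1")
  len <- diff(window)
  if (len <= 0) stop("window length must be positive")
  N <- round(len * fs)
  if (N < 4 * tw) stop("window too short for the requested time-bandwidth")
  k <- 2 * tw - 1
  t <- times[times >= window[1] & times < window[2]]
  x <- tabulate(pmin(floor((t - window[1]) * fs) + 1L, N), nbins = N)
  xc <- x - mean(x)
  H <- dpss_tapers(N, tw, k)
  nf <- floor(N / 2) + 1L
  P <- numeric(nf)
  for (j in seq_len(k)) {
    J <- stats::fft(H[, j] * xc)[seq_len(nf)]
    P <- P + (Re(J)^2 + Im(J)^2)
  }
  P <- P / k
  freq <- (seq_len(nf) - 1) / len
  hi <- freq > cutoff
  if (!any(hi)) stop("cutoff at or above the Nyquist frequency")
  P <- P / mean(P[hi])
  structure(list(freq = freq, power = P, tw = tw, n_tapers = k,
                 n_spikes = length(t)),
            class = "mt_spectrum")
}

#' @export
print.mt_spectrum <- function(x, ...) {
  cat("Multitaper point-process spectrum: TW =", x$tw, ",", x$n_tapers,
      "tapers,", x$n_spikes, "spikes\n")
  cat("  freq range:", x$freq[1], "-", max(x$freq), "Hz;",
      "normalized power (unit mean above cutoff)\n")
  invisible(x)
}

#' Average normalized power in a frequency band
#'
#' @param spec an `mt_spectrum` (or a list of them, which are averaged).
#' @param band numeric length-2 band in Hz.
#' @return mean normalized power in the band.
#' @export
band_power <- function(spec, band) {
  if (inherits(spec, "mt_spectrum")) spec <- list(spec)
  f <- spec[[1]]$freq
  sel <- f >= band[1] & f <= band[2]
  mean(rowMeans(vapply(spec, function(s) s$power, numeric(length(f))))[sel])
}

# DPSS tapers by the classical symmetric tridiagonal eigenproblem, computed
# on a reduced grid (dense eigen at n_base points) and spline-interpolated to
# the target length; each taper is renormalized to unit energy. Cached.
dpss_tapers <- function(n, nw, k, n_base = 1024L) {
  key <- sprintf("dpss_%d_%s_%d_%d", n, format(nw), k, n_base)
  hit <- .cortexstate_cache[[key]]
  if (!is.null(hit)) return(hit)
  nb <- min(n, n_base)
  W <- nw / nb
  tt <- 0:(nb - 1)
  d <- ((nb - 1 - 2 * tt) / 2)^2 * cos(2 * pi * W)
  e <- tt[-1] * (nb - tt[-1]) / 2
  M <- matrix(0, nb, nb)
  diag(M) <- d
  M[cbind(1:(nb - 1), 2:nb)] <- e
  M[cbind(2:nb, 1:(nb - 1))] <- e
  es <- eigen(M, symmetric = TRUE)
  V <- es$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers have positive mean; antisymmetric ones
  # a positive initial slope
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) { if (s < 0) V[, j] <- -V[, j] }
    else if (V[2, j] - V[1, j] < 0) V[, j] <- -V[, j]
  }
  if (nb < n) {
    xb <- seq(0, 1, length.out = nb)
    xt <- seq(0, 1, length.out = n)
    V <- vapply(seq_len(k),
                function(j) stats::spline(xb, V[, j], xout = xt)$y,
                numeric(n))
  }
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  .cortexstate_cache[[key]] <- V
  V
}
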