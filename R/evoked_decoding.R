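#' Evoked spike counts per unit and trial
#'
#' Integer spike counts of every unit in the evoked window (default the first
#' 150 ms after stimulus onset), as a units x trials matrix. Trials listed in
#' `trial_numbers` but absent from the spike table get zero columns.
#'
#' @param spikes spike events for one session (`trial_number`, `unit_id`,
#'   `time_s`).
#' @param trial_numbers trials to include as columns (default: those present).
#' @param unit_ids units to include as rows (default: those present).
#' @param window evoked window `[a, b)` in seconds (default `c(0, 0.15)`).
#' @return integer matrix (units x trials) with dimnames.
#' @export
evoked_counts <- function(spikes, trial_numbers = NULL, unit_ids = NULL,
                          window = c(0, 0.15)) {
  sel <- spikes$time_s >= window[1] & spikes$time_s < window[2]
  sp <- spikes[sel, , drop = FALSE]
  if (is.null(trial_numbers)) trial_numbers <- sort(unique(spikes$trial_number))
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  m <- matrix(0L, length(unit_ids), length(trial_numbers),
              dimnames = list(unit = as.character(unit_ids),
                              trial = as.character(trial_numbers)))
  if (nrow(sp)) {
    tb <- table(factor(sp$unit_id, levels = unit_ids),
                factor(sp$trial_number, levels = trial_numbers))
    m[] <- as.integer(tb)
  }
  m
}

#' Condition-specific decoding axes by cross-validated ridge logistic regression
#'
#' For each level of `condition_labels` separately (e.g., a choice axis fit
#' separately within each stimulus category, so that choice decoding cannot
#' reflect stimulus tuning, and vice versa), fits L2-regularized logistic
#' regression with `folds`-fold cross-validation: for every fold, the decoder
#' is trained on the remaining data (penalty chosen by inner cross-validation
#' on the training portion) and the held-out trials receive their linear
#' decision value. Fold assignment is re-randomized `reps` times and each
#' trial's final projection is the median of its held-out decision values
#' across repetitions.
#'
#' @param counts units x trials count matrix (one session).
#' @param labels two-level factor (or 0/1) to decode, per trial.
#' @param condition_labels conditioning factor per trial; one axis per level.
#'   `NULL` fits a single unconditioned axis.
#' @param folds number of outer folds (default 10, i.e. 90/10 splits).
#' @param reps number of fold re-randomizations (default 1000; reduce for
#'   exploratory runs).
#' @param seed RNG seed.
#' @param lambda penalty grid passed to glmnet (default a logarithmic grid).
#' @param inner_folds folds of the inner cross-validation that selects the
#'   penalty on each training portion.
#' @param ... further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh` to trade accuracy for speed in large sweeps).
#' @return object of class `decoder_axes`: per level, the trained weight
#'   matrix summary and per-trial projections; plus `projection`, the merged
#'   per-trial projection across levels (`NA` for trials in degenerate
#'   levels), and `flagged`, levels with fewer than 2 classes.
#' @export
fit_axes <- function(counts, labels, condition_labels = NULL, folds = 10L,
                     reps = 1000L, seed = 1L,
                     lambda = 10^seq(2, -4, length.out = 30),
                     inner_folds = 5L, ...) {
  n <- ncol(counts)
  y <- as.integer(factor(labels)) - 1L
  if (is.null(condition_labels)) condition_labels <- rep("all", n)
  cond <- factor(condition_labels)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  projection <- rep(NA_real_, n)
  levels_out <- list(); flagged <- character(0)
  for (lv in levels(cond)) {
    idx <- which(cond == lv)
    yl <- y[idx]
    if (length(unique(yl)) < 2L || min(table(yl)) < folds) {
      flagged <- c(flagged, lv)
      levels_out[[lv]] <- list(status = "degenerate",
                               n = length(idx), classes = table(yl))
      next
    }
    Xl <- t(counts[, idx, drop = FALSE])
    set.seed(derive_seed(seed, match(lv, levels(cond))))
    proj_mat <- matrix(NA_real_, length(idx), reps)
    for (r in seq_len(reps)) {
      fold <- fold_assign(yl, folds)
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- fold == f
        cvfit <- glmnet::cv.glmnet(Xl[tr, , drop = FALSE], yl[tr],
                                   family = "binomial", alpha = 0,
                                   lambda = lambda, nfolds = inner_folds,
                                   standardize = TRUE, ...)
        proj_mat[te, r] <- as.numeric(
          stats::predict(cvfit, Xl[te, , drop = FALSE],
                         s = "lambda.min", type = "link"))
      }
    }
    pr <- apply(proj_mat, 1, stats::median)
    projection[idx] <- pr
    levels_out[[lv]] <- list(status = "ok", n = length(idx),
                             projections = pr, reps = reps, folds = folds,
                             proj_mat = proj_mat)
  }
  structure(list(levels = levels_out, projection = projection,
                 flagged = flagged, folds = folds, reps = reps,
                 lambda = lambda),
            class = "decoder_axes")
}

# stratified fold assignment: balanced class counts across folds
fold_assign <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    f[ix] <- rep_len(sample(folds), length(ix))
  }
  f
}

#' @export
print.decoder_axes <- function(x, ...) {
  cat("Decoding axes:", length(x$levels), "conditioning level(s),",
      x$folds, "folds x", x$reps, "repetitions\n")
  for (lv in names(x$levels)) {
    l <- x$levels[[lv]]
    cat("  ", lv, ": ", l$status, " (n = ", l$n, ")\n", sep = "")
  }
  if (length(x$flagged))
    cat("  flagged degenerate level(s):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve for held-out projections
#'
#' @param projection decision values.
#' @param labels true two-level labels.
#' @return AUROC in `[0, 1]`.
#' @export
projection_auroc <- function(projection, labels) {
  ok <- is.finite(projection)
  y <- as.integer(factor(labels[ok])) - 1L
  p <- projection[ok]
  r <- rank(p)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evoked-decoding workflow across sessions
#'
#' For every session: builds the evoked count matrix, fits stimulus-decoding
#' axes separately within each choice (so stimulus decoding cannot reflect
#' choice tuning), and merges the held-out projections. Returns a trial-level
#' table ready for [interaction_glmm()], with per-session z-scored projections
#' and baseline innovations.
#'
#' @param evoked_spikes evoked-window spike events (all sessions).
#' @param table analysis table from [build_analysis_table()] carrying
#'   innovation columns and conditioning information.
#' @param decode `"stimulus"` (axes conditioned on choice) or `"choice"`
#'   (axes conditioned on stimulus category).
#' @param folds,reps,seed,lambda,... passed to [fit_axes()].
#' @return data frame with `session_id`, `trial_number`, `label` (0/1),
#'   `projection`, `fr_i`, `synch_i`, `proj_x_fr`, `proj_x_synch`,
#'   `prev_valid`, `prev_correct`.
#' @export
evoked_projection_table <- function(evoked_spikes, table,
                                    decode = c("stimulus", "choice"),
                                    folds = 10L, reps = 1000L, seed = 1L,
                                    lambda = 10^seq(2, -4, length.out = 30),
                                    ...) {
  decode <- match.arg(decode)
  out <- list()
  for (sid in unique(table$session_id)) {
    tb <- table[table$session_id == sid & table$trial_class == "valid", ]
    sp <- evoked_spikes[evoked_spikes$session_id == sid, ]
    if (!nrow(tb) || !nrow(sp)) next
    cnt <- evoked_counts(sp, trial_numbers = tb$trial_number)
    if (decode == "stimulus") {
      lab <- as.integer(tb$stim_category == "high")
      cond <- tb$choice
    } else {
      lab <- as.integer(tb$choice == "high")
      cond <- tb$stim_category
    }
    ax <- fit_axes(cnt, lab, cond, folds = folds, reps = reps,
                   seed = derive_seed(seed, match(sid, unique(table$session_id))),
                   lambda = lambda, ...)
    out[[sid]] <- data.frame(session_id = sid, trial_number = tb$trial_number,
                             label = lab,
                             projection = zscore_session(ax$projection),
                             fr_i = tb$fr_iz, synch_i = tb$synch_iz,
                             prev_valid = tb$prev_valid,
                             prev_correct = tb$prev_correct)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$proj_x_fr <- res$projection * res$fr_i
  res$proj_x_synch <- res$projection * res$synch_i
  res
}

#' Does baseline state modulate evoked discriminability?
#'
#' Binomial mixed model predicting the decoded label (stimulus category or
#' choice) from the trial's decoding-axis projection, the baseline firing-rate
#' and synchrony innovations, and the projection x state interaction terms,
#' fitted separately after correct and after error trials (per-session random
#' intercept and slopes). A positive projection x fr interaction after errors
#' means the evoked representation separates the categories better when
#' baseline activity is elevated.
#'
#' @param data data frame with columns `session_id`, `label` (0/1),
#'   `projection`, `fr_i`, `synch_i`, `prev_correct` (0/1) and `prev_valid`.
#' @param contexts subset(s) to fit (default both).
#' @param n_resamples,seed,boot bootstrap settings.
#' @return named list of fits, one per context.
#' @export
interaction_glmm <- function(data, contexts = c("after_correct", "after_error"),
                             n_resamples = 5000L, seed = 1L, boot = TRUE) {
  out <- list()
  for (ctx in contexts) {
    sub <- if (ctx == "after_error")
      data[data$prev_valid & data$prev_correct == 0, ]
    else data[data$prev_valid & data$prev_correct == 1, ]
    sub <- sub[is.finite(sub$projection), ]
    if (nrow(sub) < 30L) { warning("context '", ctx, "' skipped"); next }
    if (!all(c("proj_x_fr", "proj_x_synch") %in% names(sub))) {
      # interactions are formed from the per-session z-scored main effects
      sub$proj_x_fr <- sub$projection * sub$fr_i
      sub$proj_x_synch <- sub$projection * sub$synch_i
    }
    fit <- fit_glmm(label ~ projection + fr_i + synch_i +
                      proj_x_fr + proj_x_synch,
                    sub, family = "binomial")
    out[[ctx]] <- if (boot)
      hierarchical_bootstrap(fit, n_resamples = n_resamples,
                             seed = derive_seed(seed, match(ctx, contexts)))
    else fit
  }
  out
}
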