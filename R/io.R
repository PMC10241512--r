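#' Write a dataset to plain-text files
#'
#' Writes the trial table, signal table and (if present) spike tables as
#' tab-separated text with headers, and the ground truth plus configuration as
#' JSON. Every file set carries a `manifest.json` with the configuration hash
#' and master seed, so downstream stages can refuse to mix provenances.
#'
#' @param dataset a [generate_dataset()] result or a list with compatible
#'   `trials` / `signals` / `spikes` elements.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(dataset$trials, "trials.tsv")
  wt(dataset$signals, "signals.tsv")
  if (!is.null(dataset$spikes)) wt(dataset$spikes, "spikes.tsv")
  if (!is.null(dataset$evoked_spikes)) wt(dataset$evoked_spikes, "evoked_spikes.tsv")
  cfg <- dataset$config
  manifest <- list(seed = if (!is.null(cfg)) cfg$seed else NA,
                   config_hash = if (!is.null(cfg)) config_hash(cfg) else NA,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(dataset$ground_truth)) {
    gt <- lapply(dataset$ground_truth, function(g)
      lapply(g, function(el) if (is.matrix(el)) as.data.frame(el) else el))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.matrix, TRUE)],
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

TRIAL_COLS <- c("session_id", "trial_number", "iti_s", "stim_freq_khz",
                "stim_category", "evidence", "choice", "trial_class",
                "correct", "rt_s", "free_reward_flag", "intervention_flag")

#' Read and validate a dataset directory
#'
#' Reads the tab-separated tables written by [write_dataset()] (or prepared
#' externally in the same schema), validating the schema and the core
#' invariants: required columns present, trial numbers strictly increasing
#' within session (gaps produce a warning, rows are kept), and stimulus
#' category consistent with the frequency relative to the 14 kHz boundary
#' (a contradiction is a hard error naming the offending rows). If the signal
#' table carries a raw pupil column (`pupil_raw`) instead of `pupils`, it is
#' normalized per session to percent above the mean of the lowest 2% of
#' values.
#'
#' @param dir dataset directory.
#' @param boundary_khz category boundary for the consistency check.
#' @return list with `trials`, `signals`, `spikes` (or `NULL`),
#'   `evoked_spikes` (or `NULL`), `manifest`.
#' @export
read_dataset <- function(dir, boundary_khz = 14) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  trials <- rd("trials.tsv")
  if (is.null(trials)) stop("missing trials.tsv in ", dir)
  miss <- setdiff(TRIAL_COLS, names(trials))
  if (length(miss))
    stop("trials.tsv schema mismatch; missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(sign(trials$evidence) !=
                 sign(trials$stim_freq_khz - boundary_khz) |
                 (trials$stim_category == "high") !=
                 (trials$stim_freq_khz > boundary_khz))
  if (length(bad))
    stop("stim_category/evidence contradict stim_freq_khz vs the ",
         boundary_khz, " kHz boundary at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  for (sid in unique(trials$session_id)) {
    tn <- trials$trial_number[trials$session_id == sid]
    if (any(diff(tn) <= 0))
      stop("trial_number not strictly increasing in session ", sid)
    if (any(diff(tn) > 1))
      warning("trial_number gaps in session ", sid, "; rows kept")
  }
  signals <- rd("signals.tsv")
  if (!is.null(signals) && "pupil_raw" %in% names(signals) &&
      !"pupils" %in% names(signals)) {
    signals$pupils <- stats::ave(signals$pupil_raw, signals$session_id,
                                 FUN = normalize_pupil)
  }
  list(trials = trials, signals = signals, spikes = rd("spikes.tsv"),
       evoked_spikes = rd("evoked_spikes.tsv"),
       manifest = tryCatch(jsonlite::read_json(file.path(dir, "manifest.json")),
                           error = function(e) NULL))
}

#' Normalize a raw pupil trace to percent above its session minimum
#'
#' Divides by the mean of the lowest 2% of values in the session and expresses
#' the result as percent increase (100 means a doubling relative to the
#' smallest pupil sizes).
#'
#' @param x raw per-trial pupil sizes for one session.
#' @return normalized pupil in percent above the session minimum level.
#' @export
normalize_pupil <- function(x) {
  base <- mean(x[x <= stats::quantile(x, 0.02, na.rm = TRUE)], na.rm = TRUE)
  100 * (x / base - 1)
}
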