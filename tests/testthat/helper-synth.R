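# shared fixtures, built in code and cached for the duration of the test run
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a small, fast dataset for structural tests
small_dataset <- function(seed = 101, ...) {
  memo(paste0("small_", seed, "_", length(list(...))),
       generate_dataset(synth_config(n_sessions = 4, trials_per_session = 120,
                                     seed = seed, ...)))
}

small_table <- function(seed = 101) {
  memo(paste0("smalltab_", seed), {
    ds <- small_dataset(seed)
    sig <- compute_innovations(ds$signals, ds$trials)
    tab <- build_analysis_table(ds$trials, sig, apply_inclusion = FALSE)
    attr(tab, "include_outcome") <- TRUE
    tab
  })
}

# homogeneous-Poisson pooled MUA spike times on [-2, 0)
poisson_baseline <- function(rate_total = 300, window = c(-2, 0)) {
  n <- stats::rpois(1, rate_total * diff(window))
  stats::runif(n, window[1], window[2])
}
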