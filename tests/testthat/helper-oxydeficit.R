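# Shared fixtures and independent oracles for the test suite.

# O(n^2) all-pairs Mann-Whitney concordance (independent AUROC oracle)
brute_force_auroc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  sp <- scores[y]; sn <- scores[!y]
  total <- 0
  for (si in sp) total <- total + sum(si > sn) + 0.5 * sum(si == sn)
  total / (length(sp) * length(sn))
}

# invert the Hill saturation curve by bisection (independent of the
# closed-form inversion in the package)
bisect_hill_inverse <- function(target_sat, p50, n, lo = 1e-6, hi = 5000) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hill_saturation(mid, p50, n) < target_sat) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# hand-built breath set, bypassing segmentation
make_breath_set <- function(et_po2, et_pco2 = rep(36, length(et_po2)),
                            period = 4, flagged = rep(FALSE, length(et_po2))) {
  n <- length(et_po2)
  start <- (seq_len(n) - 1) * period
  df <- data.frame(start = start, end = start + period,
                   expiratory_duration = 0.6 * period,
                   et_po2 = et_po2, et_pco2 = et_pco2,
                   flagged_artifact = flagged)
  class(df) <- c("breath_set", "data.frame")
  df
}

# a trace spec (for simulate_cohort_from_traces) that can never satisfy the
# trailing 45 s steady-state rule: unsettled until 1 s before the end
never_steady_spec <- function(seed, duration = 120) {
  list(plan = breath_plan(seed = seed), duration = duration,
       spo2 = 94, settle_time = duration - 1)
}

steady_spec <- function(seed, spo2 = 94, et_po2 = 105, et_pco2 = 36,
                        duration = 120) {
  list(plan = breath_plan(et_po2 = et_po2, et_pco2 = et_pco2, seed = seed),
       duration = duration, spo2 = spo2)
}
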