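# Breath-by-breath analysis of an expired-gas trace: segmentation into
# breaths by CO2 threshold crossing, end-tidal extraction, artifact
# flagging, trailing-45 s steady-state detection, and averaging of five
# consecutive steady-state breaths into alveolar tensions.

#' Segment a gas trace into breaths
#'
#' Expirations are identified on the CO2 channel by threshold crossing with
#' hysteresis: an expiration opens when CO2 rises through `onset` mmHg and
#' closes when it falls below `onset - hysteresis`. Each breath spans from
#' its expiration onset to the next onset (half-open intervals, seconds from
#' trace start). The end-tidal CO2 is the CO2 maximum over the final 30% of
#' the expiration and the end-tidal O2 is the O2 value at that same sample.
#'
#' Artifact flagging: a breath is flagged when its expiratory duration falls
#' outside `[0.5, 10]` s, or when its end-tidal CO2 deviates from the median
#' of a reference set of breaths by more than `max(3 SD, 2)` mmHg. The
#' reference set is the trailing (up to 8) unflagged breaths when at least 3
#' exist, otherwise all other breaths in the trace — so an early cough (as
#' in a breath-2 cough artifact) is still recognized against the rest of
#' the recording.
#'
#' @param trace A [gas_trace()].
#' @param onset CO2 onset threshold, mmHg.
#' @param hysteresis Hysteresis width, mmHg.
#' @return A data frame of class `breath_set`: one row per breath with
#'   columns `start`, `end`, `expiratory_duration` (seconds), `et_po2`,
#'   `et_pco2` (mmHg) and `flagged_artifact`. Zero rows (with a warning)
#'   when no CO2 crossings exist.
#' @export
segment_breaths <- function(trace, onset = 5, hysteresis = 1) {
  stopifnot(inherits(trace, "gas_trace"))
  pco2 <- trace$pco2; po2 <- trace$po2; t <- trace$time
  lo <- onset - hysteresis

  above <- pco2 >= onset
  below <- pco2 < lo
  # state machine: in_exp switches on at rising crossings of `onset`,
  # off when the signal drops below `onset - hysteresis`
  state <- logical(length(pco2))
  in_exp <- FALSE
  for (i in seq_along(pco2)) {
    if (!in_exp && above[i]) in_exp <- TRUE
    else if (in_exp && below[i]) in_exp <- FALSE
    state[i] <- in_exp
  }
  d <- diff(c(FALSE, state))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1  # last sample of each expiration

  if (!length(starts)) {
    warning("no CO2 threshold crossings found; returning empty breath set")
    return(.breath_set(data.frame(start = numeric(0), end = numeric(0),
                                  expiratory_duration = numeric(0),
                                  et_po2 = numeric(0), et_pco2 = numeric(0),
                                  flagged_artifact = logical(0))))
  }
  # an expiration still open at trace end closes there (the recording
  # simply stopped mid-plateau)
  if (length(ends) < length(starts)) ends <- c(ends, length(t))

  n <- length(starts)
  breath_end <- c(t[starts[-1]], t[length(t)] + 1 / trace$sample_rate)
  exp_dur <- (ends - starts + 1) / trace$sample_rate
  et_pco2 <- numeric(n); et_po2 <- numeric(n)
  for (k in seq_len(n)) {
    i0 <- starts[k]; i1 <- ends[k]
    tail_from <- i0 + floor(0.7 * (i1 - i0))
    seg <- tail_from:i1
    j <- seg[which.max(pco2[seg])]
    et_pco2[k] <- pco2[j]
    et_po2[k] <- po2[j]
  }

  flagged <- exp_dur < 0.5 | exp_dur > 10
  # end-tidal CO2 outlier rule
  for (k in seq_len(n)) {
    if (flagged[k]) next
    prev <- which(!flagged[seq_len(k - 1)])
    prev <- utils::tail(prev, 8)
    ref <- if (length(prev) >= 3) et_pco2[prev] else et_pco2[-k]
    if (length(ref) >= 2) {
      tol <- max(3 * stats::sd(ref), 2)
      if (abs(et_pco2[k] - stats::median(ref)) > tol) flagged[k] <- TRUE
    }
  }

  .breath_set(data.frame(start = t[starts], end = breath_end,
                         expiratory_duration = exp_dur,
                         et_po2 = et_po2, et_pco2 = et_pco2,
                         flagged_artifact = flagged))
}

.breath_set <- function(df) {
  class(df) <- c("breath_set", "data.frame")
  df
}

#' Detect the end-tidal CO2 steady state
#'
#' Implements the operational steady-state rule: absence of variation in the
#' end-tidal CO2 signal over the preceding 45 s. Scanning breath end-times in
#' order, the earliest window is returned whose trailing 45 s (i) contains at
#' least `min_breaths` breaths, (ii) contains no artifact-flagged breath, and
#' (iii) has end-tidal CO2 range (max - min) at most `tolerance` mmHg. The
#' device never states a numeric tolerance; 2 mmHg is the package default.
#'
#' @param breaths A `breath_set` from [segment_breaths()], time-ordered.
#' @param tolerance Maximum allowed etCO2 range over the window, mmHg.
#' @param window Window length, seconds.
#' @param min_breaths Minimum breaths required in the window.
#' @return A list of class `steady_state_window` with elements
#'   `breath_indices`, `window_start`, `window_end`, `etco2_variation`,
#'   or `NULL` when no window qualifies (a valid result, not an error).
#' @export
detect_steady_state <- function(breaths, tolerance = 2, window = 45,
                                min_breaths = 5) {
  stopifnot(is.data.frame(breaths))
  n <- nrow(breaths)
  if (n == 0) return(NULL)
  for (i in seq_len(n)) {
    w_end <- breaths$end[i]
    w_start <- w_end - window
    if (w_start < min(breaths$start)) next  # not 45 s of history yet
    inside <- which(breaths$end > w_start & breaths$end <= w_end)
    if (any(breaths$flagged_artifact[inside])) next
    # breaths must actually cover the window (no leading gap)
    if (breaths$start[inside[1]] > w_start) next
    if (length(inside) < min_breaths) next
    rng <- range(breaths$et_pco2[inside])
    variation <- rng[2] - rng[1]
    if (variation <= tolerance) {
      return(structure(list(breath_indices = inside,
                            window_start = w_start,
                            window_end = w_end,
                            etco2_variation = variation),
                       class = "steady_state_window"))
    }
  }
  NULL
}

#' Summarize a steady-state measurement
#'
#' Averages the end-tidal values of the five most recent unflagged breaths
#' in the steady-state window into alveolar tensions (PAO2 from etO2, PACO2
#' from etCO2), then delegates to the physiology layer for gPaO2, OD and
#' ODFlip. The respiratory rate is derived from the median breath period in
#' the window and the respiratory quotient as `PACO2 / (PiO2 - PAO2)`.
#'
#' @param breaths A `breath_set` from [segment_breaths()].
#' @param window A `steady_state_window` from [detect_steady_state()].
#' @param spo2 Concurrent oximetry reading, percent.
#' @param config An [oxygen_curve_config()].
#' @param inspired_po2 Inspired O2 tension, mmHg.
#' @param barometric_pressure Barometric pressure, mmHg.
#' @param n_breaths Number of consecutive steady-state breaths to average.
#' @return A list of class `gas_exchange_summary` with elements `pao2`,
#'   `paco2`, `spo2`, `gpao2`, `od`, `odflip`, `respiratory_rate`, `rq`,
#'   `inspired_po2`, `barometric_pressure`.
#' @export
summarize_gas_exchange <- function(breaths, window, spo2,
                                   config = oxygen_curve_config(),
                                   inspired_po2 = 149,
                                   barometric_pressure = 760,
                                   n_breaths = 5) {
  if (is.null(window) || !inherits(window, "steady_state_window")) {
    stop("no usable measurement: steady state not achieved")
  }
  idx <- window$breath_indices
  idx <- idx[!breaths$flagged_artifact[idx]]
  if (length(idx) < n_breaths) {
    stop(sprintf("no usable measurement: fewer than %d unflagged steady-state breaths",
                 n_breaths))
  }
  use <- utils::tail(idx, n_breaths)  # the most recent qualifying breaths
  pao2 <- mean(breaths$et_po2[use])
  paco2 <- mean(breaths$et_pco2[use])
  periods <- diff(breaths$start[idx])
  rr <- 60 / stats::median(periods)
  gpao2 <- gpao2_from_spo2(spo2, paco2, config)
  od <- oxygen_deficit(pao2, gpao2)
  structure(
    list(pao2 = pao2, paco2 = paco2, spo2 = spo2, gpao2 = gpao2,
         od = od, odflip = odflip(od), respiratory_rate = rr,
         rq = paco2 / (inspired_po2 - pao2),
         inspired_po2 = inspired_po2,
         barometric_pressure = barometric_pressure),
    class = "gas_exchange_summary"
  )
}

#' @export
print.gas_exchange_summary <- function(x, ...) {
  cat(sprintf(paste0("<gas_exchange_summary>\n",
                     "  PAO2 %.1f mmHg  PACO2 %.1f mmHg  SpO2 %.1f%%\n",
                     "  gPaO2 %.1f mmHg  OD %.1f mmHg (ODFlip %.1f)\n",
                     "  RR %.1f /min  RQ %.2f\n"),
              x$pao2, x$paco2, x$spo2, x$gpao2, x$od, x$odflip,
              x$respiratory_rate, x$rq))
  invisible(x)
}

#' Analyze a gas trace end to end
#'
#' Convenience wrapper: segment, detect steady state, summarize. Errors with
#' "steady state not achieved" when no qualifying window exists.
#'
#' @param trace A [gas_trace()].
#' @param tolerance Steady-state etCO2 tolerance, mmHg.
#' @param config An [oxygen_curve_config()].
#' @return A `gas_exchange_summary`.
#' @export
analyze_trace <- function(trace, tolerance = 2,
                          config = oxygen_curve_config()) {
  breaths <- segment_breaths(trace)
  win <- detect_steady_state(breaths, tolerance = tolerance)
  if (is.null(win)) stop("steady state not achieved")
  summarize_gas_exchange(breaths, win, spo2 = trace$spo2, config = config,
                         inspired_po2 = trace$inspired_po2,
                         barometric_pressure = trace$barometric_pressure)
}
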