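# Synthetic 100 Hz expired-gas traces with planted ground truth.
#
# The generator emulates what a mainstream gas monitor records during quiet
# tidal breathing: inspiration holds the channels at inspired values, each
# expiration rises (CO2) / falls (O2) toward an end-tidal plateau, and the
# trace ends each expiration exactly on the planted end-tidal value so the
# downstream breath engine can be checked against known truth.

TRACE_SAMPLE_RATE <- 100  # Hz, fixed device rate

#' Plan for a synthetic breathing trace
#'
#' Describes the planted ground truth of a synthetic expired-gas recording:
#' breathing pattern, end-tidal plateau targets, noise, drift, and artifacts.
#'
#' @param respiratory_rate Breaths per minute (> 0).
#' @param inspiratory_fraction Fraction of each breath period spent in
#'   inspiration, in (0, 1).
#' @param et_po2,et_pco2 Planted end-tidal O2 / CO2 plateau values, mmHg.
#' @param inspired_po2,inspired_pco2 Inspired gas tensions, mmHg. Room air
#'   defaults: PiO2 about 149 (0.2093 x (760 - 47)), PiCO2 0.
#' @param plateau_noise_sd Per-breath Gaussian noise on the plateau targets,
#'   mmHg.
#' @param drift_per_min Linear drift added to both plateau targets
#'   (CO2 up, O2 down), mmHg per minute.
#' @param cough_times Times (s) at which a 0.3 s high-frequency +/-15 mmHg
#'   excursion is injected into both channels, truncating the plateau.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#'
#' @return An object of class `breath_plan`.
#' @export
breath_plan <- function(respiratory_rate = 15,
                        inspiratory_fraction = 0.4,
                        et_po2 = 105,
                        et_pco2 = 36,
                        inspired_po2 = 149,
                        inspired_pco2 = 0,
                        plateau_noise_sd = 0,
                        drift_per_min = 0,
                        cough_times = numeric(0),
                        seed = 1L) {
  stopifnot(respiratory_rate > 0,
            inspiratory_fraction > 0, inspiratory_fraction < 1,
            et_pco2 > inspired_pco2, et_po2 < inspired_po2,
            plateau_noise_sd >= 0)
  structure(
    list(respiratory_rate = respiratory_rate,
         inspiratory_fraction = inspiratory_fraction,
         et_po2 = et_po2, et_pco2 = et_pco2,
         inspired_po2 = inspired_po2, inspired_pco2 = inspired_pco2,
         plateau_noise_sd = plateau_noise_sd,
         drift_per_min = drift_per_min,
         cough_times = as.numeric(cough_times),
         seed = as.integer(seed)),
    class = "breath_plan"
  )
}

#' Construct a gas trace object
#'
#' Container for a uniformly sampled dual-channel expired-gas recording plus
#' the single concurrent oximetry reading the device pairs with it.
#'
#' @param po2,pco2 Sampled expired O2 / CO2, mmHg (equal length).
#' @param spo2 Concurrent pulse-oximetry saturation, percent, in `[50, 100]`.
#' @param barometric_pressure Barometric pressure, mmHg.
#' @param inspired_po2,inspired_pco2 Inspired tensions carried as metadata.
#' @param sample_rate Samples per second; must be 100.
#' @param start_time Time of the first sample, seconds.
#' @param meta Free-form metadata list (ground truth, provenance).
#'
#' @return An object of class `gas_trace`.
#' @export
gas_trace <- function(po2, pco2, spo2,
                      barometric_pressure = 760,
                      inspired_po2 = 149, inspired_pco2 = 0,
                      sample_rate = TRACE_SAMPLE_RATE,
                      start_time = 0, meta = list()) {
  if (sample_rate != TRACE_SAMPLE_RATE) {
    stop(sprintf("sample_rate must be %d Hz", TRACE_SAMPLE_RATE))
  }
  if (length(po2) != length(pco2)) stop("po2 and pco2 must have equal length")
  if (any(!is.finite(po2)) || any(!is.finite(pco2)) ||
      any(po2 < 0) || any(pco2 < 0)) {
    stop("all pressures must be finite and >= 0")
  }
  if (!is.finite(spo2) || spo2 < 50 || spo2 > 100) {
    stop("spo2 must be in [50, 100]")
  }
  structure(
    list(sample_rate = sample_rate,
         time = start_time + (seq_along(po2) - 1) / sample_rate,
         po2 = as.numeric(po2), pco2 = as.numeric(pco2),
         spo2 = spo2, barometric_pressure = barometric_pressure,
         inspired_po2 = inspired_po2, inspired_pco2 = inspired_pco2,
         start_time = start_time, meta = meta),
    class = "gas_trace"
  )
}

#' @export
print.gas_trace <- function(x, ...) {
  cat(sprintf("<gas_trace> %d samples @ %d Hz (%.1f s), SpO2 %.1f%%, Pbar %.0f mmHg\n",
              length(x$po2), x$sample_rate, length(x$po2) / x$sample_rate,
              x$spo2, x$barometric_pressure))
  invisible(x)
}

# Per-breath plateau targets for breath k ending its expiration at time t:
# planted value + seeded noise + linear drift + any wander offset.
.breath_targets <- function(plan, k, t_end, noise_co2, noise_o2, offset) {
  drift <- plan$drift_per_min * t_end / 60
  list(pco2 = plan$et_pco2 + noise_co2 + drift + offset,
       po2  = plan$et_po2  + noise_o2  - drift - offset)
}

# Core sampler shared by the steady and unsteady generators.
# offset_fn(k, breath_start_time) returns an etCO2 wander offset for breath k
# (applied with opposite sign to etO2).
.synthesize <- function(plan, duration, spo2, barometric_pressure,
                        offset_fn = function(k, t) 0, meta = list()) {
  period <- 60 / plan$respiratory_rate
  if (duration < period) {
    stop("duration shorter than one breath period: trace unbuildable")
  }
  if (length(plan$cough_times) && any(plan$cough_times < 0 | plan$cough_times > duration)) {
    stop("all cough_times must lie within the trace duration")
  }
  n <- round(duration * TRACE_SAMPLE_RATE)
  t <- (seq_len(n) - 1) / TRACE_SAMPLE_RATE
  po2 <- rep(plan$inspired_po2, n)
  pco2 <- rep(plan$inspired_pco2, n)

  n_breaths <- ceiling(duration / period)
  set.seed(plan$seed)
  noise_co2 <- if (plan$plateau_noise_sd > 0) stats::rnorm(n_breaths, 0, plan$plateau_noise_sd) else numeric(n_breaths)
  noise_o2  <- if (plan$plateau_noise_sd > 0) stats::rnorm(n_breaths, 0, plan$plateau_noise_sd) else numeric(n_breaths)

  insp_dur <- plan$inspiratory_fraction * period
  for (k in seq_len(n_breaths)) {
    b_start <- (k - 1) * period
    e_start <- b_start + insp_dur
    e_end <- min(b_start + period, duration)
    idx <- which(t >= e_start & t < e_end)
    if (!length(idx)) next
    te <- t[idx] - e_start
    tau <- 0.2 * (period - insp_dur)
    # normalized exponential approach: the last expiration sample lands
    # exactly on the plateau target (planted ground truth is recoverable
    # to machine precision)
    frac <- (1 - exp(-te / tau)) / (1 - exp(-max(te) / tau))
    tgt <- .breath_targets(plan, k, e_end, noise_co2[k], noise_o2[k],
                           offset_fn(k, b_start))
    pco2[idx] <- plan$inspired_pco2 + (tgt$pco2 - plan$inspired_pco2) * frac
    po2[idx] <- plan$inspired_po2 + (tgt$po2 - plan$inspired_po2) * frac
  }

  # coughs: 0.3 s of 10 Hz +/-15 mmHg oscillation in both channels
  for (tc in plan$cough_times) {
    idx <- which(t >= tc & t < tc + 0.3)
    if (!length(idx)) next
    exc <- 15 * sin(2 * pi * 10 * (t[idx] - tc))
    pco2[idx] <- pco2[idx] + exc
    po2[idx] <- po2[idx] + exc
  }
  pco2 <- pmax(pco2, 0)
  po2 <- pmax(po2, 0)

  gas_trace(po2, pco2, spo2 = spo2,
            barometric_pressure = barometric_pressure,
            inspired_po2 = plan$inspired_po2,
            inspired_pco2 = plan$inspired_pco2,
            meta = c(list(plan = plan, duration = duration), meta))
}

#' Synthesize a steady tidal-breathing trace
#'
#' Generates a 100 Hz dual-channel trace alternating inspiratory segments at
#' the inspired tensions with expiratory segments that approach the planted
#' end-tidal plateaus (normalized exponential shape, time constant 20% of
#' expiratory time). Coughs, per-breath plateau noise and linear drift are
#' applied per the plan. Deterministic given `plan$seed`.
#'
#' @param plan A [breath_plan()].
#' @param duration Trace length, seconds (at least one breath period).
#' @param spo2 Concurrent oximetry reading, percent.
#' @param barometric_pressure Barometric pressure, mmHg.
#' @return A [gas_trace()].
#' @export
#' @examples
#' tr <- synthesize_trace(breath_plan(respiratory_rate = 15), duration = 60)
synthesize_trace <- function(plan, duration, spo2 = 97,
                             barometric_pressure = 760) {
  .synthesize(plan, duration, spo2, barometric_pressure)
}

#' Synthesize a trace that settles into steady state
#'
#' Before `settle_time` the end-tidal CO2 targets wander breath-to-breath by
#' `wander_amplitude` mmHg (alternating sign, so any 45 s window touching the
#' unsettled phase exceeds a 2 mmHg tolerance); afterwards the plateaus hold
#' the planted values. A breath is "unsettled" if it starts before
#' `settle_time`. The planted settle time is recorded in
#' `trace$meta$settle_time`.
#'
#' @inheritParams synthesize_trace
#' @param settle_time Time (s) after which plateaus are stable; must be less
#'   than `duration`. Use `settle_time = duration - epsilon` for a trace that
#'   never satisfies a trailing 45 s steady-state rule.
#' @param wander_amplitude Pre-settle end-tidal CO2 excursion, mmHg.
#' @return A [gas_trace()] with ground-truth `settle_time` in `meta`.
#' @export
synthesize_unsteady_then_steady <- function(plan, settle_time, duration,
                                            spo2 = 97,
                                            barometric_pressure = 760,
                                            wander_amplitude = 6) {
  if (!is.finite(settle_time) || settle_time >= duration) {
    stop("settle_time must be finite and < duration")
  }
  offset_fn <- function(k, t_start) {
    if (t_start < settle_time) wander_amplitude * (-1)^k else 0
  }
  .synthesize(plan, duration, spo2, barometric_pressure,
              offset_fn = offset_fn,
              meta = list(settle_time = settle_time,
                          wander_amplitude = wander_amplitude))
}
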