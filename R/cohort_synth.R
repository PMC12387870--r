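# Synthetic patient cohorts: correlated (ODFlip, SpO2) draws with a
# Bernoulli outcome generated from a planted logistic model, plus an
# end-to-end variant that pushes every participant through the full
# trace -> breath engine -> physiology pipeline.

#' Plan for a synthetic cohort
#'
#' Describes the generative model of a cohort: a correlated bivariate
#' Gaussian for (ODFlip, SpO2) — SpO2 truncated by rejection to the
#' eligibility band — and a logistic outcome model with planted
#' coefficients. Defaults plant the combined-cohort multivariable
#' coefficients (ODFlip -0.153 per mmHg, SpO2 -0.315 per %, intercept
#' 38.436) over an ODFlip distribution of mean 65 / SD 15 mmHg (oxygen
#' deficit mean 35 / SD 15) and SpO2 mean 94 / SD 2%, correlated +0.6.
#'
#' @param n Number of participants.
#' @param intercept Logistic intercept, logit units.
#' @param beta_odflip Logistic coefficient on ODFlip, per mmHg.
#' @param beta_spo2 Logistic coefficient on SpO2, per percent.
#' @param odflip_mean,odflip_sd ODFlip marginal, mmHg.
#' @param spo2_mean,spo2_sd SpO2 marginal, percent.
#' @param correlation Correlation between ODFlip and SpO2, in `[-1, 1]`.
#' @param spo2_range Eligibility band for SpO2, percent; draws outside are
#'   rejected and redrawn (jointly, preserving the conditional structure).
#' @param covid_label_fraction Fraction of rows labelled COVID-positive.
#' @param seed Integer seed.
#' @return An object of class `cohort_plan`.
#' @export
cohort_plan <- function(n = 72,
                        intercept = 38.436,
                        beta_odflip = -0.153,
                        beta_spo2 = -0.315,
                        odflip_mean = 65, odflip_sd = 15,
                        spo2_mean = 94, spo2_sd = 2,
                        correlation = 0.6,
                        spo2_range = c(88, 97),
                        covid_label_fraction = 30 / 72,
                        seed = 1L) {
  stopifnot(n >= 1, odflip_sd > 0, spo2_sd > 0,
            correlation >= -1, correlation <= 1,
            covid_label_fraction >= 0, covid_label_fraction <= 1)
  structure(
    list(n = as.integer(n), intercept = intercept,
         beta_odflip = beta_odflip, beta_spo2 = beta_spo2,
         odflip_mean = odflip_mean, odflip_sd = odflip_sd,
         spo2_mean = spo2_mean, spo2_sd = spo2_sd,
         correlation = correlation, spo2_range = spo2_range,
         covid_label_fraction = covid_label_fraction,
         seed = as.integer(seed)),
    class = "cohort_plan"
  )
}

#' Simulate a patient cohort
#'
#' Draws (ODFlip, SpO2) from the plan's correlated Gaussian (Cholesky
#' construction), rejects rows with SpO2 outside the eligibility band, and
#' generates the binary supplemental-oxygen outcome from the planted
#' logistic model `logit(p) = intercept + beta_odflip * odflip +
#' beta_spo2 * spo2`. Deterministic given `plan$seed`.
#'
#' @param plan A [cohort_plan()].
#' @return A data frame (class `cohort_table`): columns `id`, `od`,
#'   `odflip`, `spo2`, `needs_supplemental_o2`, `covid_status`,
#'   `cohort_label` (`"positive"` / `"negative"`). Row-wise
#'   `odflip == 100 - od` by construction.
#' @export
simulate_cohort <- function(plan) {
  stopifnot(inherits(plan, "cohort_plan"))
  if (abs(plan$correlation) >= 1 - 1e-12 && plan$n > 1) {
    stop("degenerate covariance: |correlation| must be < 1")
  }
  set.seed(plan$seed)
  n <- plan$n
  odf <- numeric(0); sp <- numeric(0)
  while (length(odf) < n) {
    m <- max(2L * (n - length(odf)), 16L)
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    cand_odf <- plan$odflip_mean + plan$odflip_sd * z1
    cand_sp <- plan$spo2_mean +
      plan$spo2_sd * (plan$correlation * z1 + sqrt(1 - plan$correlation^2) * z2)
    keep <- cand_sp >= plan$spo2_range[1] & cand_sp <= plan$spo2_range[2]
    odf <- c(odf, cand_odf[keep]); sp <- c(sp, cand_sp[keep])
  }
  odf <- odf[seq_len(n)]; sp <- sp[seq_len(n)]
  eta <- plan$intercept + plan$beta_odflip * odf + plan$beta_spo2 * sp
  y <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
  covid <- seq_len(n) <= round(plan$covid_label_fraction * n)
  .cohort_table(data.frame(
    id = seq_len(n),
    od = 100 - odf,
    odflip = odf,
    spo2 = sp,
    needs_supplemental_o2 = y,
    covid_status = covid,
    cohort_label = ifelse(covid, "positive", "negative"),
    stringsAsFactors = FALSE
  ))
}

.cohort_table <- function(df) {
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Simulate a cohort through the full trace pipeline
#'
#' Each participant is represented by a trace specification; the oxygen
#' deficit is computed by running the complete pipeline (synthesize trace,
#' segment breaths, detect steady state, summarize), never drawn directly.
#' Participants whose traces never reach the 45 s steady state produce no
#' usable measurement and are censored from the table (with a message),
#' mirroring how a monitor yields no data file when steady state is not
#' achieved.
#'
#' @param trace_specs A list; each element is a list with components
#'   `plan` (a [breath_plan()]), `duration` (s), `spo2` (percent), and
#'   optionally `settle_time` (s; when present the trace is generated with
#'   [synthesize_unsteady_then_steady()], so `settle_time > duration - 45`
#'   yields a participant who never reaches steady state).
#' @param outcome_rule Function mapping a `gas_exchange_summary` to a
#'   logical outcome (needs supplemental O2). Default: OD above 37 mmHg.
#' @param covid_status Logical scalar or vector: label applied to rows.
#' @param tolerance Steady-state etCO2 tolerance, mmHg.
#' @param config An [oxygen_curve_config()].
#' @return A `cohort_table` with one row per participant who reached steady
#'   state; censored participants are dropped and counted in
#'   `attr(, "n_censored")`.
#' @export
simulate_cohort_from_traces <- function(trace_specs,
                                        outcome_rule = function(s) s$od > 37,
                                        covid_status = FALSE,
                                        tolerance = 2,
                                        config = oxygen_curve_config()) {
  stopifnot(is.list(trace_specs), length(trace_specs) >= 1)
  covid_status <- rep_len(covid_status, length(trace_specs))
  rows <- list(); censored <- 0L
  for (i in seq_along(trace_specs)) {
    spec <- trace_specs[[i]]
    tr <- if (!is.null(spec$settle_time)) {
      synthesize_unsteady_then_steady(spec$plan, settle_time = spec$settle_time,
                                      duration = spec$duration,
                                      spo2 = spec$spo2)
    } else {
      synthesize_trace(spec$plan, duration = spec$duration, spo2 = spec$spo2)
    }
    summ <- tryCatch(analyze_trace(tr, tolerance = tolerance, config = config),
                     error = function(e) NULL)
    if (is.null(summ)) {
      censored <- censored + 1L
      message(sprintf("participant %d censored: steady state not achieved", i))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = i, od = summ$od, odflip = summ$odflip, spo2 = summ$spo2,
      needs_supplemental_o2 = isTRUE(outcome_rule(summ)),
      covid_status = covid_status[i],
      cohort_label = ifelse(covid_status[i], "positive", "negative"),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), od = numeric(0), odflip = numeric(0),
               spo2 = numeric(0), needs_supplemental_o2 = logical(0),
               covid_status = logical(0), cohort_label = character(0))
  out <- .cohort_table(out)
  attr(out, "n_censored") <- censored
  out
}
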