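# Diagnostic-accuracy statistics: maximum-likelihood logistic regression
# with Wald inference (SPSS-style B / S.E. / Wald / df / Sig. / Exp(B)
# columns), Box-Tidwell linearity-of-the-logit checks with Bonferroni
# thresholds, ROC/AUROC with DeLong confidence intervals, Youden operating
# points, and the paired comparison of two scores on the same subjects.

#' Fit a binary logistic regression by IRLS
#'
#' Maximum-likelihood fit via iteratively reweighted least squares with
#' step-halving (the deviance never increases across iterations).
#' Convergence is declared when the largest coefficient change drops below
#' `tol`, within `max_iter` iterations. Inference is Wald: for each term,
#' `Wald = (B/SE)^2` on 1 df, `Exp(B) = exp(B)` with 95% CI
#' `exp(B +/- 1.96 SE)`. Complete separation is not "fixed": the fit is
#' returned flagged non-converged with a diagnostic message.
#'
#' @param table A data frame (e.g. a `cohort_table`).
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the logical/0-1 outcome column.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `logistic_fit`: `$terms` is a data frame with
#'   columns `term`, `B`, `SE`, `z`, `Wald`, `df`, `p`, `ExpB`, `ci_lower`,
#'   `ci_upper`; plus `$converged`, `$n_obs`, `$deviance`,
#'   `$deviance_trace`, `$formula`.
#' @export
fit_logistic <- function(table, predictors,
                         outcome = "needs_supplemental_o2",
                         tol = 1e-8, max_iter = 100) {
  stopifnot(is.data.frame(table), all(predictors %in% names(table)),
            outcome %in% names(table))
  y <- as.numeric(table[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (logical or 0/1)")
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot fit")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, predictors, drop = FALSE]))
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more terms than observations")

  dev_of <- function(eta) {
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  dev <- dev_of(eta)
  dev_trace <- dev
  converged <- FALSE
  msg <- NULL
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    beta_new <- tryCatch(drop(solve(xtw %*% X, xtw %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) { msg <- "singular information matrix"; break }
    # step-halving guarantees monotone deviance
    step <- beta_new - beta
    dev_new <- dev_of(drop(X %*% beta_new))
    h <- 0
    while (dev_new > dev + 1e-10 && h < 30) {
      step <- step / 2
      beta_new <- beta + step
      dev_new <- dev_of(drop(X %*% beta_new))
      h <- h + 1
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    dev <- dev_new
    dev_trace <- c(dev_trace, dev)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(eta)
  if (!converged && is.null(msg)) {
    msg <- if (all(mu < 1e-6 | mu > 1 - 1e-6)) {
      "possible complete separation: fitted probabilities are all 0 or 1"
    } else "did not converge within max_iter iterations"
  }
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- t(X * w) %*% X
  se <- sqrt(diag(tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p)
  })))
  B <- beta
  zstat <- B / se
  wald <- zstat^2
  terms <- data.frame(
    term = colnames(X), B = B, SE = se, z = zstat, Wald = wald, df = 1,
    p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    ExpB = exp(B),
    ci_lower = exp(B - 1.96 * se), ci_upper = exp(B + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(terms = terms, converged = converged, message = msg, n_obs = n,
         deviance = dev, deviance_trace = dev_trace,
         formula = paste(outcome, "~", paste(predictors, collapse = " + "))),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression: %s  (n = %d%s)\n", x$formula, x$n_obs,
              if (x$converged) "" else ", NOT CONVERGED"))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  tb <- x$terms
  cat(sprintf("%-14s %9s %8s %8s %3s %8s %8s %8s %8s\n",
              "", "B", "S.E.", "Wald", "df", "Sig.", "Exp(B)",
              "CI lo", "CI hi"))
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("%-14s %9.3f %8.3f %8.3f %3d %8.3g %8.3g %8.3g %8.3g\n",
                tb$term[i], tb$B[i], tb$SE[i], tb$Wald[i], tb$df[i],
                tb$p[i], tb$ExpB[i], tb$ci_lower[i], tb$ci_upper[i]))
  }
  invisible(x)
}

#' Odds ratio and 95% CI for a fitted term
#'
#' @param fit A `logistic_fit`.
#' @param term Term name.
#' @return List with `ExpB` and `ci95` (length-2 numeric).
#' @export
odds_ratio_report <- function(fit, term) {
  stopifnot(inherits(fit, "logistic_fit"))
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop(sprintf("unknown term '%s'", term))
  list(ExpB = fit$terms$ExpB[i],
       ci95 = c(fit$terms$ci_lower[i], fit$terms$ci_upper[i]))
}

#' Odds ratio arithmetic from a coefficient and its standard error
#'
#' `Exp(B) = exp(B)` with 95% CI `exp(B +/- 1.96 SE)` — the Wald odds-ratio
#' arithmetic used in standard logistic-regression output tables.
#'
#' @param B Coefficient, logit units.
#' @param SE Standard error (optional).
#' @return List with `ExpB` and, when `SE` is given, `ci95`.
#' @export
odds_ratio_from_coef <- function(B, SE = NULL) {
  out <- list(ExpB = exp(B))
  if (!is.null(SE)) out$ci95 <- c(exp(B - 1.96 * SE), exp(B + 1.96 * SE))
  out
}

#' Box-Tidwell check of linearity of the logit
#'
#' Augments the logistic model with `x * ln(x)` terms, one per continuous
#' predictor, and reports the Wald p-value of each augmentation term.
#' Linearity is accepted when every augmentation p-value is at least the
#' Bonferroni threshold `0.05 / k`, where `k` counts all terms in the
#' augmented model (intercept + predictors + augmentation terms); for a
#' two-predictor model `k = 5`, giving the threshold 0.01.
#'
#' @param table Data frame.
#' @param predictors Character vector of strictly positive predictors (after
#'   any shift).
#' @param outcome Outcome column name.
#' @param shift Named numeric of per-predictor shifts applied before taking
#'   logs (predictors must be strictly positive after shifting).
#' @return A list of class `box_tidwell` with `$checks` (data frame:
#'   `predictor`, `p_augmentation`), `$k`, `$threshold`, `$linear`, `$fit`.
#' @export
box_tidwell <- function(table, predictors,
                        outcome = "needs_supplemental_o2",
                        shift = NULL) {
  stopifnot(all(predictors %in% names(table)))
  aug <- table
  aug_names <- character(0)
  for (p in predictors) {
    x <- aug[[p]] + if (!is.null(shift) && p %in% names(shift)) shift[[p]] else 0
    if (any(x <= 0)) {
      stop(sprintf("predictor '%s' is not strictly positive; supply a shift", p))
    }
    nm <- paste0(p, "_xlnx")
    aug[[p]] <- x
    aug[[nm]] <- x * log(x)
    aug_names <- c(aug_names, nm)
  }
  fit <- fit_logistic(aug, c(predictors, aug_names), outcome = outcome)
  k <- 1 + length(predictors) + length(aug_names)
  threshold <- 0.05 / k
  pvals <- fit$terms$p[match(aug_names, fit$terms$term)]
  structure(
    list(checks = data.frame(predictor = predictors,
                             p_augmentation = pvals,
                             stringsAsFactors = FALSE),
         k = k, threshold = threshold,
         linear = all(pvals >= threshold), fit = fit),
    class = "box_tidwell"
  )
}

#' ROC curve, AUROC and DeLong confidence interval
#'
#' Thresholds are the unique score values (classification rule: score on the
#' positive side of the threshold, inclusive). The AUROC is the
#' Mann-Whitney concordance with half credit for ties, which equals the
#' trapezoidal area under the empirical curve. The 95% CI uses DeLong's
#' placement-based variance. The Youden operating point maximizes
#' `sensitivity + specificity - 1`; ties are broken toward higher
#' sensitivity, then toward the lower threshold.
#'
#' @param scores Numeric score per subject.
#' @param outcomes Logical/0-1 outcome per subject (positive class = TRUE).
#' @param direction `"higher"` if larger scores indicate the positive
#'   class, `"lower"` otherwise (e.g. SpO2 or ODFlip against needing
#'   supplemental oxygen).
#' @return An object of class `roc_result` with the curve coordinates,
#'   `auroc`, `auroc_ci95`, `youden_j`, `optimal_threshold` (on the
#'   original score scale), `optimal_sensitivity`,
#'   `optimal_one_minus_specificity`, and DeLong placements.
#' @export
roc_curve <- function(scores, outcomes, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  y <- as.logical(outcomes)
  if (any(is.na(scores)) || any(is.na(y))) stop("missing values not allowed")
  if (!any(y) || all(y)) stop("both outcome classes must be present")
  s <- if (direction == "higher") scores else -scores
  n1 <- sum(y); n0 <- sum(!y)

  # Mann-Whitney AUROC with midranks (= trapezoidal area)
  r <- rank(s, ties.method = "average")
  auroc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placements
  sp <- s[y]; sn <- s[!y]
  v10 <- vapply(sp, function(si) (sum(sn < si) + 0.5 * sum(sn == si)) / n0,
                numeric(1))
  v01 <- vapply(sn, function(sj) (sum(sp > sj) + 0.5 * sum(sp == sj)) / n1,
                numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  half <- 1.96 * sqrt(var_auc)
  ci <- c(max(0, auroc - half), min(1, auroc + half))

  thr_int <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(thr_int, function(ti) sum(s >= ti & y) / n1, numeric(1))
  oms <- vapply(thr_int, function(ti) sum(s >= ti & !y) / n0, numeric(1))
  thr_orig <- if (direction == "higher") thr_int else -thr_int

  res <- structure(
    list(thresholds = thr_orig, sensitivity = sens,
         one_minus_specificity = oms,
         auroc = auroc, auroc_ci95 = ci, direction = direction,
         n_pos = n1, n_neg = n0, v10 = v10, v01 = v01,
         outcomes = y),
    class = "roc_result"
  )
  yp <- youden_point(res)
  res$youden_j <- yp$youden_j
  res$optimal_threshold <- yp$optimal_threshold
  res$optimal_sensitivity <- yp$sensitivity
  res$optimal_one_minus_specificity <- yp$one_minus_specificity
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%d pos / %d neg, direction = %s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f to %.3f)\n",
              x$auroc, x$auroc_ci95[1], x$auroc_ci95[2]))
  cat(sprintf("  Youden J %.3f at threshold %.3g (sens %.3f, 1-spec %.3f)\n",
              x$youden_j, x$optimal_threshold, x$optimal_sensitivity,
              x$optimal_one_minus_specificity))
  invisible(x)
}

#' Youden operating point of a ROC curve
#'
#' @param roc A `roc_result`.
#' @return List with `optimal_threshold`, `youden_j`, `sensitivity`,
#'   `one_minus_specificity`.
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity - roc$one_minus_specificity
  best <- which(j >= max(j) - 1e-12)
  best <- best[roc$sensitivity[best] >= max(roc$sensitivity[best]) - 1e-12]
  i <- best[which.min(roc$thresholds[best])]
  list(optimal_threshold = roc$thresholds[i], youden_j = j[i],
       sensitivity = roc$sensitivity[i],
       one_minus_specificity = roc$one_minus_specificity[i])
}

#' Youden's J from an operating point
#'
#' `J = sensitivity + specificity - 1 = sensitivity - (1 - specificity)`.
#'
#' @param sensitivity,one_minus_specificity Operating-point coordinates.
#' @return Youden's J.
#' @export
youden_j <- function(sensitivity, one_minus_specificity) {
  sensitivity - one_minus_specificity
}

#' Convert an ODFlip ROC threshold back to the oxygen-deficit scale
#'
#' The ROC is run on ODFlip (= 100 - OD) so that, like SpO2, lower values
#' indicate the positive class; the clinically reported threshold is
#' back-converted as `OD = 100 - ODFlip`.
#'
#' @param roc A `roc_result` built on ODFlip scores.
#' @return Optimal threshold on the OD scale, mmHg.
#' @export
od_threshold_report <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  od_from_odflip(roc$optimal_threshold)
}

#' DeLong paired test for the difference of two AUROCs
#'
#' Both ROC results must come from the same subjects in the same order
#' (paired design). Tests `H0: AUROC1 == AUROC2` using the covariance of the
#' DeLong placements.
#'
#' @param roc1,roc2 `roc_result` objects on the same subjects.
#' @return List with `auroc_diff`, `se`, `z`, `p`.
#' @export
delong_paired_test <- function(roc1, roc2) {
  stopifnot(inherits(roc1, "roc_result"), inherits(roc2, "roc_result"))
  if (!identical(roc1$outcomes, roc2$outcomes)) {
    stop("paired test requires the same subjects in the same order")
  }
  n1 <- roc1$n_pos; n0 <- roc1$n_neg
  var_diff <- stats::var(roc1$v10 - roc2$v10) / n1 +
    stats::var(roc1$v01 - roc2$v01) / n0
  d <- roc1$auroc - roc2$auroc
  se <- sqrt(var_diff)
  z <- if (se > 0) d / se else Inf * sign(d)
  list(auroc_diff = d, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Full predictor-comparison recipe
#'
#' For each cohort label present in the table (and the pooled table): three
#' univariable logistic fits (OD, ODFlip, SpO2 against the outcome), one
#' multivariable fit (ODFlip + SpO2), ROC analyses for ODFlip and SpO2
#' (lower values indicate the positive class) with Youden operating points,
#' the ODFlip threshold back-converted to the OD scale, Box-Tidwell
#' linearity checks, and a DeLong paired test of the two AUROCs.
#'
#' @param table A `cohort_table` with columns `od`, `odflip`, `spo2`,
#'   `needs_supplemental_o2` and `cohort_label`.
#' @return A list of class `predictor_comparison`, one element per cohort
#'   (`positive`, `negative`, `pooled` as available), each containing
#'   `univariable` (list of `logistic_fit`), `multivariable`, `roc_odflip`,
#'   `roc_spo2`, `od_threshold`, `box_tidwell`, `delong`, `n`.
#' @export
compare_predictors <- function(table) {
  stopifnot(all(c("od", "odflip", "spo2", "needs_supplemental_o2") %in%
                  names(table)))
  cohorts <- list(pooled = table)
  if ("cohort_label" %in% names(table)) {
    for (lab in c("positive", "negative")) {
      sub <- table[table$cohort_label == lab, , drop = FALSE]
      if (nrow(sub) > 0) cohorts[[lab]] <- sub
    }
  }
  out <- lapply(cohorts, function(tb) {
    uni <- lapply(c(od = "od", odflip = "odflip", spo2 = "spo2"),
                  function(p) fit_logistic(tb, p))
    multi <- fit_logistic(tb, c("odflip", "spo2"))
    roc_f <- roc_curve(tb$odflip, tb$needs_supplemental_o2,
                       direction = "lower")
    roc_s <- roc_curve(tb$spo2, tb$needs_supplemental_o2,
                       direction = "lower")
    list(n = nrow(tb), univariable = uni, multivariable = multi,
         roc_odflip = roc_f, roc_spo2 = roc_s,
         od_threshold = od_threshold_report(roc_f),
         box_tidwell = box_tidwell(tb, c("odflip", "spo2"),
                                   shift = c(odflip = max(0, 1 - min(tb$odflip)),
                                             spo2 = max(0, 1 - min(tb$spo2)))),
         delong = delong_paired_test(roc_f, roc_s))
  })
  structure(out, class = "predictor_comparison")
}

#' @export
print.predictor_comparison <- function(x, ...) {
  for (lab in names(x)) {
    co <- x[[lab]]
    cat(sprintf("== %s cohort (n = %d) ==\n", lab, co$n))
    cat(sprintf("  AUROC ODFlip %.3f (%.3f-%.3f), Youden J %.3f at OD %.1f mmHg\n",
                co$roc_odflip$auroc, co$roc_odflip$auroc_ci95[1],
                co$roc_odflip$auroc_ci95[2], co$roc_odflip$youden_j,
                co$od_threshold))
    cat(sprintf("  AUROC SpO2   %.3f (%.3f-%.3f), Youden J %.3f at SpO2 %.1f%%\n",
                co$roc_spo2$auroc, co$roc_spo2$auroc_ci95[1],
                co$roc_spo2$auroc_ci95[2], co$roc_spo2$youden_j,
                co$roc_spo2$optimal_threshold))
    cat(sprintf("  DeLong AUROC difference %.3f (p = %.3g)\n",
                co$delong$auroc_diff, co$delong$p))
    print(co$multivariable)
  }
  invisible(x)
}
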