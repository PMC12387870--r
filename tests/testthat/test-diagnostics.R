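# Logistic regression, Box-Tidwell, ROC/DeLong, Youden, comparison recipe.

test_that("fit_logistic agrees with the glm oracle", {
  set.seed(21)
  n <- 400
  x1 <- rnorm(n, 60, 12); x2 <- rnorm(n, 94, 2)
  y <- rbinom(n, 1, plogis(20 - 0.1 * x1 - 0.15 * x2)) == 1
  d <- data.frame(odflip = x1, spo2 = x2, needs_supplemental_o2 = y)
  fit <- fit_logistic(d, c("odflip", "spo2"))
  ref <- glm(needs_supplemental_o2 ~ odflip + spo2, data = d,
             family = binomial())
  expect_true(fit$converged)
  expect_equal(fit$terms$B, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$terms$SE, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
})

test_that("2x2 collapsed data reproduces the closed-form odds ratio", {
  # x = 0: 30 pos / 70 neg;  x = 1: 60 pos / 40 neg  ->  OR = 3.5
  d <- data.frame(
    x = c(rep(0, 100), rep(1, 100)),
    needs_supplemental_o2 = c(rep(TRUE, 30), rep(FALSE, 70),
                              rep(TRUE, 60), rep(FALSE, 40))
  )
  fit <- fit_logistic(d, "x")
  i <- match("x", fit$terms$term)
  expect_equal(fit$terms$B[i], log(3.5), tolerance = 1e-8)
  # Wald SE equals the 1/a + 1/b + 1/c + 1/d contingency formula
  expect_equal(fit$terms$SE[i], sqrt(1/30 + 1/70 + 1/60 + 1/40),
               tolerance = 1e-6)
  expect_equal(odds_ratio_report(fit, "x")$ExpB, 3.5, tolerance = 1e-8)
  expect_error(odds_ratio_report(fit, "nope"), "unknown term")
})

test_that("an independent predictor fits to the null", {
  set.seed(31)
  d <- data.frame(x = rnorm(2000),
                  needs_supplemental_o2 = rbinom(2000, 1, 0.5) == 1)
  fit <- fit_logistic(d, "x")
  i <- match("x", fit$terms$term)
  expect_lt(abs(fit$terms$B[i]), 3 * fit$terms$SE[i])
  expect_lt(abs(fit$terms$ExpB[i] - 1), 0.2)
})

test_that("logistic fit internals are consistent and deviance is monotone", {
  set.seed(41)
  d <- data.frame(x = rnorm(300),
                  needs_supplemental_o2 = rbinom(300, 1, plogis(rnorm(300))) == 1)
  fit <- fit_logistic(d, "x")
  tb <- fit$terms
  expect_equal(tb$ExpB, exp(tb$B), tolerance = 1e-12)
  expect_equal(tb$ci_lower, exp(tb$B - 1.96 * tb$SE), tolerance = 1e-12)
  expect_equal(tb$ci_upper, exp(tb$B + 1.96 * tb$SE), tolerance = 1e-12)
  expect_true(all(tb$Wald >= 0))
  expect_true(all(tb$ci_lower <= tb$ExpB & tb$ExpB <= tb$ci_upper))
  expect_true(all(diff(fit$deviance_trace) <= 1e-10))
})

test_that("separation is reported, not silently fixed; single class errors", {
  d <- data.frame(x = c(1:10, 21:30),
                  needs_supplemental_o2 = rep(c(FALSE, TRUE), each = 10))
  fit <- fit_logistic(d, "x")
  expect_false(fit$converged)
  expect_match(fit$message, "separation|converge")
  expect_error(fit_logistic(
    data.frame(x = 1:10, needs_supplemental_o2 = rep(TRUE, 10)), "x"),
    "single class")
})

test_that("odds-ratio arithmetic helper matches the table convention", {
  r <- odds_ratio_from_coef(-0.153, 0.045)
  expect_equal(r$ExpB, exp(-0.153), tolerance = 1e-12)
  expect_equal(r$ci95, exp(-0.153 + c(-1, 1) * 1.96 * 0.045), tolerance = 1e-12)
  expect_equal(odds_ratio_from_coef(0)$ExpB, 1)
})

test_that("box_tidwell builds the k = 5 Bonferroni threshold for two predictors", {
  tb <- simulate_cohort(cohort_plan(n = 3000, seed = 51L))
  bt <- box_tidwell(tb, c("odflip", "spo2"))
  expect_identical(bt$k, 5)
  expect_equal(bt$threshold, 0.01)
  expect_identical(nrow(bt$checks), 2L)
  expect_error(box_tidwell(data.frame(x = c(-1, 1, 2, 3),
                                      needs_supplemental_o2 = c(TRUE, FALSE, TRUE, FALSE)),
                           "x"),
               "strictly positive")
})

test_that("box_tidwell detects a planted quadratic logit distortion", {
  set.seed(61)
  hits <- 0
  for (r in 1:20) {
    x <- runif(5000, 20, 90)
    eta <- 2 - 0.003 * (x - 55)^2   # clearly curved, non-degenerate logit
    y <- rbinom(5000, 1, plogis(eta)) == 1
    d <- data.frame(x = x, needs_supplemental_o2 = y)
    bt <- box_tidwell(d, "x")
    if (bt$checks$p_augmentation[1] < bt$threshold) hits <- hits + 1
  }
  expect_gte(hits, 16)  # power: curvature flagged in most replicates
})

test_that("roc_curve equals the brute-force concordance oracle (with ties)", {
  set.seed(71)
  for (r in 1:10) {
    n <- 150
    y <- rbinom(n, 1, 0.4) == 1
    s <- round(rnorm(n, mean = ifelse(y, 0.8, 0), sd = 1), 1)  # forces ties
    roc <- roc_curve(s, y, direction = "higher")
    expect_equal(roc$auroc, brute_force_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("roc degenerate cases: perfect separation and pure ties", {
  y <- rep(c(FALSE, TRUE), each = 10)
  expect_equal(roc_curve(c(1:10, 21:30), y)$auroc, 1)
  roc_tie <- roc_curve(rep(5, 20), y)
  expect_equal(roc_tie$auroc, 0.5)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("direction reflection symmetry holds exactly", {
  set.seed(81)
  y <- rbinom(120, 1, 0.5) == 1
  od <- rnorm(120, ifelse(y, 45, 25), 10)
  r_hi <- roc_curve(od, y, direction = "higher")
  r_lo <- roc_curve(100 - od, y, direction = "lower")
  expect_equal(r_hi$auroc, r_lo$auroc, tolerance = 1e-12)
  expect_equal(r_hi$youden_j, r_lo$youden_j, tolerance = 1e-12)
  expect_equal(od_from_odflip(r_lo$optimal_threshold), r_hi$optimal_threshold,
               tolerance = 1e-12)
})

test_that("the ROC curve is monotone and the Youden point is coherent", {
  set.seed(91)
  y <- rbinom(200, 1, 0.5) == 1
  s <- rnorm(200, ifelse(y, 1, 0))
  roc <- roc_curve(s, y)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$one_minus_specificity) >= 0))
  yp <- youden_point(roc)
  expect_equal(roc$youden_j,
               yp$sensitivity - yp$one_minus_specificity, tolerance = 1e-12)
  expect_equal(roc$youden_j,
               max(roc$sensitivity - roc$one_minus_specificity),
               tolerance = 1e-12)
  # degenerate single-threshold curve returns that threshold
  r1 <- roc_curve(rep(3, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(r1$optimal_threshold, 3)
})

test_that("DeLong CI contains the AUROC and narrows with n", {
  set.seed(101)
  widths <- vapply(c(50, 200, 1000), function(n) {
    y <- rep(c(TRUE, FALSE), length.out = n)
    s <- rnorm(n, ifelse(y, 0.7, 0))
    roc <- roc_curve(s, y)
    expect_gte(roc$auroc, roc$auroc_ci95[1])
    expect_lte(roc$auroc, roc$auroc_ci95[2])
    diff(roc$auroc_ci95)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("DeLong paired test favors the more informative score", {
  set.seed(111)
  n <- 300
  y <- rbinom(n, 1, 0.5) == 1
  strong <- rnorm(n, ifelse(y, 1.5, 0))
  weak <- strong + rnorm(n, 0, 2)        # same signal, more noise
  r1 <- roc_curve(strong, y); r2 <- roc_curve(weak, y)
  dl <- delong_paired_test(r1, r2)
  expect_gt(dl$auroc_diff, 0)
  expect_lt(dl$p, 0.05)
  expect_error(delong_paired_test(r1, roc_curve(weak[1:100], y[1:100])),
               "same subjects")
})

test_that("compare_predictors runs the full recipe with consistent bookkeeping", {
  tb <- simulate_cohort(cohort_plan(n = 300, seed = 121L))
  rep <- compare_predictors(tb)
  expect_s3_class(rep, "predictor_comparison")
  expect_setequal(names(rep), c("pooled", "positive", "negative"))
  npos <- sum(tb$cohort_label == "positive")
  expect_identical(rep$positive$n + rep$negative$n, rep$pooled$n)
  expect_identical(rep$pooled$n, 300L)
  for (co in rep) {
    # univariable OD and ODFlip estimates are exact sign flips
    b_od <- co$univariable$od$terms
    b_fl <- co$univariable$odflip$terms
    expect_equal(b_od$B[b_od$term == "od"], -b_fl$B[b_fl$term == "odflip"],
                 tolerance = 1e-6)
    expect_equal(co$od_threshold, 100 - co$roc_odflip$optimal_threshold,
                 tolerance = 1e-12)
  }
  # defaults plant extra signal in ODFlip beyond SpO2
  expect_gt(rep$pooled$roc_odflip$auroc, rep$pooled$roc_spo2$auroc)
})
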