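# Saturation-curve physiology: Hill forward/inverse, P50 correction, OD.

test_that("hill_saturation matches its definition and frozen oracle value", {
  expect_identical(hill_saturation(26.86, p50 = 26.86), 0.5)
  expect_identical(hill_saturation(0, p50 = 26.86), 0)
  # frozen from an independent high-precision evaluation of
  # (2 p50)^n / ((2 p50)^n + p50^n) at n = 2.88
  expect_equal(hill_saturation(2 * 26.86, 26.86, 2.88),
               0.880404250925403, tolerance = 1e-14)
  expect_error(hill_saturation(-1), "finite and >= 0")
  expect_error(hill_saturation(50, p50 = -3), "p50")
})

test_that("severinghaus_saturation is monotone, asymptotes to 1, rejects bad input", {
  grid <- seq(0.5, 700, by = 0.5)
  s <- severinghaus_saturation(grid)
  expect_true(all(diff(s) > 0))
  expect_gt(severinghaus_saturation(5000), 0.999)
  expect_error(severinghaus_saturation(0), "> 0")
})

test_that("Severinghaus-vs-Hill discrepancy on [40, 100] mmHg stays at its frozen bound", {
  # bound established once by dense grid scan (max 0.0094859 at 40 mmHg)
  grid <- seq(40, 100, by = 0.01)
  d <- abs(severinghaus_saturation(grid) -
             hill_saturation(grid, p50 = 26.86, n = 2.88))
  expect_lt(max(d), 0.0095)
  expect_gt(max(d), 0.009)  # regression: the two curves must not be conflated
})

test_that("corrected_p50 honors the reference point and the Bohr direction", {
  cfg <- oxygen_curve_config()
  expect_equal(corrected_p50(40, cfg), cfg$p50_standard, tolerance = 1e-14)
  expect_gt(corrected_p50(60, cfg), cfg$p50_standard)
  expect_lt(corrected_p50(30, cfg), cfg$p50_standard)
  # hand calculation: pH(60) = 6.1 + log10(24 / (0.03 * 60)) = 7.22494,
  # pH(40) = 7.40103; P50 = 26.86 * 10^(-0.48 (7.22494 - 7.40103)) = 32.6310
  ph60 <- 6.1 + log10(24 / (0.03 * 60))
  ph40 <- 6.1 + log10(24 / (0.03 * 40))
  expect_equal(corrected_p50(60, cfg), 26.86 * 10^(-0.48 * (ph60 - ph40)),
               tolerance = 1e-12)
  expect_equal(corrected_p50(60, cfg), 32.63095713, tolerance = 1e-7)
  expect_error(corrected_p50(5, cfg), "\\[10, 120\\]")
  expect_error(corrected_p50(150, cfg), "\\[10, 120\\]")
})

test_that("gpao2_from_spo2 inverts the Hill curve", {
  cfg <- oxygen_curve_config()
  # SpO2 = 50% at the reference PACO2 lands exactly on P50
  expect_equal(gpao2_from_spo2(50, 40, cfg), 26.86, tolerance = 1e-12)
  # round trip within the same functional family
  for (s in 80:99) {
    g <- gpao2_from_spo2(s, 40, cfg)
    expect_equal(100 * hill_saturation(g, corrected_p50(40, cfg), cfg$hill_n),
                 s, tolerance = 1e-9)
  }
  # independent bisection oracle at SpO2 94%, PACO2 40
  expect_equal(gpao2_from_spo2(94, 40, cfg),
               bisect_hill_inverse(0.94, corrected_p50(40, cfg), cfg$hill_n),
               tolerance = 1e-8)
  expect_warning(g100 <- gpao2_from_spo2(100, 40, cfg), "clamped")
  expect_equal(g100, gpao2_from_spo2(99.5, 40, cfg))
  expect_error(gpao2_from_spo2(30, 40, cfg), "implausible")
})

test_that("gpao2_from_spo2 is strictly monotone in SpO2 and in PACO2", {
  cfg <- oxygen_curve_config()
  set.seed(11)
  for (rep in 1:20) {
    s <- sort(runif(25, 55, 99))
    g <- vapply(s, gpao2_from_spo2, numeric(1), paco2 = runif(1, 25, 60),
                config = cfg)
    expect_true(all(diff(g) > 0))
  }
  pc <- seq(15, 110, by = 5)
  g <- vapply(pc, function(p) gpao2_from_spo2(92, p, cfg), numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("oxygen_deficit and the ODFlip involution behave as arithmetic", {
  expect_identical(oxygen_deficit(100, 63), 37)
  expect_identical(oxygen_deficit(110, 69), 41)
  expect_identical(oxygen_deficit(80, 80), 0)
  expect_warning(neg <- oxygen_deficit(60, 70), "negative")
  expect_identical(neg, -10)
  expect_identical(odflip(37), 63)
  expect_identical(odflip(100), 0)
  expect_identical(od_from_odflip(59), 41)
  x <- c(-3, 0, 12.345, 41, 99.9)
  expect_equal(od_from_odflip(odflip(x)), x, tolerance = 1e-12)
  expect_equal(odflip(od_from_odflip(x)), x, tolerance = 1e-12)
})

test_that("OD moves with SpO2 and PAO2 in the gradient-surrogate directions", {
  cfg <- oxygen_curve_config()
  od_at <- function(spo2, pao2) oxygen_deficit(pao2, gpao2_from_spo2(spo2, 40, cfg))
  s <- seq(85, 98, by = 1)
  expect_true(all(diff(vapply(s, od_at, numeric(1), pao2 = 110)) < 0))
  p <- seq(90, 120, by = 2)
  expect_true(all(diff(vapply(p, function(pp) od_at(93, pp), numeric(1))) > 0))
})

test_that("oxygen_curve_config validates its invariants", {
  expect_error(oxygen_curve_config(hill_n = -1))
  expect_error(oxygen_curve_config(spo2_clamp = c(50, 100)), "clamp")
  expect_error(oxygen_curve_config(spo2_clamp = c(99, 60)), "clamp")
})
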