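test_that("first moment: symmetry, linearity, refinement, invariances", {
  sp <- gen_spectrum(340, 8)
  expect_equal(first_moment(sp), 340, tolerance = 1e-9)
  # two equal-area narrow bands at 320 and 360 average to 340
  x <- seq(300, 380, by = 0.05)
  y <- exp(-(x - 320)^2 / (2 * 0.5^2)) + exp(-(x - 360)^2 / (2 * 0.5^2))
  expect_equal(first_moment(x, y), 340, tolerance = 1e-6)
  # skewed band agrees with a 10x refined-grid oracle
  xs <- seq(300, 400, by = 2)
  ys <- exp(-(xs - 335)^2 / (2 * 12^2)) * (1 + 0.02 * (xs - 300))
  expect_lt(abs(first_moment(xs, ys) - oracle_first_moment_fine(xs, ys)), 0.05)
  # y-scaling invariance; x-shift equivariance
  expect_equal(first_moment(xs, 7.3 * ys), first_moment(xs, ys))
  expect_equal(first_moment(xs + 5, ys), first_moment(xs, ys) + 5,
               tolerance = 1e-9)
  expect_error(first_moment(xs, 0 * ys), "zero integral")
  # red-side truncation biases the moment blue-ward
  tr <- suppressWarnings(gen_spectrum(340, 10,
                                      grid = seq(300, 350, length.out = 101)))
  expect_lt(first_moment(tr), 340)
})

test_that("CD conversion to per-residue delta-epsilon follows the scaling law", {
  expect_equal(mean_residue_delta_epsilon(0, 16e-6, 0.01, 410), 0)
  expect_equal(mean_residue_delta_epsilon(32980, 1, 1, 1), 1.0)
  base <- mean_residue_delta_epsilon(500, 16e-6, 0.01, 410)
  expect_equal(mean_residue_delta_epsilon(500, 32e-6, 0.01, 410), base / 2)
  expect_equal(mean_residue_delta_epsilon(1000, 16e-6, 0.01, 410), 2 * base)
  expect_error(mean_residue_delta_epsilon(500, -1, 0.01, 410), "positive")
})

test_that("single-sigmoid fits recover noiseless parameters exactly", {
  x <- seq(0, 3, length.out = 30)
  y <- sigmoid_sum(x, baseline = 2, amplitudes = 5, midpoints = 1.5,
                   widths = 0.2)
  fit <- fit_denaturation(x, y, n_transitions = 1)
  expect_equal(fit$transitions$midpoint, 1.5, tolerance = 1e-6)
  expect_equal(fit$transitions$width, 0.2, tolerance = 1e-5)
  expect_equal(fit$baseline, 2, tolerance = 1e-5)
  expect_true(fit$converged)
  expect_false(fit$low_confidence)
})

test_that("two-transition fits recover the planted chemical midpoints", {
  g <- gen_denaturation_curve(c(0.8, 2.6), widths = 0.15,
                              amplitudes = c(8, 12), baseline = 332,
                              noise_pct = 1, n_points = 25, seed = 5)
  fit <- fit_denaturation(g$curve, n_transitions = 2)
  expect_equal(fit$transitions$midpoint, c(0.8, 2.6), tolerance = 0.05 / 0.8)
  expect_lt(abs(fit$transitions$midpoint[1] - 0.8), 0.05)
  expect_lt(abs(fit$transitions$midpoint[2] - 2.6), 0.05)
  expect_lt(fit$transitions$midpoint[1], fit$transitions$midpoint[2])
  expect_true(all(fit$transitions$width > 0))
})

test_that("midpoint recovery is stable over replicates at 2% noise", {
  errs1 <- errs2 <- numeric(100)
  for (k in 1:100) {
    g <- gen_denaturation_curve(c(0.8, 2.6), widths = 0.15,
                                amplitudes = c(10, 10), noise_pct = 2,
                                n_points = 25, seed = 1000 + k)
    fit <- tryCatch(suppressWarnings(fit_denaturation(g$curve, n_transitions = 2)),
                    error = function(e) NULL)
    if (is.null(fit)) { errs1[k] <- errs2[k] <- NA; next }
    errs1[k] <- abs(fit$transitions$midpoint[1] - 0.8)
    errs2[k] <- abs(fit$transitions$midpoint[2] - 2.6)
  }
  expect_lt(median(errs1, na.rm = TRUE), 0.15 / 5)
  expect_lt(median(errs2, na.rm = TRUE), 0.15 / 5)
})

test_that("degenerate curves are flagged rather than fitted confidently", {
  set.seed(8)
  x <- seq(0, 5, length.out = 25)
  flat <- 10 + rnorm(25, 0, 0.05)
  res <- tryCatch(
    withCallingHandlers(
      fit_denaturation(x, flat, n_transitions = 1),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) "error")
  if (!identical(res, "error")) expect_true(res$low_confidence)
  expect_error(fit_denaturation(rev(x), flat), "increasing")
})

test_that("thermal ramps yield the midpoint temperature", {
  x <- seq(20, 90, length.out = 40)
  set.seed(9)
  y0 <- sigmoid_sum(x, baseline = -4, amplitudes = 3.5, midpoints = 55,
                    widths = 2.5)
  y <- y0 + rnorm(40, 0, 0.035)
  tm <- thermal_midpoint(x, y)
  expect_lt(abs(as.numeric(tm) - 55), 0.2)
  expect_false(attr(tm, "low_confidence"))
})

test_that("lane normalisation: fractions, display scaling, replicates", {
  lanes <- data.frame(
    lane = c("t0", "t0", "t1", "t1"),
    band = c("monomer", "dimer", "monomer", "dimer"),
    density = c(80, 20, 60, 40))
  out <- lane_normalize(lanes, scale_minor = 5, minor_bands = "dimer")
  expect_equal(out$fraction[1:2], c(0.8, 0.2))
  expect_equal(out$display[2], 1.0)  # scaled for display only
  expect_equal(out$display[1], 0.8)
  sums <- tapply(out$fraction, out$lane, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # triplicates aggregate to mean and sd per band
  tri <- data.frame(
    lane = rep(c("r1", "r2", "r3"), each = 2),
    band = rep(c("monomer", "dimer"), 3),
    density = c(80, 20, 82, 18, 78, 22))
  agg <- summarize_lanes(lane_normalize(tri))
  expect_equal(agg$mean[agg$band == "monomer"], 0.8, tolerance = 1e-12)
  expect_equal(agg$n, c(3L, 3L))
  expect_true(all(agg$sd >= 0))
  bad <- data.frame(lane = "x", band = "m", density = 0)
  expect_error(lane_normalize(bad), "zero total")
})

test_that("two-column curve files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# emission spectrum", "300 0.1", "310 0.5", "320 0.2"), f)
  cv <- read_curve(f, kind = "spectrum")
  expect_equal(cv$x, c(300, 310, 320))
  expect_equal(cv$y, c(0.1, 0.5, 0.2))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2", "2,3"), f2)
  expect_equal(read_curve(f2)$y, c(2, 3))
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "1 3"), f3)
  expect_error(read_curve(f3), "increasing")
})
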