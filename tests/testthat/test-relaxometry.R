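delays10 <- c(100, 200, 400, 700, 1000, 1500, 2000, 3000, 4500, 6000)

test_that("noiseless saturation-recovery fits return the generating parameters", {
  cases <- list(
    list(A = 1000, B = 1000, T1 = 1200,
         td = c(100, 300, 600, 1000, 1500, 2000, 3000)),
    list(A = 1148, B = 1148, T1 = 1148, td = delays10),
    list(A = 500, B = 650, T1 = 2500, td = delays10),          # A != B
    list(A = 3, B = 3, T1 = 80, td = c(20, 50, 120, 300, 600))
  )
  for (cs in cases) {
    m <- cs$A - cs$B * exp(-cs$td / cs$T1)
    f <- fit_t1_pixel(m, cs$td)
    expect_true(f$converged)
    expect_equal(f$T1, cs$T1, tolerance = 1e-6)
    expect_equal(f$A, cs$A, tolerance = 1e-6)
    expect_equal(f$B, cs$B, tolerance = 1e-6)
    expect_lt(f$rmse, 1e-5 * cs$A)
  }
})

test_that("the half-recovery identity M(T1 * ln 2) = A - B/2 is honoured", {
  # A = B = 2, T1 = 1000: the signal passes exactly through 1.0 at TD = 693.147
  td <- c(200, 693.14718055994531, 1200, 2200, 4000)
  m <- 2 - 2 * exp(-td / 1000)
  expect_equal(m[2], 1.0, tolerance = 1e-12)
  f <- fit_t1_pixel(m, td)
  expect_equal(f$T1, 1000, tolerance = 1e-6)
})

test_that("T1 estimates agree with an independent lattice search", {
  m1148 <- 1000 - 1000 * exp(-delays10 / 1148)
  f <- fit_t1_pixel(m1148, delays10)
  or <- oracle_t1_grid(m1148, delays10)
  expect_equal(f$T1, unname(or$par["T1"]), tolerance = 3 * or$step[["T1"]] / or$par[["T1"]])

  set.seed(41)
  for (i in 1:12) {
    t1 <- runif(1, 300, 3000); a <- runif(1, 500, 2000)
    m <- a - a * exp(-delays10 / t1) + rnorm(10, 0, a / 100)
    f <- fit_t1_pixel(m, delays10)
    or <- oracle_t1_grid(m, delays10)
    expect_true(f$converged)
    expect_lt(abs(f$T1 - or$par[["T1"]]), 4 * or$step[["T1"]])
    # the profiled solution can only improve on the lattice
    rss_fit <- sum((m - (f$A - f$B * exp(-delays10 / f$T1)))^2)
    rss_or <- sum((m - (or$par[["A"]] - or$par[["B"]] * exp(-delays10 / or$par[["T1"]])))^2)
    expect_lte(rss_fit, rss_or * (1 + 1e-9))
  }
})

test_that("T1 fitting is scale-equivariant and delay-unit consistent", {
  td <- delays10
  m <- 800 - 800 * exp(-td / 950)
  f1 <- fit_t1_pixel(m, td)
  f2 <- fit_t1_pixel(7.3 * m, td)
  expect_equal(f2$A, 7.3 * f1$A, tolerance = 1e-8)
  expect_equal(f2$B, 7.3 * f1$B, tolerance = 1e-8)
  expect_equal(f2$T1, f1$T1, tolerance = 1e-8)
  # delays in seconds with bounds in seconds: T1(s) * 1000 = T1(ms)
  fs <- fit_t1_pixel(m, td / 1000, t1_bounds = c(0.001, 10))
  expect_equal(fs$T1 * 1000, f1$T1, tolerance = 1e-6)
})

test_that("degenerate or inconsistent T1 inputs are rejected or flagged", {
  td <- c(100, 300, 600, 1000)
  expect_error(fit_t1_pixel(c(1, 2, 3), td), "same length")
  expect_error(fit_t1_pixel(c(1, 2), c(100, 200)), "at least 3")
  expect_error(fit_t1_pixel(c(1, 2, 3, 4), c(-1, 2, 3, 4)), "positive")
  expect_error(fit_t1_pixel(c(1, 2, 3, 4), c(100, 100, 300, 600)), "increasing")
  # decaying signal is inconsistent with saturation recovery
  f <- fit_t1_pixel(c(4, 3, 2, 1), td)
  expect_false(f$converged)
  expect_true(is.na(f$T1))
  # flat signal carries no information
  expect_false(fit_t1_pixel(c(2, 2, 2, 2), td)$converged)
})

test_that("pixel-wise T1 maps recover bimodal phantoms and honour the mask", {
  truth <- matrix(1150, 16, 16); truth[, 9:16] <- 1320
  ph <- make_t1_phantom(truth, noise_sd = 0, seed = 1)
  map <- fit_t1_map(ph$series)
  expect_equal(sort(unique(round(as.numeric(map$values), 4))), c(1150, 1320))
  expect_equal(map$values[3, 3], 1150, tolerance = 1e-6)
  expect_equal(map$values[3, 12], 1320, tolerance = 1e-6)

  mask <- truth == 1150
  ph2 <- make_t1_phantom(truth, noise_sd = 0, mask = mask, seed = 1)
  map2 <- fit_t1_map(ph2$series)
  expect_true(all(is.na(map2$values[!mask])))
  expect_equal(map2$values[mask], map$values[mask], tolerance = 1e-9)

  ph$series$mask[] <- FALSE
  expect_error(fit_t1_map(ph$series), "mask is empty")
})

test_that("T1 region means stay within 1% of truth at plateau SNR 50", {
  truth <- matrix(1150, 16, 16); truth[, 9:16] <- 1320
  for (s in 1:3) {
    ph <- make_t1_phantom(truth, noise_sd = 20, seed = s)   # A = 1000, SNR 50
    map <- fit_t1_map(ph$series)
    expect_lt(abs(map_roi_stats(map, truth == 1150)$mean / 1150 - 1), 0.01)
    expect_lt(abs(map_roi_stats(map, truth == 1320)$mean / 1320 - 1), 0.01)
  }
})

test_that("noiseless echo decays invert exactly, including the 10.3 ms case", {
  te <- c(16, 26, 36)
  f <- fit_t2_pixel(100 * exp(-te / 15), te)
  expect_equal(f$T2, 15, tolerance = 1e-9)
  expect_equal(f$S0, 100, tolerance = 1e-9)
  # control-like myocardial T2 at the acquisition echo times
  f2 <- fit_t2_pixel(1000 * exp(-te / 10.3), te)
  expect_equal(f2$T2, 10.3, tolerance = 1e-9)
})

test_that("noisy T2 estimates agree with an independent lattice search", {
  te <- c(16, 26, 36)
  set.seed(7)
  for (i in 1:10) {
    t2 <- runif(1, 8, 40)
    s <- 500 * exp(-te / t2) * exp(rnorm(3, 0, 0.03))
    f <- fit_t2_pixel(s, te)
    or <- oracle_t2_grid(s, te)
    expect_lt(abs(f$T2 - or$par[["T2"]]), 4 * or$step[["T2"]])
  }
})

test_that("non-positive signals fall back to the nonlinear T2 path", {
  te <- c(16, 26, 36, 60)
  s <- 50 * exp(-te / 12); s[4] <- 0
  f <- fit_t2_pixel(s, te)
  expect_true(f$converged)
  expect_equal(f$T2, 12, tolerance = 0.05)     # one corrupted echo of four
  expect_false(fit_t2_pixel(c(0, 0, 0), te[1:3])$converged)
})

test_that("T2 maps recover bimodal phantoms; a single-pixel mask fits one pixel", {
  truth <- matrix(10.3, 12, 12); truth[, 7:12] <- 16.3
  ph <- make_t2_phantom(truth, noise_sd = 0, seed = 1)
  map <- fit_t2_map(ph$series)
  expect_equal(sort(unique(round(as.numeric(map$values), 6))), c(10.3, 16.3))

  mask <- matrix(FALSE, 12, 12); mask[5, 5] <- TRUE
  ph1 <- make_t2_phantom(truth, noise_sd = 0, mask = mask, seed = 1)
  map1 <- fit_t2_map(ph1$series)
  expect_equal(sum(is.finite(map1$values)), 1L)
  expect_equal(map1$values[5, 5], 10.3, tolerance = 1e-6)
})

test_that("T2 region means stay within 2% at first-echo SNR 30 (seed-averaged)", {
  truth <- matrix(10.3, 32, 32); truth[, 17:32] <- 16.3
  sd30 <- 1000 * exp(-16 / 10.3) / 30
  m <- vapply(1:5, function(s) {
    ph <- make_t2_phantom(truth, S0 = 1000, noise_sd = sd30, seed = s)
    map <- fit_t2_map(ph$series)
    c(map_roi_stats(map, truth == 10.3)$mean, map_roi_stats(map, truth == 16.3)$mean)
  }, numeric(2))
  expect_lt(abs(mean(m[1, ]) / 10.3 - 1), 0.02)
  expect_lt(abs(mean(m[2, ]) / 16.3 - 1), 0.02)
})

test_that("recovered-T1 error grows monotonically with noise level", {
  truth <- matrix(1200, 10, 10)
  sds <- c(5, 30, 120)
  rmse <- vapply(sds, function(sd) {
    errs <- vapply(1:4, function(s) {
      ph <- make_t1_phantom(truth, noise_sd = sd, seed = s)
      map <- fit_t1_map(ph$series)
      sqrt(mean((map$values - 1200)^2, na.rm = TRUE))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("ROI statistics reduce to direct summation", {
  mk <- function(v) structure(list(values = v, quality = v * 0, kind = "T1"),
                              class = "parametric_map")
  u <- mk(matrix(1320, 5, 5))
  s <- map_roi_stats(u, matrix(TRUE, 5, 5))
  expect_equal(s$mean, 1320); expect_equal(s$sd, 0); expect_equal(s$n, 25L)

  two <- mk(matrix(c(10, 20, NA, NA), 2, 2))
  s2 <- map_roi_stats(two, matrix(TRUE, 2, 2))
  expect_equal(s2$mean, 15)
  expect_equal(s2$sd, 7.071, tolerance = 1e-4)   # sample SD
  expect_equal(s2$n, 2L)

  set.seed(11)
  v <- matrix(rnorm(64, 1000, 50), 8, 8)
  roi <- matrix(runif(64) > 0.5, 8, 8)
  s3 <- map_roi_stats(mk(v), roi)
  expect_equal(s3$mean, sum(v[roi]) / sum(roi), tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((v[roi] - s3$mean)^2) / (sum(roi) - 1)),
               tolerance = 1e-12)
  expect_error(map_roi_stats(mk(v), matrix(FALSE, 8, 8)), "no valid pixels")
})
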