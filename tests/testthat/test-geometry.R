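circle <- function(r, n = 256L, c0 = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(c0[1] + r * cos(th), c0[2] + r * sin(th))
}

test_that("the rasterized annular wall matches the analytic annulus area", {
  g <- slice_geometry(circle(2), circle(4))
  wm <- wall_mask(g, spacing = 0.1)
  area <- sum(wm$mask) * 0.1^2
  expect_lt(abs(area / (pi * (16 - 4)) - 1), 0.02)
})

test_that("a sub-pixel wall rasterizes to an empty mask with a warning", {
  g <- slice_geometry(circle(2), circle(2.001), thickness = 2)
  expect_warning(wm <- wall_mask(g, spacing = 0.5), "empty")
  expect_false(any(wm$mask))
})

test_that("wall rasterization agrees with brute-force point-in-polygon", {
  set.seed(5)
  for (i in 1:3) {
    endo <- random_star_polygon(20, 2, 0.5)
    epi <- random_star_polygon(24, 4, 0.6)
    g <- slice_geometry(endo, epi)
    wm <- wall_mask(g, spacing = 0.25)
    pts <- expand.grid(x = wm$x, y = wm$y)
    ref <- oracle_point_in_poly(pts$x, pts$y, epi) &
      !oracle_point_in_poly(pts$x, pts$y, endo)
    expect_equal(as.logical(wm$mask), ref)
  }
})

test_that("the 15% offset moves circular borders by closed-form amounts", {
  g <- slice_geometry(circle(2), circle(4))
  g2 <- apply_offset(g, 0.15)
  r_endo <- sqrt(rowSums(g2$endo^2)); r_epi <- sqrt(rowSums(g2$epi^2))
  expect_equal(mean(r_endo), 2.3, tolerance = 1e-3)   # + 0.15 * 2 mm wall
  expect_equal(mean(r_epi), 3.7, tolerance = 1e-3)    # - 0.15 * 2 mm wall
  expect_identical(apply_offset(g, 0), g)             # offset 0 is the identity
  expect_error(apply_offset(g, 0.5), "0.5")
})

test_that("offsetting an elliptical wall retains 70% of the wall along every ray", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  endo <- cbind(3 * cos(th), 2 * sin(th))
  epi <- cbind(5 * cos(th), 3.6 * sin(th))
  g <- slice_geometry(endo, epi)
  g2 <- apply_offset(g, 0.15, n_theta = 720L)
  ctr <- pracma::poly_center(epi[, 1], epi[, 2])
  probe <- seq(0, 2 * pi, length.out = 37)[-37]
  r <- function(poly) cmrtox:::.radius_at_angles(poly, ctr, probe)
  w_old <- r(g$epi) - r(g$endo)
  w_new <- r(g2$epi) - r(g2$endo)
  expect_equal(w_new, 0.7 * w_old, tolerance = 5e-3)
})

test_that("repeating a 15% offset differs from a single 30% offset off-circle", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  g <- slice_geometry(cbind(3 * cos(th), 2 * sin(th)),
                      cbind(5 * cos(th), 3.6 * sin(th)))
  twice <- apply_offset(apply_offset(g, 0.15), 0.15)
  once <- apply_offset(g, 0.30)
  ctr <- pracma::poly_center(g$epi[, 1], g$epi[, 2])
  probe <- seq(0.1, 2 * pi, length.out = 19)
  d <- cmrtox:::.radius_at_angles(twice$endo, ctr, probe) -
    cmrtox:::.radius_at_angles(once$endo, ctr, probe)
  expect_gt(max(abs(d)), 1e-4)
})

test_that("segment division splits a symmetric annulus into equal quadrants", {
  g <- slice_geometry(circle(2), circle(4))
  wm <- wall_mask(g, spacing = 0.05)
  sm <- divide_segments(wm, centroid = c(0, 0), septal_direction = pi / 4)
  counts <- table(sm$labels[!is.na(sm$labels)])
  expect_setequal(names(counts), c("anterior", "inferior", "lateral", "septal"))
  expect_lt(diff(range(counts)) / mean(counts), 0.01)
  # union of segments is exactly the wall
  expect_equal(sum(counts), sum(wm$mask))
})

test_that("rotating the septal direction by 90 degrees permutes the labels", {
  g <- slice_geometry(circle(2), circle(4))
  wm <- wall_mask(g, spacing = 0.1)
  a <- divide_segments(wm, centroid = c(0, 0), septal_direction = 0)
  b <- divide_segments(wm, centroid = c(0, 0), septal_direction = pi / 2)
  # what was anterior (at +90 from septal) becomes septal
  perm <- c(anterior = "septal", lateral = "anterior",
            inferior = "lateral", septal = "inferior")
  expect_equal(unname(perm[a$labels[wm$mask]]), b$labels[wm$mask])
})

test_that("segment labels match a direct atan2 quadrant computation", {
  g <- slice_geometry(circle(2), circle(4))
  wm <- wall_mask(g, spacing = 0.2)
  sd_ang <- 0.7
  sm <- divide_segments(wm, centroid = c(0, 0), septal_direction = sd_ang)
  idx <- which(wm$mask, arr.ind = TRUE)
  ang <- atan2(wm$y[idx[, 2]], wm$x[idx[, 1]])
  rel <- (ang - sd_ang + pi / 4) %% (2 * pi)
  ref <- c("septal", "anterior", "lateral", "inferior")[floor(rel / (pi / 2)) + 1]
  expect_equal(sm$labels[wm$mask], ref)
})

test_that("disc summation reproduces cylinders and scales as volume", {
  one <- slice_geometry(circle(3, 512), circle(4, 512), thickness = 2, gap = 0)
  v <- lv_volumes(list(one))
  expect_equal(v, pi * 9 * 2 / 1000, tolerance = 1e-3)   # 0.0565 ml

  set.seed(9)
  stack <- lapply(1:4, function(i)
    slice_geometry(random_star_polygon(30, 3, 0.5), random_star_polygon(30, 5, 0.5),
                   thickness = 1.5, gap = 0.5))
  v1 <- lv_volumes(stack)
  stack2 <- lapply(stack, function(s)
    slice_geometry(s$endo * 2, s$epi * 2, s$thickness * 2, s$gap * 2))
  expect_equal(lv_volumes(stack2), 8 * v1, tolerance = 1e-10)

  # shoelace oracle
  v_ref <- sum(vapply(stack, function(s)
    oracle_shoelace(s$endo) * (s$thickness + s$gap), numeric(1))) / 1000
  expect_equal(v1, v_ref, tolerance = 1e-12)
})

test_that("LV function identities and the cohort worked examples hold", {
  # control-like means: EDV 0.69, ESV 0.18 -> SV 0.51
  f <- lv_function(0.69, 0.18, hr = 281, wall_volume = 0.63)
  expect_equal(f$LVSV, 0.51)
  expect_equal(f$LVEF, 100 * 0.51 / 0.69)
  expect_equal(f$CO, 0.51 * 281 / 1000)
  expect_equal(f$LVmass, 0.63 * 1.05)
  # 12-week-like means: EDV 0.63, ESV 0.26, HR 292 -> SV 0.37, CO ~ 0.108
  f5 <- lv_function(0.63, 0.26, hr = 292)
  expect_equal(f5$LVSV, 0.37)
  expect_equal(f5$CO, 0.10804, tolerance = 1e-5)
  # identities on random inputs
  set.seed(2)
  for (i in 1:20) {
    edv <- runif(1, 0.4, 1); esv <- runif(1, 0, edv); hr <- runif(1, 200, 400)
    g <- lv_function(edv, esv, hr)
    expect_equal(g$LVSV, g$LVEDV - g$LVESV)
    expect_equal(g$LVEF, 100 * g$LVSV / g$LVEDV)
    expect_true(g$LVEF >= 0 && g$LVEF <= 100)
    expect_equal(g$CO, g$LVSV * hr / 1000)
  }
  ez <- lv_function(0.5, 0.5)
  expect_equal(ez$LVSV, 0); expect_equal(ez$LVEF, 0)
  expect_error(lv_function(0.5, 0.6), "ESV")
})

test_that("blood ROI validation enforces the < 5 mm^2 in-cavity convention", {
  endo <- circle(3)
  roi <- blood_roi(c(0.5, 0), 1.1, endo)
  expect_lt(roi$area, 5)
  expect_error(blood_roi(c(0, 0), 1.3, endo), "5 mm")       # pi * 1.3^2 > 5
  expect_error(blood_roi(c(2.5, 0), 1.0, endo), "endocardial")
  pap <- circle(0.8, c0 = c(1.5, 0))
  expect_error(blood_roi(c(0.5, 0), 1.1, endo, exclude = pap), "papillary")
  ok <- blood_roi(c(-0.9, 0), 0.9, endo, exclude = pap)
  expect_s3_class(ok, "blood_roi")
})

test_that("ED/ES phases are picked by extremal cavity area", {
  phases <- list(p1 = list(slice_geometry(circle(2.5), circle(4))),
                 p2 = list(slice_geometry(circle(3.2), circle(4.5))),
                 p3 = list(slice_geometry(circle(1.8), circle(3.8))))
  sel <- select_ed_es(phases)
  expect_equal(sel$ED, "p2")
  expect_equal(sel$ES, "p3")
})
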