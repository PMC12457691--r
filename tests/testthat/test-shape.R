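stadium_contour <- function(length = 4, width = 0.8, n_points = 200) {
  simulate_bent_rod_contour(
    contour_sim_config(length = length, width = width, curvature = 0,
                       n_points = n_points))
}

test_that("the medial axis of a stadium is straight with constant width", {
  con <- stadium_contour()
  ma <- extract_medial_axis(con$contour)
  interior <- ma$centerline[2:(nrow(ma$centerline) - 1), ]
  expect_lt(max(abs(interior[, 2])), 1e-6)  # on the y = 0 axis
  # chords through the cylindrical body (clear of the cap chords) are the
  # cell diameter
  body <- !is.na(ma$width) & abs(ma$centerline[, 1]) < 1.4
  expect_equal(ma$width[body], rep(0.8, sum(body)), tolerance = 1e-3)
  ws <- width_stats(ma, spacing_um = 0.05)
  expect_lt(ws$width_variation_um, 0.01)
  expect_equal(ws$mean_width_um, 0.8, tolerance = 0.02)
  expect_equal(ws$length_um, 4, tolerance = 0.08)
})

test_that("bent-rod centerline curvature is recovered within 15%", {
  con <- simulate_bent_rod_contour(
    contour_sim_config(length = 4, width = 0.8, curvature = 0.2,
                       n_points = 220))
  ma <- extract_medial_axis(con$contour)
  cl <- ma$centerline
  # algebraic (Kasa) circle fit as the curvature oracle
  A <- cbind(2 * cl[, 1], 2 * cl[, 2], 1)
  sol <- qr.solve(A, rowSums(cl^2))
  r_fit <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  expect_lt(abs(1 / r_fit - 0.2) / 0.2, 0.15)
})

test_that("solidity is exact on analytic polygons and a raster oracle", {
  # any convex polygon has solidity 1
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(solidity(sq), 1, tolerance = 1e-12)
  hexa <- cbind(cos(seq(0, 5) * pi / 3), sin(seq(0, 5) * pi / 3))
  expect_equal(solidity(hexa), 1, tolerance = 1e-12)

  # notched rectangle: area 3, convex hull is the full 2x2 square (area 4)
  notched <- cbind(c(0, 2, 2, 1.5, 1.5, 0.5, 0.5, 0),
                   c(0, 0, 2, 2, 1, 1, 2, 2))
  expect_equal(solidity(notched), 0.75, tolerance = 1e-12)

  # polygon-pipeline solidity against dense rasterization areas
  con <- simulate_bent_rod_contour(
    contour_sim_config(length = 4, width = 0.8, curvature = 0.25,
                       n_points = 220))
  hull <- con$contour[grDevices::chull(con$contour), ]
  oracle <- raster_area(con$contour, res = 0.008) /
    raster_area(hull, res = 0.008)
  expect_equal(solidity(con$contour), oracle, tolerance = 0.01)

  expect_error(solidity(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("a symmetric stadium scores 1 on both asymmetries", {
  con <- stadium_contour()
  ma <- extract_medial_axis(con$contour)
  expect_equal(asymmetry(con$contour, "lateral", ma), 1, tolerance = 0.01)
  expect_equal(asymmetry(con$contour, "longitudinal", ma), 1,
               tolerance = 0.01)
})

test_that("solidity and lateral asymmetry fall monotonically with curvature", {
  ks <- c(0, 0.075, 0.15, 0.225, 0.3)
  sol <- lat <- lon <- wvar <- numeric(length(ks))
  for (i in seq_along(ks)) {
    con <- simulate_bent_rod_contour(
      contour_sim_config(length = 4, width = 0.8, curvature = ks[i],
                         n_points = 220))
    ma <- extract_medial_axis(con$contour)
    sol[i] <- solidity(con$contour)
    lat[i] <- asymmetry(con$contour, "lateral", ma)
    lon[i] <- asymmetry(con$contour, "longitudinal", ma)
    wvar[i] <- width_stats(ma, 0.05)$width_variation_um
  }
  expect_true(all(diff(sol) < 0))
  expect_true(all(diff(lat) < 0))
  # a uniform arc stays longitudinally symmetric: flat near 1, never above
  expect_true(all(lon <= 1 + 1e-9))
  expect_true(all(lon > 0.95))
  # width variation stays flat without width noise
  expect_true(all(wvar < 0.01))
})

test_that("width noise of known SD is recovered within 20%", {
  con <- simulate_bent_rod_contour(
    contour_sim_config(length = 4, width = 0.8, curvature = 0,
                       width_noise_sd = 0.05, n_points = 260, seed = 3))
  ws <- width_stats(extract_medial_axis(con$contour), spacing_um = 0.03)
  expect_lt(abs(ws$width_variation_um - 0.05) / 0.05, 0.20)
})

test_that("descriptors are invariant to rigid motion, reflection and vertex order", {
  con <- simulate_bent_rod_contour(
    contour_sim_config(length = 4, width = 0.8, curvature = 0.2,
                       n_points = 220))
  base <- shape_descriptors(con$contour, spacing_um = 0.05)

  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(con$contour %*% rot, 2, c(3, -1), "+")
  d_m <- shape_descriptors(moved, spacing_um = 0.05)

  mirrored <- cbind(con$contour[, 1], -con$contour[, 2])
  d_r <- shape_descriptors(mirrored, spacing_um = 0.05)

  reversed <- con$contour[rev(seq_len(nrow(con$contour))), ]
  d_v <- shape_descriptors(reversed, spacing_um = 0.05)

  for (d2 in list(d_m, d_r, d_v)) {
    expect_equal(d2$solidity, base$solidity, tolerance = 1e-6)
    expect_equal(d2$lateral_asymmetry, base$lateral_asymmetry,
                 tolerance = 0.02)
    expect_equal(d2$longitudinal_asymmetry, base$longitudinal_asymmetry,
                 tolerance = 0.02)
    expect_equal(d2$width_variation_um, base$width_variation_um,
                 tolerance = 0.005)
    expect_equal(d2$mean_width_um, base$mean_width_um, tolerance = 0.01)
    expect_equal(d2$length_um, base$length_um, tolerance = 0.05)
  }
})

test_that("mean width preserves the ordering of true cell widths", {
  w90 <- stadium_contour(width = 0.9)
  w75 <- stadium_contour(width = 0.75)
  m90 <- width_stats(extract_medial_axis(w90$contour), 0.05)$mean_width_um
  m75 <- width_stats(extract_medial_axis(w75$contour), 0.05)$mean_width_um
  expect_gt(m90, m75)
  expect_equal(m90, 0.9, tolerance = 0.02)
  expect_equal(m75, 0.75, tolerance = 0.02)
})

test_that("round cells and self-intersecting polygons are rejected", {
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  circle <- cbind(cos(th), sin(th))
  expect_error(extract_medial_axis(circle), "elongated")
  bowtie <- cbind(c(0, 2, 0, 2), c(0, 1, 1, 0))
  expect_error(extract_medial_axis(bowtie), "not simple")
})

test_that("label masks convert to usable contours", {
  # paint a horizontal rod (stadium) into a binary mask
  ps <- 0.065
  fp <- stadium_polygon(4, 0.9, center = c(2.5, 1.5))
  nr <- 48; nc <- 96
  cx <- ((seq_len(nc)) - 1) * ps
  cy <- ((seq_len(nr)) - 1) * ps
  grid <- cbind(rep(cx, each = nr), rep(cy, times = nc))
  mask <- matrix(rodtrack:::points_in_polygon(grid, fp), nr, nc)
  cons <- mask_to_contours(mask, pixel_size = ps)
  expect_equal(length(cons), 1)
  d <- shape_descriptors(cons[[1]], spacing_um = ps)
  expect_gt(d$solidity, 0.97)
  expect_equal(d$mean_width_um, 0.9, tolerance = 0.1)
  expect_equal(d$length_um, 4, tolerance = 0.15)
})
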