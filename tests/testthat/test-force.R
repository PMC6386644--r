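test_that("uniform pressure on a closed surface integrates to zero net force", {
  for (lev in c(2, 3)) {
    s <- assign_uniform_pressure(gen_closed_sphere(1, lev), 1e4)
    f <- integrate_force(s)
    expect_lt(f$magnitude, 1e-9 * 1e4 * sum(face_areas(s)))
  }
})

test_that("bend-tube pressure force converges to sqrt(2) p pi r^2 at second order", {
  p <- 15000; r <- 0.02
  expected <- sqrt(2) * p * pi * r^2 # 26.657 N
  err <- vapply(c(24, 48, 96), function(n) {
    m <- assign_uniform_pressure(
      gen_tube_mesh(r, 90, "bend", n, n, bend_radius = 0.05), p)
    abs(integrate_force(m)$magnitude - expected)
  }, 0)
  expect_lt(err[3] / expected, 1e-3)
  slope <- stats::coef(stats::lm(log(err) ~ log(1 / c(24, 48, 96))))[2]
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
})

test_that("Poiseuille shear force matches 8 mu L Q / r^2 by fine-mesh summation", {
  r <- 0.01; L <- 0.1; mu <- 0.004; Q <- 8.3333e-5
  m <- assign_poiseuille_fields(gen_tube_mesh(r, L, "straight", 128, 128),
                                Q, mu, inlet_pressure = 1e4)
  f <- integrate_force(m)
  shear_mag <- sqrt(sum(f$shear_part^2))
  expect_equal(shear_mag, 8 * mu * L * Q / r^2, tolerance = 5e-3) # 2.667e-3 N
  # shear force is purely axial (+z) for this tube
  expect_equal(f$shear_part[1:2], c(0, 0), tolerance = 1e-15)
  # the lateral pressure force of an axisymmetric field is axial as well
  expect_lt(abs(f$pressure_part[1]) / shear_mag, 1e-6)
})

test_that("force components decompose exactly into pressure and shear parts", {
  m <- gen_tube_mesh(0.015, 60, "bend", 32, 32, bend_radius = 0.06)
  set.seed(77)
  m$face_pressure <- runif(nrow(m$faces), 9e3, 1.6e4)
  m$face_shear <- matrix(rnorm(3 * nrow(m$faces), 0, 2), ncol = 3)
  f <- integrate_force(m)
  expect_identical(f$components, f$pressure_part + f$shear_part)
  expect_equal(f$magnitude, sqrt(sum(f$components^2)), tolerance = 1e-12)
})

test_that("integrate_force is additive in the fields", {
  m <- gen_tube_mesh(0.015, 60, "bend", 24, 24, bend_radius = 0.06)
  set.seed(78)
  nf <- nrow(m$faces)
  p1 <- runif(nf, 0, 2e4); p2 <- runif(nf, -5e3, 5e3)
  s1 <- matrix(rnorm(3 * nf), ncol = 3); s2 <- matrix(rnorm(3 * nf), ncol = 3)
  fa <- integrate_force(within_fields(m, p1, s1))
  fb <- integrate_force(within_fields(m, p2, s2))
  fab <- integrate_force(within_fields(m, p1 + p2, s1 + s2))
  expect_equal(fab$components, fa$components + fb$components,
               tolerance = 1e-12)
})

test_that("physiologic fields are pressure-dominated", {
  # uniform systolic pressure plus a 5 Pa sweep-aligned shear on a 90° bend
  m <- gen_tube_mesh(0.02, 90, "bend", 64, 64, bend_radius = 0.05)
  m <- assign_uniform_pressure(m, 1.5e4)
  ctr <- face_centers(m)
  phi <- atan2(ctr[, 3], ctr[, 1])
  m$face_shear <- 5 * cbind(-sin(phi), 0, cos(phi))
  f <- integrate_force(m)
  expect_lt(sqrt(sum(f$shear_part^2)), 0.01 * sqrt(sum(f$pressure_part^2)))
})

test_that("missing fields and empty meshes are reported", {
  m <- gen_tube_mesh(0.01, 0.1, "straight", 16, 16)
  expect_error(integrate_force(m), "field error")
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3),
                          face_pressure = NULL, face_shear = NULL,
                          closed = FALSE), class = "tri_surface")
  expect_warning(a <- graft_surface_area(empty), "empty mesh")
  expect_equal(a, 0)
})

test_that("systolic peak time is found in the last cycle, earliest on ties", {
  tr <- pressure_trace(seq(0, 1, 0.01), c(rep(80, 30), 120, rep(80, 70)),
                       cycle_starts = 1L, period_s = 1)
  expect_equal(systolic_peak_time(tr), 0.30)
  flat <- pressure_trace(seq(0, 2, 0.01), rep(90, 201),
                         cycle_starts = c(1L, 101L), period_s = 1)
  expect_equal(systolic_peak_time(flat), 1.0) # first sample of last cycle
  # on a Windkessel trace the peak falls in the systolic third of the cycle
  w <- demo_inflow()
  tr_wk <- simulate_wk3(wk3_params(0.09, 1.2, 0.91), w)
  tpk <- systolic_peak_time(last_cycle(tr_wk))
  expect_lt(tpk, w$period / 3)
})

test_that("anatomical direction classification follows the frame convention", {
  expect_equal(classify_direction(force_vector(c(-1, 0, 1)))$label,
               "dorsocranial")
  expect_equal(classify_direction(force_vector(c(1, 0, -1)))$label,
               "ventrocaudal")
  expect_equal(classify_direction(force_vector(c(1, 0, 1)))$label,
               "ventrocranial")
  expect_equal(classify_direction(force_vector(c(-1, 0, -1)))$label,
               "dorsocaudal")
  expect_error(classify_direction(force_vector(c(0, 0, 0))),
               "undefined direction")
  # boundary flag within 5 degrees of a separating plane
  near <- classify_direction(force_vector(c(-0.05, 0, 1)))
  expect_true(near$boundary)
  diag45 <- classify_direction(force_vector(c(-1, 0, 1)))
  expect_false(diag45$boundary)
})

test_that("force_report bundles magnitude, direction and surface area", {
  m <- assign_uniform_pressure(
    gen_tube_mesh(0.02, 90, "bend", 48, 48, bend_radius = 0.05), 1.5e4)
  rep <- force_report(m)
  expect_equal(rep$magnitude_N, sqrt(2) * 1.5e4 * pi * 0.02^2, tolerance = 5e-3)
  expect_equal(rep$surface_area_cm2, (pi / 2) * 0.05 * 2 * pi * 0.02 * 1e4,
               tolerance = 5e-3)
  # bend sweeps from +z toward +x: net pressure force points up-and-forward
  expect_equal(rep$direction, "ventrocranial")
})
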