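test_that("Stokes-Einstein diffusivity evaluates the formula exactly", {
  cpa <- list(eta = 1e-3, r_hydro = 1e-10)
  expect_equal(stokes_einstein_D(cpa, 300),
               1.380649e-23 * 300 / (6 * pi * 1e-3 * 1e-10),
               tolerance = 1e-12)
  ## doubling the radius halves D
  cpa2 <- list(eta = 1e-3, r_hydro = 2e-10)
  expect_equal(stokes_einstein_D(cpa2, 300) * 2,
               stokes_einstein_D(cpa, 300), tolerance = 1e-12)
  expect_error(stokes_einstein_D(cpa, -5))
  ## registry values land near 1e-9 m^2/s at room temperature
  expect_gt(stokes_einstein_D(cpa_properties("EG"), 296.15), 5e-10)
  expect_lt(stokes_einstein_D(cpa_properties("EG"), 296.15), 2e-9)
  expect_lt(stokes_einstein_D(cpa_properties("PG"), 296.15),
            stokes_einstein_D(cpa_properties("EG"), 296.15))
})

test_that("uniform inlets give a uniform field", {
  g <- channel_geometry(L = 20000)
  fld <- solve_coflow(g, flow_condition(c1 = 1, c2 = 1),
                      stokes_einstein_D(ref_cpa(), 296.15), ny = 40)
  expect_equal(range(fld$c), c(1, 1), tolerance = 1e-12)
  expect_equal(fld$report$c_out_mean, 1, tolerance = 1e-12)
})

test_that("vanishing diffusivity leaves two unmixed lamellae", {
  g <- channel_geometry(L = 20000)
  fld <- solve_coflow(g, flow_condition(c1 = 1.5, c2 = 0.5), D = 1e-16,
                      ny = 40)
  expect_lt(utils::tail(fld$report$mixing_index$mixing_index, 1), 0.01)
  mid <- fld$c[nrow(fld$c), ]
  expect_equal(mid[1], 1.5, tolerance = 1e-6)
  expect_equal(mid[40], 0.5, tolerance = 1e-6)
})

test_that("flux-weighted mean is the inlet average at every station", {
  g <- channel_geometry(L = 40000)
  fld <- solve_coflow(g, flow_condition(), stokes_einstein_D(ref_cpa(), 296.15),
                      ny = 60)
  fw <- as.numeric(fld$c %*% fld$u) / sum(fld$u)
  expect_rel_equal(fw, rep(1.0, length(fw)), 1e-9)
  ## maximum principle
  expect_gte(min(fld$c), 0.5 - 1e-9)
  expect_lte(max(fld$c), 1.5 + 1e-9)
  ## mixing index is monotone along the channel
  expect_true(all(diff(fld$report$mixing_index$mixing_index) > -1e-12))
})

test_that("swapping the inlets mirrors the field about the midline", {
  g <- channel_geometry(L = 30000)
  D <- stokes_einstein_D(ref_cpa(), 296.15)
  a <- solve_coflow(g, flow_condition(c1 = 1.5, c2 = 0.5), D, ny = 60)
  b <- solve_coflow(g, flow_condition(c1 = 0.5, c2 = 1.5), D, ny = 60)
  expect_equal(a$c, b$c[, 60:1], tolerance = 1e-12)
})

test_that("cross-stream discretisation converges at second order", {
  g <- channel_geometry(L = 40000)
  f <- flow_condition()
  D <- stokes_einstein_D(ref_cpa(), 296.15)
  vals <- vapply(c(30, 60, 120, 240), function(ny) {
    dy <- g$W / ny
    fld <- solve_coflow(g, f, D, ny = ny, dx = 2 * dy^2)
    utils::tail(fld$report$mixing_index$mixing_index, 1)
  }, 0)
  err <- diff(vals)                       # successive Richardson differences
  order1 <- log2(abs(err[1] / err[2]))
  order2 <- log2(abs(err[2] / err[3]))
  expect_gt(min(order1, order2), 1.8)
  expect_lt(max(order1, order2), 2.2)
})

test_that("mixing profile interpolates inlet and outlet values", {
  g <- channel_geometry(L = 3e5)
  D <- stokes_einstein_D(ref_cpa(), 296.15)
  fld <- solve_coflow(g, flow_condition(), D, ny = 60)
  ## stream-1 side of the junction carries c1
  expect_equal(mixing_profile(fld, 0, 20)$c_M, 1.5, tolerance = 1e-9)
  ## converged outlet: the average of the two inlets
  expect_equal(mixing_profile(fld, g$L, g$W / 2)$c_M, 1.0, tolerance = 0.01)
  ## midline profile settles monotonically toward 1.0 after the entrance
  xs <- seq(0.2 * g$L, g$L, length.out = 40)
  prof <- mixing_profile(fld, xs, g$W / 2)$c_M
  expect_true(all(diff(prof) <= 1e-9) || all(diff(prof) >= -1e-9))
  expect_error(mixing_profile(fld, -10, 20), "outside")
})

test_that("capture-region shear follows 6Q/(W H^2)", {
  g <- channel_geometry()
  expect_equal(capture_region_shear(g, 10),
               6 * (10 * 1e9 / 60) / (200 * 150^2), tolerance = 1e-12)
  expect_equal(capture_region_shear(g, 10), 222, tolerance = 0.01)
  expect_equal(capture_region_shear(g, 20), 2 * capture_region_shear(g, 10))
  ## 30 uL/min bubble-purge rate is exactly 3x the perfusion value
  expect_equal(capture_region_shear(g, 30), 3 * capture_region_shear(g, 10))
})

test_that("washout time is dead volume over flow rate", {
  g <- channel_geometry()
  ## 0.01 uL dead volume at 10 uL/min -> 0.06 s
  dead_len <- 0.01 * 1e9 / (g$W * g$H)
  expect_equal(washout_time(g, 10, dead_length_um = dead_len), 0.06,
               tolerance = 1e-12)
  expect_lt(washout_time(g, 1e6), 1e-3)
  ## independent check: trapezoidal summation of segment volumes
  segs <- seq(0, 2000, by = 10)
  vol_trap <- sum(diff(segs) * g$W * g$H)
  expect_equal(washout_time(g, flow_condition(), dead_length_um = 2000),
               vol_trap / (20 * 1e9 / 60), tolerance = 1e-9)
})
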