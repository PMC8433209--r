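test_that("isotonic environment is a fixed point of the 2-p system", {
  traj <- simulate_2p(ref_params(), ref_geom(), perfusion_env(m_cpa = 0),
                      ref_cpa(), seq(0, 600, by = 20))
  expect_equal(traj$v_norm, rep(1, nrow(traj)), tolerance = 1e-8)
})

test_that("impermeant hypertonic challenge reaches the Boyle-van 't Hoff volume", {
  geom <- ref_geom()
  p0 <- membrane_params(0.8, 0)                  # Ps = 0: impermeant
  env <- perfusion_env(m_salt_e = 2 * 0.29, m_cpa = 0, m_salt_iso = 0.29)
  closed <- geom$vb + (1 - geom$vb) / 2
  expect_equal(equilibrium_volume(p0, geom, env, ref_cpa()), closed,
               tolerance = 1e-12)
  sim <- simulate_2p(p0, geom, env, ref_cpa(), c(0, 3000))
  expect_equal(sim$v_norm[2], closed, tolerance = 1e-6)
})

test_that("with Ps = 0 no CPA enters: solute amount stays exactly zero", {
  geom <- ref_geom()
  p0 <- membrane_params(0.8, 0)
  env <- perfusion_env(m_cpa = 1.5)
  ## CPA contributes to volume only via ns * vbar; with two CPAs of very
  ## different vbar the trajectory must be identical if ns == 0
  a <- simulate_2p(p0, geom, env, cpa_properties("EG"), seq(0, 300, 10))
  b <- simulate_2p(p0, geom, env, cpa_properties("PG"), seq(0, 300, 10))
  expect_identical(a$v_norm, b$v_norm)
  ## and the equilibrium is the impermeant closed form
  expect_equal(min(a$v_norm),
               equilibrium_volume(p0, geom, env, cpa_properties("EG")),
               tolerance = 1e-4)
})

test_that("permeant equilibrium matches the numerically solved 2-eq system", {
  geom <- ref_geom(); cpa <- ref_cpa()
  env <- perfusion_env(m_cpa = 1.5)
  ## independent oracle: solve water balance + concentration equality for
  ## Vw with uniroot, without using the closed form
  Vw0 <- (1 - geom$vb) * geom$V0
  n_salt <- env$m_salt_iso * Vw0
  f <- function(Vw) (n_salt + env$m_cpa * Vw) / Vw - (env$m_salt_e + env$m_cpa)
  Vw_eq <- stats::uniroot(f, c(1e-3 * Vw0, 10 * Vw0), tol = 1e-12)$root
  v_oracle <- (Vw_eq + env$m_cpa * Vw_eq * cpa$vbar + geom$vb * geom$V0) / geom$V0
  expect_equal(equilibrium_volume(ref_params(), geom, env, cpa), v_oracle,
               tolerance = 1e-9)
  ## vb -> 1 limit: nothing osmotically active, v stays 1
  geom1 <- cell_geometry(vb = 1 - 1e-9)
  expect_equal(equilibrium_volume(ref_params(), geom1, env, cpa), 1,
               tolerance = 1e-6)
})

test_that("adaptive solution matches the fixed-step RK4 reference", {
  geom <- ref_geom()
  tt <- seq(0, 600, by = 20)
  a <- simulate_2p(ref_params(), geom, perfusion_env(m_cpa = 1.5),
                   ref_cpa(), tt)
  b <- simulate_2p_rk4(ref_params(), geom, perfusion_env(m_cpa = 1.5),
                       ref_cpa(), tt, dt = 1e-3)
  expect_rel_equal(a$v_norm, b$v_norm, 1e-5)
})

test_that("permeant step produces shrink-then-swell with one interior minimum", {
  traj <- ref_trajectory()
  mv <- min_volume(traj)
  expect_lt(mv$v_min, traj$v_norm[1])
  expect_lt(mv$v_min, traj$v_norm[nrow(traj)])
  expect_gt(mv$t_min, traj$time_s[1])
  ## single sign change of the derivative at the sampling resolution
  d <- diff(traj$v_norm)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  ## ties broken by earliest time on a constant trajectory
  flat <- volume_trajectory(0:5, rep(1, 6))
  expect_equal(min_volume(flat), list(t_min = 0, v_min = 1))
})

test_that("minimum volume deepens with CPA concentration", {
  vmins <- vapply(c(0.5, 1.0, 1.5), function(conc) {
    min_volume(simulate_2p(ref_params(), ref_geom(),
                           perfusion_env(m_cpa = conc), ref_cpa(),
                           seq(0, 600, by = 2)))$v_min
  }, 0)
  expect_true(all(diff(vmins) < 0))
})

test_that("trajectory depends on Lp*A and Ps*A only (dimensional consistency)", {
  geom <- ref_geom()
  geom2 <- cell_geometry(V0 = geom$V0, vb = geom$vb, A = 2 * geom$A)
  env <- perfusion_env(m_cpa = 1.5)
  tt <- seq(0, 600, by = 10)
  a <- simulate_2p(membrane_params(0.8, 0.25), geom, env, ref_cpa(), tt)
  b <- simulate_2p(membrane_params(0.4, 0.125), geom2, env, ref_cpa(), tt)
  expect_equal(a$v_norm, b$v_norm, tolerance = 1e-9)
})

test_that("ramped boundary condition converges to the step response", {
  geom <- ref_geom(); tt <- seq(0, 600, by = 10)
  step <- simulate_2p(ref_params(), geom, perfusion_env(m_cpa = 1.5),
                      ref_cpa(), tt)
  ramp <- simulate_2p(ref_params(), geom,
                      perfusion_env(m_cpa = 1.5, schedule = "ramp",
                                    tau = 0.05), ref_cpa(), tt)
  expect_equal(ramp$v_norm, step$v_norm, tolerance = 1e-3)
  ## a slow ramp shallows the minimum
  slow <- simulate_2p(ref_params(), geom,
                      perfusion_env(m_cpa = 1.5, schedule = "ramp",
                                    tau = 30), ref_cpa(), tt)
  expect_gt(min_volume(slow)$v_min, min_volume(step)$v_min)
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_2p(ref_params(), ref_geom(),
                           perfusion_env(m_cpa = 1.5), ref_cpa(),
                           c(0, 10, 10, 20)), "strictly increasing")
  expect_error(volume_trajectory(c(0, 1), c(1, -0.2)), "positive")
  expect_error(membrane_params(-1, 0.2))
  expect_error(membrane_params(0.8, -0.1))
  expect_error(cell_geometry(vb = 1.2))
  expect_error(cpa_properties("DMSO"), "unknown CPA")
})
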