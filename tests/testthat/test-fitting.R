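test_that("normalize_volume divides by the first sample", {
  tr <- normalize_volume(c(0, 10, 20), c(100, 80, 90))
  expect_equal(tr$v_norm, c(1.0, 0.8, 0.9))
  expect_equal(normalize_volume(0:2, rep(7, 3))$v_norm, rep(1, 3))
  expect_error(normalize_volume(0:2, c(0, 80, 90)), "positive")
})

test_that("noise-free self-fit recovers the generating parameters", {
  fit <- fit_2p(ref_trajectory(), ref_geom(), perfusion_env(m_cpa = 1.5),
                ref_cpa())
  expect_true(fit$converged)
  expect_lt(abs(fit$params$Lp - 0.8) / 0.8, 1e-3)
  expect_lt(abs(fit$params$Ps - 0.25) / 0.25, 1e-3)
  expect_lt(fit$rmse, 1e-6)
  ## covariance is symmetric positive semidefinite
  expect_equal(fit$cov, t(fit$cov))
  expect_true(all(eigen(fit$cov, symmetric = TRUE)$values >= -1e-20))
})

test_that("estimator is invariant to rescaling raw volumes", {
  traj <- ref_trajectory()
  geom <- ref_geom(); env <- perfusion_env(m_cpa = 1.5)
  V0 <- geom$V0
  raw <- traj$v_norm * V0
  f1 <- fit_2p(normalize_volume(traj$time_s, raw), geom, env, ref_cpa())
  f2 <- fit_2p(normalize_volume(traj$time_s, raw * 3.7), geom, env, ref_cpa())
  expect_equal(f1$params$Lp, f2$params$Lp, tolerance = 1e-10)
  expect_equal(f1$params$Ps, f2$params$Ps, tolerance = 1e-10)
})

test_that("bias of both estimators shrinks as noise shrinks", {
  traj <- ref_trajectory()
  geom <- ref_geom(); env <- perfusion_env(m_cpa = 1.5)
  rng <- cryoperm:::.seeded_rng(314)
  med_err <- vapply(c(0.02, 0.005), function(sigma) {
    errs <- vapply(1:8, function(k) {
      v <- pmax(traj$v_norm + sigma * rng$rnorm(nrow(traj)), 0.25)
      f <- fit_2p(volume_trajectory(traj$time_s, v), geom, env, ref_cpa(),
                  init = membrane_params(0.5, 0.5))
      max(abs(f$params$Lp - 0.8) / 0.8, abs(f$params$Ps - 0.25) / 0.25)
    }, 0)
    stats::median(errs)
  }, 0)
  expect_lt(med_err[2], med_err[1])
  expect_lt(med_err[2], 0.02)
})

test_that("a Ps = 0 ground truth is recovered at the Ps lower bound", {
  geom <- ref_geom()
  ## CPA present outside but never entering: the absence of re-swelling
  ## identifies Ps = 0
  env <- perfusion_env(m_cpa = 1.5)
  tt <- seq(0, 600, by = 10)
  traj <- simulate_2p(membrane_params(0.8, 0), geom, env, ref_cpa(), tt)
  fit <- fit_2p(traj, geom, env, ref_cpa())
  expect_true(fit$converged)
  expect_lt(abs(fit$params$Lp - 0.8) / 0.8, 1e-3)
  expect_lt(fit$params$Ps, 1e-3)
  ## and the plateau matches the impermeant closed form
  expect_equal(min(traj$v_norm),
               equilibrium_volume(membrane_params(0.8, 0), geom, env,
                                  ref_cpa()), tolerance = 1e-4)
})

test_that("flat isotonic trajectory is flagged unidentifiable", {
  geom <- ref_geom(); env <- perfusion_env(m_cpa = 0)
  traj <- simulate_2p(ref_params(), geom, env, ref_cpa(), seq(0, 100, 10))
  expect_warning(fit <- fit_2p(traj, geom, env, ref_cpa()),
                 "identifiable")
  expect_false(fit$identifiable)
  expect_lt(fit$rmse, 1e-8)     # every parameter pair fits a flat line
})

test_that("residuals of a correct-model fit are white (Durbin-Watson)", {
  traj <- ref_trajectory()
  rng <- cryoperm:::.seeded_rng(271)
  v <- pmax(traj$v_norm + 0.01 * rng$rnorm(nrow(traj)), 0.25)
  fit <- fit_2p(volume_trajectory(traj$time_s, v), ref_geom(),
                perfusion_env(m_cpa = 1.5), ref_cpa(),
                init = membrane_params(0.5, 0.5))
  r <- fit$residuals
  dw <- sum(diff(r)^2) / sum(r^2)
  expect_gt(dw, 1.5)
  expect_lt(dw, 2.5)
})

test_that("concentration series recovers an imposed monotone Lp trend", {
  geom <- ref_geom(); cpa <- ref_cpa()
  conc <- c(0.5, 1.0, 1.5); Lps <- c(0.6, 0.8, 1.0)
  tt <- seq(0, 600, by = 10)
  trajs <- lapply(seq_along(conc), function(i)
    simulate_2p(membrane_params(Lps[i], 0.25), geom,
                perfusion_env(m_cpa = conc[i]), cpa, tt))
  names(trajs) <- conc
  ser <- fit_concentration_series(trajs, geom, cpa)
  expect_false(ser$partial)
  expect_true(all(diff(ser$table$Lp) > 0))
  expect_equal(unname(ser$trend["Lp"]), "increasing")
})

test_that("identical-parameter series is reported flat", {
  geom <- ref_geom(); cpa <- ref_cpa()
  tt <- seq(0, 600, by = 10)
  trajs <- lapply(c(0.5, 1.0, 1.5), function(cc)
    simulate_2p(ref_params(), geom, perfusion_env(m_cpa = cc), cpa, tt))
  names(trajs) <- c(0.5, 1.0, 1.5)
  ser <- fit_concentration_series(trajs, geom, cpa)
  expect_equal(max(ser$table$Lp) - min(ser$table$Lp), 0, tolerance = 1e-3)
  expect_equal(unname(ser$trend["Lp"]), "flat")
  expect_equal(unname(ser$trend["Ps"]), "flat")
})

test_that("series preconditions are enforced", {
  tr <- ref_trajectory()
  expect_error(fit_concentration_series(stats::setNames(list(tr), "1.5"),
                                        ref_geom(), ref_cpa()), ">= 2")
  expect_error(fit_2p(volume_trajectory(0:5, rep(1, 6)), ref_geom(),
                      perfusion_env(), ref_cpa()), "at least 10")
})

test_that("trajectory CSV round-trips exactly", {
  tr <- ref_trajectory()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$v_norm, tr$v_norm, tolerance = 1e-12)
  header <- readLines(path, n = 1)
  expect_equal(header, "time_s,v_norm")
})
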