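## Nonlinear least-squares estimation of (Lp, Ps) from normalised
## volume-time data, and the concentration-dependence analysis across the
## three perfusion channels.

#' Normalise raw volumes to the first sample
#'
#' `v_norm[i] = V[i] / V[1]`, removing between-oocyte size differences;
#' the first sample must be taken at isotonic equilibrium.
#'
#' @param times seconds, strictly increasing.
#' @param raw_volumes volumes, um^3 (any consistent unit; the fit is
#'   invariant to rescaling).
#' @return [volume_trajectory()].
#' @export
normalize_volume <- function(times, raw_volumes) {
  stopifnot(length(times) == length(raw_volumes))
  if (!is.finite(raw_volumes[1]) || raw_volumes[1] <= 0)
    stop("first (isotonic) volume must be positive")
  volume_trajectory(times, raw_volumes / raw_volumes[1])
}

## residual vector for the LM optimiser; th = (log Lp, log(Ps + eps)) is
## handled by the caller -- here plain (Lp, Ps)
.resid_2p <- function(par, trajectory, geom, env, cpa, rtol) {
  params <- membrane_params(max(par[1], 1e-8), max(par[2], 0))
  sim <- simulate_2p(params, geom, env, cpa, trajectory$time_s,
                     rtol = rtol, atol = rtol * 1e-2)
  sim$v_norm - trajectory$v_norm
}

#' Fit the two-parameter transport model to a volume trajectory
#'
#' Unweighted nonlinear least squares of [simulate_2p()] against observed
#' normalised volume, by bounded Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). Unless an initial guess is supplied, five
#' log-spaced multi-starts (seeded, so reproducible) are run and the best
#' optimum kept. The parameter covariance is the Jacobian-based
#' linearisation at the optimum.
#'
#' A trajectory whose osmotic excursion is too small carries no
#' information on (Lp, Ps); when `min(v_norm) > 0.97` the result is
#' flagged `identifiable = FALSE` and a warning is raised.
#'
#' @param trajectory [volume_trajectory()] (>= 10 samples).
#' @param geom [cell_geometry()].
#' @param env [perfusion_env()] of the challenge.
#' @param cpa [cpa_properties()].
#' @param init optional [membrane_params()] initial guess; when given, the
#'   fit starts there only.
#' @param lower,upper box bounds on (Lp, Ps).
#' @param rtol forward-simulation tolerance used inside the fit.
#' @param n_starts number of multi-start points when `init` is absent.
#' @param seed RNG seed for the multi-start draw.
#' @return list of class `fit_2p` with `params` ([membrane_params()]),
#'   `rmse`, `cov` (2x2), `n_iter`, `converged`, `identifiable`, `env`,
#'   `residuals`.
#' @export
fit_2p <- function(trajectory, geom, env, cpa, init = NULL,
                   lower = c(Lp = 1e-4, Ps = 0), upper = c(Lp = 100, Ps = 100),
                   rtol = 1e-8, n_starts = 5, seed = 1729) {
  stopifnot(inherits(trajectory, "volume_trajectory"))
  if (nrow(trajectory) < 10)
    stop("need at least 10 samples to fit the 2-p model")
  if (any(trajectory$v_norm <= geom$vb) || any(trajectory$v_norm > 2))
    stop("v_norm outside (vb, 2]: trajectory violates model invariants")

  identifiable <- min(trajectory$v_norm) <= 0.97
  if (!identifiable)
    warning("volume excursion < 3%: (Lp, Ps) weakly identifiable")

  starts <- if (!is.null(init)) {
    matrix(c(init$Lp, init$Ps), nrow = 1)
  } else {
    ## default centre (0.5, 0.5) plus log-spaced spread, deterministic
    rng <- .seeded_rng(seed)
    g <- cbind(Lp = exp(log(0.5) + rng$runif(n_starts - 1, -2, 2)),
               Ps = exp(log(0.5) + rng$runif(n_starts - 1, -2, 2)))
    rbind(c(0.5, 0.5), g)
  }

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[k, ], lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = .resid_2p, trajectory = trajectory,
                         geom = geom, env = env, cpa = cpa, rtol = rtol,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    return(structure(list(params = NULL, rmse = NA_real_, cov = NULL,
                          n_iter = 0L, converged = FALSE,
                          identifiable = identifiable, env = env,
                          residuals = NULL), class = "fit_2p"))

  n <- nrow(trajectory)
  rmse <- sqrt(best$deviance / n)
  covm <- tryCatch({
    JtJ <- best$hessian      # nls.lm stores t(J) %*% J
    sigma2 <- best$deviance / max(n - 2, 1)
    V <- sigma2 * solve(JtJ)
    dimnames(V) <- list(c("Lp", "Ps"), c("Lp", "Ps"))
    V
  }, error = function(e) NULL)
  converged <- best$info %in% 1:4
  structure(list(
    params = membrane_params(best$par[1], max(best$par[2], 0)),
    rmse = rmse, cov = covm, n_iter = best$niter,
    converged = converged, identifiable = identifiable, env = env,
    residuals = as.numeric(best$fvec)),
    class = "fit_2p")
}

#' @export
print.fit_2p <- function(x, ...) {
  if (is.null(x$params)) {
    cat("2-p fit: did not converge\n"); return(invisible(x))
  }
  cat(sprintf("2-p fit: Lp = %.4f um/min/atm, Ps = %.4f um/s (rmse %.4g%s%s)\n",
              x$params$Lp, x$params$Ps, x$rmse,
              if (x$converged) "" else ", NOT converged",
              if (x$identifiable) "" else ", weakly identifiable"))
  invisible(x)
}

#' Fit a concentration series and report the permeability trend
#'
#' Independent 2-p fits at each CPA concentration (one captured oocyte per
#' channel of the gradient chip), plus the sign of the Spearman rank
#' correlation of the fitted Lp and Ps against concentration --
#' "increasing", "flat" or "decreasing".
#'
#' @param trajectories named list of [volume_trajectory()]; names are the
#'   CPA concentrations in mol/L, strictly increasing.
#' @param geom,cpa as in [fit_2p()].
#' @param m_salt_e,temp_K environment shared across channels.
#' @param ... passed to [fit_2p()].
#' @param flat_tol relative spread below which the trend is called flat.
#' @return list of class `concentration_series`: `concentrations`, `fits`,
#'   `table` (data.frame `conc_M, Lp, Ps, rmse, converged`), `trend`
#'   (named character for Lp and Ps), `partial`.
#' @export
fit_concentration_series <- function(trajectories, geom, cpa,
                                     m_salt_e = 0.29, temp_K = 296.15,
                                     ..., flat_tol = 0.02) {
  conc <- as.numeric(names(trajectories))
  if (length(conc) < 2) stop("concentration series requires >= 2 concentrations")
  if (any(is.na(conc)) || any(diff(conc) <= 0))
    stop("names(trajectories) must be strictly increasing concentrations")
  fits <- lapply(seq_along(conc), function(i) {
    env <- perfusion_env(m_salt_e = m_salt_e, m_cpa = conc[i], temp_K = temp_K)
    fit_2p(trajectories[[i]], geom, env, cpa, ...)
  })
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tab <- data.frame(
    conc_M = conc,
    Lp = vapply(fits, function(f) if (is.null(f$params)) NA_real_ else f$params$Lp, 0),
    Ps = vapply(fits, function(f) if (is.null(f$params)) NA_real_ else f$params$Ps, 0),
    rmse = vapply(fits, function(f) f$rmse, 0),
    converged = ok)
  trend <- c(Lp = .trend_label(conc, tab$Lp, flat_tol),
             Ps = .trend_label(conc, tab$Ps, flat_tol))
  structure(list(concentrations = conc, fits = fits, table = tab,
                 trend = trend, cpa = cpa, partial = !all(ok)),
            class = "concentration_series")
}

.trend_label <- function(x, y, flat_tol) {
  if (any(is.na(y))) return(NA_character_)
  spread <- (max(y) - min(y)) / max(mean(y), .Machine$double.eps)
  if (spread < flat_tol) return("flat")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  if (is.na(rho) || rho == 0) "flat" else if (rho > 0) "increasing" else "decreasing"
}

#' Read / write trajectory CSV
#'
#' Plain-text interchange format: header `time_s, v_norm`, UTF-8,
#' '.' decimal.
#' @param trajectory [volume_trajectory()].
#' @param path file path.
#' @return `read_trajectory_csv` returns a [volume_trajectory()].
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[, c("time_s", "v_norm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "v_norm") %in% names(d)))
    stop("trajectory CSV must have columns time_s, v_norm")
  volume_trajectory(d$time_s, d$v_norm)
}

## Small local RNG stream (xorshift-based via R, isolated so package code
## never disturbs the caller's .Random.seed).
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample_int = with_state(function(n) sample.int(n)))
}
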