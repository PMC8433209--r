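## Two-parameter (2-p) membrane transport model: coupled ODEs for the cell
## water volume Vw and the intracellular permeant-cryoprotectant amount Ns.
## No reflection coefficient: water flux is driven by the total osmolality
## difference, solute flux by the CPA concentration difference.
##
##   dVw/dt = -Lp A R T [ (m_salt_e + m_cpa_e(t)) - (n_salt + n_s)/Vw ]
##   dNs/dt =  Ps A [ m_cpa_e(t) - n_s/Vw ]
##   V(t)   =  Vw + n_s vbar + vb V0
##
## with n_salt = m_salt_iso * Vw(0) the fixed intracellular impermeant
## content, and surface area A held at the isotonic spherical value.

#' Membrane permeability parameters
#'
#' The two estimands of the perfusion experiment: hydraulic conductivity
#' `Lp` (um min^-1 atm^-1) and cryoprotectant permeability `Ps` (um s^-1).
#' `Ps = 0` encodes an impermeant solute.
#'
#' @param Lp hydraulic conductivity, um min^-1 atm^-1; must be > 0.
#' @param Ps solute permeability, um s^-1; must be >= 0.
#' @return list of class `membrane_params`.
#' @export
membrane_params <- function(Lp, Ps) {
  stopifnot(is.numeric(Lp), length(Lp) == 1, Lp > 0,
            is.numeric(Ps), length(Ps) == 1, Ps >= 0)
  structure(list(Lp = Lp, Ps = Ps), class = "membrane_params")
}

#' Cell geometry
#'
#' Isotonic total volume `V0` (um^3), osmotically inactive fraction `vb`,
#' and membrane surface area `A` (um^2). By default `A` is fixed at the
#' isotonic spherical value `4 pi r0^2` (the zona pellucida keeps captured
#' oocytes near-spherical, so area is treated as constant during the
#' shrink--swell excursion). Supplying `A` overrides the spherical default.
#'
#' The default `V0` corresponds to a 35 um cytoplasm radius, typical for a
#' mouse oocyte without zona.
#'
#' @param V0 isotonic total cell volume, um^3.
#' @param vb osmotically inactive volume fraction, in (0, 1).
#' @param A optional surface area, um^2.
#' @return list of class `cell_geometry` with `V0`, `vb`, `A`, `r0`.
#' @export
cell_geometry <- function(V0 = 4 / 3 * pi * 35^3, vb = 0.19, A = NULL) {
  stopifnot(V0 > 0, vb > 0, vb < 1)
  r0 <- (3 * V0 / (4 * pi))^(1 / 3)
  if (is.null(A)) A <- 4 * pi * r0^2
  stopifnot(A > 0)
  structure(list(V0 = V0, vb = vb, A = A, r0 = r0), class = "cell_geometry")
}

#' Extracellular environment and CPA schedule
#'
#' Impermeant (salt) osmolality, the extracellular CPA concentration
#' schedule, and temperature. The schedule is either an instantaneous step
#' to `m_cpa` at t = 0 (the default) or an exponential ramp
#' `m_cpa (1 - exp(-t / tau))` modelling finite solution replacement in
#' the capture region; `tau` can be taken from [washout_time()].
#'
#' @param m_salt_e extracellular impermeant osmolality, osmol/L.
#' @param m_cpa target extracellular CPA concentration, mol/L.
#' @param temp_K absolute temperature, K (default room temperature 23 C).
#' @param schedule `"step"` or `"ramp"`.
#' @param tau ramp time constant, s (required for `"ramp"`).
#' @param m_salt_iso isotonic impermeant osmolality the cell was
#'   equilibrated at before the challenge (defaults to `m_salt_e`).
#' @return list of class `perfusion_env`.
#' @export
perfusion_env <- function(m_salt_e = 0.29, m_cpa = 0, temp_K = 296.15,
                          schedule = c("step", "ramp"), tau = NULL,
                          m_salt_iso = m_salt_e) {
  schedule <- match.arg(schedule)
  stopifnot(m_salt_e > 0, m_cpa >= 0, temp_K > 0, m_salt_iso > 0)
  if (schedule == "ramp") stopifnot(is.numeric(tau), tau > 0)
  structure(list(m_salt_e = m_salt_e, m_cpa = m_cpa, temp_K = temp_K,
                 schedule = schedule, tau = tau, m_salt_iso = m_salt_iso),
            class = "perfusion_env")
}

## extracellular CPA concentration at time t (vectorised)
m_cpa_at <- function(env, t) {
  if (env$schedule == "step") rep(env$m_cpa, length(t))
  else env$m_cpa * (1 - exp(-pmax(t, 0) / env$tau))
}

#' Volume trajectory container
#'
#' Normalised total volume V(t)/V0 sampled at strictly increasing times.
#'
#' @param times seconds, strictly increasing.
#' @param v_norm normalised volume, same length.
#' @return data.frame of class `volume_trajectory` with columns
#'   `time_s`, `v_norm`.
#' @export
volume_trajectory <- function(times, v_norm) {
  stopifnot(length(times) == length(v_norm), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(v_norm)) || any(v_norm <= 0))
    stop("v_norm must be finite and positive")
  structure(data.frame(time_s = as.numeric(times),
                       v_norm = as.numeric(v_norm)),
            class = c("volume_trajectory", "data.frame"))
}

## initial state at isotonic equilibrium, in internal units
.init_state <- function(geom, env) {
  Vw0 <- (1 - geom$vb) * geom$V0
  c(Vw = Vw0, ns = 0)
}

## RHS of the 2-p system in internal units; Lp pre-converted to um/(s atm)
.rhs_2p <- function(t, y, p) {
  m_cpa_e <- if (p$schedule_step) p$m_cpa else
    p$m_cpa * (1 - exp(-max(t, 0) / p$tau))
  Vw <- y[1]; ns <- y[2]
  osm_i <- (p$n_salt + ns) / Vw
  dVw <- -p$Lp_s * p$A * p$RT * ((p$m_salt_e + m_cpa_e) - osm_i)
  dns <- p$Ps * p$A * (m_cpa_e - ns / Vw)
  list(c(dVw, dns))
}

.model_pars <- function(params, geom, env) {
  Vw0 <- (1 - geom$vb) * geom$V0
  list(Lp_s = params$Lp / 60, Ps = params$Ps, A = geom$A,
       RT = .const$R_atm * env$temp_K,
       m_salt_e = env$m_salt_e, m_cpa = env$m_cpa,
       n_salt = env$m_salt_iso * Vw0,
       schedule_step = identical(env$schedule, "step"),
       tau = if (is.null(env$tau)) 1 else env$tau)
}

#' Simulate the two-parameter volume response
#'
#' Integrates the 2-p system from isotonic equilibrium (or a supplied
#' initial state) and returns the normalised total volume at the requested
#' times, using an adaptive stiff/non-stiff solver
#' ([deSolve::lsoda()]) at tight tolerances so the result is independent
#' of the step-size control.
#'
#' @param params [membrane_params()].
#' @param geom [cell_geometry()].
#' @param env [perfusion_env()].
#' @param cpa [cpa_properties()] of the permeant solute (supplies `vbar`).
#' @param times sampling times, s, strictly increasing; `times[1]` is the
#'   instant of the concentration step.
#' @param init optional `c(Vw, ns)` initial state in internal units.
#' @param rtol,atol solver tolerances.
#' @return [volume_trajectory()] sampled at `times`.
#' @export
simulate_2p <- function(params, geom, env, cpa, times,
                        init = NULL, rtol = 1e-10, atol = 1e-12) {
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("times must be non-empty and strictly increasing")
  p <- .model_pars(params, geom, env)
  y0 <- if (is.null(init)) .init_state(geom, env) else init
  ## lsoda needs times starting at the initial instant
  t0 <- times[1]
  out <- deSolve::lsoda(y = y0, times = times, func = .rhs_2p, parms = p,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("2-p integration failed to converge at the requested tolerance")
  Vw <- out[, "Vw"]; ns <- out[, "ns"]
  if (any(Vw <= 0)) stop("2-p integration produced non-positive water volume")
  v <- (Vw + ns * cpa$vbar + geom$vb * geom$V0) / geom$V0
  volume_trajectory(times, v)
}

#' Fixed-step RK4 reference integration of the 2-p system
#'
#' Classical fourth-order Runge-Kutta at a fixed step (default 1 ms),
#' implemented in C++ and fully independent of the adaptive solver behind
#' [simulate_2p()]. Used as the brute-force reference the adaptive
#' solution is checked against.
#'
#' @inheritParams simulate_2p
#' @param dt fixed step, s.
#' @return [volume_trajectory()] sampled at `times`.
#' @export
simulate_2p_rk4 <- function(params, geom, env, cpa, times, dt = 1e-3) {
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("times must be non-empty and strictly increasing")
  p <- .model_pars(params, geom, env)
  y0 <- .init_state(geom, env)
  st <- rk4_2p_cpp(times, y0[1], y0[2], dt,
                   p$Lp_s, p$Ps, p$A, p$RT, p$m_salt_e, p$m_cpa,
                   p$n_salt, p$schedule_step, p$tau)
  v <- (st[, 1] + st[, 2] * cpa$vbar + geom$vb * geom$V0) / geom$V0
  volume_trajectory(times, v)
}

#' Long-time equilibrium normalised volume
#'
#' Closed-form asymptote of the 2-p system under a constant extracellular
#' environment. At equilibrium water is in osmotic balance and (for a
#' permeant solute, `Ps > 0`) the intracellular CPA concentration equals
#' the extracellular one, so
#' `Vw_eq = m_salt_iso Vw0 / m_salt_e` and `Ns_eq = m_cpa Vw_eq`;
#' for an impermeant challenge (`Ps = 0`) the CPA stays outside and
#' `Vw_eq = m_salt_iso Vw0 / (m_salt_e + m_cpa)` (Boyle-van 't Hoff).
#'
#' @inheritParams simulate_2p
#' @return normalised equilibrium volume, dimensionless.
#' @export
equilibrium_volume <- function(params, geom, env, cpa) {
  ## a ramped schedule tends to the same plateau as the step
  Vw0 <- (1 - geom$vb) * geom$V0
  n_salt <- env$m_salt_iso * Vw0
  if (params$Ps > 0 || env$m_cpa == 0) {
    Vw_eq <- n_salt / env$m_salt_e
    ns_eq <- if (params$Ps > 0) env$m_cpa * Vw_eq else 0
  } else {
    Vw_eq <- n_salt / (env$m_salt_e + env$m_cpa)
    ns_eq <- 0
  }
  (Vw_eq + ns_eq * cpa$vbar + geom$vb * geom$V0) / geom$V0
}

#' Location of the shrink--swell volume minimum
#'
#' Time and value of the sampled minimum of a trajectory; ties are broken
#' by the earliest time. For a permeant-CPA step this is the turning point
#' between dehydration and CPA-driven re-swelling.
#'
#' @param trajectory [volume_trajectory()].
#' @return list `(t_min, v_min)`.
#' @export
min_volume <- function(trajectory) {
  stopifnot(nrow(trajectory) >= 1)
  i <- which.min(trajectory$v_norm)   # which.min already takes the first tie
  list(t_min = trajectory$time_s[i], v_min = trajectory$v_norm[i])
}
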