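## Serpentine-mixer model: steady laminar co-flow of two miscible streams
## in a rectangular microchannel, reduced to the parabolized (boundary
## layer) advection-diffusion equation
##
##   u(y) dc/dx = D d2c/dy2,   u(y) plane-Poiseuille across the width W,
##
## marched axially with an implicit (backward-Euler) scheme on a
## cell-centred cross-stream grid with zero-flux side walls. At the
## Reynolds numbers of the chip (Re << 1 at 10 uL/min in a 200 x 150 um
## duct) the momentum problem is the analytic laminar profile and axial
## diffusion is negligible against advection (axial Peclet >> 1), so the
## full Navier-Stokes + species FEM reduces to this desk-scale model.

#' Mixing-channel geometry
#'
#' Rectangular serpentine channel, width `W` x height `H` in um (chip
#' default 200 x 150), straightened to an equivalent unrolled length `L`
#' (no Dean recirculation at Re << 1, so bends only add length). The
#' capture micropillars (radius 20 um, height 150 um) enter only the
#' capture-region estimates, not the mixing solve.
#'
#' @param W,H channel width and height, um.
#' @param L unrolled channel length, um.
#' @param pillar_radius,pillar_height capture micropillar size, um.
#' @return list of class `channel_geometry`.
#' @export
channel_geometry <- function(W = 200, H = 150, L = 20000,
                             pillar_radius = 20, pillar_height = 150) {
  stopifnot(W > 0, H > 0, L > 0, pillar_radius > 0, pillar_height > 0)
  structure(list(W = W, H = H, L = L, pillar_radius = pillar_radius,
                 pillar_height = pillar_height), class = "channel_geometry")
}

#' Inlet flow condition
#'
#' @param Q1,Q2 inlet volumetric flow rates, uL/min (chip default 10 each).
#' @param c1,c2 inlet concentrations, mol/L.
#' @param temp_K temperature, K.
#' @return list of class `flow_condition`.
#' @export
flow_condition <- function(Q1 = 10, Q2 = 10, c1 = 1.5, c2 = 0.5,
                           temp_K = 296.15) {
  stopifnot(Q1 > 0, Q2 > 0, c1 >= 0, c2 >= 0, temp_K > 0)
  structure(list(Q1 = Q1, Q2 = Q2, c1 = c1, c2 = c2, temp_K = temp_K),
            class = "flow_condition")
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = k_B T / (6 pi eta r)` for a solute of hydrodynamic radius `r` in a
#' solution of dynamic viscosity `eta`.
#'
#' @param cpa [cpa_properties()] supplying `eta` (Pa s) and `r_hydro` (m).
#' @param temp_K absolute temperature, K.
#' @return diffusivity, m^2/s.
#' @examples
#' stokes_einstein_D(cpa_properties("EG"), 296.15)
#' @export
stokes_einstein_D <- function(cpa, temp_K) {
  stopifnot(temp_K > 0, cpa$eta > 0, cpa$r_hydro > 0)
  .const$k_B * temp_K / (6 * pi * cpa$eta * cpa$r_hydro)
}

#' Solve the steady co-flow concentration field
#'
#' Marches `u(y) dc/dx = D d2c/dy2` from the junction (stream 1 occupying
#' `y < W Q1/(Q1+Q2)`, stream 2 the rest) to the channel exit. The
#' cross-stream operator is the standard second-order zero-flux Laplacian
#' on a cell-centred grid; each axial step solves a constant tridiagonal
#' system, factorised once. The scheme conserves the flux-weighted mean
#' concentration exactly and respects the maximum principle.
#'
#' @param geom [channel_geometry()].
#' @param flow [flow_condition()].
#' @param D solute diffusivity, m^2/s (e.g. [stokes_einstein_D()]).
#' @param ny number of cross-stream cells.
#' @param nx number of axial stations stored (the march uses `dx`).
#' @param dx axial step, um; default `L / 4000`. Grid-convergence studies
#'   that refine `dy` should take `dx` proportional to `dy^2` so the
#'   first-order axial error shrinks at the same rate as the second-order
#'   cross-stream error.
#' @param check if `TRUE` (default) assert the maximum principle and
#'   solute conservation on the computed field.
#' @return list of class `concentration_field`: `x`, `y` (um), `c`
#'   (nx x ny matrix, mol/L), `u` (um/s at the y cells), `geom`, `flow`,
#'   `D`, and `report` — a `mixing_report` with `c_out_mean`
#'   (flux-weighted), `mixing_index` along `x`, `L90`, `L99`,
#'   `wall_shear_rate`.
#' @export
solve_coflow <- function(geom, flow, D, ny = 80, nx = 201, dx = NULL,
                         check = TRUE) {
  W <- geom$W; H <- geom$H; L <- geom$L
  dy <- W / ny
  y <- (seq_len(ny) - 0.5) * dy                     # cell centres, um
  Qtot_um3 <- (flow$Q1 + flow$Q2) * 1e9 / 60        # uL/min -> um^3/s
  u_mean <- Qtot_um3 / (W * H)                      # um/s
  u <- 6 * u_mean * (y / W) * (1 - y / W)           # plane Poiseuille in y
  D_um <- D * 1e12                                  # m^2/s -> um^2/s

  if (is.null(dx)) dx <- L / 4000
  n_steps <- max(ceiling(L / dx), nx - 1)
  dx <- L / n_steps

  ## inlet split so that the flux carried by stream 1 is Q1/(Q1+Q2):
  ## streams enter side by side; split position by flow fraction of the
  ## Poiseuille flux integral
  frac <- flow$Q1 / (flow$Q1 + flow$Q2)
  cum_flux <- cumsum(u) / sum(u)
  c0 <- ifelse(cum_flux <= frac + 1e-12, flow$c1, flow$c2)
  ## fractional cell at the interface keeps the flux-weighted mean exact
  j <- which(cum_flux > frac + 1e-12)[1]
  if (!is.na(j) && j >= 1) {
    below <- if (j > 1) cum_flux[j - 1] else 0
    w1 <- (frac - below) / (cum_flux[j] - below)
    c0[j] <- w1 * flow$c1 + (1 - w1) * flow$c2
  }

  ## backward-Euler march: (U/dx + D L) c_new = U c_old / dx
  ## L = -(1/dy^2) * tridiag(-1, 2, -1) with zero-flux ends
  main <- rep(2, ny); main[c(1, ny)] <- 1
  Lmat <- Matrix::bandSparse(ny, ny, k = c(-1, 0, 1),
                             diagonals = list(rep(-1, ny - 1), main,
                                              rep(-1, ny - 1))) / dy^2
  A <- Matrix::Diagonal(x = u / dx) + D_um * Lmat
  fac <- Matrix::lu(A)

  x_store <- seq(0, L, length.out = nx)
  cmat <- matrix(NA_real_, nx, ny)
  cmat[1, ] <- c0
  cvec <- c0
  store_i <- 2
  for (s in seq_len(n_steps)) {
    cvec <- as.numeric(Matrix::solve(fac, u * cvec / dx))
    xs <- s * dx
    while (store_i <= nx && x_store[store_i] <= xs + 1e-9) {
      cmat[store_i, ] <- cvec
      store_i <- store_i + 1
    }
  }
  ## flux-weighted mean and mixing index along x
  fw_mean <- as.numeric(cmat %*% u) / sum(u)
  sd_x <- apply(cmat, 1, stats::sd)
  sd0 <- sd_x[1]
  mix_idx <- if (sd0 > 0) 1 - sd_x / sd0 else rep(1, nx)
  mix_idx <- pmin(pmax(mix_idx, 0), 1)
  L90 <- if (any(mix_idx >= 0.9)) x_store[which(mix_idx >= 0.9)[1]] else NA_real_
  L99 <- if (any(mix_idx >= 0.99)) x_store[which(mix_idx >= 0.99)[1]] else NA_real_

  if (check) {
    lo <- min(flow$c1, flow$c2) - 1e-9; hi <- max(flow$c1, flow$c2) + 1e-9
    if (any(cmat < lo) || any(cmat > hi))
      stop("maximum principle violated in co-flow solve")
    if (max(abs(fw_mean - fw_mean[1])) > 1e-8 * max(fw_mean[1], 1))
      stop("solute conservation violated in co-flow solve")
  }

  report <- structure(list(
    c_out_mean = fw_mean[nx],
    c_out_cross_mean = mean(cmat[nx, ]),
    mixing_index = data.frame(x_um = x_store, mixing_index = mix_idx),
    L90 = L90, L99 = L99,
    wall_shear_rate = capture_region_shear(geom, flow)),
    class = "mixing_report")

  structure(list(x = x_store, y = y, c = cmat, u = u, geom = geom,
                 flow = flow, D = D, report = report),
            class = "concentration_field")
}

#' Sample a concentration field at arbitrary points
#'
#' Bilinear interpolation of `c(x, y)` at the requested points (the
#' analogue of probing the simulated field at monitoring points along the
#' serpentine).
#'
#' @param field `concentration_field` from [solve_coflow()].
#' @param x_um,y_um point coordinates, um (recycled to equal length).
#' @return data.frame `x_um, y_um, c_M`.
#' @export
mixing_profile <- function(field, x_um, y_um) {
  n <- max(length(x_um), length(y_um))
  x_um <- rep_len(x_um, n); y_um <- rep_len(y_um, n)
  W <- field$geom$W; L <- field$geom$L
  if (any(x_um < 0 | x_um > L | y_um < 0 | y_um > W))
    stop("sample point outside the channel domain")
  ## clamp y to the cell-centre range (constant extrapolation in the
  ## half-cell next to each wall, consistent with zero flux)
  yc <- pmin(pmax(y_um, field$y[1]), field$y[length(field$y)])
  cM <- vapply(seq_len(n), function(k) {
    ix <- findInterval(x_um[k], field$x, all.inside = TRUE)
    iy <- findInterval(yc[k], field$y, all.inside = TRUE)
    x1 <- field$x[ix]; x2 <- field$x[ix + 1]
    y1 <- field$y[iy]; y2 <- field$y[iy + 1]
    tx <- if (x2 > x1) (x_um[k] - x1) / (x2 - x1) else 0
    ty <- if (y2 > y1) (yc[k] - y1) / (y2 - y1) else 0
    (1 - tx) * ((1 - ty) * field$c[ix, iy] + ty * field$c[ix, iy + 1]) +
      tx * ((1 - ty) * field$c[ix + 1, iy] + ty * field$c[ix + 1, iy + 1])
  }, 0)
  data.frame(x_um = x_um, y_um = y_um, c_M = cM)
}

#' Capture-region wall shear rate
#'
#' Analytic laminar estimate for a wide rectangular duct,
#' `gamma_w = 6 Q / (W H^2)`.
#'
#' @param geom [channel_geometry()].
#' @param flow [flow_condition()] (total rate `Q1 + Q2` is used) or a
#'   single numeric channel flow rate in uL/min.
#' @return wall shear rate, 1/s.
#' @export
capture_region_shear <- function(geom, flow) {
  Q <- if (is.numeric(flow)) flow else (flow$Q1 + flow$Q2)
  Q_um3 <- Q * 1e9 / 60
  6 * Q_um3 / (geom$W * geom$H^2)
}

#' Washout time of the capture region
#'
#' Dead volume between the mixer exit and the captured oocyte divided by
#' the channel flow rate; supplies the ramp time constant of
#' [perfusion_env()] when solution replacement is modelled as gradual.
#'
#' @param geom [channel_geometry()].
#' @param flow [flow_condition()] or numeric uL/min.
#' @param dead_length_um length of channel from mixer exit to the capture
#'   pillars, um.
#' @return time, s.
#' @export
washout_time <- function(geom, flow, dead_length_um = 2000) {
  Q <- if (is.numeric(flow)) flow else (flow$Q1 + flow$Q2)
  Q_um3 <- Q * 1e9 / 60
  vol_um3 <- geom$W * geom$H * dead_length_um
  vol_um3 / Q_um3
}
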