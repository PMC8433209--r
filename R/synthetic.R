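## Synthetic micrograph and trajectory generator: the stand-in for the
## perfusion videos. Renders one roughly circular oocyte per frame --
## cytoplasm disk + fixed-outer-radius zona pellucida annulus on a
## textured background -- whose cytoplasm radius follows a 2-p
## shrink--swell trajectory, with the ground-truth cytoplasm mask
## (255 = oocyte, 0 = elsewhere) and (Lp, Ps) known exactly.

#' Rendering specification for synthetic micrographs
#'
#' Bright-field-like contrast defaults: dark cytoplasm (90), intermediate
#' zona (140), light background (180) on the 8-bit scale. The zona outer
#' radius is fixed at `r0 + zona_thickness` for the whole sequence: the
#' zona does not shrink with the cytoplasm, mirroring its mechanical
#' supporting role in the chip.
#'
#' @param image_size canvas side, px (square frames).
#' @param px_size um per pixel.
#' @param r0 isotonic cytoplasm radius, px.
#' @param zona_thickness zona annulus thickness, px.
#' @param bg,zona,cytoplasm mean intensities, 8-bit.
#' @param noise_sigma i.i.d. Gaussian pixel noise sd, 8-bit units
#'   (clipped to \[0, 255\]).
#' @param illumination_gradient peak-to-peak relative intensity slope
#'   across the frame (0 = flat illumination).
#' @param edge_soft edge softness of the disk/annulus boundaries, px.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(image_size = 256, px_size = 1, r0 = 70,
                        zona_thickness = 8, bg = 180, zona = 140,
                        cytoplasm = 90, noise_sigma = 10,
                        illumination_gradient = 0.05, edge_soft = 1.5) {
  stopifnot(image_size >= 32, px_size > 0, r0 > 0, zona_thickness >= 0,
            r0 + zona_thickness < image_size / 2,
            all(c(bg, zona, cytoplasm) >= 0), all(c(bg, zona, cytoplasm) <= 255),
            noise_sigma >= 0, illumination_gradient >= 0)
  structure(list(image_size = image_size, px_size = px_size, r0 = r0,
                 zona_thickness = zona_thickness, bg = bg, zona = zona,
                 cytoplasm = cytoplasm, noise_sigma = noise_sigma,
                 illumination_gradient = illumination_gradient,
                 edge_soft = edge_soft), class = "render_spec")
}

## smooth radial step: 1 inside radius r, 0 outside, soft edge
.soft_disk <- function(dist, r, soft) {
  if (soft <= 0) as.numeric(dist <= r) else stats::plogis((r - dist) / soft)
}

#' Render a single synthetic micrograph frame
#'
#' @param spec [render_spec()].
#' @param radius_px cytoplasm radius for this frame, px.
#' @param center optional c(x, y) centre, px; default frame centre.
#' @param rng optional list with a `rnorm` function (an internal seeded
#'   stream); when absent the frame is noise-free.
#' @return list `frame` (matrix, 0--255 doubles) and `mask` (matrix in
#'   {0, 255} covering the cytoplasm only).
#' @export
render_frame <- function(spec, radius_px, center = NULL, rng = NULL) {
  n <- spec$image_size
  if (radius_px + spec$zona_thickness >= n / 2)
    stop("oocyte (cytoplasm + zona) does not fit inside the frame")
  if (is.null(center)) center <- c(n / 2 + 0.5, n / 2 + 0.5)
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  dist <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  r_outer <- spec$r0 + spec$zona_thickness        # fixed: zona doesn't shrink
  in_cyt  <- .soft_disk(dist, radius_px, spec$edge_soft)
  in_out  <- .soft_disk(dist, r_outer, spec$edge_soft)
  img <- spec$bg * (1 - in_out) + spec$zona * (in_out - in_cyt) +
    spec$cytoplasm * in_cyt
  if (spec$illumination_gradient > 0)
    img <- img * (1 + spec$illumination_gradient * ((xs - 1) / (n - 1) - 0.5))
  if (!is.null(rng) && spec$noise_sigma > 0)
    img <- img + spec$noise_sigma * matrix(rng$rnorm(n * n), n, n)
  img <- pmin(pmax(img, 0), 255)
  mask <- matrix(0, n, n)
  mask[dist <= radius_px] <- 255
  list(frame = img, mask = mask)
}

#' Ground-truth scenario: parameters plus their simulated trajectory
#'
#' Bundles membrane parameters, geometry, environment and CPA with the
#' 2-p trajectory they generate at the frame times; the reference object
#' every recovery test closes the loop against.
#'
#' @inheritParams simulate_2p
#' @return list of class `scenario_truth`.
#' @export
scenario_truth <- function(params, geom, env, cpa,
                           times = seq(0, 600, by = 2)) {
  traj <- simulate_2p(params, geom, env, cpa, times)
  structure(list(params = params, geom = geom, env = env, cpa = cpa,
                 trajectory = traj, times = times), class = "scenario_truth")
}

#' The six standard perfusion scenarios
#'
#' EG and PG at 0.5, 1.0, 1.5 mol/L, the concentration schedule of the
#' three-channel gradient chip, with declared default membrane parameters.
#'
#' @param Lp,Ps membrane parameters used for every scenario.
#' @param times frame times, s (default 1 frame / 2 s over 600 s).
#' @param geom [cell_geometry()].
#' @return named list of six [scenario_truth()] objects
#'   (`"EG_0.5"`, ..., `"PG_1.5"`).
#' @export
standard_scenarios <- function(Lp = 0.8, Ps = 0.25,
                               times = seq(0, 600, by = 2),
                               geom = cell_geometry()) {
  params <- membrane_params(Lp, Ps)
  out <- list()
  for (cpa_name in c("EG", "PG")) {
    cpa <- cpa_properties(cpa_name)
    for (conc in c(0.5, 1.0, 1.5)) {
      env <- perfusion_env(m_cpa = conc)
      out[[sprintf("%s_%.1f", cpa_name, conc)]] <-
        scenario_truth(params, geom, env, cpa, times)
    }
  }
  out
}

#' Noisy trajectory tables from ground-truth scenarios
#'
#' Adds i.i.d. Gaussian noise on v_norm to each scenario trajectory,
#' `n_replicates` replicates per scenario, fully determined by `seed`.
#'
#' @param scenarios list of [scenario_truth()].
#' @param noise_sigma additive noise sd on v_norm.
#' @param n_replicates replicates per scenario.
#' @param seed integer seed.
#' @param dir optional directory; when given, truth and noisy tables are
#'   written side by side as CSV (`<name>_truth.csv`,
#'   `<name>_rep<k>.csv`).
#' @return list per scenario: `truth` ([volume_trajectory()]) and
#'   `replicates` (list of noisy [volume_trajectory()]).
#' @export
make_trajectory_dataset <- function(scenarios, noise_sigma = 0.01,
                                    n_replicates = 1, seed = 1,
                                    dir = NULL) {
  rng <- .seeded_rng(seed)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    truth <- sc$trajectory
    reps <- lapply(seq_len(n_replicates), function(k) {
      v <- truth$v_norm + noise_sigma * rng$rnorm(nrow(truth))
      volume_trajectory(truth$time_s, pmax(v, 1e-6))
    })
    if (!is.null(dir)) {
      write_trajectory_csv(truth, file.path(dir, paste0(nm, "_truth.csv")))
      for (k in seq_len(n_replicates))
        write_trajectory_csv(reps[[k]],
                             file.path(dir, sprintf("%s_rep%02d.csv", nm, k)))
    }
    list(truth = truth, replicates = reps)
  })
  names(out) <- names(scenarios)
  out
}

#' Render a micrograph sequence from a ground-truth scenario
#'
#' Per-frame cytoplasm radius `r(t) = r0 v_norm(t)^(1/3)` (equivalent
#' sphere), rendered with a fixed zona outer radius; returns frames and
#' ground-truth cytoplasm masks.
#'
#' @param truth [scenario_truth()].
#' @param spec [render_spec()].
#' @param seed integer seed for the pixel noise.
#' @return list of class `micrograph_sequence`: `frames`, `masks` (lists
#'   of matrices), `times`, `radii_px`, `spec`, `truth`.
#' @export
render_sequence <- function(truth, spec = render_spec(), seed = 1) {
  rng <- .seeded_rng(seed)
  radii <- spec$r0 * truth$trajectory$v_norm^(1 / 3)
  if (any(radii + spec$zona_thickness >= spec$image_size / 2))
    stop("trajectory radius overflows the frame")
  frames <- vector("list", length(radii)); masks <- frames
  for (i in seq_along(radii)) {
    fm <- render_frame(spec, radii[i], rng = rng)
    frames[[i]] <- fm$frame; masks[[i]] <- fm$mask
  }
  structure(list(frames = frames, masks = masks,
                 times = truth$trajectory$time_s, radii_px = radii,
                 spec = spec, truth = truth),
            class = "micrograph_sequence")
}

#' Build the canonical synthetic segmentation benchmark
#'
#' Train/validation image+mask pairs drawn from randomised single-oocyte
#' frames (radius, centre jitter, intensity jitter, noise), plus the six
#' standard perfusion scenarios. Default size 200 train / 25 validation
#' (a scaled-down counterpart of a 2000/250 split); `paper_scale = TRUE`
#' generates 2000/250.
#'
#' @param seed integer seed; everything is a pure function of it.
#' @param n_train,n_val set sizes.
#' @param paper_scale if `TRUE`, use 2000/250 regardless of
#'   `n_train`/`n_val`.
#' @param image_size canvas side, px.
#' @param noise_sigma pixel noise sd, 8-bit units.
#' @param dir optional directory; when given, writes
#'   `images/`, `masks/` PNGs and a `manifest.csv`
#'   (`frame_path, mask_path, split`).
#' @return list: `train`, `val` (lists of `list(frame, mask)`),
#'   `scenarios` ([standard_scenarios()]), `seed`.
#' @export
make_benchmark <- function(seed = 7, n_train = 200, n_val = 25,
                           paper_scale = FALSE, image_size = 256,
                           noise_sigma = 10, dir = NULL) {
  if (paper_scale) { n_train <- 2000; n_val <- 250 }
  rng <- .seeded_rng(seed)
  draw <- function(n_img) {
    lapply(seq_len(n_img), function(i) {
      r <- rng$runif(1, 0.45, 0.85) * image_size / 2 - 10
      zt <- round(rng$runif(1, 5, 10))
      jit <- rng$runif(2, -8, 8)
      spec <- render_spec(image_size = image_size, r0 = r,
                          zona_thickness = zt,
                          bg = rng$runif(1, 170, 195),
                          zona = rng$runif(1, 130, 150),
                          cytoplasm = rng$runif(1, 80, 105),
                          noise_sigma = noise_sigma,
                          illumination_gradient = rng$runif(1, 0, 0.08))
      render_frame(spec, r, center = image_size / 2 + 0.5 + jit, rng = rng)
    })
  }
  train <- draw(n_train)
  val <- draw(n_val)
  scenarios <- standard_scenarios()
  if (!is.null(dir)) {
    for (d in c("images", "masks"))
      dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    sets <- list(train = train, val = val)
    for (split in names(sets)) {
      for (i in seq_along(sets[[split]])) {
        fp <- file.path(dir, "images", sprintf("%s_%04d.png", split, i))
        mp <- file.path(dir, "masks", sprintf("%s_%04d.png", split, i))
        write_gray_png(sets[[split]][[i]]$frame, fp)
        write_gray_png(sets[[split]][[i]]$mask, mp)
        rows[[length(rows) + 1]] <- data.frame(frame_path = fp, mask_path = mp,
                                               split = split)
      }
    }
    utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(train = train, val = val, scenarios = scenarios, seed = seed)
}

#' Grayscale PNG I/O
#'
#' 8-bit single-channel round trip on the 0--255 scale (values are
#' rounded on write).
#' @param img numeric matrix on the 0--255 scale.
#' @param path file path.
#' @return `read_gray_png` returns a matrix on the 0--255 scale.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(round(pmin(pmax(img, 0), 255)) / 255, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 255
}
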