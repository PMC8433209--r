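## Micrograph -> cytoplasm mask -> equivalent-sphere volume. Two
## backends: a deterministic classical morphology pipeline (the oracle
## standing in for manual annotation) and the compact encoder-decoder
## network (network.R). Masks follow the 255/0 convention and cover the
## cytoplasm only, excluding the zona pellucida annulus.

#' Classical oocyte segmentation
#'
#' Deterministic pipeline: Gaussian smoothing, global Otsu threshold
#' separating the (dark) oocyte from the (light) background, hole
#' filling, largest connected component, then annulus removal. Because
#' the zona pellucida is intermediate in intensity between cytoplasm and
#' background, the annulus is removed by an isodata threshold restricted
#' to the object ("threshold" method, the default, which adapts to the
#' actual zona thickness); a fixed-radius erosion is available as the
#' `"erode"` alternative.
#'
#' @param frame numeric matrix on the 0--255 scale.
#' @param min_area minimum object area, px; smaller detections return an
#'   empty mask (a valid "not found" result).
#' @param smooth_sigma Gaussian smoothing sd, px.
#' @param annulus `"threshold"` or `"erode"`.
#' @param erode_px erosion radius for `annulus = "erode"`, px.
#' @return mask matrix in {0, 255}; all zero when no oocyte is found.
#' @export
segment_classical <- function(frame, min_area = 500, smooth_sigma = 2,
                              annulus = c("threshold", "erode"),
                              erode_px = 8) {
  annulus <- match.arg(annulus)
  n <- dim(frame)
  img <- EBImage::Image(frame / 255)
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  smv <- EBImage::imageData(sm)
  ## the histogram is trimodal -- dark cytoplasm, intermediate zona, light
  ## background -- so a single two-class threshold is unreliable (it tends
  ## to land on the zona mode); use a two-threshold (three-class) Otsu
  if (stats::sd(smv) < 1e-3) return(matrix(0, n[1], n[2]))
  th3 <- .otsu2_thresholds(as.numeric(smv))
  ## featureless-frame guard: a real oocyte is far darker than background;
  ## when the putative object class sits within noise of the background
  ## class there is nothing to segment
  mu_bg_all <- stats::median(smv[smv >= th3[2]])
  mu_obj_all <- stats::median(smv[smv < th3[2]])
  if (!is.finite(mu_bg_all) || !is.finite(mu_obj_all) ||
      mu_bg_all - mu_obj_all < 20 / 255)
    return(matrix(0, n[1], n[2]))
  obj <- smv < th3[2]                 # cytoplasm + zona
  obj <- .largest_component(obj, min_area)
  if (!any(obj)) return(matrix(0, n[1], n[2]))
  obj <- EBImage::fillHull(EBImage::Image(obj * 1)) > 0.5
  obj <- matrix(as.logical(obj), n[1], n[2])

  if (annulus == "threshold") {
    ## cut at the half-intensity contour between the cytoplasm and zona
    ## class levels: the smoothed edge profile is symmetric about the true
    ## boundary, so the midpoint of the two class medians is unbiased in
    ## radius; fall back to the whole object if the classes are degenerate
    mu_cyt <- stats::median(smv[smv < th3[1]])
    mu_zona <- stats::median(smv[smv >= th3[1] & smv < th3[2]])
    cyt <- if (is.finite(mu_cyt) && is.finite(mu_zona) &&
               mu_zona - mu_cyt > 10 / 255)
      obj & (smv < (mu_cyt + mu_zona) / 2) else obj
    cyt <- .largest_component(cyt, min_area)
    if (any(cyt)) {
      cyt <- EBImage::fillHull(EBImage::Image(cyt * 1)) > 0.5
      cyt <- matrix(as.logical(cyt), n[1], n[2])
    }
  } else {
    brush <- EBImage::makeBrush(2 * erode_px + 1, shape = "disc")
    cyt <- EBImage::erode(EBImage::Image(obj * 1), brush) > 0.5
    cyt <- matrix(as.logical(cyt), n[1], n[2])
    cyt <- .largest_component(cyt, min_area)
  }
  if (sum(cyt) < min_area) return(matrix(0, n[1], n[2]))
  matrix(255 * as.numeric(cyt), n[1], n[2])
}

## Two-threshold (three-class) Otsu on a 256-bin histogram: exhaustive
## search maximising the between-class variance. Returns c(t_low, t_high)
## on the input scale.
.otsu2_thresholds <- function(vals, n_bins = 256) {
  rng <- range(vals)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(vals, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- cumsum(h); s <- cumsum(h * mids)
  W <- w[n_bins]; S <- s[n_bins]
  best <- -Inf; t_best <- c(1L, 2L)
  for (i in 1:(n_bins - 2)) {
    w1 <- w[i]; if (w1 == 0) next
    s1 <- s[i]
    j <- (i + 1):(n_bins - 1)
    w2 <- w[j] - w1; s2 <- s[j] - s1
    w3 <- W - w[j]; s3 <- S - s[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    v <- rep(-Inf, length(j))
    v[ok] <- s1^2 / w1 + s2[ok]^2 / w2[ok] + s3[ok]^2 / w3[ok]
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; t_best <- c(i, j[k]) }
  }
  edges[t_best + 1L]
}

## keep the largest connected component at least min_area px, else empty
.largest_component <- function(bin, min_area) {
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labv <- EBImage::imageData(lab)
  if (max(labv) == 0) return(bin & FALSE)
  sizes <- tabulate(labv[labv > 0])
  k <- which.max(sizes)
  if (sizes[k] < min_area) return(bin & FALSE)
  matrix(labv == k, nrow(bin), ncol(bin))
}

#' Dice coefficient and pixel accuracy between two masks
#'
#' @param mask,ref matrices on the {0, 255} (or logical) convention.
#' @return list `dice`, `pixel_accuracy`, both in \[0, 1\].
#' @export
segmentation_metrics <- function(mask, ref) {
  a <- mask > 0; b <- ref > 0
  inter <- sum(a & b)
  dice <- if (sum(a) + sum(b) == 0) 1 else 2 * inter / (sum(a) + sum(b))
  list(dice = dice, pixel_accuracy = mean(a == b))
}

#' Equivalent-sphere volume from a cytoplasm mask
#'
#' The segmented area is converted to the radius of the equal-area circle
#' and then to the volume of the sphere with that radius:
#' `r_eq = sqrt(A px_size^2 / pi)`, `V = 4/3 pi r_eq^3`.
#'
#' @param mask matrix in {0, 255}.
#' @param px_size um per pixel.
#' @return volume, um^3.
#' @export
mask_to_volume <- function(mask, px_size = 1) {
  area_px <- sum(mask > 0)
  if (area_px == 0) stop("no object: empty mask has no volume")
  r_eq <- sqrt(area_px * px_size^2 / pi)
  4 / 3 * pi * r_eq^3
}

#' Segment a time-ordered sequence and extract the volume trajectory
#'
#' Per-frame segmentation (classical backend or a trained network),
#' equivalent-sphere volumes, then normalisation to the first frame.
#' Isolated frames with an empty mask are filled by linear interpolation
#' of the volume; more than 20% empty frames invalidates the trajectory.
#'
#' @param frames list of matrices (0--255), time-ordered.
#' @param times frame times, s.
#' @param backend `"classical"` or `"network"`.
#' @param net trained network (required for `backend = "network"`).
#' @param px_size um per pixel.
#' @param qc_dir optional directory for contour-overlay QC PNGs.
#' @param ... passed to [segment_classical()].
#' @return list of class `tracked_sequence`: `trajectory`
#'   ([volume_trajectory()]), `volumes_um3`, `masks`, `n_empty`.
#' @export
track_sequence <- function(frames, times, backend = c("classical", "network"),
                           net = NULL, px_size = 1, qc_dir = NULL, ...) {
  backend <- match.arg(backend)
  stopifnot(length(frames) == length(times))
  if (backend == "network" && is.null(net))
    stop("backend = 'network' needs a trained network")
  masks <- lapply(frames, function(f) {
    if (backend == "classical") segment_classical(f, ...)
    else predict_mask(net, f)
  })
  areas <- vapply(masks, function(m) sum(m > 0), 0)
  empty <- areas == 0
  if (mean(empty) > 0.20)
    stop("invalid trajectory: ", sum(empty), "/", length(empty),
         " frames have empty masks (> 20%)")
  vols <- ifelse(empty, NA_real_,
                 vapply(seq_along(masks), function(i)
                   if (empty[i]) NA_real_ else mask_to_volume(masks[[i]], px_size), 0))
  if (any(empty)) {
    ## isolated gaps only: interpolate; a leading/trailing gap or a run of
    ## gaps longer than 1 is not trusted
    runs <- rle(empty)
    if (empty[1] || empty[length(empty)] || any(runs$lengths[runs$values] > 1))
      stop("invalid trajectory: empty-mask frames are not isolated interior frames")
    vols <- stats::approx(times[!empty], vols[!empty], xout = times)$y
  }
  if (!is.null(qc_dir)) {
    dir.create(qc_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(frames))
      write_gray_png(.contour_overlay(frames[[i]], masks[[i]]),
                     file.path(qc_dir, sprintf("frame_%04d.png", i)))
  }
  structure(list(trajectory = normalize_volume(times, vols),
                 volumes_um3 = vols, masks = masks, n_empty = sum(empty)),
            class = "tracked_sequence")
}

## frame with the one-pixel mask boundary burnt in at full white
.contour_overlay <- function(frame, mask) {
  if (!any(mask > 0)) return(frame)
  m <- EBImage::Image((mask > 0) * 1)
  er <- EBImage::erode(m, EBImage::makeBrush(3, "box"))
  boundary <- (mask > 0) & !(matrix(as.logical(er), nrow(mask), ncol(mask)))
  out <- frame
  out[boundary] <- 255
  out
}

#' Mask PNG I/O on the {0, 255} convention
#'
#' @param mask matrix in {0, 255}.
#' @param path file path.
#' @return `read_mask_png` returns a {0, 255} matrix.
#' @export
write_mask_png <- function(mask, path) {
  write_gray_png(ifelse(mask > 0, 255, 0), path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  ifelse(read_gray_png(path) > 127, 255, 0)
}
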