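# Synthetic 3D fluorescence stacks and focus quantification.
#
# Rendering: each focus is a 3D Gaussian spot; the widefield optics blur it
# further (Gaussian PSF, exact in quadrature), then Poisson shot noise and
# Gaussian read noise are added. Quantification: Richardson-Lucy restoration
# with the known PSF, robust background, thresholded 3D local maxima with a
# minimum separation, and moment-based spot measurement.

#' Acquisition / optics parameters
#'
#' Defaults describe the acquisition geometry used throughout: 100x
#' objective, 20 z-slices over 4 um, typical widefield blur.
#'
#' @param voxel_xy_um Lateral voxel size, um.
#' @param voxel_z_um Axial step, um; `n_slices * voxel_z_um` must equal
#'   `depth_um`.
#' @param n_slices Number of z slices.
#' @param depth_um Total stack depth, um.
#' @param field_um Lateral field of view (square), um.
#' @param blur_lateral_um,blur_axial_um Gaussian PSF sigmas, um.
#' @param background Mean background signal, counts/voxel.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param spot_sigma_um Default intrinsic lateral spot sigma, um (axial
#'   sigma is 1.5x larger).
#' @param spot_intensity Default peak spot amplitude, counts.
#' @return List of class `optics_params`.
#' @export
optics_params <- function(voxel_xy_um = 0.065, voxel_z_um = 0.2,
                          n_slices = 20, depth_um = 4, field_um = 6.5,
                          blur_lateral_um = 0.1, blur_axial_um = 0.3,
                          background = 10, read_noise_sd = 2,
                          spot_sigma_um = 0.12, spot_intensity = 150) {
  if (abs(n_slices * voxel_z_um - depth_um) > 1e-9)
    stop("need n_slices x voxel_z_um == depth_um", call. = FALSE)
  if (blur_lateral_um <= 0 || blur_axial_um <= 0)
    stop("blur widths must be positive", call. = FALSE)
  structure(as.list(environment()), class = "optics_params")
}

stack_axes <- function(optics) {
  nx <- round(optics$field_um / optics$voxel_xy_um)
  list(
    nx = nx, ny = nx, nz = optics$n_slices,
    x = (seq_len(nx) - (nx + 1) / 2) * optics$voxel_xy_um,
    y = (seq_len(nx) - (nx + 1) / 2) * optics$voxel_xy_um,
    z = (seq_len(optics$n_slices) - (optics$n_slices + 1) / 2) *
      optics$voxel_z_um)
}

#' Render a focus set into a synthetic 3D stack
#'
#' Foci may carry optional columns `intensity` (peak counts before blur) and
#' `sigma_um` (intrinsic lateral sigma); otherwise the optics defaults are
#' used. The blurred spot is the intrinsic Gaussian convolved with the PSF
#' (sigmas added in quadrature), evaluated analytically; noise is Poisson
#' shot noise on signal + background plus Gaussian read noise. The noiseless
#' volume and the ground-truth table are stored for recovery tests.
#'
#' @param foci Focus data.table (`x_um, y_um, z_um`, optional `intensity`,
#'   `sigma_um`); an empty table renders a noise-only stack.
#' @param optics An [optics_params()].
#' @param noise Add noise (default TRUE).
#' @return Object of class `image_stack`: list with `data` (nx x ny x nz
#'   array), `ideal` (noiseless), `optics`, `ground_truth`.
#' @export
render_stack <- function(foci, optics = optics_params(), noise = TRUE) {
  ax <- stack_axes(optics)
  vol <- array(0, dim = c(ax$nx, ax$ny, ax$nz))
  foci <- data.table::as.data.table(foci)
  n <- nrow(foci)
  amp <- if ("intensity" %in% names(foci)) foci$intensity else
    rep(optics$spot_intensity, n)
  sig <- if ("sigma_um" %in% names(foci)) foci$sigma_um else
    rep(optics$spot_sigma_um, n)
  for (i in seq_len(n)) {
    # intrinsic spot (x) PSF = Gaussian with quadrature-summed sigmas;
    # amplitude is conserved peak-wise for the intrinsic spot scale
    sl <- sqrt(sig[i]^2 + optics$blur_lateral_um^2)
    sa <- sqrt((1.5 * sig[i])^2 + optics$blur_axial_um^2)
    peak <- amp[i] * (sig[i]^2 / sl^2) * (1.5 * sig[i] / sa)
    ix <- which(abs(ax$x - foci$x_um[i]) < 4 * sl)
    iy <- which(abs(ax$y - foci$y_um[i]) < 4 * sl)
    iz <- which(abs(ax$z - foci$z_um[i]) < 4 * sa)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax$x[ix] - foci$x_um[i])^2 / (2 * sl^2))
    gy <- exp(-(ax$y[iy] - foci$y_um[i])^2 / (2 * sl^2))
    gz <- exp(-(ax$z[iz] - foci$z_um[i])^2 / (2 * sa^2))
    vol[ix, iy, iz] <- vol[ix, iy, iz, drop = FALSE] +
      peak * (gx %o% gy) %o% gz
  }
  data <- vol + optics$background
  if (noise) {
    data <- array(stats::rpois(length(data), pmax(data, 0)), dim = dim(data)) +
      array(stats::rnorm(length(data), sd = optics$read_noise_sd),
            dim = dim(data))
  }
  structure(list(data = data, ideal = vol, optics = optics,
                 ground_truth = foci),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels (%.3f x %.3f um), %d ground-truth foci\n",
              d[1], d[2], d[3], x$optics$voxel_xy_um, x$optics$voxel_z_um,
              nrow(x$ground_truth)))
  invisible(x)
}

gaussian_psf_array <- function(dims, sigma_vox) {
  g1 <- function(n, s) {
    # wrap-around-centred 1D Gaussian (index 1 = origin)
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-d^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- g1(dims[1], sigma_vox[1])
  ky <- g1(dims[2], sigma_vox[2])
  kz <- g1(dims[3], sigma_vox[3])
  (kx %o% ky) %o% kz
}

fft_conv <- function(x, otf) Re(stats::fft(stats::fft(x) * otf, inverse = TRUE)) /
  length(x)

#' Richardson-Lucy restoration of a stack
#'
#' Fixed-iteration multiplicative deconvolution with the (known, synthetic)
#' Gaussian PSF of the optics; deterministic for a fixed input.
#'
#' @param stack An `image_stack`.
#' @param iterations Number of RL iterations.
#' @return The stack with `data` replaced by the restored volume (class kept).
#' @export
richardson_lucy <- function(stack, iterations = 10) {
  o <- stack$optics
  sig_vox <- c(o$blur_lateral_um / o$voxel_xy_um,
               o$blur_lateral_um / o$voxel_xy_um,
               o$blur_axial_um / o$voxel_z_um)
  psf <- gaussian_psf_array(dim(stack$data), sig_vox)
  otf <- stats::fft(psf)
  otf_conj <- Conj(otf)
  obs <- pmax(stack$data, 1e-6)
  est <- obs
  for (i in seq_len(iterations)) {
    blurred <- pmax(fft_conv(est, otf), 1e-6)
    est <- est * fft_conv(obs / blurred, otf_conj)
  }
  stack$data <- est
  stack$restored <- TRUE
  stack
}

#' Detection parameters
#'
#' @param restore_iterations Richardson-Lucy iterations (0 skips
#'   restoration).
#' @param smooth_um Post-restoration Gaussian smoothing sigma, um.
#' @param threshold_sd Detection threshold in robust SDs (MAD) above the
#'   median background.
#' @param min_separation_um Minimum distance between distinct foci, um
#'   (below the 0.5 um cluster linkage so cluster members stay countable).
#' @param window_um Half-width of the measurement window, um.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(restore_iterations = 10, smooth_um = 0.08,
                             threshold_sd = 10, min_separation_um = 0.25,
                             window_um = 0.5) {
  stopifnot(restore_iterations >= 0, smooth_um > 0, threshold_sd > 0,
            min_separation_um > 0)
  structure(as.list(environment()), class = "detection_params")
}

local_maxima_3d <- function(a) {
  d <- dim(a)
  res <- array(TRUE, dim = d)
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  pad <- -Inf
  for (s in seq_len(nrow(shifts))) {
    b <- array(pad, dim = d)
    xs <- max(1, 1 + shifts$dx[s]):min(d[1], d[1] + shifts$dx[s])
    ys <- max(1, 1 + shifts$dy[s]):min(d[2], d[2] + shifts$dy[s])
    zs <- max(1, 1 + shifts$dz[s]):min(d[3], d[3] + shifts$dz[s])
    b[xs, ys, zs] <- a[xs - shifts$dx[s], ys - shifts$dy[s],
                       zs - shifts$dz[s]]
    res <- res & (a >= b)
  }
  res
}

smooth_stack <- function(a, sigma_vox) {
  otf <- stats::fft(gaussian_psf_array(dim(a), sigma_vox))
  fft_conv(a, otf)
}

#' Detect foci in a 3D stack
#'
#' Restoration (fixed-iteration Richardson-Lucy with the known PSF), light
#' smoothing, robust background estimation, thresholded 3D local maxima with
#' a minimum mutual separation, then per-spot moment measurement
#' ([measure_width_3d()]). Deterministic for a fixed stack.
#'
#' @param stack An `image_stack` (must carry optics calibration).
#' @param params A [detection_params()].
#' @return data.table of focus measurements: `x_um, y_um, z_um, peak,
#'   intensity` (background-subtracted integral), `width_um` (lateral FWHM),
#'   `fit_ok`.
#' @export
detect_foci <- function(stack, params = detection_params()) {
  if (!inherits(stack, "image_stack") || is.null(stack$optics))
    stop("stack is missing optics calibration metadata", call. = FALSE)
  o <- stack$optics
  work <- if (params$restore_iterations > 0)
    richardson_lucy(stack, params$restore_iterations) else stack
  a <- work$data
  sm_vox <- c(params$smooth_um / o$voxel_xy_um,
              params$smooth_um / o$voxel_xy_um,
              max(params$smooth_um / o$voxel_z_um, 0.3))
  a <- smooth_stack(a, sm_vox)
  bg <- stats::median(a)
  noise <- stats::mad(a)
  thr <- bg + params$threshold_sd * max(noise, 1e-9)
  ax <- stack_axes(o)
  cand <- which(local_maxima_3d(a) & a > thr, arr.ind = TRUE)
  empty <- data.table::data.table(
    x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
    peak = numeric(0), intensity = numeric(0), width_um = numeric(0),
    fit_ok = logical(0))
  if (nrow(cand) == 0L) return(empty)
  vals <- a[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  pos <- cbind(ax$x[cand[, 1]], ax$y[cand[, 2]], ax$z[cand[, 3]])
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dmin <- min(sqrt(rowSums(
      (pos[keep, , drop = FALSE] - matrix(pos[i, ], sum(keep), 3L,
                                          byrow = TRUE))^2)))
    keep[i] <- dmin >= params$min_separation_um
  }
  cand <- cand[keep, , drop = FALSE]
  raw <- stack$data
  bg_raw <- stats::median(raw)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    m <- measure_spot(a, cand[i, ], o, ax, bg, params$window_um)
    # spots wider than the window: re-measure with a doubled window
    if (isTRUE(m$fit_ok) && !is.na(m$width_um) &&
        m$width_um > params$window_um)
      m <- measure_spot(a, cand[i, ], o, ax, bg, 2 * params$window_um)
    # degeneracy guard on the unprocessed data: a real spot covers several
    # raw voxels above half maximum, a lone hot voxel does not
    wx <- max(1L, round(params$window_um / o$voxel_xy_um))
    wz <- max(1L, round(params$window_um / o$voxel_z_um))
    d <- dim(raw)
    ix <- max(1, cand[i, 1] - wx):min(d[1], cand[i, 1] + wx)
    iy <- max(1, cand[i, 2] - wx):min(d[2], cand[i, 2] + wx)
    iz <- max(1, cand[i, 3] - wz):min(d[3], cand[i, 3] + wz)
    w_raw <- raw[ix, iy, iz] - bg_raw
    if (sum(w_raw > 0.5 * max(w_raw)) < 3L) {
      m$fit_ok <- FALSE
      m$width_um <- NA_real_
    }
    m
  })
  data.table::rbindlist(out)
}

# moment-based measurement of one spot around a peak voxel
measure_spot <- function(a, peak_idx, optics, ax, bg, window_um) {
  wx <- max(1L, round(window_um / optics$voxel_xy_um))
  wz <- max(1L, round(window_um / optics$voxel_z_um))
  d <- dim(a)
  ix <- max(1, peak_idx[1] - wx):min(d[1], peak_idx[1] + wx)
  iy <- max(1, peak_idx[2] - wx):min(d[2], peak_idx[2] + wx)
  iz <- max(1, peak_idx[3] - wz):min(d[3], peak_idx[3] + wz)
  w <- pmax(a[ix, iy, iz, drop = FALSE] - bg, 0)
  tot <- sum(w)
  n_above <- sum(w > 0.25 * max(w))
  if (tot <= 0 || n_above < 3L) {
    return(data.table::data.table(
      x_um = ax$x[peak_idx[1]], y_um = ax$y[peak_idx[2]],
      z_um = ax$z[peak_idx[3]], peak = a[peak_idx[1], peak_idx[2],
                                         peak_idx[3]],
      intensity = tot, width_um = NA_real_, fit_ok = FALSE))
  }
  px <- apply(w, 1L, sum); py <- apply(w, 2L, sum); pz <- apply(w, 3L, sum)
  mx <- sum(ax$x[ix] * px) / tot
  my <- sum(ax$y[iy] * py) / tot
  mz <- sum(ax$z[iz] * pz) / tot
  vx <- sum((ax$x[ix] - mx)^2 * px) / tot
  vy <- sum((ax$y[iy] - my)^2 * py) / tot
  lat_sd <- sqrt((vx + vy) / 2)
  data.table::data.table(
    x_um = mx, y_um = my, z_um = mz,
    peak = a[peak_idx[1], peak_idx[2], peak_idx[3]],
    intensity = tot, width_um = 2 * sqrt(2 * log(2)) * lat_sd,
    fit_ok = TRUE)
}

#' Lateral FWHM of a detected focus
#'
#' Measured on the restored volume as the moment FWHM in the lateral plane
#' within a window around the focus.
#'
#' @param stack An `image_stack` (restored or raw).
#' @param focus One row of the [detect_foci()] output (or any list with
#'   `x_um, y_um, z_um`).
#' @param window_um Measurement half-window, um.
#' @return Width in um, or `NA` (flagged) when the spot is degenerate.
#' @export
measure_width_3d <- function(stack, focus, window_um = 0.5) {
  o <- stack$optics
  ax <- stack_axes(o)
  idx <- c(which.min(abs(ax$x - focus$x_um)),
           which.min(abs(ax$y - focus$y_um)),
           which.min(abs(ax$z - focus$z_um)))
  bg <- stats::median(stack$data)
  measure_spot(stack$data, idx, o, ax, bg, window_um)$width_um
}

#' Maximum-intensity z projection
#'
#' Replicates the workflow of stacking all slices into one 2D image before
#' counting.
#'
#' @param stack An `image_stack`.
#' @return 2D matrix.
#' @export
max_projection <- function(stack) apply(stack$data, c(1L, 2L), max)

#' Label 3D connected components of a mask
#'
#' 26-connectivity; label propagation until fixpoint (components here are
#' small bright spots, so few iterations suffice).
#'
#' @param mask Logical 3D array.
#' @return Integer array, 0 = background, components numbered from 1.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(idx)) return(lab)
  arr <- arrayInd(idx, d)
  labels <- seq_along(idx)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  lin <- function(m) (m[, 3] - 1L) * d[1] * d[2] + (m[, 2] - 1L) * d[1] + m[, 1]
  pos_lin <- lin(arr)
  repeat {
    changed <- FALSE
    for (s in seq_len(nrow(shifts))) {
      nb <- sweep(arr, 2L, shifts[s, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      m <- match(lin(nb[ok, , drop = FALSE]), pos_lin)
      hit <- which(ok)[!is.na(m)]
      m <- m[!is.na(m)]
      if (length(m)) {
        newlab <- pmin(labels[hit], labels[m])
        if (any(newlab < labels[hit]) || any(newlab < labels[m])) {
          labels[hit] <- newlab
          labels[m] <- pmin(labels[m], newlab)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  labels <- as.integer(factor(labels, levels = unique(sort(labels))))
  lab[idx] <- labels
  lab
}

#' Write / read a stack as multi-page TIFF with sidecar metadata
#'
#' Intensities are stored as 16-bit (clamped at `scale_max`); voxel
#' calibration goes to `<path>.meta.yaml` and the ground truth, if present,
#' to `<path>.truth.tsv`.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param scale_max Intensity mapped to the 16-bit ceiling.
#' @return `write_stack` the path invisibly; `read_stack` an `image_stack`
#'   (without the noiseless `ideal` volume).
#' @export
write_stack <- function(stack, path, scale_max = 4096) {
  slices <- lapply(seq_len(dim(stack$data)[3]), function(k)
    pmin(pmax(stack$data[, , k] / scale_max, 0), 1))
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  o <- stack$optics
  meta <- list(voxel_xy_um = o$voxel_xy_um, voxel_z_um = o$voxel_z_um,
               n_slices = o$n_slices, depth_um = o$depth_um,
               field_um = o$field_um, blur_lateral_um = o$blur_lateral_um,
               blur_axial_um = o$blur_axial_um, background = o$background,
               read_noise_sd = o$read_noise_sd, scale_max = scale_max)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  if (!is.null(stack$ground_truth) && nrow(stack$ground_truth))
    utils::write.table(stack$ground_truth, paste0(path, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path))
    stop("stack is missing optics calibration metadata (", meta_path, ")",
         call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  slices <- tiff::readTIFF(path, all = TRUE)
  data <- simplify2array(slices) * meta$scale_max
  o <- optics_params(voxel_xy_um = meta$voxel_xy_um,
                     voxel_z_um = meta$voxel_z_um, n_slices = meta$n_slices,
                     depth_um = meta$depth_um, field_um = meta$field_um,
                     blur_lateral_um = meta$blur_lateral_um,
                     blur_axial_um = meta$blur_axial_um,
                     background = meta$background,
                     read_noise_sd = meta$read_noise_sd)
  gt_path <- paste0(path, ".truth.tsv")
  gt <- if (file.exists(gt_path))
    data.table::as.data.table(utils::read.table(gt_path, header = TRUE,
                                                sep = "\t")) else NULL
  structure(list(data = data, ideal = NULL, optics = o, ground_truth = gt),
            class = "image_stack")
}
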