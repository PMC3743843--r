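# Synthetic gammaH2AX focus generator: time-resolved focus sets under
# NHEJ-proficient / deficient repair kinetics, plus parametric track-like and
# X-ray-like point patterns. These emulate the qualitative behaviour of the
# experimental time courses; none of their defaults is fitted to measured
# focus counts.

#' Repair-kinetics parameters
#'
#' Focus loss is emulated as two-class exponential decay: foci in large
#' clusters (complex damage) disappear with the slow half-life, isolated or
#' small-cluster foci with the fast one. An NHEJ-deficient (XLF-like)
#' genotype multiplies both rates by `deficiency_factor` (~0: essentially no
#' repair over the observation window).
#'
#' @param fast_halflife_h Half-life of simple foci, hours.
#' @param slow_halflife_h Half-life of clustered/complex foci, hours.
#' @param slow_cluster_min Minimum cluster multiplicity scored as complex.
#' @param deficiency_factor Multiplier on both repair rates (1 = wild type,
#'   ~0.05 = XLF-deficient).
#' @param background_foci Spontaneous foci per cell (not subject to decay).
#' @return List of class `repair_params`.
#' @export
repair_params <- function(fast_halflife_h = 2, slow_halflife_h = 12,
                          slow_cluster_min = 4, deficiency_factor = 1,
                          background_foci = 0) {
  if (fast_halflife_h <= 0 || slow_halflife_h <= 0)
    stop("half-lives must be positive", call. = FALSE)
  if (deficiency_factor < 0)
    stop("`deficiency_factor` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "repair_params")
}

#' Repair parameters for a genotype
#'
#' @param genotype `"wt"` (NHEJ-proficient, 48BR-like) or `"xlf"`
#'   (NHEJ-deficient, 2BN-like).
#' @return A [repair_params()].
#' @export
genotype_params <- function(genotype = c("wt", "xlf")) {
  genotype <- match.arg(genotype)
  if (genotype == "wt") repair_params() else
    repair_params(deficiency_factor = 0.05)
}

as_foci <- function(points, ...) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  dt <- data.table::data.table(x_um = points[, 1], y_um = points[, 2],
                               z_um = points[, 3], ...)
  dt
}

#' Evolve a focus set over time under repair kinetics
#'
#' Each focus draws one exponential survival time at its class rate (slow
#' when it belongs to a cluster of at least `slow_cluster_min` members, fast
#' otherwise), scaled by the deficiency factor; it is present at time `t`
#' iff its survival time exceeds `t`. Counts are therefore monotone
#' non-increasing in time for every seed, and `deficiency_factor = 0` keeps
#' the set constant.
#'
#' @param foci data.table with `x_um, y_um, z_um` (e.g. from
#'   [foci_from_dsbs()] or [generate_xray_like()]).
#' @param params A [repair_params()].
#' @param times_h Non-negative time points, hours.
#' @param linkage_um Cluster linkage used to classify fast vs slow foci.
#' @return Named list (one element per time, names `"t<hours>"`) of focus
#'   data.tables with a `cluster_id` column (cluster membership at t = 0).
#' @export
evolve_foci <- function(foci, params = repair_params(), times_h,
                        linkage_um = 0.5) {
  if (any(times_h < 0)) stop("`times_h` must be >= 0", call. = FALSE)
  foci <- data.table::as.data.table(foci)
  n <- nrow(foci)
  cl <- if (n) cluster_foci(cbind(foci$x_um, foci$y_um, foci$z_um),
                            linkage_um) else integer(0)
  sizes <- if (n) as.integer(table(cl)[as.character(cl)]) else integer(0)
  halflife <- ifelse(sizes >= params$slow_cluster_min,
                     params$slow_halflife_h, params$fast_halflife_h)
  rate <- log(2) / halflife * params$deficiency_factor
  survival <- ifelse(rate > 0, stats::rexp(n, rate = pmax(rate, 1e-300)), Inf)
  out <- lapply(times_h, function(t) {
    keep <- survival > t
    f <- foci[keep]
    f[, cluster_id := cl[keep]]
    f
  })
  names(out) <- paste0("t", times_h)
  out
}

#' Convert DSB events to a focus set
#'
#' One focus per DSB at its position; the `complexity` attribute counts DSBs
#' merged within `merge_um` (foci closer than the microscope can ever
#' separate become one focus of higher complexity).
#'
#' @param dsbs DsbEvent table from [simulate_damage()].
#' @param merge_um Merge distance, um (default 0.05: sub-resolution).
#' @return Focus data.table `x_um, y_um, z_um, complexity`.
#' @export
foci_from_dsbs <- function(dsbs, merge_um = 0.05) {
  if (is.null(dsbs) || nrow(dsbs) == 0L)
    return(data.table::data.table(x_um = numeric(0), y_um = numeric(0),
                                  z_um = numeric(0), complexity = integer(0)))
  pts <- cbind(dsbs$x_um, dsbs$y_um, dsbs$z_um)
  cl <- cluster_foci(pts, merge_um)
  dt <- data.table::data.table(x_um = dsbs$x_um, y_um = dsbs$y_um,
                               z_um = dsbs$z_um, cl = cl)
  dt[, .(x_um = mean(x_um), y_um = mean(y_um), z_um = mean(z_um),
         complexity = .N), by = cl][, cl := NULL][]
}

#' Generate an X-ray-like (sparse) focus pattern
#'
#' Foci are placed uniformly over the nucleus in small clusters: cluster
#' multiplicities follow a truncated geometric law (mostly singletons, tail
#' bounded at `max_multiplicity`), members jittered by `spread_um`. This is
#' the low-LET reference pattern: no track, cluster multiplicities rarely
#' above ~7.
#'
#' @param n_foci Target total number of foci (>= 0).
#' @param nucleus A [nucleus_geometry()].
#' @param p_geom Geometric parameter of the multiplicity law (P(m) ~
#'   (1-p)^(m-1) p).
#' @param max_multiplicity Hard upper bound on cluster multiplicity.
#' @param spread_um Within-cluster member jitter SD, um.
#' @return Focus data.table `x_um, y_um, z_um, complexity` (complexity 1).
#' @export
generate_xray_like <- function(n_foci, nucleus = nucleus_geometry(),
                               p_geom = 0.5, max_multiplicity = 10,
                               spread_um = 0.15) {
  if (n_foci == 0)
    return(data.table::data.table(x_um = numeric(0), y_um = numeric(0),
                                  z_um = numeric(0), complexity = integer(0)))
  mult <- integer(0)
  while (sum(mult) < n_foci) {
    m <- pmin(1L + stats::rgeom(n_foci, p_geom), max_multiplicity)
    mult <- c(mult, m)
  }
  k <- which(cumsum(mult) >= n_foci)[1L]
  mult <- mult[seq_len(k)]
  mult[k] <- mult[k] - (sum(mult) - n_foci)
  centres <- sample_in_nucleus(length(mult), nucleus, margin_um = 0.3)
  idx <- rep(seq_along(mult), mult)
  pos <- centres[idx, , drop = FALSE] +
    matrix(stats::rnorm(3L * length(idx), sd = spread_um), ncol = 3L)
  as_foci(pos, complexity = 1L)
}

#' Generate an Fe-track-like (clustered) focus pattern
#'
#' Parametric stand-in for the DSB pattern of a single high-LET traversal:
#' clusters seeded along the track axis with large multiplicities (up to
#' ~30), members spread so that they merge in the raw image but separate
#' after restoration, plus a sparse delta-electron halo component.
#'
#' @param nucleus A [nucleus_geometry()].
#' @param clusters_per_um Cluster seeds per um of track.
#' @param mean_multiplicity Mean cluster multiplicity (Poisson, floor 1).
#' @param spread_um Within-cluster member spread SD, um.
#' @param halo_foci Expected number of isolated off-track (delta-electron)
#'   foci.
#' @param halo_radius_um Radial scale of the halo, um.
#' @return Focus data.table with `x_um, y_um, z_um, complexity, label`
#'   (`"track"` / `"halo"`); the track runs along x through the origin.
#' @export
generate_fe_track_like <- function(nucleus = nucleus_geometry(),
                                   clusters_per_um = 1.2,
                                   mean_multiplicity = 8,
                                   spread_um = 0.18, halo_foci = 4,
                                   halo_radius_um = 3) {
  half <- nucleus$diameter_um / 2 - 0.5
  n_cl <- stats::rpois(1L, clusters_per_um * 2 * half)
  parts <- list()
  if (n_cl > 0) {
    cx <- stats::runif(n_cl, -half, half)
    m <- pmax(1L, stats::rpois(n_cl, mean_multiplicity))
    idx <- rep(seq_len(n_cl), m)
    pos <- cbind(cx[idx], 0, 0) +
      matrix(stats::rnorm(3L * length(idx), sd = spread_um), ncol = 3L)
    parts$track <- as_foci(pos, complexity = 1L, label = "track")
  }
  n_halo <- stats::rpois(1L, halo_foci)
  if (n_halo > 0) {
    hx <- stats::runif(n_halo, -half, half)
    r <- abs(stats::rnorm(n_halo, sd = halo_radius_um))
    th <- stats::runif(n_halo, 0, 2 * pi)
    depth_scale <- nucleus$depth_um / nucleus$diameter_um
    pos <- cbind(hx, r * cos(th), r * sin(th) * depth_scale)
    parts$halo <- as_foci(pos, complexity = 1L, label = "halo")
  }
  if (length(parts) == 0L)
    return(as_foci(matrix(numeric(0), ncol = 3L), complexity = integer(0),
                   label = character(0)))
  data.table::rbindlist(parts)
}

#' Uniform random points inside the nuclear ellipsoid
#'
#' @param n Number of points.
#' @param nucleus A [nucleus_geometry()].
#' @param margin_um Keep-out margin from the boundary, um.
#' @return n x 3 matrix (um).
#' @export
sample_in_nucleus <- function(n, nucleus = nucleus_geometry(),
                              margin_um = 0) {
  a <- nucleus$diameter_um / 2 - margin_um
  c_ <- nucleus$depth_um / 2 - margin_um * nucleus$depth_um / nucleus$diameter_um
  out <- matrix(NA_real_, n, 3L)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 2L + 8L
    cand <- cbind(stats::runif(m, -a, a), stats::runif(m, -a, a),
                  stats::runif(m, -c_, c_))
    ok <- (cand[, 1] / a)^2 + (cand[, 2] / a)^2 + (cand[, 3] / c_)^2 <= 1
    take <- min(sum(ok), n - got)
    if (take > 0) {
      out[got + seq_len(take), ] <- cand[which(ok)[seq_len(take)], , drop = FALSE]
      got <- got + take
    }
  }
  out
}
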