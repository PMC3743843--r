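# Track structure: delta-electron spectrum, range-energy model, and stochastic
# energy-deposition patterns for a single heavy-ion traversal.

ELECTRON_MC2_MEV <- 0.5109989  # electron rest energy
AMU_MEV <- 931.494             # atomic mass unit

# Free calibration of the simplified transport model (see vignette):
#  - spectrum lower cutoff 10 eV (makes the sub-100 eV fraction 90% under 1/E^2)
#  - ~60 eV deposited per walk step, ~15 eV per collision left on the axis
TRACK_DEFAULTS <- list(
  emin_ev = 10,
  ev_per_step = 60,
  core_ev = 0,            # all collision energy is carried by the electron
  core_sigma_um = 0.004,  # impact-parameter spread of primary collisions
  dir_jitter = 0.5,
  spur_ev = 12,      # each energy-loss event resolves into ~12 eV ionisations
  spur_sigma_um = 0.0008
)

# range-energy power law: log-log linear between anchor points
# (10 eV, 1 nm), (100 eV, 3 nm), (10 keV, 4 um), (1.12 MeV, 300 um)
RANGE_ANCHORS_EV <- c(10, 100, 1e4, 1.12e6)
RANGE_ANCHORS_UM <- c(1e-3, 3e-3, 4, 300)

#' Kinematic maximum delta-electron energy
#'
#' Relativistic free-electron limit `2 m_e c^2 beta^2 gamma^2` for an ion of
#' the given kinetic energy per nucleon.
#'
#' @param energy_per_nucleon MeV per nucleon (> 0).
#' @return Maximum secondary-electron kinetic energy, eV.
#' @examples
#' kinematic_emax(416) / 1e6   # ~1.12 MeV for Fe at the cell surface
#' @export
kinematic_emax <- function(energy_per_nucleon) {
  if (any(!is.finite(energy_per_nucleon)) || any(energy_per_nucleon <= 0))
    stop("`energy_per_nucleon` must be positive", call. = FALSE)
  gamma <- 1 + energy_per_nucleon / AMU_MEV
  beta2 <- 1 - 1 / gamma^2
  2 * ELECTRON_MC2_MEV * beta2 * gamma^2 * 1e6
}

#' Closed-form CDF of the truncated 1/E^2 delta spectrum
#'
#' `P(E <= e)` for `dN/dE` proportional to `1/E^2` on `[emin, emax]`.
#'
#' @param e Energy (eV) at which to evaluate the CDF.
#' @param emax,emin Spectrum bounds, eV.
#' @return Probability.
#' @examples
#' delta_spectrum_cdf(100, kinematic_emax(416))  # ~0.90
#' @export
delta_spectrum_cdf <- function(e, emax, emin = TRACK_DEFAULTS$emin_ev) {
  if (emax <= emin || emin <= 0)
    stop("need emax > emin > 0", call. = FALSE)
  e <- pmin(pmax(e, emin), emax)
  (1 / emin - 1 / e) / (1 / emin - 1 / emax)
}

#' Sample delta-electron energies from the truncated 1/E^2 spectrum
#'
#' Inverse-CDF sampling of `dN/dE` proportional to `1/E^2` on `[emin, emax]`.
#'
#' @param n Number of samples (>= 0).
#' @param emax Upper (kinematic) energy bound, eV.
#' @param emin Lower cutoff, eV; default 10 eV.
#' @return Numeric vector of energies within `[emin, emax]`.
#' @examples
#' e <- sample_delta_spectrum(1e4, kinematic_emax(416))
#' mean(e < 100)  # ~0.90
#' @export
sample_delta_spectrum <- function(n, emax, emin = TRACK_DEFAULTS$emin_ev) {
  if (emax <= emin || emin <= 0)
    stop("need emax > emin > 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  1 / (1 / emin - u * (1 / emin - 1 / emax))
}

#' Electron range-energy model
#'
#' Piecewise power law (log-log linear between pinned anchors) giving the
#' straight-ahead range of an electron of the given kinetic energy: about a
#' nanometre at the 10 eV cutoff, a few nm at 100 eV, 2.5 um at 10 keV and a
#' few hundred um at the MeV kinematic tail.
#'
#' @param energy_ev Electron kinetic energy, eV; must be >= the 10 eV cutoff.
#' @return Range in um; strictly increasing in energy.
#' @examples
#' electron_range(c(10, 100, 1e4))
#' @export
electron_range <- function(energy_ev) {
  if (any(!is.finite(energy_ev)) || any(energy_ev < TRACK_DEFAULTS$emin_ev))
    stop("`energy_ev` must be >= the 10 eV spectrum cutoff", call. = FALSE)
  le <- log(energy_ev)
  lx <- log(RANGE_ANCHORS_EV)
  ly <- log(RANGE_ANCHORS_UM)
  seg <- findInterval(le, lx, rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), 3L)  # extrapolate last segment beyond 1.12 MeV
  slope <- (ly[seg + 1L] - ly[seg]) / (lx[seg + 1L] - lx[seg])
  exp(ly[seg] + slope * (le - lx[seg]))
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Generate one stochastic track realisation
#'
#' Simplified track-structure model: ionising collisions occur along the ion
#' axis (smeared by the `core_sigma_um` impact-parameter spread); each
#' collision may leave `core_ev` on the axis (tagged `core`) and ejects a
#' delta electron with energy drawn from the truncated 1/E^2 spectrum. The
#' electron loses roughly `ev_per_step` eV per step of a persistent random
#' walk whose step lengths follow the residual-range law, so it ends in a
#' dense terminal cluster at [electron_range()] of its energy; each
#' energy-loss event is further resolved into ~`spur_ev` eV sub-ionisations
#' within `spur_sigma_um` (tagged `delta`). Electrons are drawn until the
#' cumulative collision energy fills the budget `LET x path_length`, which
#' calibrates every realisation to the nominal LET (final electron clamped
#' to the remaining budget).
#'
#' Emission is azimuthally uniform with polar angle from the free-electron
#' kinematics `cos(theta) = sqrt(E/Emax)`: slow electrons leave near
#' perpendicular, the rare energetic ones are thrown forward.
#'
#' @param beam An [ion_beam()].
#' @param entry Entry point, numeric length-3 (um).
#' @param direction Beam direction, numeric length-3; need not be normalised.
#' @param path_length_um Traversed path length, um (> 0; 0 gives an empty
#'   track).
#' @param seed Optional integer seed recorded in the realisation; when given,
#'   the track is reproducible independently of the caller's RNG state.
#' @param transport Named list overriding entries of the transport
#'   calibration (`emin_ev`, `ev_per_step`, `core_ev`, `dir_jitter`,
#'   `spur_ev`, `spur_sigma_um`).
#' @return A `track_realisation`: list with `beam`, `entry`, `direction`
#'   (unit), `path_length_um`, `seed`, and `depositions`, a data.table with
#'   columns `x_um, y_um, z_um, energy_ev, origin, parent_id`.
#' @examples
#' tr <- generate_track(ion_beam("Fe"), c(-6.335, 0, 0), c(1, 0, 0), 12.67,
#'                      seed = 1)
#' sum(tr$depositions$energy_ev) / 12.67 / 1e3  # ~200 keV/um
#' @export
generate_track <- function(beam, entry = c(0, 0, 0), direction = c(1, 0, 0),
                           path_length_um, seed = NULL,
                           transport = TRACK_DEFAULTS) {
  stopifnot(inherits(beam, "ion_beam"))
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("`direction` must be a non-zero vector", call. = FALSE)
  if (path_length_um < 0)
    stop("`path_length_um` must be >= 0", call. = FALSE)
  u <- direction / nrm
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  p <- utils::modifyList(TRACK_DEFAULTS, transport)
  emax <- kinematic_emax(beam$energy_per_nucleon)
  budget_ev <- beam$let * 1e3 * path_length_um
  empty <- data.table::data.table(
    x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
    energy_ev = numeric(0), origin = character(0), parent_id = integer(0))
  if (budget_ev < p$emin_ev + p$core_ev) {
    return(structure(list(beam = beam, entry = entry, direction = u,
                          path_length_um = path_length_um,
                          seed = if (is.null(seed)) NA_integer_ else seed,
                          depositions = empty),
                     class = "track_realisation"))
  }

  # draw collisions until the energy budget is filled
  mean_e <- log(emax / p$emin_ev) / (1 / p$emin_ev - 1 / emax) + p$core_ev
  energies <- numeric(0)
  repeat {
    need <- budget_ev - sum(energies) - length(energies) * p$core_ev
    if (need <= 0) break
    n_extra <- max(16L, ceiling(1.2 * need / mean_e))
    energies <- c(energies, sample_delta_spectrum(n_extra, emax, p$emin_ev))
  }
  tot <- cumsum(energies + p$core_ev)
  k <- which(tot >= budget_ev)[1L]
  energies <- energies[seq_len(k)]
  # clamp the last electron to the remaining budget (keeps every track on-LET)
  overshoot <- tot[k] - budget_ev
  energies[k] <- max(p$emin_ev, energies[k] - overshoot)
  n <- length(energies)

  # collision sites uniform along the traversed path, smeared perpendicular
  # to the axis by the impact-parameter spread of the physical core
  s <- sort(stats::runif(n, 0, path_length_um))
  sites <- cbind(entry[1] + s * u[1], entry[2] + s * u[2], entry[3] + s * u[3])

  # emission directions: kinematic polar angle, uniform azimuth
  # orthonormal frame (u, e1, e2)
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ct <- sqrt(pmin(energies / emax, 1))
  st <- sqrt(1 - ct^2)
  phi <- stats::runif(n, 0, 2 * pi)
  if (p$core_sigma_um > 0) {
    sites <- sites +
      stats::rnorm(n, sd = p$core_sigma_um) %o% e1 +
      stats::rnorm(n, sd = p$core_sigma_um) %o% e2
  }
  d0 <- ct %o% u +
    (st * cos(phi)) %o% e1 +
    (st * sin(phi)) %o% e2

  n_steps <- pmax(1L, as.integer(round(energies / p$ev_per_step)))
  rng_um <- electron_range(energies)

  # single-step electrons (the bulk of the spectrum): one deposit at range
  one <- n_steps == 1L
  dep_list <- vector("list", 2L)
  if (any(one)) {
    pos <- sites[one, , drop = FALSE] + rng_um[one] * d0[one, , drop = FALSE]
    dep_list[[1L]] <- data.table::data.table(
      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
      energy_ev = energies[one], origin = "delta",
      parent_id = which(one))
  }
  multi <- which(!one)
  if (length(multi)) {
    parts <- vector("list", length(multi))
    for (j in seq_along(multi)) {
      i <- multi[j]
      k_i <- n_steps[i]
      # deposition spacing from the residual range: sparse while fast, a
      # dense terminal cluster where the electron stops (at its full range)
      e_grid <- pmax(energies[i] - (0:k_i) * (energies[i] / k_i), p$emin_ev)
      steps <- -diff(electron_range(e_grid))
      # persistent walk: direction = normalised (d0 + Brownian perturbation);
      # the accumulating jitter makes slow electrons tortuous (elastic
      # scattering: dense local blobs) while fast ones run nearly straight
      sd_jit <- p$dir_jitter * min(1, (1e3 / energies[i])^0.25)
      w <- apply(matrix(stats::rnorm(3L * k_i, sd = sd_jit), ncol = 3L),
                 2L, cumsum)
      dirs <- normalize_rows(matrix(d0[i, ], k_i, 3L, byrow = TRUE) + w)
      pos <- matrix(sites[i, ], k_i, 3L, byrow = TRUE) +
        apply(dirs * steps, 2L, cumsum)
      parts[[j]] <- data.table::data.table(
        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
        energy_ev = energies[i] / k_i, origin = "delta", parent_id = i)
    }
    dep_list[[2L]] <- data.table::rbindlist(parts)
  }
  parts <- dep_list[!vapply(dep_list, is.null, TRUE)]
  if (p$core_ev > 0) {
    core <- data.table::data.table(
      x_um = sites[, 1], y_um = sites[, 2], z_um = sites[, 3],
      energy_ev = p$core_ev, origin = "core", parent_id = seq_len(n))
    parts <- c(list(core), parts)
  }
  deps <- data.table::rbindlist(parts)
  # spur substructure: each energy-loss event is a nanometre-scale cluster of
  # ~spur_ev ionisations rather than a single point
  m <- pmax(1L, as.integer(round(deps$energy_ev / p$spur_ev)))
  idx <- rep(seq_len(nrow(deps)), m)
  mm <- length(idx)
  deps <- data.table::data.table(
    x_um = deps$x_um[idx] + stats::rnorm(mm, sd = p$spur_sigma_um),
    y_um = deps$y_um[idx] + stats::rnorm(mm, sd = p$spur_sigma_um),
    z_um = deps$z_um[idx] + stats::rnorm(mm, sd = p$spur_sigma_um),
    energy_ev = deps$energy_ev[idx] / m[idx],
    origin = deps$origin[idx], parent_id = deps$parent_id[idx])

  structure(list(beam = beam, entry = entry, direction = u,
                 path_length_um = path_length_um,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 depositions = deps),
            class = "track_realisation")
}

#' @export
print.track_realisation <- function(x, ...) {
  e <- sum(x$depositions$energy_ev)
  cat(sprintf("<track_realisation> %s, %.3g eV in %d depositions over %.2f um (%.1f keV/um)\n",
              x$beam$species, e, nrow(x$depositions), x$path_length_um,
              if (x$path_length_um > 0) e / 1e3 / x$path_length_um else 0))
  invisible(x)
}

#' Azimuthally averaged radial energy density of a track
#'
#' Histogram of deposited energy per unit volume in cylindrical shells around
#' the track axis, on logarithmic radial bins.
#'
#' @param track A `track_realisation` (or a list of them sharing one axis).
#' @param rmin_um,rmax_um Radial window, um.
#' @param nbins Number of logarithmic bins.
#' @return data.table with `r_um` (geometric bin centre) and `density_ev_um3`.
#' @export
radial_energy_profile <- function(track, rmin_um = 0.005, rmax_um = 5,
                                  nbins = 24) {
  tracks <- if (inherits(track, "track_realisation")) list(track) else track
  ax <- tracks[[1L]]
  edges <- exp(seq(log(rmin_um), log(rmax_um), length.out = nbins + 1L))
  e_sum <- numeric(nbins)
  path <- 0
  for (tr in tracks) {
    d <- tr$depositions
    r <- radial_distance(cbind(d$x_um, d$y_um, d$z_um),
                         axis_point = ax$entry, axis_dir = ax$direction)
    b <- findInterval(r, edges)
    keep <- b >= 1L & b <= nbins
    e_sum <- e_sum + as.numeric(
      rowsum(d$energy_ev[keep], factor(b[keep], levels = seq_len(nbins))))
    path <- path + tr$path_length_um
  }
  shell_vol <- pi * (edges[-1L]^2 - edges[-(nbins + 1L)]^2) * path
  data.table::data.table(
    r_um = sqrt(edges[-1L] * edges[-(nbins + 1L)]),
    energy_ev = e_sum,
    density_ev_um3 = e_sum / shell_vol)
}

#' Write / read a deposition table as tab-separated text
#'
#' Columns `x_um, y_um, z_um, energy_ev, origin, parent_id`; transparently
#' gzipped when the path ends in `.gz`.
#'
#' @param depositions A deposition data.table (e.g. `track$depositions`).
#' @param path Output file path.
#' @return `write_depositions` the path, invisibly; `read_depositions` a
#'   data.table.
#' @export
write_depositions <- function(depositions, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(depositions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_depositions
#' @export
read_depositions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.table::as.data.table(df)
}
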