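# DNA target model and strand-break / DSB scoring.
#
# Break rules: a direct single-strand break wherever > 10 eV (strictly) is
# deposited in a sugar-phosphate site; indirect breaks with probability 0.13
# per OH-radical/backbone encounter; a DSB when two SSBs sit on opposite
# strands within 10 bp (inclusive).

#' Damage-model parameters
#'
#' The break-scoring rules (energy threshold, indirect probability, DSB
#' window, DNA density, segment length) default to their reference values.
#' The backbone geometry follows common track-structure conventions; the radical
#' chemistry (`g_oh_per_100ev`, `diffusion_rms_nm`, `reaction_radius_nm`) is
#' the model's free calibration, chosen so the shipped defaults reproduce the
#' reference Fe-track DSB yields (see the methods vignette).
#'
#' @param e_threshold_ev Direct-break energy threshold per site, eV (strict >).
#' @param p_indirect Break probability per radical-backbone encounter.
#' @param dsb_window_bp Maximum opposite-strand separation scored as a DSB
#'   (inclusive).
#' @param dna_density_mbp_um3 DNA concentration, Mbp/um^3.
#' @param segment_bp Length of one linear B-form segment, bp.
#' @param helix_radius_nm Backbone helical radius, nm.
#' @param site_radius_nm Radius of the sugar-phosphate site sphere, nm.
#' @param rise_nm_per_bp Axial rise per bp, nm.
#' @param bp_per_turn Helical period, bp per turn (fixed B-form value).
#' @param g_oh_per_100ev OH-radical yield per 100 eV deposited in water.
#' @param diffusion_rms_nm RMS 3D displacement of the one-jump radical
#'   diffusion step, nm (scavenging-limited lifetime).
#' @param reaction_radius_nm Radical-backbone reaction radius, nm.
#' @return A list of class `damage_params`.
#' @export
damage_params <- function(e_threshold_ev = 10, p_indirect = 0.13,
                          dsb_window_bp = 10, dna_density_mbp_um3 = 13.4,
                          segment_bp = 150, helix_radius_nm = 1.0,
                          site_radius_nm = 0.4, rise_nm_per_bp = 0.34,
                          bp_per_turn = 10.5, g_oh_per_100ev = 0.45,
                          diffusion_rms_nm = 1.5, reaction_radius_nm = 1.0) {
  if (dna_density_mbp_um3 <= 0) stop("DNA density must be positive", call. = FALSE)
  if (p_indirect < 0 || p_indirect > 1) stop("`p_indirect` must be in [0,1]", call. = FALSE)
  structure(as.list(environment()), class = "damage_params")
}

CELL_UM <- 0.06  # lazy-instantiation grid pitch, um

#' Instantiate DNA segments exhaustively in a box
#'
#' Segment count is Poisson with mean `volume x density x 1e6 / segment_bp`;
#' centres uniform, orientations isotropic. This is the explicit counterpart
#' of the lazy instantiation used by [simulate_damage()]; both follow the
#' same law.
#'
#' @param lower,upper Numeric length-3 box corners, um.
#' @param params A [damage_params()].
#' @return data.table with `segment_id`, centre `x_um,y_um,z_um` and
#'   orientation `ux,uy,uz` (unit vectors).
#' @examples
#' seg <- instantiate_segments(c(0, 0, 0), c(0.2, 0.2, 0.2))
#' @export
instantiate_segments <- function(lower, upper, params = damage_params()) {
  stopifnot(length(lower) == 3L, length(upper) == 3L, all(upper >= lower))
  vol <- prod(upper - lower)
  n <- stats::rpois(1L, vol * params$dna_density_mbp_um3 * 1e6 / params$segment_bp)
  if (n == 0L)
    return(data.table::data.table(
      segment_id = integer(0), x_um = numeric(0), y_um = numeric(0),
      z_um = numeric(0), ux = numeric(0), uy = numeric(0), uz = numeric(0)))
  ctr <- sapply(1:3, function(k) stats::runif(n, lower[k], upper[k]))
  u <- matrix(stats::rnorm(3L * n), ncol = 3L)
  u <- normalize_rows(u)
  data.table::data.table(
    segment_id = seq_len(n), x_um = ctr[, 1], y_um = ctr[, 2], z_um = ctr[, 3],
    ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

# transverse frame for a unit vector, matching the C++ kernel convention
segment_frame <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Position of one sugar-phosphate site
#'
#' @param segment One-row segment (as from [instantiate_segments()]).
#' @param strand 0 or 1.
#' @param bp 0-based bp index along the segment.
#' @param params A [damage_params()].
#' @return Numeric length-3 position, um.
#' @export
site_position <- function(segment, strand, bp, params = damage_params()) {
  u <- c(segment$ux, segment$uy, segment$uz)
  fr <- segment_frame(u)
  axial <- (bp - (params$segment_bp - 1) / 2) * params$rise_nm_per_bp * 1e-3
  phi <- 2 * pi * bp / params$bp_per_turn + strand * pi
  c(segment$x_um, segment$y_um, segment$z_um) + axial * u +
    params$helix_radius_nm * 1e-3 * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
}

# Assign each point to its nearest backbone site within `radius_um`, against
# an explicit segment table. Pure data.table; used by the exhaustive scoring
# route and by tests.
assign_sites_explicit <- function(points, radius_um, segments,
                                  params = damage_params()) {
  n <- nrow(points)
  na_out <- data.table::data.table(
    point = seq_len(n), segment_id = NA_integer_, strand = NA_integer_,
    bp = NA_integer_, site_x = NA_real_, site_y = NA_real_, site_z = NA_real_)
  if (n == 0L || nrow(segments) == 0L) return(na_out)
  half_len <- (params$segment_bp - 1) / 2 * params$rise_nm_per_bp * 1e-3
  hr <- params$helix_radius_nm * 1e-3
  rise <- params$rise_nm_per_bp * 1e-3
  reach <- half_len + hr + radius_um
  key <- function(ix, iy, iz) paste(ix, iy, iz)
  segs <- data.table::copy(segments)
  segs[, cell := key(floor(x_um / CELL_UM), floor(y_um / CELL_UM),
                     floor(z_um / CELL_UM))]
  halo <- ceiling(reach / CELL_UM)
  off <- as.matrix(expand.grid(a = -halo:halo, b = -halo:halo, c = -halo:halo))
  pix <- floor(points[, 1] / CELL_UM); piy <- floor(points[, 2] / CELL_UM)
  piz <- floor(points[, 3] / CELL_UM)
  cand <- data.table::rbindlist(lapply(seq_len(nrow(off)), function(j)
    data.table::data.table(point = seq_len(n),
                           cell = key(pix + off[j, 1], piy + off[j, 2],
                                      piz + off[j, 3]))))
  pairs <- merge(cand, segs, by = "cell", allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) return(na_out)
  pairs[, `:=`(px = points[point, 1], py = points[point, 2],
               pz = points[point, 3])]
  pairs[, `:=`(vx = px - x_um, vy = py - y_um, vz = pz - z_um)]
  pairs[, t_ax := vx * ux + vy * uy + vz * uz]
  pairs <- pairs[abs(t_ax) <= half_len + radius_um]
  if (nrow(pairs) == 0L) return(na_out)
  pairs[, r_perp := sqrt((vx - t_ax * ux)^2 + (vy - t_ax * uy)^2 +
                         (vz - t_ax * uz)^2)]
  pairs <- pairs[abs(r_perp - hr) <= radius_um]
  if (nrow(pairs) == 0L) return(na_out)
  # expand to candidate (bp, strand) sites around the axial coordinate
  kspan <- ceiling(radius_um / rise)
  pairs[, bp0 := round(t_ax / rise + (params$segment_bp - 1) / 2)]
  grid <- data.table::CJ(dk = -kspan:kspan, strand = 0:1)
  sites <- pairs[, {
    bp_cand <- rep(bp0, nrow(grid)) + grid$dk
    ok <- bp_cand >= 0 & bp_cand <= params$segment_bp - 1
    list(bp = bp_cand[ok], strand = grid$strand[ok])
  }, by = .(point, segment_id, px, py, pz, x_um, y_um, z_um, ux, uy, uz)]
  if (nrow(sites) == 0L) return(na_out)
  # site positions (frame computed per segment)
  fr <- sites[, {
    f <- segment_frame(c(ux[1], uy[1], uz[1]))
    .(e1x = f$e1[1], e1y = f$e1[2], e1z = f$e1[3],
      e2x = f$e2[1], e2y = f$e2[2], e2z = f$e2[3])
  }, by = segment_id]
  sites <- merge(sites, fr, by = "segment_id")
  sites[, axial := (bp - (params$segment_bp - 1) / 2) * rise]
  sites[, phi := 2 * pi * bp / params$bp_per_turn + strand * pi]
  sites[, `:=`(sx = x_um + axial * ux + hr * (cos(phi) * e1x + sin(phi) * e2x),
               sy = y_um + axial * uy + hr * (cos(phi) * e1y + sin(phi) * e2y),
               sz = z_um + axial * uz + hr * (cos(phi) * e1z + sin(phi) * e2z))]
  sites[, d2 := (px - sx)^2 + (py - sy)^2 + (pz - sz)^2]
  sites <- sites[d2 <= radius_um^2]
  if (nrow(sites) == 0L) return(na_out)
  sites[, `:=`(bp = as.integer(bp), strand = as.integer(strand))]
  best <- sites[order(d2), .SD[1L], by = point,
                .SDcols = c("segment_id", "strand", "bp", "sx", "sy", "sz")]
  out <- merge(na_out[, .(point)], best, by = "point", all.x = TRUE)
  data.table::setnames(out, c("sx", "sy", "sz"),
                       c("site_x", "site_y", "site_z"))
  out[]
}

empty_breaks <- function() data.table::data.table(
  segment_id = integer(0), strand = integer(0), bp = integer(0),
  mechanism = character(0), x_um = numeric(0), y_um = numeric(0),
  z_um = numeric(0))

#' Score direct strand breaks
#'
#' A break is recorded at a (segment, strand, bp) site when the energy of the
#' depositions assigned to that site sums to strictly more than the 10 eV
#' threshold. Each deposition is assigned to its nearest site within the
#' site radius; depositions missing all DNA score nothing.
#'
#' @param depositions data.table with `x_um, y_um, z_um, energy_ev` (e.g.
#'   `track$depositions`).
#' @param segments Explicit segment table from [instantiate_segments()].
#' @param params A [damage_params()].
#' @return StrandBreak data.table: `segment_id, strand, bp, mechanism,
#'   x_um, y_um, z_um` (site position), at most one row per site.
#' @export
score_direct <- function(depositions, segments, params = damage_params()) {
  if (is.null(depositions) || nrow(depositions) == 0L) return(empty_breaks())
  pts <- cbind(depositions$x_um, depositions$y_um, depositions$z_um)
  asg <- assign_sites_explicit(pts, params$site_radius_nm * 1e-3, segments,
                               params)
  asg[, energy_ev := depositions$energy_ev]
  hits <- asg[!is.na(segment_id),
              .(energy_ev = sum(energy_ev), x_um = site_x[1L],
                y_um = site_y[1L], z_um = site_z[1L]),
              by = .(segment_id, strand, bp)]
  hits <- hits[energy_ev > params$e_threshold_ev]
  if (nrow(hits) == 0L) return(empty_breaks())
  hits[, mechanism := "direct"]
  hits[, .(segment_id, strand, bp, mechanism, x_um, y_um, z_um)]
}

#' Generate OH radicals from water energy depositions
#'
#' Radical count per deposition is Poisson with mean `energy x G / 100 eV`;
#' each radical takes one isotropic Gaussian jump of the configured RMS
#' diffusion length from its parent deposition.
#'
#' @param depositions data.table with `x_um, y_um, z_um, energy_ev`.
#' @param params A [damage_params()].
#' @return data.table `x_um, y_um, z_um, parent` (row of the parent
#'   deposition).
#' @export
generate_radicals <- function(depositions, params = damage_params()) {
  if (is.null(depositions) || nrow(depositions) == 0L)
    return(data.table::data.table(x_um = numeric(0), y_um = numeric(0),
                                  z_um = numeric(0), parent = integer(0)))
  n_rad <- stats::rpois(nrow(depositions),
                        depositions$energy_ev * params$g_oh_per_100ev / 100)
  parent <- rep(seq_len(nrow(depositions)), n_rad)
  m <- length(parent)
  sd_axis <- params$diffusion_rms_nm * 1e-3 / sqrt(3)
  data.table::data.table(
    x_um = depositions$x_um[parent] + stats::rnorm(m, sd = sd_axis),
    y_um = depositions$y_um[parent] + stats::rnorm(m, sd = sd_axis),
    z_um = depositions$z_um[parent] + stats::rnorm(m, sd = sd_axis),
    parent = parent)
}

#' Score indirect (radical-mediated) strand breaks
#'
#' Radicals are generated from the depositions (or supplied directly via
#' `radicals`); a radical reaching within the reaction radius of a backbone
#' site reacts with its nearest such site and induces a break there with
#' probability `p_indirect`. At most one break is kept per site.
#'
#' @param depositions Deposition table (ignored when `radicals` is given).
#' @param segments Explicit segment table.
#' @param params A [damage_params()].
#' @param radicals Optional pre-generated radical table
#'   (`x_um, y_um, z_um`).
#' @return StrandBreak data.table as in [score_direct()], with
#'   `mechanism = "indirect"`.
#' @export
score_indirect <- function(depositions, segments, params = damage_params(),
                           radicals = NULL) {
  if (is.null(radicals)) radicals <- generate_radicals(depositions, params)
  if (nrow(radicals) == 0L) return(empty_breaks())
  pts <- cbind(radicals$x_um, radicals$y_um, radicals$z_um)
  asg <- assign_sites_explicit(pts, params$reaction_radius_nm * 1e-3,
                               segments, params)
  enc <- asg[!is.na(segment_id)]
  if (nrow(enc) == 0L) return(empty_breaks())
  enc <- enc[stats::runif(.N) < params$p_indirect]
  if (nrow(enc) == 0L) return(empty_breaks())
  brk <- enc[, .SD[1L], by = .(segment_id, strand, bp),
             .SDcols = c("site_x", "site_y", "site_z")]
  brk[, mechanism := "indirect"]
  data.table::setnames(brk, c("site_x", "site_y", "site_z"),
                       c("x_um", "y_um", "z_um"))
  brk[, .(segment_id, strand, bp, mechanism, x_um, y_um, z_um)]
}

#' Pair strand breaks into double-strand breaks
#'
#' Within each segment, opposite-strand break pairs separated by at most the
#' DSB window (10 bp, inclusive) are matched into the maximum number of
#' DSBs; among maximum matchings the one with the smallest total bp
#' separation is chosen (candidate pairs considered by ascending separation,
#' ties broken by the lower bp index). Each break enters at most one DSB.
#' Break sets per segment are tiny, so the optimum is found by bounded
#' search; pathological segments (> 18 candidate pairs) fall back to the
#' greedy rule.
#'
#' @param breaks StrandBreak table from [score_direct()] /
#'   [score_indirect()] (rows may be concatenated; duplicate sites keep the
#'   first, so bind direct breaks first).
#' @param params A [damage_params()].
#' @return DsbEvent data.table: `dsb_id, segment_id, bp0, bp1, bp_midpoint,
#'   x_um, y_um, z_um` (midpoint of the two break sites), `mechanisms`
#'   (e.g. `"direct+indirect"`).
#' @examples
#' b <- data.table::data.table(segment_id = 1L, strand = c(0L, 1L),
#'                             bp = c(100L, 109L), mechanism = "direct",
#'                             x_um = 0, y_um = 0, z_um = 0)
#' pair_dsbs(b)
#' @export
pair_dsbs <- function(breaks, params = damage_params()) {
  empty <- data.table::data.table(
    dsb_id = integer(0), segment_id = integer(0), bp0 = integer(0),
    bp1 = integer(0), bp_midpoint = numeric(0), x_um = numeric(0),
    y_um = numeric(0), z_um = numeric(0), mechanisms = character(0))
  if (is.null(breaks) || nrow(breaks) == 0L) return(empty)
  breaks <- unique(data.table::as.data.table(breaks),
                   by = c("segment_id", "strand", "bp"))
  out <- list()
  for (sid in unique(breaks$segment_id)) {
    b <- breaks[segment_id == sid]
    b0 <- b[strand == 0L]; b1 <- b[strand == 1L]
    if (nrow(b0) == 0L || nrow(b1) == 0L) next
    cand <- data.table::CJ(i = seq_len(nrow(b0)), j = seq_len(nrow(b1)))
    cand[, dbp := abs(b0$bp[i] - b1$bp[j])]
    cand <- cand[dbp <= params$dsb_window_bp]
    if (nrow(cand) == 0L) next
    cand <- cand[order(dbp, pmin(b0$bp[i], b1$bp[j]), b0$bp[i])]
    take <- match_pairs(cand, nrow(b0), nrow(b1))
    for (r in take) {
      i <- cand$i[r]; j <- cand$j[r]
      out[[length(out) + 1L]] <- data.table::data.table(
        segment_id = sid, bp0 = b0$bp[i], bp1 = b1$bp[j],
        bp_midpoint = (b0$bp[i] + b1$bp[j]) / 2,
        x_um = (b0$x_um[i] + b1$x_um[j]) / 2,
        y_um = (b0$y_um[i] + b1$y_um[j]) / 2,
        z_um = (b0$z_um[i] + b1$z_um[j]) / 2,
        mechanisms = paste(sort(c(b0$mechanism[i], b1$mechanism[j])),
                           collapse = "+"))
    }
  }
  if (length(out) == 0L) return(empty)
  res <- data.table::rbindlist(out)
  res[, dsb_id := .I]
  data.table::setcolorder(res, "dsb_id")
  res[]
}

# choose candidate pairs realising the maximum matching with minimum total
# bp separation; `cand` rows sorted by preference (ascending dbp, then bp)
match_pairs <- function(cand, n0, n1) {
  nr <- nrow(cand)
  greedy <- function() {
    used0 <- logical(n0); used1 <- logical(n1); sel <- integer(0)
    for (r in seq_len(nr)) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used0[i] || used1[j]) next
      used0[i] <- TRUE; used1[j] <- TRUE
      sel <- c(sel, r)
    }
    sel
  }
  if (nr > 18L) return(greedy())
  best_count <- -1L; best_sum <- Inf; best_sel <- integer(0)
  rec <- function(k, used0, used1, count, dsum, sel) {
    if (count + (nr - k + 1L) < best_count) return(invisible())
    if (k > nr) {
      if (count > best_count ||
          (count == best_count && dsum < best_sum)) {
        best_count <<- count; best_sum <<- dsum; best_sel <<- sel
      }
      return(invisible())
    }
    i <- cand$i[k]; j <- cand$j[k]
    if (!used0[i] && !used1[j]) {
      used0[i] <- TRUE; used1[j] <- TRUE
      rec(k + 1L, used0, used1, count + 1L, dsum + cand$dbp[k], c(sel, k))
      used0[i] <- FALSE; used1[j] <- FALSE
    }
    rec(k + 1L, used0, used1, count, dsum, sel)
  }
  rec(1L, logical(n0), logical(n1), 0L, 0, integer(0))
  best_sel
}

inside_ellipsoid <- function(points, nucleus) {
  a <- nucleus$diameter_um / 2
  c_ <- nucleus$depth_um / 2
  (points[, 1] / a)^2 + (points[, 2] / a)^2 + (points[, 3] / c_)^2 <= 1
}

# chord length of the line entry + t*dir inside the nuclear ellipsoid
# (nucleus centred at the origin, polar axis along z)
nucleus_chord <- function(nucleus, entry, direction) {
  a <- nucleus$diameter_um / 2
  c_ <- nucleus$depth_um / 2
  u <- direction / sqrt(sum(direction^2))
  s <- c(1 / a^2, 1 / a^2, 1 / c_^2)
  A <- sum(s * u^2)
  B <- 2 * sum(s * entry * u)
  C <- sum(s * entry^2) - 1
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(list(length = 0, t0 = NA_real_, t1 = NA_real_))
  t0 <- (-B - sqrt(disc)) / (2 * A)
  t1 <- (-B + sqrt(disc)) / (2 * A)
  list(length = t1 - t0, t0 = t0, t1 = t1)
}

#' Simulate DSB induction by a single ion traversal
#'
#' Composes the full chain: track generation ([generate_track()]), lazy DNA
#' segment instantiation near the deposition pattern, direct and indirect
#' strand-break scoring, DSB pairing ([pair_dsbs()]) and restriction to the
#' nuclear volume. The track runs along `direction` through `entry`
#' (defaults: horizontal central chord, along +x).
#'
#' @param beam An [ion_beam()].
#' @param nucleus A [nucleus_geometry()] (centred at the origin, depth along
#'   z).
#' @param params A [damage_params()].
#' @param entry,direction Track line; by default the central horizontal
#'   chord.
#' @param seed Optional integer seed for a reproducible realisation.
#' @param transport Transport-calibration overrides passed to
#'   [generate_track()].
#' @return A list of class `damage_result` with `dsbs` (DsbEvent table plus
#'   `radial_um`, perpendicular distance to the track axis), `breaks` (all
#'   SSBs before nucleus clipping), `n_segments` instantiated, the track
#'   `axis`, and summary `counts` (`dsb_total`, `dsb_within_1um`,
#'   `dsb_beyond_1um`, `ssb`).
#' @examples
#' \donttest{
#' res <- simulate_damage(ion_beam("Fe"), nucleus_geometry(), seed = 1)
#' res$counts
#' }
#' @export
simulate_damage <- function(beam, nucleus, params = damage_params(),
                            entry = NULL, direction = c(1, 0, 0),
                            seed = NULL, transport = TRACK_DEFAULTS) {
  stopifnot(inherits(beam, "ion_beam"), inherits(nucleus, "nucleus_geometry"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(entry)) entry <- c(-nucleus$diameter_um / 2, 0, 0)
  u <- direction / sqrt(sum(direction^2))
  chord <- nucleus_chord(nucleus, entry, u)
  mk_empty <- function(n_seg = 0) {
    dsbs <- pair_dsbs(NULL, params)
    dsbs[, radial_um := numeric(0)]
    structure(list(dsbs = dsbs, breaks = empty_breaks(), n_segments = n_seg,
                   axis = list(point = entry, direction = u),
                   counts = c(dsb_total = 0, dsb_within_1um = 0,
                              dsb_beyond_1um = 0, ssb = 0),
                   beam = beam, nucleus = nucleus, params = params,
                   seed = if (is.null(seed)) NA_integer_ else seed),
              class = "damage_result")
  }
  if (chord$length <= 0) return(mk_empty())

  # simulate over the in-nucleus chord
  start <- entry + chord$t0 * u
  track <- generate_track(beam, start, u, chord$length,
                          transport = transport)
  deps <- track$depositions
  radicals <- generate_radicals(deps, params)

  # one lazy segment realisation scores depositions and radicals together
  pts <- rbind(cbind(deps$x_um, deps$y_um, deps$z_um),
               cbind(radicals$x_um, radicals$y_um, radicals$z_um))
  search <- c(rep(params$site_radius_nm * 1e-3, nrow(deps)),
              rep(params$reaction_radius_nm * 1e-3, nrow(radicals)))
  asg <- assign_sites_lazy(pts, search, params$dna_density_mbp_um3,
                           as.integer(params$segment_bp),
                           params$rise_nm_per_bp * 1e-3,
                           params$helix_radius_nm * 1e-3, CELL_UM)
  nd <- nrow(deps)
  idx_dep <- seq_len(nd)
  dep_hit <- data.table::data.table(
    segment_id = asg$segment_id[idx_dep], strand = asg$strand[idx_dep],
    bp = asg$bp[idx_dep], site_x = asg$site_x[idx_dep],
    site_y = asg$site_y[idx_dep], site_z = asg$site_z[idx_dep],
    energy_ev = deps$energy_ev)
  direct <- dep_hit[!is.na(segment_id),
                    .(energy_ev = sum(energy_ev), x_um = site_x[1L],
                      y_um = site_y[1L], z_um = site_z[1L]),
                    by = .(segment_id, strand, bp)]
  direct <- direct[energy_ev > params$e_threshold_ev]
  direct[, `:=`(mechanism = "direct", energy_ev = NULL)]

  # radicals born from depositions that themselves sit on DNA are discarded:
  # only water depositions are converted to radicals
  on_dna <- which(!is.na(asg$segment_id[idx_dep]))
  if (nrow(radicals)) {
    keep <- !(radicals$parent %in% on_dna)
    idx_rad <- nd + seq_len(nrow(radicals))
    enc <- data.table::data.table(
      segment_id = asg$segment_id[idx_rad], strand = asg$strand[idx_rad],
      bp = asg$bp[idx_rad], site_x = asg$site_x[idx_rad],
      site_y = asg$site_y[idx_rad], site_z = asg$site_z[idx_rad])[keep]
    enc <- enc[!is.na(segment_id)]
    enc <- enc[stats::runif(.N) < params$p_indirect]
    indirect <- enc[, .SD[1L], by = .(segment_id, strand, bp),
                    .SDcols = c("site_x", "site_y", "site_z")]
    data.table::setnames(indirect, c("site_x", "site_y", "site_z"),
                         c("x_um", "y_um", "z_um"))
    indirect[, mechanism := "indirect"]
  } else {
    indirect <- empty_breaks()
  }
  breaks <- data.table::rbindlist(list(
    direct[, .(segment_id, strand, bp, mechanism, x_um, y_um, z_um)],
    indirect[, .(segment_id, strand, bp, mechanism, x_um, y_um, z_um)]))
  breaks <- unique(breaks, by = c("segment_id", "strand", "bp"))

  dsbs <- pair_dsbs(breaks, params)
  if (nrow(dsbs)) {
    dsbs <- dsbs[inside_ellipsoid(cbind(x_um, y_um, z_um), nucleus)]
    dsbs[, dsb_id := .I]
  }
  dsbs[, radial_um := if (.N) radial_distance(cbind(x_um, y_um, z_um),
                                              start, u) else numeric(0)]
  structure(list(
    dsbs = dsbs, breaks = breaks, n_segments = asg$n_segments,
    axis = list(point = start, direction = u),
    counts = c(dsb_total = nrow(dsbs),
               dsb_within_1um = sum(dsbs$radial_um <= 1),
               dsb_beyond_1um = sum(dsbs$radial_um > 1),
               ssb = nrow(breaks)),
    beam = beam, nucleus = nucleus, params = params,
    seed = if (is.null(seed)) NA_integer_ else seed),
    class = "damage_result")
}

#' @export
print.damage_result <- function(x, ...) {
  cat(sprintf("<damage_result> %d DSBs (%d within 1 um, %d beyond), %d SSBs, %d segments\n",
              x$counts["dsb_total"], x$counts["dsb_within_1um"],
              x$counts["dsb_beyond_1um"], x$counts["ssb"],
              as.integer(x$n_segments)))
  invisible(x)
}

#' Replicate DSB simulations and summarise yields
#'
#' @param beam,nucleus,params As in [simulate_damage()].
#' @param n_replicates Number of independent traversals.
#' @param seed Optional master seed; replicate `i` uses `seed + i`.
#' @return data.table with one row per replicate
#'   (`dsb_total, dsb_within_1um, dsb_beyond_1um, ssb`); means are in
#'   `attr(, "means")`.
#' @export
simulate_damage_replicates <- function(beam, nucleus, n_replicates = 50,
                                       params = damage_params(), seed = NULL,
                                       transport = TRACK_DEFAULTS) {
  rows <- lapply(seq_len(n_replicates), function(i) {
    res <- simulate_damage(beam, nucleus, params,
                           seed = if (is.null(seed)) NULL else seed + i,
                           transport = transport)
    data.table::as.data.table(as.list(res$counts))
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "means", colMeans(out))
  out[]
}
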