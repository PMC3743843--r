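# Spatial classification of DSBs/foci relative to the ion trajectory and
# partition of focus point patterns into clusters.

#' Perpendicular distance from points to a track axis
#'
#' @param points Numeric length-3 vector or an n x 3 matrix of positions (um).
#' @param axis_point A point on the axis (um).
#' @param axis_dir Axis direction; need not be normalised, must be non-zero.
#' @return Numeric vector of perpendicular distances to the infinite line.
#' @examples
#' radial_distance(c(3, 3, 4), c(0, 0, 0), c(1, 0, 0))  # 5
#' @export
radial_distance <- function(points, axis_point = c(0, 0, 0),
                            axis_dir = c(1, 0, 0)) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  nrm <- sqrt(sum(axis_dir^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("`axis_dir` must be a non-zero vector", call. = FALSE)
  u <- axis_dir / nrm
  d <- sweep(points, 2L, axis_point)
  t_ax <- d %*% u
  perp <- d - t_ax %*% t(u)
  sqrt(rowSums(perp^2))
}

#' Classify foci as track, intermediate or non-track
#'
#' Track damage lies within 1 um of the trajectory (the radius inside which
#' the simulation concentrates DSBs); non-track (delta-electron) foci are
#' scored only beyond a 2 um exclusion zone; everything between is labelled
#' `intermediate` and excluded from both counts.
#'
#' @param points n x 3 matrix of focus positions (um).
#' @param axis_point,axis_dir Track axis; see [radial_distance()].
#' @param track_radius_um Inner radius, default 1 um.
#' @param exclusion_radius_um Non-track exclusion radius, default 2 um.
#' @return Character vector of labels `"track"`, `"intermediate"`,
#'   `"non_track"`, one per point.
#' @export
classify_track_membership <- function(points, axis_point = c(0, 0, 0),
                                      axis_dir = c(1, 0, 0),
                                      track_radius_um = 1,
                                      exclusion_radius_um = 2) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L) return(character(0))
  r <- radial_distance(points, axis_point, axis_dir)
  ifelse(r <= track_radius_um, "track",
         ifelse(r > exclusion_radius_um, "non_track", "intermediate"))
}

#' Partition foci into clusters by single-linkage distance
#'
#' Two foci belong to the same cluster when they can be joined by a chain of
#' neighbours each at most `linkage_um` apart (single-linkage connected
#' components). The default 0.5 um is the separation at which neighbouring
#' clusters are scored as distinct.
#'
#' @param points n x 3 matrix of focus positions (um). Use
#'   `mode = "projected"` to cluster on the (x, y) projection, mirroring
#'   scoring on stacked 2D images.
#' @param linkage_um Single-linkage distance, um (> 0).
#' @param mode `"3d"` (default) or `"projected"`.
#' @return Integer vector of cluster ids (1-based, ordered by first member);
#'   a partition of the input.
#' @examples
#' pts <- cbind(c(0, 0.3, 0.9), 0, 0)
#' cluster_foci(pts)  # 1 1 2
#' @export
cluster_foci <- function(points, linkage_um = 0.5, mode = c("3d", "projected")) {
  mode <- match.arg(mode)
  if (!is.numeric(linkage_um) || linkage_um <= 0)
    stop("`linkage_um` must be positive", call. = FALSE)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  if (mode == "projected") points <- points[, 1:2, drop = FALSE]
  hc <- stats::hclust(stats::dist(points), method = "single")
  raw <- stats::cutree(hc, h = linkage_um)
  # relabel in order of first appearance so ids are input-order stable
  as.integer(factor(raw, levels = unique(raw)))
}

#' Summarise clusters of a focus set
#'
#' @param points n x 3 matrix of focus positions (um).
#' @param cluster_id Integer labels from [cluster_foci()].
#' @param window_um Scoring-window side length; clusters whose extent exceeds
#'   it are flagged rather than split. Default 1.5 um.
#' @return data.table with one row per cluster: `cluster_id`, `n_foci`,
#'   centroid columns, `extent_um` (maximum pairwise member distance) and
#'   `flagged` (extent exceeds the window).
#' @export
summarize_clusters <- function(points, cluster_id, window_um = 1.5) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  stopifnot(nrow(points) == length(cluster_id))
  if (nrow(points) == 0L)
    return(data.table::data.table(
      cluster_id = integer(0), n_foci = integer(0), x_um = numeric(0),
      y_um = numeric(0), z_um = numeric(0), extent_um = numeric(0),
      flagged = logical(0)))
  ids <- sort(unique(cluster_id))
  out <- lapply(ids, function(id) {
    m <- points[cluster_id == id, , drop = FALSE]
    ext <- if (nrow(m) > 1L) max(stats::dist(m)) else 0
    data.table::data.table(
      cluster_id = id, n_foci = nrow(m),
      x_um = mean(m[, 1]), y_um = mean(m[, 2]), z_um = mean(m[, 3]),
      extent_um = ext, flagged = ext > window_um)
  })
  data.table::rbindlist(out)
}

#' Distribution of foci counts per cluster
#'
#' @param cluster_sizes Integer vector of per-cluster member counts (e.g.
#'   `summarize_clusters(...)$n_foci`), or a cluster-id vector from
#'   [cluster_foci()] with `from_ids = TRUE`.
#' @param from_ids Interpret the input as per-focus cluster ids.
#' @return data.table with `n_foci` and `percent`; percentages sum to 100
#'   (empty input gives an empty table).
#' @examples
#' foci_per_cluster_distribution(c(3, 3, 5, 10))
#' @export
foci_per_cluster_distribution <- function(cluster_sizes, from_ids = FALSE) {
  if (from_ids) cluster_sizes <- as.integer(table(cluster_sizes))
  if (length(cluster_sizes) == 0L)
    return(data.table::data.table(n_foci = integer(0), percent = numeric(0)))
  tab <- table(cluster_sizes)
  data.table::data.table(
    n_foci = as.integer(names(tab)),
    percent = 100 * as.numeric(tab) / sum(tab))
}

#' Length/width metrics of a focus track
#'
#' Length is the extent of the point set along its principal axis, width the
#' maximal extent in the perpendicular plane. A pattern qualifies as a
#' particle track when length > 8 um and width > 1 um (strict inequalities);
#' patterns shorter than `min_length_um` are treated as indistinguishable
#' from delta-electron foci and never qualify.
#'
#' @param points n x 2 or n x 3 matrix of focus positions (um); 2D input is
#'   treated as an (x, y) projection.
#' @param min_length_um Patterns below this length are non-tracks
#'   (default 0.025 um).
#' @return List of class `track_metrics` with `length_um`, `width_um`,
#'   `passes_criteria`.
#' @export
track_metrics <- function(points, min_length_um = 0.025) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (nrow(points) == 0L)
    return(structure(list(length_um = 0, width_um = 0,
                          passes_criteria = FALSE), class = "track_metrics"))
  ctr <- sweep(points, 2L, colMeans(points))
  if (nrow(points) == 1L) {
    len <- 0; wid <- 0
  } else {
    pc <- stats::prcomp(ctr, center = FALSE)
    scores <- ctr %*% pc$rotation
    len <- diff(range(scores[, 1]))
    wid <- if (ncol(scores) > 1L)
      max(apply(scores[, -1L, drop = FALSE], 2L, function(s) diff(range(s))))
    else 0
  }
  structure(list(length_um = len, width_um = wid,
                 passes_criteria = len > 8 && wid > 1 && len >= min_length_um),
            class = "track_metrics")
}

#' @export
print.track_metrics <- function(x, ...) {
  cat(sprintf("<track_metrics> length %.2f um, width %.2f um, %s\n",
              x$length_um, x$width_um,
              if (x$passes_criteria) "qualifies as track" else "not a track"))
  invisible(x)
}
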