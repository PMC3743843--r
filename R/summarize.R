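# Run-level summaries: per-time focus counts, clusters, complexity and
# non-track statistics.

#' Summarise a focus time course
#'
#' For each time point: total foci per cell, clusters per cell, mean foci
#' per cluster (complexity), non-track focus count (radial distance from the
#' track axis beyond the 2 um exclusion zone) and the foci-per-cluster
#' distribution.
#'
#' @param foci_by_time Named list of focus tables (`x_um, y_um, z_um`), as
#'   returned by [evolve_foci()] or built from [detect_foci()] output; names
#'   like `"t8"` give the time in hours (otherwise supply `times_h`).
#' @param axis_point,axis_dir Track axis for the non-track classification;
#'   `NULL` skips it.
#' @param times_h Optional numeric time points overriding the names.
#' @param linkage_um Cluster linkage, um.
#' @return List with `totals` (one row per time) and `distribution`
#'   (foci-per-cluster percentage rows per time).
#' @export
summarize_timecourse <- function(foci_by_time, axis_point = c(0, 0, 0),
                                 axis_dir = c(1, 0, 0), times_h = NULL,
                                 linkage_um = 0.5) {
  stopifnot(length(foci_by_time) >= 1L)
  if (is.null(times_h)) {
    times_h <- as.numeric(sub("^t", "", names(foci_by_time)))
    if (any(is.na(times_h)))
      stop("supply `times_h` or name the list elements t<hours>",
           call. = FALSE)
  }
  totals <- list(); dists <- list()
  for (k in seq_along(foci_by_time)) {
    f <- data.table::as.data.table(foci_by_time[[k]])
    pts <- cbind(f$x_um, f$y_um, f$z_um)
    n <- nrow(f)
    if (n) {
      cl <- cluster_foci(pts, linkage_um)
      sizes <- as.integer(table(cl))
      non_track <- if (!is.null(axis_dir))
        sum(classify_track_membership(pts, axis_point, axis_dir) ==
              "non_track") else NA_integer_
      dists[[k]] <- data.table::data.table(
        time_h = times_h[k], foci_per_cluster_distribution(sizes))
    } else {
      sizes <- integer(0)
      non_track <- if (!is.null(axis_dir)) 0L else NA_integer_
    }
    totals[[k]] <- data.table::data.table(
      time_h = times_h[k], total_foci = n,
      clusters = length(sizes),
      mean_foci_per_cluster = if (length(sizes)) mean(sizes) else NA_real_,
      max_cluster = if (length(sizes)) max(sizes) else 0L,
      non_track_foci = non_track)
  }
  list(totals = data.table::rbindlist(totals),
       distribution = data.table::rbindlist(dists))
}
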