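# Shared fixtures: the reference beam/nucleus conditions and small builders.

fe_beam <- function() ion_beam("Fe", energy_per_nucleon = 416, let = 200)
c_beam <- function() ion_beam("C", energy_per_nucleon = 290, let = 70)
ref_nucleus <- function() nucleus_geometry(12.67, 2.8)

# a single DNA segment centred at the origin along +x
unit_segment <- function(ux = 1, uy = 0, uz = 0) {
  data.table::data.table(segment_id = 1L, x_um = 0, y_um = 0, z_um = 0,
                         ux = ux, uy = uy, uz = uz)
}

# focus table from a position matrix
as_foci_table <- function(m) {
  data.table::data.table(x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
}

# deposition table from a position matrix
deps_at <- function(pos, energy_ev) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3L)
  data.table::data.table(x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                         energy_ev = energy_ev)
}

# brute-force single-linkage connected components (O(n^2) oracle)
brute_components <- function(points, linkage) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  adj <- as.matrix(stats::dist(points)) <= linkage
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# exhaustive maximum matching of opposite-strand pairs within the bp window
# (enumerates all matchings; feasible for <= 8 breaks per segment)
brute_max_matching <- function(b0, b1, window) {
  pairs <- list()
  for (i in seq_along(b0)) for (j in seq_along(b1))
    if (abs(b0[i] - b1[j]) <= window) pairs[[length(pairs) + 1L]] <- c(i, j)
  if (!length(pairs)) return(0L)
  best <- 0L
  recurse <- function(k, used0, used1, count) {
    if (k > length(pairs)) { best <<- max(best, count); return(invisible()) }
    p <- pairs[[k]]
    if (!used0[p[1]] && !used1[p[2]]) {
      used0[p[1]] <- TRUE; used1[p[2]] <- TRUE
      recurse(k + 1L, used0, used1, count + 1L)
      used0[p[1]] <- FALSE; used1[p[2]] <- FALSE
    }
    recurse(k + 1L, used0, used1, count)
  }
  recurse(1L, logical(length(b0)), logical(length(b1)), 0L)
  best
}
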