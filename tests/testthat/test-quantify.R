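# End-to-end quantification: recovery, cluster statistics, time courses.

test_that("end-to-end focus recovery is >=90% with <=5% false positives", {
  set.seed(70)
  o <- optics_params(field_um = 4.16)
  n_stacks <- 12
  n_true <- 0; n_found_true <- 0; n_false <- 0
  for (k in seq_len(n_stacks)) {
    # isolated foci (>= 0.6 um mutual separation) on a jittered grid
    gx <- seq(-1.4, 1.4, length.out = 4)
    centres <- as.matrix(expand.grid(gx, gx))
    centres <- centres[sample(nrow(centres), 5), ]
    gt <- as_foci_table(cbind(centres + runif(10, -0.1, 0.1),
                              runif(5, -0.8, 0.8)))
    stack <- render_stack(gt, o)
    found <- detect_foci(stack)
    n_true <- n_true + nrow(gt)
    for (i in seq_len(nrow(gt))) {
      d <- sqrt((found$x_um - gt$x_um[i])^2 + (found$y_um - gt$y_um[i])^2 +
                  (found$z_um - gt$z_um[i])^2)
      if (length(d) && min(d) < 0.3) n_found_true <- n_found_true + 1
    }
    matched <- vapply(seq_len(nrow(found)), function(j) {
      d <- sqrt((gt$x_um - found$x_um[j])^2 + (gt$y_um - found$y_um[j])^2 +
                  (gt$z_um - found$z_um[j])^2)
      min(d) < 0.3
    }, logical(1))
    n_false <- n_false + sum(!matched)
  }
  expect_gte(n_found_true / n_true, 0.90)
  expect_lte(n_false / max(n_found_true, 1), 0.05)
})

test_that("recovered cluster statistics match the generated ground truth", {
  set.seed(71)
  o <- optics_params(field_um = 4.16)
  # three clusters with known multiplicities, well separated
  mk_cluster <- function(centre, n) {
    ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
    cbind(centre[1] + 0.28 * cos(ang), centre[2] + 0.28 * sin(ang),
          centre[3])
  }
  gt <- as_foci_table(rbind(mk_cluster(c(-1.2, -1.2, 0), 3),
                            mk_cluster(c(1.2, 1.2, 0.4), 4),
                            matrix(c(1.2, -1.2, -0.4), 1)))
  stack <- render_stack(gt, o)
  found <- detect_foci(stack, detection_params(restore_iterations = 25))
  cl <- cluster_foci(cbind(found$x_um, found$y_um, found$z_um), 0.8)
  sizes <- sort(as.integer(table(cl)))
  truth <- sort(as.integer(table(cluster_foci(
    cbind(gt$x_um, gt$y_um, gt$z_um), 0.8))))
  # total-variation distance between the two size distributions
  all_sizes <- union(sizes, truth)
  tv <- 0.5 * sum(abs(
    vapply(all_sizes, function(s) mean(sizes == s), numeric(1)) -
      vapply(all_sizes, function(s) mean(truth == s), numeric(1))))
  expect_lt(tv, 0.35)
  expect_equal(length(sizes), length(truth), tolerance = 1)
})

test_that("non-track counting switches exactly at the 2 um boundary", {
  axis_p <- c(0, 0, 0); axis_d <- c(1, 0, 0)
  base <- rbind(c(0, 0.5, 0), c(2, 3, 0))
  n1 <- sum(classify_track_membership(rbind(base, c(1, 2.01, 0)),
                                      axis_p, axis_d) == "non_track")
  n2 <- sum(classify_track_membership(rbind(base, c(1, 1.99, 0)),
                                      axis_p, axis_d) == "non_track")
  expect_identical(n1 - n2, 1L)
})

test_that("summarised time courses show repair-dependent complexity decay", {
  set.seed(72)
  foci <- generate_fe_track_like(ref_nucleus(), clusters_per_um = 1.5,
                                 mean_multiplicity = 10)
  times <- c(8, 16, 24)
  wt <- evolve_foci(foci, genotype_params("wt"), times)
  sum_wt <- summarize_timecourse(wt)
  expect_identical(sum_wt$totals$time_h, times)
  # mean cluster complexity strictly decreasing 8 -> 16 -> 24 h
  expect_true(all(diff(sum_wt$totals$mean_foci_per_cluster) < 0))
  # XLF-like: totals essentially flat
  set.seed(72)
  xlf <- evolve_foci(foci, genotype_params("xlf"), times)
  sum_xlf <- summarize_timecourse(xlf)
  drop_wt <- 1 - sum_wt$totals$total_foci[3] / sum_wt$totals$total_foci[1]
  drop_xlf <- 1 - sum_xlf$totals$total_foci[3] / sum_xlf$totals$total_foci[1]
  expect_gt(drop_wt, 0.4)
  expect_lt(drop_xlf, 0.15)
  # distribution rows are percentages summing to 100 per time point
  tot <- sum_wt$distribution[, sum(percent), by = time_h]$V1
  expect_equal(tot, rep(100, length(tot)))
})

test_that("simple count summaries are exact", {
  pts <- as_foci_table(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0),
                             c(3, 0.5, 0), c(3.1, 0.5, 0),
                             c(-3, -0.5, 0.2)))
  s <- summarize_timecourse(list(t1 = pts), axis_dir = c(1, 0, 0))
  expect_identical(s$totals$total_foci, 6L)
  expect_identical(s$totals$clusters, 3L)
  expect_equal(s$totals$mean_foci_per_cluster, 2)
})
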