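# Delta-electron spectrum, range-energy model and track realisations.

test_that("kinematic maximum follows the relativistic free-electron limit", {
  # oracle: gamma = 1 + T/931.494, Emax = 2 m_e c^2 (gamma^2 - 1)
  for (t_mev in c(416, 290, 50)) {
    g <- 1 + t_mev / 931.494
    expect_equal(kinematic_emax(t_mev), 2 * 0.5109989e6 * (g^2 - 1),
                 tolerance = 1e-9)
  }
  expect_equal(kinematic_emax(416) / 1e6, 1.117, tolerance = 0.001)
  expect_equal(kinematic_emax(290) / 1e6, 0.735, tolerance = 0.001)
  # nonrelativistic limit: vanishes linearly
  expect_lt(kinematic_emax(1e-4), 0.5)
  expect_error(kinematic_emax(-1), "positive")
})

test_that("truncated 1/E^2 spectrum: closed form and samples agree", {
  emax <- kinematic_emax(416)
  # ~90% of delta electrons fall below 100 eV
  expect_equal(delta_spectrum_cdf(100, emax), 0.90, tolerance = 0.001)
  set.seed(5)
  e <- sample_delta_spectrum(1e5, emax)
  expect_true(all(e >= 10 & e <= emax))
  expect_equal(mean(e < 100), 0.9, tolerance = 0.01)
  # Kolmogorov-Smirnov distance against the closed-form CDF
  ks <- suppressWarnings(stats::ks.test(e, function(q)
    delta_spectrum_cdf(q, emax)))
  expect_lt(unname(ks$statistic), 0.01)
  expect_identical(sample_delta_spectrum(0, emax), numeric(0))
  expect_error(sample_delta_spectrum(10, 5, 10), "emax > emin")
})

test_that("range-energy model is monotone and pinned at its anchors", {
  expect_lt(electron_range(100), 0.005)      # sub-100 eV: a few nm
  expect_equal(electron_range(10), 0.001)    # cutoff floor
  expect_equal(electron_range(1e4), 4)       # pinned keV anchor
  expect_equal(electron_range(1.12e6), 300, tolerance = 1e-6)
  e <- exp(seq(log(10), log(2e6), length.out = 200))
  expect_true(all(diff(electron_range(e)) > 0))
  expect_error(electron_range(5), "cutoff")
  # electrons with ranges of order 100 um are very rare (< 0.1%)
  set.seed(6)
  e <- sample_delta_spectrum(1e6, kinematic_emax(416))
  expect_lt(mean(electron_range(e) >= 100), 0.001)
})

test_that("track realisations are LET-calibrated", {
  beam <- fe_beam()
  set.seed(10)
  lets <- replicate(20, {
    tr <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 6)
    sum(tr$depositions$energy_ev) / 1e3 / 6
  })
  expect_true(all(abs(lets - 200) / 200 < 0.10))   # each track within 10%
  expect_lt(abs(mean(lets) - 200) / 200, 0.02)     # ensemble within 2%
})

test_that("tracks are deterministic under a fixed seed", {
  beam <- fe_beam()
  t1 <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 2, seed = 99)
  t2 <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 2, seed = 99)
  expect_identical(t1$depositions, t2$depositions)
  t3 <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 2, seed = 100)
  expect_false(isTRUE(all.equal(t1$depositions, t3$depositions)))
})

test_that("degenerate track inputs are handled", {
  beam <- fe_beam()
  expect_error(generate_track(beam, c(0, 0, 0), c(0, 0, 0), 5), "non-zero")
  tr <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 0)
  expect_identical(nrow(tr$depositions), 0L)
})

test_that("radial energy density falls off roughly as 1/r^2", {
  beam <- fe_beam()
  set.seed(20)
  tracks <- lapply(1:6, function(i)
    generate_track(beam, c(0, 0, 0), c(1, 0, 0), 12.67))
  prof <- radial_energy_profile(tracks, rmin_um = 0.01, rmax_um = 1,
                                nbins = 12)
  keep <- prof$density_ev_um3 > 0
  fit <- stats::lm(log(density_ev_um3) ~ log(r_um), data = prof[keep])
  expect_equal(unname(stats::coef(fit)[2]), -2, tolerance = 0.3)
})

test_that("total track energy matches LET x path and origins are tagged", {
  beam <- fe_beam()
  tr <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 12.67, seed = 3)
  expect_equal(sum(tr$depositions$energy_ev), 200e3 * 12.67,
               tolerance = 0.01)
  # shipped calibration carries all energy through delta electrons
  expect_identical(unique(tr$depositions$origin), "delta")
  # with an explicit on-axis collision deposit, core tagging appears and
  # those depositions hug the axis (within the impact-parameter spread)
  tr2 <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 2, seed = 3,
                        transport = list(core_ev = 15))
  core <- tr2$depositions[origin == "core"]
  expect_gt(nrow(core), 0)
  expect_setequal(unique(tr2$depositions$origin), c("core", "delta"))
  expect_lt(max(sqrt(core$y_um^2 + core$z_um^2)), 0.02)
})

test_that("deposition tables round-trip through TSV", {
  beam <- fe_beam()
  tr <- generate_track(beam, c(0, 0, 0), c(1, 0, 0), 0.5, seed = 4)
  f <- tempfile(fileext = ".tsv.gz")
  write_depositions(tr$depositions, f)
  back <- read_depositions(f)
  expect_equal(as.data.frame(back), as.data.frame(tr$depositions),
               tolerance = 1e-12)
  unlink(f)
})
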