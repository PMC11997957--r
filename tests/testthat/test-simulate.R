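test_that("the default dartboard layout has 24 regions over 3 rings", {
  lay <- make_stimulus_layout()
  expect_identical(nrow(lay), 24L)
  expect_identical(sort(unique(lay$ring)), 1:3)
  expect_identical(sort(unique(lay$wedge)), 1:8)
})

test_that("wedges touching the vertical meridian are flagged bilateral", {
  lay <- make_stimulus_layout()
  # 45-degree wedges: those with a boundary at 90 or 270 degrees
  expect_identical(sum(lay$bilateral), 12L)
  for (i in seq_len(nrow(lay))) {
    touches <- (lay$angle_start[i] <= 90 && lay$angle_end[i] >= 90) ||
      (lay$angle_start[i] <= 270 && lay$angle_end[i] >= 270)
    expect_identical(lay$bilateral[i], touches)
  }
  # unilateral regions project contralaterally
  uni <- lay[!lay$bilateral, ]
  mid <- (uni$angle_start + uni$angle_end) / 2
  expect_identical(uni$hemifield,
                   ifelse(mid > 90 & mid < 270, "left", "right"))
})

test_that("targets land on the requested hemisphere at ring-scaled depth", {
  tpl <- build_experiment_template()
  truth <- tpl$truth
  mesh <- tpl$mesh
  lay <- tpl$config
  # contralateral organisation: left-hemifield stimuli on the right cortex
  lay_df <- make_stimulus_layout()
  for (i in seq_len(nrow(truth))) {
    expect_identical(mesh$hemisphere[truth$vertex[i]], truth$hemi[i])
    reg <- lay_df[lay_df$region == truth$region[i], ]
    if (reg$hemifield == "left") expect_identical(truth$hemi[i], "right")
    if (reg$hemifield == "right") expect_identical(truth$hemi[i], "left")
  }
  # bilateral regions have exactly two rows, one per hemisphere
  n_rows <- table(truth$region)
  expect_identical(sum(n_rows == 2L), 12L)
  # eccentricity rings map to geodesic distance from the pole anchor
  anchors <- attr(truth, "anchors")
  for (h in c("left", "right")) {
    d <- geodesic_distances(mesh, anchors[[h]])
    tr <- truth[truth$hemi == h, ]
    err <- abs(d[tr$vertex] - c(10, 20, 30)[tr$ring])
    expect_lt(max(err), 7)  # within one ico2 edge of the nominal depth
  }
})

test_that("target spacing characterization matches direct recomputation", {
  tpl <- build_experiment_template()
  nd <- target_neighbor_distances(tpl$mesh, tpl$truth)
  i <- which(nd$region == 5L)[1L]
  same <- tpl$truth$hemi == nd$hemi[i] & tpl$truth$vertex != nd$vertex[i]
  d <- geodesic_distances(tpl$mesh, nd$vertex[i])[tpl$truth$vertex[same]]
  expect_equal(nd$mean_neighbor_mm[i], mean(d), tolerance = 1e-12)
  expect_equal(nd$min_neighbor_mm[i], min(d), tolerance = 1e-12)
})

test_that("noiseless evoked responses equal the forward-projected pulse", {
  tpl <- build_experiment_template()
  tr <- tpl$truth[tpl$truth$region == 1L, ]
  times <- seq(-50, 450, by = 2)
  sim <- simulate_evoked(tpl$leadfield, diag(tpl$sensors$n), tpl$mesh,
                         tr$vertex, tr$amplitude, times = times,
                         noise = FALSE)
  L <- megpool:::as_leadfield_matrix(tpl$leadfield)
  expect_equal(sim$Y, L %*% sim$x, tolerance = 1e-12)
  # pulse peaks at the requested latency up to the 2 ms sampling grid
  # (83 ms falls between the 82 and 84 ms samples)
  peak_col <- which.max(colSums(abs(sim$x)))
  expect_lte(abs(times[peak_col] - 83), 1)
})

test_that("noise calibration realizes the requested amplitude SNR", {
  tpl <- build_experiment_template()
  tr <- tpl$truth[tpl$truth$region == 1L, ]
  times <- seq(-50, 450, by = 2)
  Sigma <- megpool:::with_seed(4, megpool:::random_noise_cov(tpl$sensors$n))
  # the calibration targets the expected whitened-RMS SNR of the *noisy*
  # data; a single draw fluctuates, so average the estimator over draws
  snrs <- vapply(1:30, function(s) {
    sim <- simulate_evoked(tpl$leadfield, Sigma, tpl$mesh, tr$vertex,
                           tr$amplitude, times = times, snr_target = 2,
                           seed = s)
    estimate_snr(sim$Y, sim$Sigma_used, times)
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 2) / 2, 0.05)
})

test_that("experiments are reproducible from the master seed", {
  cfg <- list(subdivisions = 1)
  e1 <- simulate_experiment(2, master_seed = 7, config = cfg)
  e2 <- simulate_experiment(2, master_seed = 7, config = cfg)
  e3 <- simulate_experiment(2, master_seed = 8, config = cfg)
  expect_identical(e1$subjects[[2L]]$evoked, e2$subjects[[2L]]$evoked)
  expect_identical(e1$subjects[[1L]]$truth, e2$subjects[[1L]]$truth)
  expect_false(identical(e1$subjects[[1L]]$evoked[[1L]],
                         e3$subjects[[1L]]$evoked[[1L]]))
  # all derived seeds stay below 2^31
  expect_true(all(e1$metadata$subject_seeds < 2^31))
})

test_that("experiment metadata records the flash bookkeeping", {
  e <- simulate_experiment(1, master_seed = 1,
                           config = list(subdivisions = 1))
  expect_identical(e$metadata$flashes_per_run, 258)
  expect_identical(e$metadata$runs, 7)
  expect_identical(e$metadata$flashes_per_region, 1806)
})

test_that("per-subject target jitter stays within the configured bound", {
  e <- simulate_experiment(3, master_seed = 5,
                           config = list(noise = FALSE))
  cap <- e$config$target_jitter_mm
  for (s in e$subjects) {
    for (i in seq_len(nrow(s$truth))) {
      d <- geodesic_distances(e$mesh, e$truth$vertex[i])[s$truth$vertex[i]]
      expect_lte(d, cap)
      expect_identical(e$mesh$hemisphere[s$truth$vertex[i]],
                       e$truth$hemi[i])
    }
  }
})
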