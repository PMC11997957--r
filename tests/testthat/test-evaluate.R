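# evaluation: peak timing, peak vertices, distances, Winsorized statistics

test_that("GFP peak timing finds an interior pulse and flags window-edge slopes", {
  times <- seq(0, 150, by = 1)
  n <- 8
  pulse <- exp(-0.5 * ((times - 83) / 10)^2)
  Y <- outer(rnorm(n, sd = 1) + 1, pulse)
  pk <- find_peak_time(Y, times)
  expect_equal(pk$time, 83)
  expect_false(pk$boundary)

  # monotonically rising signal: argmax on the 100 ms edge, flagged
  ramp <- times / max(times)
  Y2 <- outer(seq_len(n) / n, ramp)
  pk2 <- find_peak_time(Y2, times)
  expect_equal(pk2$time, 100)
  expect_true(pk2$boundary)

  # a channel-common offset at each time leaves the GFP argmax unchanged
  Y3 <- Y + matrix(rep(10 * sin(times / 5), each = n), n)
  expect_equal(find_peak_time(Y3, times)$time, 83)

  expect_error(find_peak_time(Y, times, window = c(500, 600)), "window")
})

test_that("subject-median peak time excludes boundary-flagged regions", {
  expect_equal(subject_median_peak_time(c(80, 85, 90)), 85)
  expect_equal(subject_median_peak_time(c(80, 100, 90),
                                        c(FALSE, TRUE, FALSE)), 85)
  expect_error(subject_median_peak_time(c(100, 100), c(TRUE, TRUE)),
               "boundary")
})

test_that("peak vertices: global argmax, per-hemisphere argmax, zero rejection", {
  mesh <- build_template_space(subdivisions = 0)
  p <- nrow(mesh$vertices)
  left <- hemisphere_vertices(mesh, "left")
  right <- hemisphere_vertices(mesh, "right")

  x <- rep(0, p)
  x[left[3]] <- -5   # magnitude decides, sign does not
  x[right[2]] <- 4
  pk <- find_peak_vertices(x, mesh)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$vertex, left[3])

  pk2 <- find_peak_vertices(x, mesh, bilateral = TRUE)
  expect_equal(nrow(pk2), 2L)
  expect_equal(sort(pk2$vertex), sort(c(left[3], right[2])))

  # a contralateral global max is returned as-is; hemisphere correctness
  # is judged by the outlier rule downstream
  x3 <- rep(0, p)
  x3[right[1]] <- 1
  expect_equal(find_peak_vertices(x3, mesh)$hemi, "right")

  expect_error(find_peak_vertices(rep(0, p), mesh), "no peak")
})

test_that("peak-target distance flags wrong hemisphere and the 80 mm cap", {
  mesh <- build_template_space(subdivisions = 1)
  left <- hemisphere_vertices(mesh, "left")
  right <- hemisphere_vertices(mesh, "right")

  same <- peak_target_distance(mesh, left[1], left[1])
  expect_equal(same$distance, 0)
  expect_false(same$outlier)

  wrong <- peak_target_distance(mesh, right[1], left[1])
  expect_true(wrong$outlier)
  expect_true(wrong$wrong_hemisphere)
  expect_equal(wrong$distance, Inf)

  # distances above the cap are outliers even on the correct hemisphere
  g <- geodesic_distances(mesh, left[1])
  far <- left[which.max(g[left])]
  d_far <- unname(g[far])
  res <- peak_target_distance(mesh, far, left[1], cap = d_far - 1)
  expect_false(res$wrong_hemisphere)
  expect_true(res$outlier)
})

test_that("Winsorized statistics replace flagged rows by the cap", {
  st <- winsorized_stats(c(10, 90, 20), c(FALSE, TRUE, FALSE))
  expect_equal(st$median, 20)
  expect_equal(st$mean, mean(c(10, 80, 20)))
  expect_equal(st$n_outliers, 1)

  plain <- winsorized_stats(c(5, 7, 9))
  expect_equal(plain$mean, 7)
  expect_equal(plain$sd, sd(c(5, 7, 9)))

  # 24 rows with 2 planted outliers: equals manual recomputation, and the
  # Winsorized sd never exceeds the raw sd when outliers are above the cap
  set.seed(99)
  d <- c(runif(22, 0, 60), 120, 200)
  flag <- d > 80
  st24 <- winsorized_stats(d, flag)
  manual <- ifelse(flag, 80, d)
  expect_equal(st24$mean, mean(manual))
  expect_equal(st24$median, median(manual))
  expect_equal(st24$sd, sd(manual))
  expect_lte(st24$sd, sd(d))

  expect_error(winsorized_stats(numeric(0)), "no distances")
})

test_that("pipeline is deterministic: same seed gives byte-identical CSV output", {
  cfg <- list(noise = FALSE, position_jitter_mm = 0,
              gain_jitter_fraction = 0, target_jitter_mm = 0,
              amplitude_jitter = 0, peak_time_subject_sd = 0,
              peak_time_region_sd = 0)
  run <- function() run_pipeline(n_subjects = 2, master_seed = 7,
                                 group_sizes = c(1, 2),
                                 methods = "elora_avg", regions = c(1, 5),
                                 config = cfg)
  t1 <- run()
  t2 <- run()
  d1 <- tempfile()
  d2 <- tempfile()
  p1 <- write_evaluation(t1, d1)
  p2 <- write_evaluation(t2, d2)
  for (f in c("rows", "summary")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # summary is recomputable from rows
  sub <- t1$rows[t1$rows$group_size == 2, ]
  st <- winsorized_stats(sub$distance_mm, sub$outlier)
  expect_equal(t1$summary$median_mm[t1$summary$group_size == 2], st$median)
})

test_that("size-1 averaged eLORETA equals the representative subject's own rows", {
  cfg <- list(noise = FALSE, position_jitter_mm = 0,
              gain_jitter_fraction = 0, target_jitter_mm = 0,
              amplitude_jitter = 0, peak_time_subject_sd = 0,
              peak_time_region_sd = 0)
  tab <- run_pipeline(n_subjects = 3, master_seed = 5, group_sizes = c(1, 3),
                      methods = "elora_avg", regions = c(1, 2),
                      config = cfg)
  rep_id <- tab$manifest$representative
  n1 <- tab$rows[tab$rows$group_size == 1, ]
  own <- tab$per_subject[tab$per_subject$subject == rep_id, ]
  expect_equal(n1$peak_vertex, own$peak_vertex)
  expect_equal(n1$distance_mm, own$distance_mm)
  expect_equal(n1$outlier, own$outlier)
})
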