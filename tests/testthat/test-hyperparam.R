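# hyperparameter searches against stub solvers and active-count contracts

test_that("active counts: zeros, single spikes, and monotone thresholding", {
  expect_equal(count_active(list(rep(0, 10), rep(0, 10))), 0)
  one <- rep(0, 10)
  one[4] <- 1e-9
  expect_equal(count_active(list(one, one)), 1)
  # relative threshold: vertices below rel_threshold * max are inactive
  x <- c(1, 0.5, 1e-3, 1e-8)
  expect_equal(count_active(list(x), rel_threshold = 1e-6), 3)
  expect_equal(count_active(list(x), rel_threshold = 1e-2), 2)
  # sweep monotone non-increasing in the threshold over random estimates
  set.seed(21)
  for (k in 1:50) {
    x <- rnorm(30) * rbinom(30, 1, 0.4)
    if (max(abs(x)) == 0) next
    counts <- vapply(c(1e-6, 1e-4, 1e-2, 0.5),
                     function(th) count_active(list(x), th), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  expect_error(count_active(list(x), rel_threshold = 2), "rel_threshold")
})

test_that("mu_max search localizes a step transition and suggests mu_max/2", {
  # stub solver: active count steps from 3 to 500 at mu = 17
  stub <- function(mu) if (mu < 17) 3 else 500
  res <- find_mu_max(stub, target_active = 3, bracket = c(0.5, 1),
                     tol = 0.01)
  expect_lt(abs(res$value - 17) / 17, 0.01)
  expect_equal(res$mu_suggested, res$value / 2)
  expect_true(res$converged)
  # bracket widths strictly decreasing
  widths <- vapply(res$brackets, function(b) b[2] / b[1], numeric(1))
  expect_true(all(diff(widths) < 0))
  # collapse to all-zero counts as leaving the sparse regime too
  stub0 <- function(mu) if (mu < 17) 3 else 0
  res0 <- find_mu_max(stub0, target_active = 3, bracket = c(0.5, 1),
                      tol = 0.01)
  expect_lt(abs(res0$value - 17) / 17, 0.01)
  # doubling the tolerance reduces the probe count
  loose <- find_mu_max(stub, target_active = 3, bracket = c(0.5, 1),
                       tol = 0.02)
  expect_lt(nrow(search_trace(loose)), nrow(search_trace(res)))
  # a non-sparse lower endpoint is rejected
  expect_error(find_mu_max(function(mu) 500, target_active = 3),
               "sparse regime")
})

test_that("lambda search hits the target band on a closed-form stub", {
  # stub with active count 50*(1-lambda): target 3 means lambda ~ 0.94
  stub <- function(l) round(50 * (1 - l))
  res <- find_lambda(stub, target_active = 3)
  expect_lt(abs(res$value - 0.94), 0.03)
  expect_lte(abs(stub(res$value) - 3), 1)
  # the probed trace is recorded in evaluation order with both columns
  tr <- search_trace(res)
  expect_named(tr, c("value", "active"))
  expect_true(all(tr$active == round(50 * (1 - tr$value))))
  # a non-monotone response beyond the slack is an error with the trace
  bad <- function(l) 400 * l
  err <- tryCatch(find_lambda(bad, target_active = 90),
                  error = function(e) e)
  expect_match(conditionMessage(err), "non-increasing")
  expect_s3_class(attr(err, "trace"), "data.frame")
  # an unreachable target fails with the trace attached
  err2 <- tryCatch(find_lambda(function(l) 0, target_active = 10),
                   error = function(e) e)
  expect_match(conditionMessage(err2), "no lambda")
})

test_that("searches are deterministic and calibration lands near its target", {
  stub <- function(mu) if (mu < 4.2) 5 else 100
  r1 <- find_mu_max(stub, 5, tol = 0.02)
  r2 <- find_mu_max(stub, 5, tol = 0.02)
  expect_identical(r1$value, r2$value)
  expect_identical(search_trace(r1), search_trace(r2))

  # end-to-end calibration on a tiny noiseless problem: active count at
  # the calibrated hyperparameters within +/-1 of the target
  cfg <- list(noise = FALSE, position_jitter_mm = 0,
              gain_jitter_fraction = 0, target_jitter_mm = 0,
              amplitude_jitter = 0, peak_time_subject_sd = 0,
              peak_time_region_sd = 0)
  exp_ <- simulate_experiment(2, master_seed = 3, config = cfg)
  metric <- transport_ground_metric(exp_$mesh)
  L_list <- lapply(exp_$subjects, `[[`, "leadfield")
  t_idx <- which.min(abs(exp_$subjects[[1]]$times - 83))
  Y_list <- lapply(exp_$subjects, function(su) su$evoked[[1]][, t_idx])
  hp <- calibrate_mwe(L_list, Y_list, metric, target_active = 3,
                      mu_tol = 0.25, tol = 1e-3, max_iter = 8)
  expect_true(hp$lambda > 0 && hp$lambda < 1)
  expect_true(hp$mu > 0)
  expect_equal(hp$mu, hp$mu_max / 2)
  sol <- solve_mwe(L_list, Y_list, hp, metric, tol = 1e-3, max_iter = 8)
  expect_lte(abs(count_active(sol) - 3), 1)
  searches <- attr(hp, "searches")
  expect_s3_class(searches$lambda, "search_result")
  expect_s3_class(searches$mu_max, "search_result")
})
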