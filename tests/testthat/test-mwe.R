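# minimum Wasserstein estimates: metric, transport costs, prox, solver

test_that("ground metric is symmetric, zero-diagonal, normalized, hemisphere-blocked", {
  mesh <- build_template_space(subdivisions = 1)
  metric <- transport_ground_metric(mesh)
  expect_setequal(metric$hemis, c("left", "right"))
  for (h in metric$hemis) {
    B <- metric$blocks[[h]]
    expect_equal(B, t(B))
    expect_equal(diag(B), rep(0, nrow(B)))
    expect_true(all(is.finite(B)))
    expect_lte(max(B), 1)
  }
  # normalization: the recorded scale restores squared millimetres
  g <- geodesic_distances(mesh, metric$idx$left[1])
  expect_equal(metric$blocks$left[1, 2] * metric$scale_mm2,
               unname(g[metric$idx$left[2]])^2)
})

test_that("lambda_max matches hand arithmetic and lambda = 1 kills the solution", {
  # hand case: 2 sensors, 3 sources, integer entries
  L <- rbind(c(1, 2, 0),
             c(0, 1, 3))
  y <- c(2, 1)
  # L'y = (2, 5, 3); max abs = 5; n = 2 sensors
  expect_equal(compute_lambda_max(list(L), list(y)), 2.5)
  expect_equal(compute_lambda_max(list(L), list(c(0, 0))), 0)
  # multiple subjects: the max over subjects
  expect_equal(compute_lambda_max(list(L, L), list(y, 2 * y)), 5)

  mesh <- build_template_space(subdivisions = 1)
  metric <- transport_ground_metric(mesh)
  sensors <- make_sensor_array(16, radius = 120)
  lf <- build_leadfield(mesh, sensors)
  yv <- lf$L[, 5] * 1e-8
  hp <- mwe_hyperparams(lambda = 1, mu = 0, p = metric$p)
  sol <- solve_mwe(list(lf), list(yv), hp, metric)
  expect_equal(max(abs(sol$estimates[[1]]$X)), 0)
  expect_equal(sol$active_counts, 0)
})

test_that("half-thresholding prox is exact against a dense numerical oracle", {
  expect_equal(prox_lq_half(0, 1), 0)
  expect_equal(prox_lq_half(c(-2, 0.3, 5), 0), c(-2, 0.3, 5))
  # grid of (v, threshold) pairs vs direct 1-D minimization
  for (th in c(0.05, 0.3, 1, 2.5)) {
    for (v in seq(-4, 4, length.out = 20)) {
      z <- prox_lq_half(v, th)
      obj <- function(t) 0.5 * (t - v)^2 + th * sqrt(abs(t))
      # numerical minimum over a fine grid plus local refinement
      grid <- seq(-1.5 * abs(v) - 1, 1.5 * abs(v) + 1, length.out = 4001)
      t0 <- grid[which.min(obj(grid))]
      opt <- stats::optimize(obj, c(t0 - 0.01, t0 + 0.01))
      best <- if (obj(0) <= opt$objective) 0 else opt$minimum
      expect_equal(obj(z), obj(best), tolerance = 1e-6)
    }
  }
  # odd symmetry
  expect_equal(prox_lq_half(-3, 0.4), -prox_lq_half(3, 0.4))
})

test_that("unbalanced transport cost: displacement monotone, sign-separated, LP limit", {
  mesh <- build_template_space(subdivisions = 1)
  metric <- transport_ground_metric(mesh)
  p <- metric$p
  left <- metric$idx$left
  eps <- 5 / (3 * p)

  # moving the target mass farther away costs more
  x <- rep(0, p)
  x[left[1]] <- 1
  g <- geodesic_distances(mesh, left[1])
  near <- left[order(g[left])[2]]
  far <- left[which.max(g[left])]
  y_self <- x
  y_near <- rep(0, p); y_near[near] <- 1
  y_far <- rep(0, p); y_far[far] <- 1
  c_self <- unbalanced_wasserstein(x, y_self, metric, eps, 1)
  c_near <- unbalanced_wasserstein(x, y_near, metric, eps, 1)
  c_far <- unbalanced_wasserstein(x, y_far, metric, eps, 1)
  expect_lt(c_self, c_near)
  expect_lt(c_near, c_far)

  # opposite-sign vectors cannot be matched: all mass destroyed at gamma
  xm <- rep(0, p); xm[left[2]] <- 0.7     # purely positive
  ym <- rep(0, p); ym[left[4]] <- -0.4    # purely negative
  gam <- 2.5
  expect_equal(unbalanced_wasserstein(xm, ym, metric, eps, gam),
               gam * (0.7 + 0.4), tolerance = 1e-8)

  # eps -> 0, gamma -> Inf limit equals the exact transport LP on a
  # small balanced within-hemisphere instance
  set.seed(31)
  src <- left[c(1, 3, 7)]
  dst <- left[c(2, 5, 9)]
  a_m <- c(0.5, 0.3, 0.2)
  b_m <- c(0.4, 0.4, 0.2)
  xa <- rep(0, p); xa[src] <- a_m
  yb <- rep(0, p); yb[dst] <- b_m
  C <- metric$blocks$left[match(src, left), match(dst, left)]
  lp <- lp_transport_cost(a_m, b_m, C)
  # near the balanced limit (large gamma) the scaling iterations converge
  # slowly and report hitting their cap; the cost itself is accurate
  expect_warning(
    ent <- unbalanced_wasserstein(xa, yb, metric, eps = 1e-3, gamma = 200),
    "scaling stopped")
  expect_equal(ent, lp, tolerance = 0.01)
})

test_that("barycenters: identity, midpoint concentration, order invariance", {
  mesh <- build_template_space(subdivisions = 1)
  metric <- transport_ground_metric(mesh)
  p <- metric$p
  left <- metric$idx$left
  eps <- 5 / (3 * p)

  # identical point masses: barycenter peaks at the same vertex
  x <- rep(0, p); x[left[6]] <- 1
  bar <- wasserstein_barycenter(list(x, x, x), metric, eps, 1)
  expect_equal(which.max(abs(bar)), left[6])

  # two equal masses: barycenter peaks near the brute-force minimizer of
  # the summed transport cost over all single-vertex candidates
  u <- left[1]
  g <- geodesic_distances(mesh, u)
  v <- left[order(g[left])][8]  # a few edges away, same hemisphere
  xu <- rep(0, p); xu[u] <- 1
  xv <- rep(0, p); xv[v] <- 1
  cand_cost <- vapply(left, function(w) {
    xw <- rep(0, p); xw[w] <- 1
    unbalanced_wasserstein(xu, xw, metric, eps, 1) +
      unbalanced_wasserstein(xv, xw, metric, eps, 1)
  }, numeric(1))
  w_star <- left[which.min(cand_cost)]
  bar2 <- wasserstein_barycenter(list(xu, xv), metric, eps, 1)
  peak <- which.max(abs(bar2))
  edge <- min(g[left][g[left] > 0])
  expect_lte(unname(geodesic_distances(mesh, w_star)[peak]), 1.5 * edge)

  # permutation invariance
  y <- rep(0, p); y[left[9]] <- -0.5
  b1 <- wasserstein_barycenter(list(x, y), metric, eps, 1)
  b2 <- wasserstein_barycenter(list(y, x), metric, eps, 1)
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("solver: reduced single-subject problem, symmetry, monotone trace", {
  cfg <- list(noise = FALSE, position_jitter_mm = 0,
              gain_jitter_fraction = 0, target_jitter_mm = 0,
              amplitude_jitter = 0, peak_time_subject_sd = 0,
              peak_time_region_sd = 0)
  exp_ <- simulate_experiment(1, master_seed = 2, config = cfg)
  mesh <- exp_$mesh
  metric <- transport_ground_metric(mesh)
  lf <- exp_$subjects[[1]]$leadfield
  t_idx <- which.min(abs(exp_$subjects[[1]]$times - 83))
  y <- exp_$subjects[[1]]$evoked[[1]][, t_idx]

  hp <- mwe_hyperparams(lambda = 0.01, mu = 0, p = metric$p)
  sol <- solve_mwe(list(lf), list(y), hp, metric, tol = 1e-6)
  expect_true(sol$converged)
  tr <- sol$objective_trace
  expect_true(all(diff(tr) <= 1e-10 * (abs(tr[-length(tr)]) + 1e-300)))

  # reduced-problem oracle: an independent proximal-gradient descent on
  # 1/(2n)||y - Lx||^2 + lam*sum sqrt|x| never beats the solver.  The
  # sqrt penalty is not invariant under rescaling, so the comparison is
  # done on the solver's internally rescaled problem (leadfield divided
  # by its median column norm, data by its maximum amplitude), which is
  # where the lambda fraction is defined
  L <- lf$L / stats::median(sqrt(colSums(lf$L^2)))
  ys <- y / max(abs(y))
  n <- nrow(L)
  lam <- 0.01 * max(abs(crossprod(L, ys))) / n
  obj <- function(x) {
    sum((ys - L %*% x)^2) / (2 * n) + lam * sum(sqrt(abs(x)))
  }
  alpha <- n / (svd(L, nu = 0, nv = 0)$d[1]^2) * 0.9
  xg <- rep(0, ncol(L))
  for (k in 1:500) {
    xg <- prox_lq_half(xg - alpha * drop(crossprod(L, L %*% xg - ys)) / n,
                       alpha * lam)
  }
  x_pkg <- drop(sol$estimates[[1]]$X[, 1]) / sol$amp_unit
  expect_lte(obj(x_pkg), obj(xg) * (1 + 1e-8))
  # fixed point: one prox-gradient step from the solution does not improve
  x_step <- prox_lq_half(
    x_pkg - alpha * drop(crossprod(L, L %*% x_pkg - ys)) / n, alpha * lam)
  expect_lte(obj(x_pkg), obj(x_step) * (1 + 1e-6))

  # identical subjects give identical estimates under coupling
  hp2 <- mwe_hyperparams(lambda = 0.01, mu = 0.5, p = metric$p)
  sol3 <- solve_mwe(list(lf, lf, lf), list(y, y, y), hp2, metric,
                    tol = 1e-5, max_iter = 20)
  X <- lapply(sol3$estimates, function(e) drop(e$X[, 1]))
  expect_equal(X[[1]], X[[2]], tolerance = 1e-8)
  expect_equal(X[[1]], X[[3]], tolerance = 1e-8)
  tr3 <- sol3$objective_trace
  expect_true(all(diff(tr3) <= 1e-10 * (abs(tr3[-length(tr3)]) + 1e-300)))
})
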