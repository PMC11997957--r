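#' Hyperparameter calibration by modified binary searches
#'
#' The sparsity level `lambda` and the barycenter coupling `mu` are not
#' free knobs: `lambda` is calibrated so that a target number of source
#' points is active on average (3 for unilateral stimuli, 6 for stimuli on
#' the vertical meridian), and `mu` is set to half the transition value
#' `mu_max` beyond which the estimates leave the target-sparse regime.
#' Both calibrations are bisections against the solver's active-count
#' response; they are deterministic given the solver.
#'
#' @name hyperparam_search
#' @keywords internal
NULL

#' Mean active source count of an MWE solution
#'
#' A vertex is active if its amplitude magnitude exceeds `rel_threshold`
#' times the largest magnitude of that subject's estimate; an all-zero
#' estimate has 0 active vertices.  Returns the mean over subjects.
#'
#' @param solution An `mwe_solution` from [solve_mwe()], or a list of
#'   signed amplitude vectors.
#' @param rel_threshold Relative activity threshold in (0, 1).
#' @return Mean active count (scalar).
#' @export
count_active <- function(solution, rel_threshold = 1e-6) {
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  xs <- if (inherits(solution, "mwe_solution")) {
    lapply(solution$estimates, function(e) drop(e$X[, 1L]))
  } else {
    lapply(solution, function(e) {
      if (inherits(e, "source_estimate")) drop(e$X[, 1L]) else as.numeric(e)
    })
  }
  mean(vapply(xs, function(x) {
    m <- max(abs(x))
    if (m == 0) 0 else sum(abs(x) > rel_threshold * m)
  }, numeric(1)))
}

new_search_result <- function(parameter, value, brackets, trace, converged) {
  structure(list(parameter = parameter, value = value,
                 brackets = brackets, trace = trace, converged = converged),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s = %.6g (%s, %d evaluations)\n",
              x$parameter, x$value,
              if (x$converged) "converged" else "NOT converged",
              nrow(x$trace)))
  invisible(x)
}

#' Search trace as a data frame
#'
#' The (parameter value, mean active count) pairs probed during a search,
#' in evaluation order; suitable for `write.csv()` to reproduce
#' sparsity-transition curves.
#'
#' @param result A `search_result`.
#' @return A data frame with columns `value` and `active`.
#' @export
search_trace <- function(result) {
  stopifnot(inherits(result, "search_result"))
  result$trace
}

#' Find the sparsity-transition coupling strength mu_max
#'
#' `mu_max` is the largest coupling `mu` at which the solution stays in
#' the target-sparse regime.  The sparse regime is left either by
#' densification (mean active count above `target_active *
#' spread_factor`) or by collapse to the all-zero estimate (mean active
#' count below 1); the upper bracket is expanded geometrically until a
#' non-sparse point is found, then a log-scale bisection narrows the
#' bracket to relative width `tol` and the geometric midpoint is
#' returned.  The recommended downstream value is `mu_max / 2` (field
#' `mu_suggested`).
#'
#' @param active_fn Function of `mu` returning the mean active count of
#'   the solved problem at that coupling (with `lambda` held fixed).
#' @param target_active Calibration target for the active count.
#' @param bracket Initial `c(mu_lo, mu_hi)`; `mu_lo` must be in the
#'   sparse regime.
#' @param spread_factor Densification threshold multiplier.
#' @param tol Relative final bracket width.
#' @param max_expand Maximum number of geometric bracket expansions.
#' @return A `search_result` with `value = mu_max` and `mu_suggested`.
#' @export
find_mu_max <- function(active_fn, target_active, bracket = c(1e-3, 1),
                        spread_factor = 5, tol = 0.05, max_expand = 30) {
  stopifnot(length(bracket) == 2L, bracket[1] > 0, bracket[2] > bracket[1],
            target_active >= 1, spread_factor > 1, tol > 0)
  trace <- data.frame(value = numeric(0), active = numeric(0))
  probe <- function(mu) {
    a <- active_fn(mu)
    trace[nrow(trace) + 1L, ] <<- c(mu, a)
    a
  }
  sparse <- function(a) a <= target_active * spread_factor && a >= 1
  lo <- bracket[1]
  hi <- bracket[2]
  if (!sparse(probe(lo))) {
    stop("lower bracket endpoint is not in the sparse regime", call. = FALSE)
  }
  expansions <- 0L
  while (sparse(probe(hi))) {
    expansions <- expansions + 1L
    if (expansions > max_expand) {
      stop(sprintf(
        "could not bracket the sparsity transition in %d expansions",
        max_expand), call. = FALSE)
    }
    lo <- hi
    hi <- 2 * hi
  }
  brackets <- list(c(lo, hi))
  while (hi / lo - 1 > tol) {
    mid <- sqrt(lo * hi)
    if (sparse(probe(mid))) lo <- mid else hi <- mid
    brackets[[length(brackets) + 1L]] <- c(lo, hi)
  }
  res <- new_search_result("mu_max", sqrt(lo * hi), brackets, trace, TRUE)
  res$mu_suggested <- res$value / 2
  res
}

#' Find the sparsity level lambda for a target active count
#'
#' Bisection on the `lambda` fraction in `[0, 1]` for a mean active count
#' within plus or minus 1 of `target_active`, assuming the active count is
#' non-increasing in `lambda`; the assumption is verified on the probed
#' trace and a violation beyond `monotone_slack` counts is an error.
#'
#' @param active_fn Function of the `lambda` fraction returning the mean
#'   active count (with `mu` held fixed).
#' @param target_active Target mean active count (3 for unilateral
#'   regions, 6 for vertical-meridian regions).
#' @param tol Minimum bracket width before giving up.
#' @param monotone_slack Tolerated active-count increase between
#'   increasing `lambda` probes.
#' @return A `search_result` with `value` = the calibrated fraction.
#' @export
find_lambda <- function(active_fn, target_active, tol = 1e-3,
                        monotone_slack = 1) {
  stopifnot(target_active >= 1, tol > 0)
  trace <- data.frame(value = numeric(0), active = numeric(0))
  probe <- function(l) {
    a <- active_fn(l)
    trace[nrow(trace) + 1L, ] <<- c(l, a)
    a
  }
  check_monotone <- function() {
    o <- order(trace$value)
    viol <- diff(trace$active[o]) - monotone_slack
    if (any(viol > 0)) {
      err <- simpleError(paste0("active count is not non-increasing in ",
                                "lambda (trace attached as attribute)"))
      attr(err, "trace") <- trace
      stop(err)
    }
  }
  lo <- 0
  hi <- 1
  brackets <- list(c(lo, hi))
  result <- NULL
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    a <- probe(mid)
    if (abs(a - target_active) <= 1) {
      result <- mid
      break
    }
    if (a > target_active) lo <- mid else hi <- mid
    brackets[[length(brackets) + 1L]] <- c(lo, hi)
  }
  check_monotone()
  if (is.null(result)) {
    err <- simpleError(sprintf(
      "no lambda with active count within 1 of target %g (bracket [%g, %g])",
      target_active, lo, hi))
    attr(err, "trace") <- trace
    stop(err)
  }
  new_search_result("lambda", result, brackets, trace, TRUE)
}

#' Calibrate MWE hyperparameters for one problem
#'
#' The full calibration: `lambda` is searched at `mu = 0`, `mu_max` is
#' searched at that `lambda`, `mu` is set to `mu_max / 2`, and `lambda`
#' is re-checked once at the final `mu` (kept if still within target,
#' re-searched otherwise).
#'
#' @param L_list,Y_list,metric As in [solve_mwe()].
#' @param target_active 3 for unilateral regions, 6 for bilateral.
#' @param rel_threshold Active-vertex threshold for [count_active()].
#' @param mu_bracket Initial bracket for [find_mu_max()].
#' @param mu_tol Relative bracket tolerance for [find_mu_max()]; the
#'   downstream value is only `mu_max / 2`, so a loose tolerance is
#'   usually adequate.
#' @param ... Passed to [solve_mwe()] (e.g. `tol`, `max_iter`).
#' @return An `mwe_hyperparams` with `lambda`, `mu`, `mu_max` filled in
#'   and the two `search_result`s attached as attribute `"searches"`.
#' @export
calibrate_mwe <- function(L_list, Y_list, metric, target_active,
                          rel_threshold = 1e-6, mu_bracket = c(1e-3, 1),
                          mu_tol = 0.05, ...) {
  p <- metric$p
  act <- function(lambda, mu) {
    sol <- solve_mwe(L_list, Y_list,
                     mwe_hyperparams(lambda = lambda, mu = mu, p = p),
                     metric, ...)
    count_active(sol, rel_threshold)
  }
  s_lam <- find_lambda(function(l) act(l, 0), target_active)
  s_mu <- find_mu_max(function(m) act(s_lam$value, m), target_active,
                      bracket = mu_bracket, tol = mu_tol)
  mu <- s_mu$mu_suggested
  a_final <- act(s_lam$value, mu)
  lam <- s_lam$value
  if (abs(a_final - target_active) > 1) {
    s_lam <- find_lambda(function(l) act(l, mu), target_active)
    lam <- s_lam$value
  }
  hp <- mwe_hyperparams(lambda = lam, mu = mu, p = p,
                        mu_max = s_mu$value)
  attr(hp, "searches") <- list(lambda = s_lam, mu_max = s_mu)
  hp
}
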