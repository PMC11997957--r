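#' Evaluation: peak timing, peak vertices, distances, Winsorized reports
#'
#' Source estimates are scored by the geodesic distance between the
#' estimated peak vertex and the target vertex of the stimulated region.
#' Peaks are selected at the subject-median sensor peak time within the
#' 60-100 ms window; unilateral regions use the global amplitude maximum,
#' vertical-meridian (bilateral) regions one maximum per hemisphere.
#' Distances above 80 mm or peaks on the wrong hemisphere are outliers and
#' Winsorized to 80 mm in all summary statistics.
#'
#' @name evaluation_report
#' @keywords internal
NULL

#' Sensor-space peak time within a window
#'
#' The peak statistic is the global field power: the RMS across channels
#' after removing the mean across channels at each time sample.  The
#' boundary flag marks an argmax on either window edge (a slope, not a
#' peak).
#'
#' @param Y N x T sensor matrix.
#' @param times Length-T time axis, ms.
#' @param window Two-element analysis window, ms.
#' @return List with `time` (ms), `boundary` (logical), `gfp` (the full
#'   GFP trace).
#' @export
find_peak_time <- function(Y, times, window = c(60, 100)) {
  stopifnot(is.matrix(Y), length(times) == ncol(Y))
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L) {
    stop("`window` does not overlap the time axis", call. = FALSE)
  }
  Z <- sweep(Y, 2L, colMeans(Y))
  gfp <- sqrt(colMeans(Z^2))
  k <- idx[which.max(gfp[idx])]
  list(time = times[k], boundary = k == idx[1L] || k == idx[length(idx)],
       gfp = gfp)
}

#' Subject-level median peak time
#'
#' Median of the per-region peak times after removing boundary-flagged
#' values; this single time is used for all of the subject's inversions.
#'
#' @param times Per-region peak times, ms.
#' @param boundary Per-region boundary flags.
#' @return Scalar median time, ms.
#' @export
subject_median_peak_time <- function(times, boundary = rep(FALSE,
                                                           length(times))) {
  stopifnot(length(times) == length(boundary))
  keep <- !boundary
  if (!any(keep)) {
    stop(paste0("all region peak times lie on the window boundary; ",
                "review the peak window"), call. = FALSE)
  }
  stats::median(times[keep])
}

#' Peak vertex selection for one region
#'
#' Unilateral regions: the single vertex with the globally largest
#' amplitude magnitude.  Bilateral (vertical-meridian) regions: one such
#' vertex per hemisphere.  Ties break toward the lower vertex id (which is
#' what `which.max` returns).
#'
#' @param estimate A `source_estimate` (its first/only time column is
#'   used) or a bare amplitude vector.
#' @param mesh The template [meg_mesh] (for hemisphere labels).
#' @param bilateral Logical: select one peak per hemisphere.
#' @return A data frame with `hemi`, `vertex`, `amplitude` (one row, or
#'   one per hemisphere).
#' @export
find_peak_vertices <- function(estimate, mesh, bilateral = FALSE) {
  x <- if (inherits(estimate, "source_estimate")) {
    drop(estimate$X[, 1L])
  } else {
    as.numeric(estimate)
  }
  stopifnot(length(x) == nrow(mesh$vertices))
  a <- abs(x)
  if (max(a) == 0) {
    stop("all-zero estimate has no peak", call. = FALSE)
  }
  if (!bilateral) {
    v <- which.max(a)
    return(data.frame(hemi = mesh$hemisphere[v], vertex = v,
                      amplitude = x[v]))
  }
  hemis <- unique(mesh$hemisphere)
  do.call(rbind, lapply(hemis, function(h) {
    ii <- hemisphere_vertices(mesh, h)
    v <- ii[which.max(a[ii])]
    data.frame(hemi = h, vertex = v, amplitude = x[v])
  }))
}

#' Geodesic peak-target distance and outlier flag
#'
#' Outliers are peaks on the wrong hemisphere (flagged regardless of any
#' distance) or farther than `cap` mm from the target along the cortex.
#'
#' @param mesh The template [meg_mesh].
#' @param peak_vertex,target_vertex Vertex indices.
#' @param cap Outlier distance threshold, mm.
#' @return List with `distance` (mm; `Inf` across hemispheres),
#'   `outlier`, `wrong_hemisphere`.
#' @export
peak_target_distance <- function(mesh, peak_vertex, target_vertex,
                                 cap = 80) {
  wrong <- mesh$hemisphere[peak_vertex] != mesh$hemisphere[target_vertex]
  d <- if (wrong) {
    Inf
  } else {
    unname(geodesic_distances(mesh, target_vertex)[peak_vertex])
  }
  list(distance = d, outlier = wrong || d > cap, wrong_hemisphere = wrong)
}

#' Winsorized summary statistics of peak-target distances
#'
#' Outlier-flagged distances are replaced by `cap` (80 mm), then the
#' arithmetic mean, median and standard deviation are computed.
#'
#' @param distances Numeric distances, mm.
#' @param outlier Logical outlier flags (same length).
#' @param cap Replacement value, mm.
#' @return List with `mean`, `median`, `sd`, `n`, `n_outliers`.
#' @export
winsorized_stats <- function(distances, outlier = rep(FALSE,
                                                      length(distances)),
                             cap = 80) {
  if (length(distances) == 0L) {
    stop("no distances to summarize", call. = FALSE)
  }
  stopifnot(length(outlier) == length(distances))
  x <- ifelse(outlier, cap, distances)
  list(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
       n = length(x), n_outliers = sum(outlier))
}

# abort with the failing pipeline stage name attached
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# evaluate one estimate against the template truth of one region:
# one row per required hemisphere side
evaluate_region <- function(estimate, mesh, truth_rows, bilateral,
                            cap = 80) {
  peaks <- find_peak_vertices(estimate, mesh, bilateral = bilateral)
  do.call(rbind, lapply(seq_len(nrow(truth_rows)), function(i) {
    tr <- truth_rows[i, ]
    pk <- if (bilateral) peaks[peaks$hemi == tr$hemi, ] else peaks
    pt <- peak_target_distance(mesh, pk$vertex[1L], tr$vertex, cap = cap)
    data.frame(region = tr$region, hemi = tr$hemi,
               peak_vertex = pk$vertex[1L], target_vertex = tr$vertex,
               distance_mm = pt$distance, outlier = pt$outlier,
               wrong_hemisphere = pt$wrong_hemisphere)
  }))
}

#' Run the full simulation-inversion-evaluation pipeline
#'
#' Simulates a multi-subject experiment, finds each subject's median
#' sensor peak time, inverts every region with eLORETA (and optionally
#' MWE) at that time, selects the representative subject, forms nested
#' groups, averages estimates per group, and scores all methods with
#' Winsorized peak-target distance statistics in a Table-style layout.
#' Deterministic given `master_seed`.
#'
#' Methods: `"elora_avg"` averages eLORETA magnitude estimates over the
#' group; `"mwe"` reports the representative subject's estimate from the
#' group MWE solve; `"mwe_avg"` averages the absolute MWE estimates over
#' the group.  MWE hyperparameters are calibrated once per region type
#' (unilateral target 3 active, bilateral target 6) on the full subject
#' set and reused across group sizes.
#'
#' @param n_subjects Number of simulated subjects.
#' @param master_seed Master seed; all randomness derives from it.
#' @param group_sizes Nested group sizes (non-decreasing, max at most
#'   `n_subjects`).
#' @param methods Subset of `c("elora_avg", "mwe", "mwe_avg")`.
#' @param config Overrides for [default_experiment_config()].
#' @param layout Stimulus layout.
#' @param template Optional [build_experiment_template()] result.
#' @param regions Region ids to evaluate (default all).
#' @param mwe_tol,mwe_max_iter Solver controls for [solve_mwe()].
#' @param verbose Print stage progress to stderr.
#' @return An `evaluation_table`: `rows` (one per method x group size x
#'   region x hemisphere side), `summary` (Winsorized mean/median/sd per
#'   method x group size), `per_subject` (single-subject eLORETA rows),
#'   `manifest` (seeds, ordering, groups, peak times, hyperparameters).
#' @export
run_pipeline <- function(n_subjects = 20, master_seed = 1,
                         group_sizes = c(1, 5, 10, 15, 20),
                         methods = c("elora_avg", "mwe", "mwe_avg"),
                         config = list(), layout = make_stimulus_layout(),
                         template = NULL, regions = NULL,
                         mwe_tol = 1e-4, mwe_max_iter = 30,
                         verbose = FALSE) {
  methods <- match.arg(methods, c("elora_avg", "mwe", "mwe_avg"),
                       several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  exp <- with_stage("simulate", simulate_experiment(
    n_subjects, master_seed, layout = layout, config = config,
    template = template))
  mesh <- exp$mesh
  cfg <- exp$config
  if (is.null(regions)) regions <- layout$region
  S <- length(exp$subjects)
  stopifnot(max(group_sizes) <= S, all(diff(group_sizes) >= 0))

  # subject-median peak times from sensor-space GFP
  say("pipeline: peak timing")
  peak_times <- with_stage("peak_timing", vapply(exp$subjects, function(su) {
    pk <- lapply(layout$region, function(r) {
      find_peak_time(su$evoked[[r]], su$times)
    })
    subject_median_peak_time(vapply(pk, `[[`, numeric(1), "time"),
                             vapply(pk, `[[`, logical(1), "boundary"))
  }, numeric(1)))
  t_idx <- vapply(peak_times, function(t) {
    which.min(abs(cfg$times - t))
  }, integer(1))

  # per-subject eLORETA magnitude estimates at the subject-median time
  say("pipeline: eLORETA inversion")
  p <- nrow(mesh$vertices)
  elora <- with_stage("elora", lapply(seq_len(S), function(s) {
    su <- exp$subjects[[s]]
    if (cfg$noise) {
      snr <- mean(vapply(layout$region, function(r) {
        estimate_snr(su$evoked[[r]], su$Sigma, su$times)
      }, numeric(1)))
      lambda2 <- regularization_from_snr(snr)
    } else {
      snr <- Inf
      lambda2 <- 0
    }
    w <- elora_weights(su$leadfield, su$Sigma, lambda2 = lambda2)
    op <- elora_inverse_operator(su$leadfield, w, su$Sigma,
                                 lambda2 = lambda2)
    est <- vapply(layout$region, function(r) {
      abs(drop(op$W %*% su$evoked[[r]][, t_idx[s]]))
    }, numeric(p))
    list(estimates = est, snr = snr, lambda2 = lambda2)
  }))

  bilat <- layout$bilateral
  names(bilat) <- layout$region
  truth_by_region <- split(exp$truth, exp$truth$region)

  # single-subject eLORETA scoring -> representative selection
  say("pipeline: representative selection")
  per_subject <- with_stage("representative", do.call(rbind, lapply(
    seq_len(S), function(s) {
      rws <- do.call(rbind, lapply(regions, function(r) {
        evaluate_region(elora[[s]]$estimates[, r], mesh,
                        truth_by_region[[as.character(r)]], bilat[[r]])
      }))
      cbind(subject = s, rws)
    })))
  med <- vapply(split(per_subject, per_subject$subject), function(d) {
    stats::median(ifelse(d$outlier, 80, d$distance_mm))
  }, numeric(1))
  representative <- as.integer(select_representative(med))
  ordering <- subject_ordering(seq_len(S), representative)
  groups <- build_groups(ordering, group_sizes)

  rows <- list()
  add_rows <- function(method, size, df) {
    rows[[length(rows) + 1L]] <<- cbind(method = method,
                                        group_size = size, df)
  }

  if ("elora_avg" %in% methods) {
    say("pipeline: group-averaged eLORETA")
    with_stage("elora_avg", for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (r in regions) {
        avg <- rowMeans(vapply(g, function(s) elora[[s]]$estimates[, r],
                               numeric(p)))
        add_rows("elora_avg", group_sizes[gi],
                 evaluate_region(avg, mesh,
                                 truth_by_region[[as.character(r)]],
                                 bilat[[r]]))
      }
    })
  }

  hyper_by_type <- NULL
  mwe_methods <- intersect(methods, c("mwe", "mwe_avg"))
  if (length(mwe_methods) > 0) {
    metric <- with_stage("transport_metric", transport_ground_metric(mesh))
    L_all <- lapply(exp$subjects, `[[`, "leadfield")
    y_region <- function(g, r) {
      lapply(g, function(s) exp$subjects[[s]]$evoked[[r]][, t_idx[s]])
    }
    say("pipeline: MWE calibration")
    hyper_by_type <- with_stage("mwe_calibration", {
      types <- unique(bilat[as.character(regions)])
      # calibration probes only need the active-count response, so run
      # them on a small subject subset with capped solver iterations and
      # a loose mu bracket; the solves used for the table are full
      cal_idx <- seq_len(min(S, 3L))
      out <- list()
      for (b in types) {
        r0 <- regions[bilat[as.character(regions)] == b][1L]
        out[[if (b) "bilateral" else "unilateral"]] <-
          calibrate_mwe(L_all[cal_idx], y_region(cal_idx, r0), metric,
                        target_active = if (b) 6 else 3,
                        mu_tol = 0.25,
                        tol = max(mwe_tol, 1e-3),
                        max_iter = min(mwe_max_iter, 8L))
      }
      out
    })
    say("pipeline: MWE group solves")
    with_stage("mwe", for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (r in regions) {
        hp <- hyper_by_type[[if (bilat[[r]]) "bilateral" else "unilateral"]]
        sol <- solve_mwe(lapply(g, function(s) L_all[[s]]),
                         y_region(g, r), hp, metric,
                         tol = mwe_tol, max_iter = mwe_max_iter)
        tr <- truth_by_region[[as.character(r)]]
        if ("mwe" %in% mwe_methods) {
          add_rows("mwe", group_sizes[gi],
                   evaluate_region(sol$estimates[[1L]], mesh, tr,
                                   bilat[[r]]))
        }
        if ("mwe_avg" %in% mwe_methods) {
          avg <- average_estimates(sol$estimates, use_absolute = TRUE)
          add_rows("mwe_avg", group_sizes[gi],
                   evaluate_region(avg, mesh, tr, bilat[[r]]))
        }
      }
    })
  }

  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  summary <- do.call(rbind, lapply(
    split(rows, list(rows$method, rows$group_size), drop = TRUE),
    function(d) {
      st <- winsorized_stats(d$distance_mm, d$outlier)
      data.frame(method = d$method[1L], group_size = d$group_size[1L],
                 mean_mm = st$mean, median_mm = st$median, sd_mm = st$sd,
                 n = st$n, n_outliers = st$n_outliers)
    }))
  summary <- summary[order(summary$method, summary$group_size), ]
  rownames(summary) <- NULL

  structure(list(
    rows = rows, summary = summary, per_subject = per_subject,
    manifest = list(
      master_seed = master_seed, n_subjects = S,
      group_sizes = group_sizes, methods = methods, regions = regions,
      flashes_per_region = exp$metadata$flashes_per_region,
      subject_seeds = exp$metadata$subject_seeds,
      peak_times_ms = peak_times,
      subject_median_distance_mm = unname(med),
      representative = representative, ordering = ordering,
      groups = groups,
      snr = vapply(elora, `[[`, numeric(1), "snr"),
      lambda2 = vapply(elora, `[[`, numeric(1), "lambda2"),
      mwe_hyperparams = lapply(hyper_by_type, function(h) {
        list(lambda = h$lambda, mu = h$mu, mu_max = h$mu_max,
             eps = h$eps, gamma = h$gamma)
      }))),
    class = "evaluation_table")
}

#' @export
print.evaluation_table <- function(x, ...) {
  cat(sprintf("<evaluation_table> %d rows, %d subjects, seed %d\n",
              nrow(x$rows), x$manifest$n_subjects,
              x$manifest$master_seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation table to disk
#'
#' `rows` and `summary` as CSV, the manifest as JSON; all plain text.
#'
#' @param table An `evaluation_table` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(table, dir) {
  stopifnot(inherits(table, "evaluation_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(rows = file.path(dir, "rows.csv"),
             summary = file.path(dir, "summary.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(table$rows, paths[["rows"]], row.names = FALSE)
  utils::write.csv(table$summary, paths[["summary"]], row.names = FALSE)
  jsonlite::write_json(table$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
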