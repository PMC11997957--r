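#' Synthetic multi-subject retinotopy experiments
#'
#' The generator emulates the statistical structure of a multifocal
#' retinotopic-mapping MEG study: 24 stimulus regions arranged in 3
#' eccentricity rings of 8 polar-angle wedges, evoked responses peaking
#' around 83 ms with an amplitude SNR near 2, a shared template source
#' space with per-subject leadfield and target jitter, and contralateral
#' organization (left visual field projecting to the right hemisphere).
#' Regions whose wedge touches the vertical meridian are flagged bilateral
#' and activate one source per hemisphere.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Build the multifocal dartboard stimulus layout
#'
#' @param rings Number of eccentricity rings (default 3).
#' @param wedges Number of polar-angle wedges (default 8).
#' @param radii_deg Strictly increasing ring boundary radii in degrees of
#'   visual angle, length `rings + 1`.
#' @return A `stimulus_layout` data frame with one row per region:
#'   `region`, `ring`, `wedge`, `inner_deg`, `outer_deg`, `angle_start`,
#'   `angle_end` (degrees, counter-clockwise from the right horizontal
#'   meridian), `bilateral`, and `hemifield` (`"left"`, `"right"` or
#'   `"both"`).
#' @export
make_stimulus_layout <- function(rings = 3, wedges = 8,
                                 radii_deg = c(0.5, 2.3, 4.7, 8.4)) {
  stopifnot(rings >= 1, wedges >= 1)
  if (length(radii_deg) != rings + 1 || any(diff(radii_deg) <= 0)) {
    stop("`radii_deg` must be strictly increasing with length rings + 1",
         call. = FALSE)
  }
  step <- 360 / wedges
  grid <- expand.grid(wedge = seq_len(wedges), ring = seq_len(rings))
  a0 <- (grid$wedge - 1) * step
  a1 <- grid$wedge * step
  # a wedge is bilateral when its angular span touches the vertical
  # meridian (90 or 270 degrees), where bilateral activation is expected
  touches <- function(lo, hi, m) lo <= m & hi >= m
  bilateral <- touches(a0, a1, 90) | touches(a0, a1, 270)
  mid <- (a0 + a1) / 2
  hemifield <- ifelse(bilateral, "both",
                      ifelse(mid > 90 & mid < 270, "left", "right"))
  out <- data.frame(region = seq_len(nrow(grid)),
                    ring = grid$ring, wedge = grid$wedge,
                    inner_deg = radii_deg[grid$ring],
                    outer_deg = radii_deg[grid$ring + 1],
                    angle_start = a0, angle_end = a1,
                    bilateral = bilateral, hemifield = hemifield)
  class(out) <- c("stimulus_layout", "data.frame")
  out
}

# posterior anchor ("occipital pole" surrogate) of one hemisphere:
# the most posterior (minimum y) vertex
hemisphere_anchor <- function(mesh, hemi) {
  idx <- hemisphere_vertices(mesh, hemi)
  idx[which.min(mesh$vertices[idx, 2L])]
}

# angle of each vertex around the anchor, in a fixed tangent frame
anchor_angles <- function(mesh, hemi, anchor) {
  ctr <- mesh$hemisphere_centers[hemi, ]
  n_hat <- mesh$vertices[anchor, ] - ctr
  n_hat <- n_hat / sqrt(sum(n_hat^2))
  e1 <- c(0, 0, 1) - n_hat[3] * n_hat
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n_hat[2] * e1[3] - n_hat[3] * e1[2],
          n_hat[3] * e1[1] - n_hat[1] * e1[3],
          n_hat[1] * e1[2] - n_hat[2] * e1[1])
  rel <- sweep(mesh$vertices, 2L, mesh$vertices[anchor, ], `-`)
  atan2(rel %*% e2, rel %*% e1) * 180 / pi
}

#' Place ground-truth target vertices for a stimulus layout
#'
#' Maps each stimulus region to a target vertex on the template mesh:
#' eccentricity ring determines the geodesic distance from the posterior
#' "occipital pole" anchor of the hemisphere, and the wedge's polar angle
#' determines the direction around that anchor.  Unilateral regions are
#' mapped contralaterally (left visual field to the right hemisphere);
#' bilateral regions get one target per hemisphere.
#'
#' @param mesh A two-hemisphere [meg_mesh] from [build_template_space()].
#' @param layout A `stimulus_layout` from [make_stimulus_layout()].
#' @param seed Integer seed (placement is deterministic; the seed is
#'   recorded for provenance).
#' @param ecc_geodesic_mm Geodesic distance from the pole anchor for each
#'   eccentricity ring, mm.
#' @param base_amplitude True source amplitude for ring 1, A*m.
#' @param ring_amplitude_scale Multiplicative amplitude factor per ring;
#'   outer rings are weaker.
#' @param peak_time_ms Template peak latency of the evoked response, ms.
#' @return A `ground_truth` data frame with one row per (region,
#'   hemisphere side): `region`, `ring`, `wedge`, `hemi`, `vertex`,
#'   `amplitude`, `peak_time`.  Attributes `anchors` (named vertex ids)
#'   and `seed` are attached.
#' @export
place_targets <- function(mesh, layout, seed = 1,
                          ecc_geodesic_mm = c(10, 20, 30),
                          base_amplitude = 1e-8,
                          ring_amplitude_scale = c(1, 0.8, 0.6),
                          peak_time_ms = 83) {
  rings <- max(layout$ring)
  if (length(ecc_geodesic_mm) < rings ||
      length(ring_amplitude_scale) < rings) {
    stop("need one eccentricity distance and amplitude scale per ring",
         call. = FALSE)
  }
  hemis <- c("left", "right")
  anchors <- vapply(hemis, function(h) hemisphere_anchor(mesh, h),
                    integer(1))
  geo <- lapply(hemis, function(h) geodesic_distances(mesh, anchors[[h]]))
  names(geo) <- hemis
  ang <- lapply(hemis, function(h) anchor_angles(mesh, h, anchors[[h]]))
  names(ang) <- hemis
  max_reach <- vapply(hemis, function(h) {
    max(geo[[h]][is.finite(geo[[h]])])
  }, numeric(1))
  if (any(max_reach < max(ecc_geodesic_mm[seq_len(rings)]))) {
    stop("mesh patch too small for the requested eccentricity distances",
         call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    reg <- layout[i, ]
    phi <- (reg$angle_start + reg$angle_end) / 2
    sides <- switch(reg$hemifield,
                    left = "right", right = "left",
                    both = c("left", "right"))
    d_k <- ecc_geodesic_mm[reg$ring]
    for (h in sides) {
      # visual polar angle -> cortical angle around the pole anchor;
      # mirrored on the right hemisphere so the vertical meridian maps
      # consistently on both sides
      theta_t <- if (h == "right") 180 - phi else phi
      cand <- hemisphere_vertices(mesh, h)
      g <- geo[[h]][cand]
      dth <- ((ang[[h]][cand] - theta_t + 180) %% 360) - 180
      score <- (g - d_k)^2 + (d_k * dth * pi / 180)^2
      v <- cand[which.min(score)]
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg$region, ring = reg$ring, wedge = reg$wedge,
        hemi = h, vertex = v,
        amplitude = base_amplitude * ring_amplitude_scale[reg$ring],
        peak_time = peak_time_ms)
    }
  }
  truth <- do.call(rbind, rows)
  class(truth) <- c("ground_truth", "data.frame")
  attr(truth, "anchors") <- anchors
  attr(truth, "seed") <- seed
  truth
}

#' Characterize target spacing on the mesh
#'
#' For each target, the mean and minimum geodesic distance to the other
#' targets on the same hemisphere -- the scale against which peak-to-target
#' distances should be read.
#'
#' @param mesh The template [meg_mesh].
#' @param truth A `ground_truth` from [place_targets()].
#' @return A data frame with `region`, `hemi`, `vertex`,
#'   `mean_neighbor_mm`, `min_neighbor_mm`.
#' @export
target_neighbor_distances <- function(mesh, truth) {
  out <- truth[, c("region", "hemi", "vertex")]
  out$mean_neighbor_mm <- NA_real_
  out$min_neighbor_mm <- NA_real_
  for (i in seq_len(nrow(truth))) {
    same <- truth$hemi == truth$hemi[i] & truth$vertex != truth$vertex[i]
    if (!any(same)) next
    d <- geodesic_distances(mesh, truth$vertex[i])[truth$vertex[same]]
    out$mean_neighbor_mm[i] <- mean(d)
    out$min_neighbor_mm[i] <- min(d)
  }
  out
}

# Gaussian-in-time source pulse on the target vertices, with a fraction of
# the amplitude leaked to 1-ring mesh neighbours (a minimal non-pointlike
# spatial extent).  Returns the P x T source amplitude matrix.
source_time_course <- function(mesh, vertices, amplitudes, times,
                               peak_time, sigma_ms = 10, spread = 0.3) {
  p <- nrow(mesh$vertices)
  x_spatial <- numeric(p)
  for (j in seq_along(vertices)) {
    v <- vertices[j]
    x_spatial[v] <- x_spatial[v] + amplitudes[j]
    if (spread > 0) {
      nb <- as.integer(igraph::neighbors(mesh$graph, v))
      if (length(nb) > 0) {
        x_spatial[nb] <- x_spatial[nb] + spread * amplitudes[j]
      }
    }
  }
  pulse <- exp(-(times - peak_time)^2 / (2 * sigma_ms^2))
  outer(x_spatial, pulse)
}

#' Simulate one evoked response
#'
#' `Y = L x(t) + E`, where `x(t)` is a smooth unimodal (Gaussian, sigma =
#' `sigma_ms`) pulse at the target vertex or vertices with a fraction
#' `spread` leaked to their 1-ring neighbours, and `E` is drawn
#' independently per time sample from a scaled noise covariance.  When
#' `noise_scale` is `NULL` the covariance scale is calibrated so that the
#' whitened-RMS amplitude SNR of the response over 0-300 ms (see
#' [estimate_snr()]) equals `snr_target`.
#'
#' @param leadfield A `leadfield` (or bare N x P matrix).
#' @param Sigma N x N noise covariance shape (any scale; see
#'   `noise_scale`).
#' @param mesh The source-space [meg_mesh].
#' @param vertices Active target vertex indices.
#' @param amplitudes True source amplitudes (A*m), one per vertex.
#' @param times Time axis in ms.
#' @param peak_time True peak latency, ms.
#' @param snr_target Desired amplitude SNR (> 1); ignored when
#'   `noise_scale` is given or `noise = FALSE`.
#' @param sigma_ms Temporal width of the source pulse, ms.
#' @param spread Fraction of the amplitude leaked to 1-ring neighbours.
#' @param noise Logical; `FALSE` returns the noiseless `L x(t)`.
#' @param noise_scale Optional fixed multiplier for `Sigma`.
#' @param seed Integer seed for the noise draw.
#' @return List with `Y` (N x T), `times`, `Sigma_used` (the scaled
#'   covariance actually drawn from; `NULL` when noiseless),
#'   `noise_scale`, and `x` (P x T true source time course).
#' @export
simulate_evoked <- function(leadfield, Sigma, mesh, vertices, amplitudes,
                            times = seq(-50, 450, by = 2), peak_time = 83,
                            snr_target = 2, sigma_ms = 10, spread = 0.3,
                            noise = TRUE, noise_scale = NULL, seed = 1) {
  L <- as_leadfield_matrix(leadfield)
  x <- source_time_course(mesh, vertices, amplitudes, times, peak_time,
                          sigma_ms, spread)
  S <- L %*% x
  if (!noise) {
    return(list(Y = S, times = times, Sigma_used = NULL, noise_scale = 0,
                x = x))
  }
  if (is.null(noise_scale)) {
    if (snr_target <= 1) {
      stop("`snr_target` must exceed 1 for the whitened-RMS estimator",
           call. = FALSE)
    }
    noise_scale <- calibrate_noise_scale(list(S), Sigma, times, snr_target)
  }
  Sigma_used <- noise_scale * Sigma
  E <- with_seed(seed, draw_noise(Sigma_used, ncol(S)))
  list(Y = S + E, times = times, Sigma_used = Sigma_used,
       noise_scale = noise_scale, x = x)
}

# solve for the covariance multiplier c such that the mean (over signals
# and window samples) of sqrt(s_t^2 / c + 1) equals snr_target, where s_t
# is the whitened RMS of the noiseless signal under the unscaled Sigma
calibrate_noise_scale <- function(signals, Sigma, times,
                                  snr_target, window = c(0, 300)) {
  Wh <- whitener(Sigma)
  idx <- which(times >= window[1] & times <= window[2])
  s2 <- unlist(lapply(signals, function(S) {
    colMeans((Wh %*% S[, idx, drop = FALSE])^2)
  }))
  f <- function(lc) mean(sqrt(s2 / 10^lc + 1)) - snr_target
  lo <- log10(max(s2) + .Machine$double.xmin) - 16
  hi <- log10(max(s2) + .Machine$double.xmin) + 4
  10^stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

draw_noise <- function(Sigma, t) {
  R <- chol(Sigma)
  t(R) %*% matrix(stats::rnorm(nrow(Sigma) * t), nrow(Sigma), t)
}

# diagonal-plus-low-rank random SPD noise covariance shape
random_noise_cov <- function(n, rank = 3) {
  B <- matrix(stats::rnorm(n * rank), n, rank) / sqrt(rank)
  diag(stats::runif(n, 0.5, 1.5)) + 0.5 * B %*% t(B)
}

# deterministic child seed derivation, kept below 2^31
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(i)) %%
               2147483629)
}

#' Precompute the seed-independent part of an experiment
#'
#' Mesh, sensor array, base leadfield and template target placement are
#' deterministic given the layout and configuration; computing them once
#' and passing the result to [simulate_experiment()] saves substantial
#' time when sweeping master seeds.
#'
#' @param layout A `stimulus_layout`.
#' @param config Optional overrides of [default_experiment_config()].
#' @return A list with `mesh`, `sensors`, `leadfield`, `truth`, `config`.
#' @export
build_experiment_template <- function(layout = make_stimulus_layout(),
                                      config = list()) {
  cfg <- utils::modifyList(default_experiment_config(), config)
  mesh <- build_template_space(cfg$subdivisions, cfg$radius,
                               cfg$hemisphere_gap)
  sensors <- make_sensor_array(cfg$n_sensors, cfg$sensor_radius,
                               cfg$sensor_z_min)
  list(mesh = mesh, sensors = sensors,
       leadfield = build_leadfield(mesh, sensors),
       truth = place_targets(mesh, layout,
                             ecc_geodesic_mm = cfg$ecc_geodesic_mm,
                             base_amplitude = cfg$base_amplitude,
                             ring_amplitude_scale = cfg$ring_amplitude_scale,
                             peak_time_ms = cfg$peak_time),
       config = cfg)
}

#' Simulate a complete multi-subject experiment
#'
#' Generates the template mesh, sensor array, stimulus layout and ground
#' truth, then per subject: a jittered leadfield, a random
#' diagonal-plus-low-rank noise covariance (scale calibrated once per
#' subject so the subject-mean amplitude SNR across regions equals
#' `snr_target`), per-subject jittered targets (geodesic jitter, amplitude
#' and latency jitter), and one evoked response per stimulus region
#' (bilateral regions activate both hemispheres simultaneously).
#' Everything is reproducible from `master_seed`.
#'
#' @param n_subjects Number of subjects.
#' @param master_seed Integer master seed.
#' @param layout A `stimulus_layout`; default 3 rings x 8 wedges.
#' @param config Optional named list overriding entries of
#'   [default_experiment_config()].
#' @param template Optional precomputed template from
#'   [build_experiment_template()] (mesh, sensors, base leadfield and
#'   target placement are deterministic given `layout` and `config`, so
#'   they can be shared across master seeds).
#' @return A `meg_experiment`: list with `mesh`, `sensors`, `layout`,
#'   `truth` (template `ground_truth`), `subjects` (each with `id`,
#'   `leadfield`, `Sigma`, `noise_scale`, `truth`, `evoked` -- one N x T
#'   matrix per region -- and `times`), `config`, `metadata` (flash
#'   bookkeeping and seeds), `master_seed`.
#' @export
simulate_experiment <- function(n_subjects, master_seed = 1,
                                layout = make_stimulus_layout(),
                                config = list(), template = NULL) {
  stopifnot(n_subjects >= 1)
  if (is.null(template)) {
    template <- build_experiment_template(layout, config)
  }
  cfg <- template$config
  mesh <- template$mesh
  sensors <- template$sensors
  base_lf <- template$leadfield
  truth <- template$truth
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    seed_s <- child_seed(master_seed, s)
    lf <- jitter_subject(base_lf, mesh, sensors, seed = seed_s,
                         position_jitter_mm = cfg$position_jitter_mm,
                         gain_jitter_fraction = cfg$gain_jitter_fraction)
    Sigma_shape <- with_seed(child_seed(seed_s, 1),
                             random_noise_cov(sensors$n))
    st <- with_seed(child_seed(seed_s, 2),
                    jitter_truth(truth, mesh, cfg))
    # one noise scale per subject: subject-mean SNR across regions hits
    # the target, so per-region SNR varies with source depth/eccentricity
    signals <- lapply(split(seq_len(nrow(st)), st$region), function(ii) {
      as_leadfield_matrix(lf) %*%
        source_time_course(mesh, st$vertex[ii], st$amplitude[ii],
                           cfg$times, st$peak_time[ii][1],
                           cfg$sigma_ms, cfg$spread)
    })
    noise_scale <- if (cfg$noise) {
      calibrate_noise_scale(signals, Sigma_shape, cfg$times,
                            cfg$snr_target)
    } else 0
    evoked <- vector("list", nrow(layout))
    for (r in layout$region) {
      ii <- which(st$region == r)
      sim <- simulate_evoked(lf, Sigma_shape, mesh,
                             vertices = st$vertex[ii],
                             amplitudes = st$amplitude[ii],
                             times = cfg$times,
                             peak_time = st$peak_time[ii][1],
                             sigma_ms = cfg$sigma_ms, spread = cfg$spread,
                             noise = cfg$noise, noise_scale = noise_scale,
                             seed = child_seed(seed_s, 100 + r))
      evoked[[r]] <- sim$Y
    }
    subjects[[s]] <- list(id = s, leadfield = lf,
                          Sigma = if (cfg$noise) {
                            noise_scale * Sigma_shape
                          } else Sigma_shape,
                          noise_scale = noise_scale, truth = st,
                          evoked = evoked, times = cfg$times,
                          seed = seed_s)
  }
  structure(list(mesh = mesh, sensors = sensors, layout = layout,
                 truth = truth, subjects = subjects, config = cfg,
                 metadata = list(
                   flashes_per_run = cfg$flashes_per_run,
                   runs = cfg$runs,
                   flashes_per_region = cfg$flashes_per_run * cfg$runs,
                   master_seed = master_seed,
                   subject_seeds = vapply(subjects, `[[`, 0L, "seed")),
                 master_seed = master_seed),
            class = "meg_experiment")
}

#' @export
print.meg_experiment <- function(x, ...) {
  cat(sprintf(paste0("<meg_experiment> %d subjects, %d regions, ",
                     "%d sources, %d sensors\n"),
              length(x$subjects), nrow(x$layout),
              nrow(x$mesh$vertices), x$sensors$n))
  cat(sprintf("  %d flashes/run x %d runs = %d flashes per region\n",
              x$metadata$flashes_per_run, x$metadata$runs,
              x$metadata$flashes_per_region))
  invisible(x)
}

# per-subject anatomical/functional jitter of the template ground truth:
# target vertex moved within a geodesic ball, amplitude and latency
# jittered; assumes the caller set the RNG state
jitter_truth <- function(truth, mesh, cfg) {
  st <- truth
  for (i in seq_len(nrow(st))) {
    if (cfg$target_jitter_mm > 0) {
      d <- geodesic_distances(mesh, st$vertex[i])
      cand <- which(d <= cfg$target_jitter_mm &
                      mesh$hemisphere == st$hemi[i])
      st$vertex[i] <- cand[sample.int(length(cand), 1L)]
    }
    st$amplitude[i] <- st$amplitude[i] *
      (1 + (2 * stats::runif(1) - 1) * cfg$amplitude_jitter)
  }
  # one latency per region (both hemisphere sides peak together) plus a
  # common subject offset, clipped inside the 60-100 ms analysis window
  subj_off <- stats::rnorm(1, 0, cfg$peak_time_subject_sd)
  for (r in unique(st$region)) {
    ii <- which(st$region == r)
    t_r <- st$peak_time[ii][1] + subj_off +
      stats::rnorm(1, 0, cfg$peak_time_region_sd)
    st$peak_time[ii] <- min(max(t_r, 62), 98)
  }
  st
}

#' Default experiment generator configuration
#'
#' The values emulate the study conditions at desk scale: template
#' icosphere source space, 64-sensor helmet, amplitude SNR 2 over the
#' 0-300 ms response window, evoked peak at 83 ms, 258 flashes per run and
#' 7 runs per region, and modest inter-subject anatomical/functional
#' jitter.
#'
#' @return Named list of generator parameters.
#' @export
default_experiment_config <- function() {
  list(
    subdivisions = 2,           # 162 sources per hemisphere
    radius = 35,                # mm, per-hemisphere sphere radius
    hemisphere_gap = 72,        # mm between centres; spheres stay disjoint
    n_sensors = 64,
    sensor_radius = 120,        # mm helmet
    sensor_z_min = -60,         # mm, helmet covers top and sides
    times = seq(-50, 450, by = 2),  # ms, evoked analysis window
    peak_time = 83,             # ms, template V1 peak latency
    peak_time_subject_sd = 5,   # ms, per-subject latency offset
    peak_time_region_sd = 5,    # ms, per-region latency jitter
    sigma_ms = 10,              # ms, temporal width of the source pulse
    spread = 0.3,               # neighbour leakage of the source patch
    base_amplitude = 1e-8,      # A*m, ring-1 source amplitude
    ring_amplitude_scale = c(1, 0.8, 0.6),  # outer rings weaker
    amplitude_jitter = 0.3,     # relative per-subject amplitude jitter
    ecc_geodesic_mm = c(10, 20, 30),  # ring -> distance from pole anchor
    snr_target = 2,
    noise = TRUE,
    position_jitter_mm = 3,     # per-subject leadfield vertex jitter
    gain_jitter_fraction = 0.1, # per-subject leadfield gain jitter
    target_jitter_mm = 10,      # per-subject target scatter (~1 cm, the
                                # scale of inter-subject variability of
                                # early visual areas on a template)
    flashes_per_run = 258,
    runs = 7)
}
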