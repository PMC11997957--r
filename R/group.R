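#' Group analysis: averaging, representative selection, nested groups
#'
#' Multi-subject pooling happens in source space: per-subject estimates on
#' the shared template are averaged vertex-wise.  For the sparse MWE
#' estimates the average is taken on absolute values so that opposite
#' dipole moments do not cancel.  Group sizes are nested: each group
#' extends the previous one, starting from the most representative
#' subject (the one whose median peak-target distance is closest to the
#' group median) and continuing in ascending subject id.
#'
#' @name group_analysis
#' @keywords internal
NULL

#' Vertex-wise average of source estimates
#'
#' Arithmetic mean over subjects, vertex by vertex (and time sample by
#' time sample).  With `use_absolute` the mean of magnitudes is taken
#' instead, which prevents opposite dipole moments from cancelling; the
#' result is then flagged as a magnitude (unsigned) estimate.
#'
#' @param estimates List of `source_estimate`s with identical dimensions
#'   and time axes.
#' @param use_absolute Average `|amplitude|` instead of signed amplitude.
#' @return A `source_estimate`.
#' @export
average_estimates <- function(estimates, use_absolute = FALSE) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, logical(1), "source_estimate")))
  dims <- vapply(estimates, function(e) dim(e$X), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("estimates do not share a common vertex/time grid", call. = FALSE)
  }
  times <- estimates[[1L]]$times
  for (e in estimates) {
    if (!identical(e$times, times)) {
      stop("estimates do not share a common time axis", call. = FALSE)
    }
  }
  acc <- matrix(0, dims[1, 1], dims[2, 1])
  for (e in estimates) {
    acc <- acc + (if (use_absolute) abs(e$X) else e$X)
  }
  new_source_estimate(acc / length(estimates), times = times,
                      signed = !use_absolute &&
                        all(vapply(estimates, function(e) isTRUE(e$signed),
                                   logical(1))))
}

#' Select the most representative subject
#'
#' The subject whose median peak-target distance is closest to the median
#' of all subjects' medians; ties are broken toward the lower subject id.
#'
#' @param median_distances Named numeric vector (names = subject ids) or
#'   plain numeric vector (ids = positions) of per-subject median
#'   distances, mm.
#' @return The selected subject id (integer when ids are positional,
#'   otherwise the name).
#' @export
select_representative <- function(median_distances) {
  if (length(median_distances) == 0L) {
    stop("`median_distances` must contain at least one subject",
         call. = FALSE)
  }
  ids <- names(median_distances)
  if (is.null(ids)) ids <- seq_along(median_distances)
  ord <- order(as_numeric_id(ids))
  x <- as.numeric(median_distances)[ord]
  ids <- ids[ord]
  gm <- stats::median(x)
  ids[which.min(abs(x - gm))]  # which.min takes the first (lowest id) tie
}

# subject ids sort numerically when they look numeric, lexically otherwise
as_numeric_id <- function(ids) {
  n <- suppressWarnings(as.numeric(ids))
  if (any(is.na(n))) rank(ids) else n
}

#' Nested subject groups from an ordering
#'
#' Prefix groups of the ordered subject list: the representative subject
#' first, the remaining subjects in ascending id.
#'
#' @param ordering Vector of subject ids with the representative first
#'   (e.g. from [subject_ordering()]).
#' @param sizes Non-decreasing group sizes, each at most
#'   `length(ordering)`.
#' @return Named list of id vectors, one per size (`"n1"`, `"n5"`, ...).
#' @export
build_groups <- function(ordering, sizes = c(1, 5, 10, 15, 20)) {
  stopifnot(length(ordering) >= 1L, !anyDuplicated(ordering))
  if (any(diff(sizes) < 0)) {
    stop("`sizes` must be non-decreasing", call. = FALSE)
  }
  if (max(sizes) > length(ordering)) {
    stop("largest group size exceeds the number of subjects",
         call. = FALSE)
  }
  out <- lapply(sizes, function(k) ordering[seq_len(k)])
  names(out) <- paste0("n", sizes)
  out
}

#' Subject ordering for nested groups
#'
#' The representative subject first, then all remaining subjects in
#' ascending id.
#'
#' @param subject_ids Vector of all subject ids.
#' @param representative The id returned by [select_representative()].
#' @return The ordered id vector.
#' @export
subject_ordering <- function(subject_ids, representative) {
  if (!representative %in% subject_ids) {
    stop("`representative` is not among `subject_ids`", call. = FALSE)
  }
  rest <- subject_ids[subject_ids != representative]
  c(representative, rest[order(as_numeric_id(rest))])
}
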