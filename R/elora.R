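#' eLORETA: weighted minimum-norm inversion with zero localization error
#'
#' eLORETA solves the MEG inverse problem with a diagonal weighting matrix
#' `D` determined by a fixed-point iteration,
#' `d_i = (1/x0) * sqrt( L_i' (L D^-1 L' + lambda2 * Sigma)^-1 L_i )`,
#' after which the inverse operator is
#' `W = D^-1 L' (L D^-1 L' + lambda2 * Sigma)^-1`.
#' The square-root weighting is what gives eLORETA its defining property:
#' for noiseless single-dipole data with `lambda2 = 0`, the absolute
#' estimate attains its maximum exactly at the true source.  The reference
#' amplitude `x0 = 1` A*m sets the unit of `D` to 1/(A*m)^2.
#'
#' Regularization convention: `Sigma` is rescaled to unit mean diagonal and
#' multiplied by `lambda2 * trace(L D^-1 L')/N`, so that
#' `lambda2 = 1/SNR^2` keeps its meaning regardless of the absolute scales
#' of the noise covariance and the leadfield.
#'
#' @name inverse_elora
#' @keywords internal
NULL

#' Regularization parameter from an amplitude SNR
#'
#' `lambda2 = 1 / snr^2`; an SNR of 2 gives `lambda2 = 0.25`.
#'
#' @param snr Positive amplitude signal-to-noise ratio.
#' @return The scalar regularization parameter `lambda2`.
#' @export
regularization_from_snr <- function(snr) {
  if (length(snr) != 1L || is.na(snr) || snr <= 0) {
    stop("`snr` must be a single positive number", call. = FALSE)
  }
  1 / snr^2
}

#' Estimate the amplitude SNR of an evoked response
#'
#' Whitened-RMS estimator: the data are whitened by `Sigma^{-1/2}`, the RMS
#' over sensors is taken at each time sample, and the result is averaged
#' over the analysis window.  Pure noise drawn from `Sigma` therefore
#' yields an SNR close to 1, and the estimator is homogeneous of degree 1
#' in the data.
#'
#' @param Y N x T evoked data matrix (tesla).
#' @param Sigma N x N symmetric positive-definite noise covariance (T^2).
#' @param times Length-T time axis in ms.
#' @param window Two-element window (ms) over which the whitened RMS is
#'   averaged; default 0 to 300 ms, the duration of the visual response.
#' @return Scalar amplitude SNR.
#' @export
estimate_snr <- function(Y, Sigma, times, window = c(0, 300)) {
  stopifnot(is.matrix(Y), nrow(Sigma) == nrow(Y), length(times) == ncol(Y))
  idx <- which(times >= window[1] & times <= window[2])
  if (length(idx) == 0L) {
    stop("`window` does not overlap the time axis", call. = FALSE)
  }
  Wh <- whitener(Sigma)
  Z <- Wh %*% Y[, idx, drop = FALSE]
  mean(sqrt(colMeans(Z^2)))
}

# symmetric inverse square root of an SPD matrix
whitener <- function(Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) <= 0 ||
      min(e$values) < max(e$values) * .Machine$double.eps * 100) {
    stop("noise covariance is singular or not positive definite",
         call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Fixed-point eLORETA weights
#'
#' Iterates the diagonal weight update from a uniform start until the
#' maximum relative change in the weights falls below `tol`.
#'
#' @param L N x P leadfield matrix (a bare matrix or a `leadfield`).
#' @param Sigma N x N noise covariance; ignored when `lambda2 = 0`.
#' @param lambda2 Non-negative regularization parameter.
#' @param x0 Reference source amplitude, A*m.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum number of fixed-point iterations.
#' @return An `elora_weights` object: `d` (P positive weights),
#'   `iterations`, `residual` (last relative change), `converged`,
#'   `residual_history`.
#' @export
elora_weights <- function(L, Sigma = NULL, lambda2 = 0, x0 = 1,
                          tol = 1e-6, max_iter = 100) {
  L <- as_leadfield_matrix(L)
  stopifnot(all(is.finite(L)), lambda2 >= 0)
  n <- nrow(L)
  p <- ncol(L)
  Sn <- NULL
  if (lambda2 > 0) {
    if (is.null(Sigma)) {
      stop("`Sigma` is required when `lambda2` > 0", call. = FALSE)
    }
    Sn <- Sigma / mean(diag(Sigma))
  }
  d <- rep(1, p)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    K <- L %*% (t(L) / d)                 # L D^-1 L'
    if (lambda2 > 0) {
      K <- K + lambda2 * (sum(diag(K)) / n) * Sn
    }
    M <- sym_pinv(K)
    quad <- colSums(L * (M %*% L))        # L_i' M L_i
    d_new <- sqrt(pmax(quad, 0)) / x0
    if (any(d_new <= 0)) {
      stop("eLORETA weight update produced a non-positive weight ",
           "(magnetically silent source?)", call. = FALSE)
    }
    rel <- max(abs(d_new - d) / pmax(d, .Machine$double.xmin))
    hist <- c(hist, rel)
    d <- d_new
    if (rel < tol) {
      return(structure(list(d = d, x0 = x0, iterations = it, residual = rel,
                            converged = TRUE, residual_history = hist),
                       class = "elora_weights"))
    }
  }
  stop(sprintf(
    "eLORETA weights did not converge in %d iterations (last residual %.3g)",
    max_iter, hist[length(hist)]), call. = FALSE)
}

# symmetric (pseudo-)inverse with an eigenvalue cutoff
sym_pinv <- function(K, rcond = 1e-12) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- e$values > max(e$values) * rcond
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

as_leadfield_matrix <- function(L) {
  if (inherits(L, "leadfield")) L$L else L
}

#' Assemble the eLORETA inverse operator
#'
#' `W = D^-1 L' (L D^-1 L' + lambda2 * Sigma)^-1`, using the converged
#' weights and the same covariance-scaling convention as [elora_weights()].
#' A pseudo-inverse is used for the sensor-space kernel so rank-deficient
#' kernels (e.g. `lambda2 = 0` with duplicated sensors) degrade gracefully.
#'
#' @inheritParams elora_weights
#' @param weights An `elora_weights` object from [elora_weights()].
#' @return An `inverse_operator`: `W` (P x N), `lambda2`, `d`.
#' @export
elora_inverse_operator <- function(L, weights, Sigma = NULL, lambda2 = 0) {
  L <- as_leadfield_matrix(L)
  stopifnot(inherits(weights, "elora_weights"), weights$converged)
  d <- weights$d
  n <- nrow(L)
  K <- L %*% (t(L) / d)
  if (lambda2 > 0) {
    if (is.null(Sigma)) {
      stop("`Sigma` is required when `lambda2` > 0", call. = FALSE)
    }
    K <- K + lambda2 * (sum(diag(K)) / n) * (Sigma / mean(diag(Sigma)))
  }
  W <- (t(L) / d) %*% sym_pinv(K)
  structure(list(W = W, lambda2 = lambda2, d = d),
            class = "inverse_operator")
}

#' Apply an inverse operator to sensor data
#'
#' `X = W Y`, one source-amplitude column per time sample.  Estimates are
#' signed; magnitudes are taken only at evaluation time.
#'
#' @param op An `inverse_operator`.
#' @param Y N x T sensor data (or a length-N vector).
#' @param times Optional length-T time axis carried into the estimate.
#' @return A `source_estimate`: `X` (P x T), `times`, `signed = TRUE`.
#' @export
apply_inverse <- function(op, Y, times = NULL) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  if (nrow(Y) != ncol(op$W)) {
    stop("sensor dimension of `Y` does not match the inverse operator",
         call. = FALSE)
  }
  new_source_estimate(op$W %*% Y, times = times, signed = TRUE)
}

#' Construct a source estimate
#'
#' @param X P x T amplitude matrix (or a length-P vector).
#' @param times Optional length-T time axis, ms.
#' @param signed `TRUE` for signed amplitudes, `FALSE` for magnitudes.
#' @return A `source_estimate`.
#' @export
new_source_estimate <- function(X, times = NULL, signed = TRUE) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  structure(list(X = X, times = times, signed = signed),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d sources x %d samples (%s)\n",
              nrow(x$X), ncol(x$X),
              if (isTRUE(x$signed)) "signed" else "magnitude"))
  invisible(x)
}
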