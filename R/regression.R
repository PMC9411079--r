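# Log-linearized weighted Gaussian regression of peak profiles.
#
# A Gaussian profile I(x) = I0 * exp(-(x - x0)^2 / (2 sigma^2)) becomes,
# after log transform, the second-order polynomial
#   ln I(x) = beta0 + beta1 * x + beta2 * x^2
# with x0 = -beta1 / (2 beta2), sigma = sqrt(-1 / (2 beta2)) and
# ln I0 = beta0 - beta1^2 / (4 beta2). Fitting the parabola by weighted
# linear least squares replaces iterative non-linear optimization and
# yields the coefficient variance-covariance matrix needed for the
# Data Quality Score.

#' Regression weights for a peak profile
#'
#' The log transform amplifies noise in the profile tails, so points are
#' weighted by their share of the profile's total intensity raised to a
#' power: `w_i = (I_i / sum(I))^p`. The default power 2 suits Orbitrap
#' profiles; the weights are computed over the single profile only and are
#' invariant under intensity rescaling.
#'
#' @param intensity Numeric vector of positive intensities (one profile).
#' @param weight_power Non-negative exponent `p` (default 2).
#' @return Numeric vector of weights, same length as `intensity`.
#' @examples
#' compute_weights(c(1, 1, 2))  # 0.0625 0.0625 0.25
#' @export
compute_weights <- function(intensity, weight_power = 2) {
  if (!length(intensity)) stop("empty intensity vector")
  if (any(intensity <= 0)) stop("intensities must be positive")
  if (weight_power < 0) stop("weight_power must be >= 0")
  (intensity / sum(intensity))^weight_power
}

# Single-profile weighted parabola fit in conditioned coordinates.
# x is centered at the (leftmost) maximum-intensity point and scaled by the
# profile half-width before solving; beta and cov_beta are transformed back
# to centered (unscaled) coordinates. Returns a RegressionResult.
.fit_parabola <- function(mz, intensity, weight_power = 2) {
  n <- length(mz)
  y <- log(intensity)
  if (any(!is.finite(y)))
    return(.reject("nonfinite"))
  shift <- mz[which.max(intensity)]
  scale <- max(abs(mz - shift))
  if (scale == 0) scale <- 1
  u <- (mz - shift) / scale
  X <- cbind(1, u, u * u)
  w <- compute_weights(intensity, weight_power)
  A <- crossprod(X, w * X)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(.reject("nonfinite"))
  beta_u <- drop(Ainv %*% crossprod(X, w * y))
  res <- y - drop(X %*% beta_u)
  dof <- n - 3L
  mse <- sum(w * res^2) / dof
  cov_u <- mse * Ainv
  .finish_fit(beta_u, cov_u, mse, dof, y, shift, scale, n)
}

# Shared tail of the per-profile and blocked solvers: rescale coefficients
# and covariance from u = (x - shift)/scale back to centered x, and attach
# the fit diagnostics.
.finish_fit <- function(beta_u, cov_u, mse, dof, y, shift, scale, n) {
  J <- diag(c(1, 1 / scale, 1 / scale^2))
  beta <- drop(J %*% beta_u)
  cov_beta <- J %*% cov_u %*% J
  structure(
    list(beta = beta,
         cov_beta = cov_beta,
         mse = mse,
         dof = dof,
         nrmse = sqrt(mse) / mean(y),
         x_shift = shift,
         n_points = n),
    class = "RegressionResult")
}

.reject <- function(reason, profile = NULL) {
  structure(
    list(reason = reason,
         scan_id = profile$scan_id, scan_index = profile$scan_index,
         start = profile$start, end = profile$end,
         n_points = length(profile$mz)),
    class = "RejectRecord")
}

#' Fit isolated peak profiles by weighted log-domain regression
#'
#' Fits each profile's log intensities with a second-order polynomial by
#' weighted linear least squares, returning the coefficient estimates with
#' their variance-covariance matrix (`MSE * (X'WX)^-1`), the weighted mean
#' square error on `n - 3` degrees of freedom, and the normalized RMSE
#' (square root of the MSE divided by the profile's mean log intensity).
#' Profiles with fewer than `min_points` points are rejected without
#' fitting, since a residual degree of freedom requires at least 4 points.
#'
#' @param profiles List of `PeakProfile` objects (see [isolate_profiles()]).
#' @param weight_power Weighting exponent, see [compute_weights()].
#' @param min_points Minimum number of points for a fit (default 4).
#' @param method `"per_profile"` solves each profile's 3x3 normal equations
#'   independently; `"blocked"` assembles all profiles into one
#'   block-diagonal sparse Vandermonde system and solves it in a single
#'   sparse operation. Both are numerically equivalent; the blocked path
#'   mirrors how large spectra are processed in one pass.
#' @return A list, parallel to `profiles`, of `RegressionResult` or
#'   `RejectRecord` objects (`reason` one of `"min_points"`,
#'   `"nonfinite"`).
#' @export
fit_profiles <- function(profiles, weight_power = 2, min_points = 4,
                         method = c("per_profile", "blocked")) {
  method <- match.arg(method)
  if (min_points < 4)
    warning("min_points < 4 leaves no residual degree of freedom; ",
            "results will be rejected at the fitting stage")
  if (method == "per_profile") {
    lapply(profiles, function(p) {
      if (length(p$mz) < max(min_points, 4L)) return(.reject("min_points", p))
      r <- .fit_parabola(p$mz, p$intensity, weight_power)
      if (inherits(r, "RejectRecord")) .reject(r$reason, p) else r
    })
  } else {
    .fit_profiles_blocked(profiles, weight_power, min_points)
  }
}

# Blocked sparse solve: one block-diagonal Vandermonde system over all
# fittable profiles (3 columns per profile), solved through Matrix's sparse
# Cholesky. Each block uses the same centering and scaling as the
# per-profile path, so the two agree to solver precision.
.fit_profiles_blocked <- function(profiles, weight_power, min_points) {
  out <- vector("list", length(profiles))
  fit_idx <- integer(0)
  for (i in seq_along(profiles)) {
    if (length(profiles[[i]]$mz) < max(min_points, 4L))
      out[[i]] <- .reject("min_points", profiles[[i]])
    else fit_idx <- c(fit_idx, i)
  }
  m <- length(fit_idx)
  if (!m) return(out)
  ns <- vapply(profiles[fit_idx], function(p) length(p$mz), integer(1))
  shifts <- vapply(profiles[fit_idx],
                   function(p) p$mz[which.max(p$intensity)], numeric(1))
  scales <- vapply(seq_len(m), function(k) {
    s <- max(abs(profiles[[fit_idx[k]]]$mz - shifts[k]))
    if (s == 0) 1 else s
  }, numeric(1))
  row_off <- cumsum(c(0L, ns[-m]))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  yall <- numeric(sum(ns)); wall <- numeric(sum(ns))
  for (k in seq_len(m)) {
    p <- profiles[[fit_idx[k]]]
    u <- (p$mz - shifts[k]) / scales[k]
    idx <- row_off[k] + seq_len(ns[k])
    rows <- c(rows, rep(idx, 3L))
    cols <- c(cols, rep(3L * (k - 1L) + 1:3, each = ns[k]))
    vals <- c(vals, rep(1, ns[k]), u, u * u)
    yall[idx] <- log(p$intensity)
    wall[idx] <- compute_weights(p$intensity, weight_power)
  }
  if (any(!is.finite(yall))) {
    # fall back to per-profile handling so the offending profile alone
    # is rejected
    return(fit_profiles(profiles, weight_power, min_points,
                        method = "per_profile"))
  }
  X <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(sum(ns), 3L * m))
  W <- Matrix::Diagonal(x = wall)
  A <- Matrix::crossprod(X, W %*% X)
  Ainv <- Matrix::solve(A, Matrix::Diagonal(3L * m))
  beta_all <- as.numeric(Ainv %*% Matrix::crossprod(X, as.numeric(W %*% yall)))
  resid <- yall - as.numeric(X %*% beta_all)
  for (k in seq_len(m)) {
    jdx <- 3L * (k - 1L) + 1:3
    idx <- row_off[k] + seq_len(ns[k])
    dof <- ns[k] - 3L
    mse <- sum(wall[idx] * resid[idx]^2) / dof
    cov_u <- mse * as.matrix(Ainv[jdx, jdx])
    out[[fit_idx[k]]] <- .finish_fit(beta_all[jdx], cov_u, mse, dof,
                                     yall[idx], shifts[k], scales[k], ns[k])
  }
  out
}

#' Recover Gaussian peak parameters from a parabola fit
#'
#' Back-transforms the fitted polynomial coefficients into the Gaussian
#' peak parameters: centroid position, standard deviation (peak width),
#' height and area, together with their propagated standard errors. A fit
#' with `beta2 >= 0` does not describe a downward-opening parabola --- the
#' Gaussian width would be complex --- and is rejected.
#'
#' @param result A `RegressionResult` from [fit_profiles()].
#' @return A `GaussianPeak` (fields `x0`, `sigma`, `height`, `area`,
#'   `d_height`, `d_sigma`, `d_area`, plus the fit diagnostics `mse`,
#'   `nrmse`, `dof`, `n_points`) or a `RejectRecord` with reason
#'   `"beta2_nonneg"` or `"nonfinite"`.
#'
#' @details Uncertainties are propagated from the coefficient covariance
#'   `C`: with `t = -beta1/(2 beta2)` the apex position in centered
#'   coordinates, `d_height = height * sqrt(g' C g)` where
#'   `g = (1, t, t^2)` is the gradient of `ln I0`;
#'   `d_sigma = sqrt(C[3,3]) / (4 sigma beta2^2)`; and the area error
#'   combines the two without a cross term,
#'   `d_area = sqrt(2 pi) * sqrt(sigma^2 d_height^2 + height^2 d_sigma^2)`.
#' @export
backtransform <- function(result) {
  if (inherits(result, "RejectRecord")) return(result)
  b <- result$beta
  if (any(!is.finite(b))) return(.reject("nonfinite"))
  if (b[3] >= 0) {
    rej <- .reject("beta2_nonneg")
    rej$scan_id <- result$scan_id
    return(rej)
  }
  t0 <- -b[2] / (2 * b[3])            # apex in centered coordinates
  x0 <- t0 + result$x_shift
  sigma <- sqrt(-1 / (2 * b[3]))
  height <- exp(b[1] - b[2]^2 / (4 * b[3]))
  area <- height * sigma * sqrt(2 * pi)
  C <- result$cov_beta
  g <- c(1, t0, t0 * t0)
  d_height <- height * sqrt(max(0, drop(crossprod(g, C %*% g))))
  d_sigma <- sqrt(max(0, C[3, 3])) / (4 * sigma * b[3]^2)
  d_area <- sqrt(2 * pi) * sqrt(sigma^2 * d_height^2 + height^2 * d_sigma^2)
  vals <- c(x0, sigma, height, area, d_height, d_sigma, d_area)
  if (any(!is.finite(vals))) return(.reject("nonfinite"))
  structure(
    list(x0 = x0, sigma = sigma, height = height, area = area,
         d_height = d_height, d_sigma = d_sigma, d_area = d_area,
         mse = result$mse, nrmse = result$nrmse, dof = result$dof,
         n_points = result$n_points),
    class = "GaussianPeak")
}
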