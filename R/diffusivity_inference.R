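#' One-dimensional trajectory of a permeant
#'
#' A uniformly sampled time series of the permeant's position along the
#' membrane normal, together with the bias potential under which it was
#' generated (the total potential governing the dynamics) and the reflecting
#' boundaries of the simulation cell.
#'
#' @param z positions in Angstrom.
#' @param dt time step in ns (> 0).
#' @param bias total potential actually applied during generation, as a PMF
#'   \code{\link{profile1d}}; NULL means flat.
#' @param boundaries reflecting limits \code{c(lo, hi)} in Angstrom.
#' @return object of class \code{"trajectory1d"}.
#' @export
trajectory1d <- function(z, dt, bias = NULL, boundaries = range(z)) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  z <- as.numeric(z)
  if (any(z < boundaries[1] - 1e-9 | z > boundaries[2] + 1e-9))
    stop("trajectory leaves the stated boundaries")
  if (!is.null(bias)) stopifnot(inherits(bias, "profile1d"))
  structure(list(z = z, dt = dt, times = (seq_along(z) - 1) * dt,
                 bias = bias, boundaries = boundaries),
            class = "trajectory1d")
}

#' @export
print.trajectory1d <- function(x, ...) {
  cat(sprintf("<trajectory1d> %d frames, dt = %g ns (%.4g ns total), z in [%g, %g] A\n",
              length(x$z), x$dt, x$dt * (length(x$z) - 1),
              min(x$z), max(x$z)))
  invisible(x)
}

#' Inverse-PMF biasing potential
#'
#' Applying the negated PMF as an external bias flattens the free-energy
#' landscape, letting the permeant diffuse freely along z so its
#' position-dependent diffusivity can be sampled everywhere.
#'
#' @param pmf a PMF \code{\link{profile1d}}.
#' @return a \code{\link{profile1d}} with values \eqn{-w(z)} on the same grid.
#' @export
inverse_bias <- function(pmf) {
  stopifnot(inherits(pmf, "profile1d"), pmf$kind == "pmf")
  profile1d(pmf$z, -pmf$values, kind = "pmf", units = pmf$units,
            label = paste("inverse of", pmf$label))
}

#' MAP estimate of a position-dependent diffusivity profile
#'
#' Fits a piecewise-constant diffusivity \eqn{D(z)} (one value per bin) to
#' lag-time displacements of a 1D trajectory under a known total potential
#' \eqn{U(z)}, using the short-lag Gaussian (Euler) propagator of the
#' Smoluchowski equation: a displacement starting at \eqn{z} is modelled as
#' \deqn{\Delta z \sim N\big((-\beta D\,U'(z) + D')\,\tau,\; 2 D \tau\big)}
#' with \eqn{\tau} the lag time and \eqn{D, D'} evaluated at the starting
#' bin.  D is parameterized as \eqn{e^\theta} to enforce positivity, and a
#' Gaussian smoothness prior on adjacent \eqn{\Delta\theta} regularizes the
#' profile.  The posterior is maximized with L-BFGS-B using an analytic
#' gradient; per-bin uncertainties come from the curvature (observed
#' information) at the optimum.
#'
#' Displacements are taken at non-overlapping lag intervals.  The Gaussian
#' propagator ignores reflections, so samples starting within
#' \code{edge_buffer} of a reflecting boundary are dropped; by default the
#' buffer is four step standard deviations, which makes an undetected
#' reflection among the retained samples vanishingly rare.  Endpoints are
#' never used for trimming, so no censoring bias is introduced.
#'
#' @param traj a \code{\link{trajectory1d}}.
#' @param potential total potential governing the dynamics (a PMF
#'   \code{\link{profile1d}}); defaults to the trajectory's bias, or flat.
#' @param bin_width bin width in Angstrom (default 1).
#' @param lag lag in steps (default 1); the lag time is \code{lag * dt}.
#' @param smoothness prior standard deviation of adjacent log-D increments
#'   (default 0.5); larger is rougher.
#' @param tc a \code{\link{thermo}} object (temperature only).
#' @param min_counts minimum displacement samples per interior bin
#'   (default 10).
#' @param edge_buffer exclusion zone next to each boundary (Angstrom);
#'   default NULL chooses \code{max(bin_width, 4 * sqrt(2 D tau))} from a
#'   global moment estimate of D.
#' @return object of class \code{"diffusivity_estimate"}: \code{profile}
#'   (a diffusivity \code{\link{profile1d}} on bin centers),
#'   \code{uncertainty} (per-bin ~95% half-width, same units),
#'   \code{grid} (bin edges), \code{diagnostics} (counts, optimizer info,
#'   mean displacement per bin width).
#' @export
infer_diffusivity <- function(traj, potential = traj$bias, bin_width = 1,
                              lag = 1L, smoothness = 0.5, tc = thermo(),
                              min_counts = 10L, edge_buffer = NULL) {
  stopifnot(inherits(traj, "trajectory1d"))
  tau <- lag * traj$dt
  idx <- seq.int(1L, length(traj$z) - lag, by = lag)
  z0 <- traj$z[idx]
  dz <- traj$z[idx + lag] - z0
  lo <- traj$boundaries[1]; hi <- traj$boundaries[2]
  if (is.null(edge_buffer)) {
    D_rough <- mean(dz^2) / (2 * tau)
    edge_buffer <- max(bin_width, 4 * sqrt(2 * D_rough * tau))
  }
  keep <- z0 > lo + edge_buffer & z0 < hi - edge_buffer
  z0 <- z0[keep]; dz <- dz[keep]
  if (!length(z0)) stop("no usable displacement samples after edge trimming")

  edges <- seq(lo + edge_buffer, hi - edge_buffer, by = bin_width)
  if (edges[length(edges)] < hi - edge_buffer - 1e-9)
    edges <- c(edges, hi - edge_buffer)
  nb <- length(edges) - 1L
  if (nb < 1L) stop("bin_width too large for the trimmed domain")
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- findInterval(z0, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > nb] <- nb
  counts <- tabulate(bin, nb)
  if (any(counts < min_counts))
    stop("insufficient sampling in bin(s): ",
         paste(which(counts < min_counts), collapse = ", "),
         " (fewer than ", min_counts, " displacement samples)")

  # force -U'(z) at sample starts
  if (is.null(potential)) {
    force <- rep(0, length(z0))
  } else {
    gr <- pracma::gradient(potential$values, potential$z)
    force <- -stats::approx(potential$z, gr, xout = z0, rule = 2)$y
  }
  beta <- tc$beta
  h <- diff(centers)
  mean_abs_dz <- mean(abs(dz))
  warn_lag <- mean_abs_dz > bin_width  # steps jump across bins; D(z) blurred

  # per-bin sufficient statistics for the gradient accumulation
  sum_by_bin <- function(x) {
    out <- numeric(nb); t <- tapply(x, bin, sum)
    out[as.integer(names(t))] <- as.numeric(t); out
  }

  # gradient of piecewise-constant D over bin centers (central differences)
  dgrad <- function(D) {
    g <- numeric(nb)
    if (nb >= 3L) g[2:(nb - 1)] <- (D[3:nb] - D[1:(nb - 2)]) / (centers[3:nb] - centers[1:(nb - 2)])
    if (nb >= 2L) {
      g[1] <- (D[2] - D[1]) / h[1]
      g[nb] <- (D[nb] - D[nb - 1]) / h[nb - 1]
    }
    g
  }

  neglogpost <- function(theta) {
    D <- exp(theta)
    g <- dgrad(D)
    Di <- D[bin]; mu <- (-beta * Di * force + g[bin]) * tau
    v <- 2 * Di * tau
    r <- dz - mu
    nll <- sum(0.5 * log(2 * pi * v) + r^2 / (2 * v))
    if (nb >= 2L)
      nll <- nll + sum(diff(theta)^2) / (2 * smoothness^2)
    nll
  }

  grad_neglogpost <- function(theta) {
    D <- exp(theta)
    g <- dgrad(D)
    Di <- D[bin]; mu <- (-beta * Di * force + g[bin]) * tau
    v <- 2 * Di * tau
    r <- dz - mu
    dl_dmu <- -r / v
    dl_dv <- 0.5 / v - r^2 / (2 * v^2)
    # w.r.t. the bin's own D through mu's drift term and the variance
    gD <- sum_by_bin(dl_dmu * (-beta * force) * tau + dl_dv * 2 * tau)
    # w.r.t. neighbouring D through the central-difference D'
    s_mu <- sum_by_bin(dl_dmu) * tau   # per-bin sum of dl/dmu, times tau
    for (i in seq_len(nb)) {
      si <- s_mu[i]
      if (si == 0) next
      if (i == 1L && nb >= 2L) {
        gD[2] <- gD[2] + si / h[1]; gD[1] <- gD[1] - si / h[1]
      } else if (i == nb && nb >= 2L) {
        gD[nb] <- gD[nb] + si / h[nb - 1]; gD[nb - 1] <- gD[nb - 1] - si / h[nb - 1]
      } else if (nb >= 3L) {
        span <- centers[i + 1] - centers[i - 1]
        gD[i + 1] <- gD[i + 1] + si / span
        gD[i - 1] <- gD[i - 1] - si / span
      }
    }
    gth <- gD * D
    if (nb >= 2L) {
      d <- diff(theta) / smoothness^2
      gth <- gth + c(-d, 0) + c(0, d)
    }
    gth
  }

  # moment initialization: per-bin second moment of displacements
  m2 <- sum_by_bin(dz^2) / pmax(counts, 1L)
  theta0 <- log(pmax(m2 / (2 * tau), 1e-6))
  fit <- stats::optim(theta0, neglogpost, grad_neglogpost, method = "L-BFGS-B",
                      control = list(maxit = 500L, factr = 1e7))
  theta <- fit$par
  # observed information from a finite-difference Hessian diagonal
  eps <- 1e-4
  hdiag <- vapply(seq_len(nb), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (grad_neglogpost(tp)[i] - grad_neglogpost(tm)[i]) / (2 * eps)
  }, 0)
  sd_theta <- ifelse(hdiag > 0, 1 / sqrt(hdiag), NA_real_)
  D <- exp(theta)
  # with fewer than 3 bins a full profile1d cannot be formed; return the
  # same fields as a plain list
  prof <- if (nb >= 3L)
    profile1d(centers, D, kind = "diffusivity", label = "MAP diffusivity")
  else list(z = centers, values = D, kind = "diffusivity", units = "A^2/ns",
            label = "MAP diffusivity")
  structure(list(
    profile = prof,
    uncertainty = D * (exp(1.96 * sd_theta) - 1),
    grid = edges,
    diagnostics = list(counts = counts, n_samples = length(dz),
                       lag_time = tau, mean_abs_step = mean_abs_dz,
                       lag_warning = warn_lag,
                       convergence = fit$convergence,
                       neg_log_posterior = fit$value)),
    class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("<diffusivity_estimate> %d bins, D in [%.3g, %.3g] A^2/ns (%d samples, lag %g ns)\n",
              length(x$profile$z), min(x$profile$values), max(x$profile$values),
              x$diagnostics$n_samples, x$diagnostics$lag_time))
  invisible(x)
}

#' Mean-squared-displacement diffusivity oracle
#'
#' Independent, assumption-light estimate of a (position-independent)
#' diffusion coefficient: fits MSD(\eqn{\tau}) = 2 D \eqn{\tau} over a window
#' of lag times by least squares through the origin.  Valid for effectively
#' unbiased motion away from boundaries.
#'
#' @param traj a \code{\link{trajectory1d}}.
#' @param window maximum lag in steps (default 10).
#' @return list with \code{D} (A^2/ns), \code{msd} (data.frame of lag time
#'   vs MSD) and \code{degenerate} (TRUE for a frozen trajectory).
#' @export
msd_oracle <- function(traj, window = 10L) {
  stopifnot(inherits(traj, "trajectory1d"))
  n <- length(traj$z)
  if (window >= n) stop("window exceeds trajectory length")
  lags <- seq_len(window)
  msd <- vapply(lags, function(k)
    mean((traj$z[(k + 1):n] - traj$z[1:(n - k)])^2), 0)
  tau <- lags * traj$dt
  if (all(msd == 0)) {
    warning("zero-displacement trajectory; D = 0 is degenerate")
    return(list(D = 0, msd = data.frame(tau = tau, msd = msd),
                degenerate = TRUE))
  }
  D <- sum(tau * msd) / (2 * sum(tau^2))   # LS fit of msd = 2 D tau
  list(D = D, msd = data.frame(tau = tau, msd = msd), degenerate = FALSE)
}
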