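#' One-dimensional profile along the membrane normal
#'
#' The common currency of the pipeline: a scalar quantity sampled on a
#' strictly increasing grid of positions \code{z} (in Angstrom) along the
#' membrane normal.  Two kinds are supported: a potential of mean force
#' (\code{"pmf"}, kcal/mol) and a position-dependent diffusivity
#' (\code{"diffusivity"}, Angstrom^2/ns, strictly positive).
#'
#' @param z numeric vector of positions (Angstrom), strictly increasing,
#'   length >= 3.
#' @param values numeric vector of samples, same length as \code{z}, finite.
#' @param kind \code{"pmf"} or \code{"diffusivity"}.
#' @param units unit string; defaults to \code{"kcal/mol"} for PMFs and
#'   \code{"A^2/ns"} for diffusivities.
#' @param label free-text label (e.g. a microstate name).
#' @return an object of class \code{"profile1d"}.
#' @export
profile1d <- function(z, values, kind = c("pmf", "diffusivity"),
                      units = NULL, label = "") {
  kind <- match.arg(kind)
  z <- as.numeric(z)
  values <- as.numeric(values)
  if (length(z) != length(values))
    stop("z and values must have the same length")
  if (length(z) < 3L)
    stop("a profile needs at least 3 grid points")
  if (!all(is.finite(z)) || !all(is.finite(values)))
    stop("z and values must be finite")
  dz <- diff(z)
  if (any(dz <= 0)) {
    i <- which(dz <= 0)[1L] + 1L
    stop(sprintf("grid not strictly increasing at row %d (z = %g after z = %g)",
                 i, z[i], z[i - 1L]))
  }
  if (kind == "diffusivity" && any(values <= 0))
    stop("diffusivity profiles must be positive everywhere")
  if (is.null(units))
    units <- if (kind == "pmf") "kcal/mol" else "A^2/ns"
  structure(list(z = z, values = values, kind = kind,
                 units = units, label = label),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> kind=%s  %d points, z in [%g, %g] A, %s%s\n",
              x$kind, length(x$z), min(x$z), max(x$z), x$units,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Thermodynamic conditions
#'
#' Temperature and pH bundle used throughout.  The Boltzmann constant is
#' fixed at 0.0019872041 kcal/(mol K); the default temperature of 310 K is
#' physiological.
#'
#' @param temperature temperature in K (> 0).
#' @param pH solution pH.
#' @return object of class \code{"thermo_conditions"} with fields
#'   \code{temperature}, \code{pH}, \code{kB}, \code{beta} (1/kcal mol^-1).
#' @export
thermo <- function(temperature = 310, pH = 7) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  kB <- 0.0019872041
  structure(list(temperature = temperature, pH = pH, kB = kB,
                 beta = 1 / (kB * temperature)),
            class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf("<thermo> T = %g K, pH = %g, beta = %.6g mol/kcal\n",
              x$temperature, x$pH, x$beta))
  invisible(x)
}

#' Read a profile from two-column text
#'
#' Files contain two whitespace-delimited columns (z, value).  Lines starting
#' with \code{#} are comments; the optional headers \code{# units: <u>} and
#' \code{# kind: <k>} are honoured (an explicit \code{kind} argument wins
#' over the header).
#'
#' @param path file path.
#' @param kind profile kind; if missing, taken from the \code{# kind:} header
#'   (default \code{"pmf"}).
#' @param label optional label; defaults to the file name.
#' @return a validated \code{\link{profile1d}}.
#' @export
read_profile <- function(path, kind = NULL, label = basename(path)) {
  lines <- readLines(path)
  hdr_units <- sub("^#\\s*units:\\s*", "", grep("^#\\s*units:", lines, value = TRUE))
  hdr_kind  <- sub("^#\\s*kind:\\s*",  "", grep("^#\\s*kind:",  lines, value = TRUE))
  if (is.null(kind))
    kind <- if (length(hdr_kind)) trimws(hdr_kind[1L]) else "pmf"
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(dat), "\\s+")
  if (any(lengths(fields) < 2L))
    stop("malformed input: each data row needs two columns")
  z <- as.numeric(vapply(fields, `[[`, "", 1L))
  v <- as.numeric(vapply(fields, `[[`, "", 2L))
  units <- if (length(hdr_units)) trimws(hdr_units[1L]) else NULL
  profile1d(z, v, kind = kind, units = units, label = label)
}

#' Write a profile to two-column text
#'
#' Emits \code{# kind:} and \code{# units:} headers followed by the data at
#' full double precision, so a write/read round trip is lossless.
#'
#' @param p a \code{\link{profile1d}}.
#' @param path output file path.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "profile1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", p$kind),
               sprintf("# units: %s", p$units)), con)
  writeLines(sprintf("%.17g %.17g", p$z, p$values), con)
  invisible(path)
}

#' Resample a profile onto a new grid
#'
#' Linear interpolation; extrapolation beyond the original grid is refused.
#'
#' @param p a \code{\link{profile1d}}.
#' @param grid target z values (strictly increasing, within the original
#'   range up to a tiny numerical tolerance).
#' @return a \code{\link{profile1d}} on \code{grid}.
#' @export
resample_profile <- function(p, grid) {
  stopifnot(inherits(p, "profile1d"))
  grid <- as.numeric(grid)
  tol <- 1e-9 * max(1, diff(range(p$z)))
  if (min(grid) < min(p$z) - tol || max(grid) > max(p$z) + tol)
    stop(sprintf("resampling grid [%g, %g] extends beyond profile range [%g, %g]",
                 min(grid), max(grid), min(p$z), max(p$z)))
  grid <- pmin(pmax(grid, min(p$z)), max(p$z))
  v <- stats::approx(p$z, p$values, xout = grid)$y
  profile1d(grid, v, kind = p$kind, units = p$units, label = p$label)
}

#' Symmetrize a profile about the bilayer midplane
#'
#' Bilayers built with identical monolayers have mirror-symmetric profiles in
#' the infinite-sampling limit; finite sampling breaks the symmetry, and the
#' residual asymmetry is a convergence diagnostic.  The profile is reflected
#' about z = 0 (after optional recentring by the grid midpoint) and averaged
#' with its mirror image on the common reflected grid.  For PMFs the
#' symmetrized profile is re-anchored so the mean over the outermost
#' \code{bulk_frac} of each tail is zero; for diffusivities the mirror
#' average is arithmetic by default (harmonic available).
#'
#' @param p a \code{\link{profile1d}} whose grid spans both signs of z
#'   (after recentring).
#' @param recenter subtract the grid midpoint before reflecting (default
#'   TRUE); profiles already centred are unaffected up to numerics.
#' @param bulk_frac fraction of each tail used as the bulk reference for
#'   PMF anchoring (default 0.1).
#' @param mean_type \code{"arithmetic"} (default) or \code{"harmonic"}
#'   mirror average, relevant for diffusivity profiles.
#' @return list with components \code{sym} (the symmetrized profile) and
#'   \code{deviation} (a profile of \eqn{|p(z) - sym(z)|}, the per-point
#'   asymmetry).
#' @export
symmetrize <- function(p, recenter = TRUE, bulk_frac = 0.1,
                       mean_type = c("arithmetic", "harmonic")) {
  stopifnot(inherits(p, "profile1d"))
  mean_type <- match.arg(mean_type)
  z <- p$z
  if (recenter) {
    mid <- (min(z) + max(z)) / 2
    z <- z - mid
  }
  if (min(z) >= 0 || max(z) <= 0)
    stop("grid covers only one sign of z; cannot reflect about the midplane")
  L <- min(max(z), -min(z))
  keep <- z[z >= -L & z <= L]
  g <- sort(unique(round(c(keep, -keep), 10)))
  vp <- stats::approx(z, p$values, xout = g)$y
  vm <- stats::approx(z, p$values, xout = -g)$y
  vs <- if (mean_type == "arithmetic") (vp + vm) / 2 else 2 / (1 / vp + 1 / vm)
  if (p$kind == "pmf")
    vs <- vs - .bulk_reference(g, vs, bulk_frac)
  sym <- profile1d(g, vs, kind = p$kind, units = p$units, label = p$label)
  # deviation is measured against the un-anchored mirror average so it
  # reflects asymmetry only, not the anchoring shift
  vs_raw <- if (mean_type == "arithmetic") (vp + vm) / 2 else 2 / (1 / vp + 1 / vm)
  dev <- profile1d(g, abs(vp - vs_raw), kind = p$kind, units = p$units,
                   label = paste(p$label, "asymmetry"))
  list(sym = sym, deviation = dev)
}

# mean over the outermost `frac` of each tail; used as the bulk-water zero
.bulk_reference <- function(z, v, frac = 0.1) {
  n <- length(z)
  k <- max(1L, ceiling(frac * n / 2))
  mean(c(v[seq_len(k)], v[seq.int(n - k + 1L, n)]))
}

#' Shift a PMF by a constant free energy
#'
#' Used to place tautomer PMFs on a common free-energy scale: a state whose
#' bulk population is a factor \eqn{r} of the anchor state's sits
#' \eqn{-k_B T \ln r} above it.
#'
#' @param p a PMF \code{\link{profile1d}}.
#' @param dG shift in kcal/mol (added uniformly).
#' @return shifted profile on the same grid.
#' @export
shift_profile <- function(p, dG) {
  stopifnot(inherits(p, "profile1d"))
  if (p$kind != "pmf") stop("only PMF profiles can be shifted")
  profile1d(p$z, p$values + dG, kind = "pmf", units = p$units, label = p$label)
}

#' Free-energy shift from a tautomer population ratio
#'
#' Returns \eqn{\Delta G = -k_B T \ln(r)} for a bulk population ratio
#' \eqn{r = f_{\mathrm{state}}/f_{\mathrm{anchor}}}.  For tetracycline at
#' 310 K, \eqn{r = 10^{-2.83}} gives about +4.01 kcal/mol.
#'
#' @param ratio positive population ratio.
#' @param tc a \code{\link{thermo}} object.
#' @return shift in kcal/mol.
#' @export
tautomer_shift_energy <- function(ratio, tc = thermo()) {
  if (!is.finite(ratio) || ratio <= 0)
    stop("ratio must be a positive number")
  -tc$kB * tc$temperature * log(ratio)
}

#' Landmark features of a symmetrized permeation PMF
#'
#' Reports the central barrier (maximum over \code{|z| <= barrier_window}
#' relative to the bulk reference), and interfacial wells (local minima lying
#' below the bulk reference) with their positions and depths.
#'
#' @param p a symmetrized PMF \code{\link{profile1d}}.
#' @param barrier_window half-width (Angstrom) of the central window searched
#'   for the barrier; default 5.
#' @param bulk_frac tail fraction defining the bulk reference; default 0.1.
#' @return list with \code{barrier}, \code{barrier_position}, \code{bulk}
#'   (the reference value), and \code{wells}, a data.frame with columns
#'   \code{position} and \code{depth} (negative, relative to bulk).
#' @export
profile_features <- function(p, barrier_window = 5, bulk_frac = 0.1) {
  stopifnot(inherits(p, "profile1d"))
  if (p$kind != "pmf") stop("profile features are defined for PMFs")
  z <- p$z; v <- p$values
  bulk <- .bulk_reference(z, v, bulk_frac)
  cen <- abs(z) <= barrier_window
  if (!any(cen)) cen <- which.min(abs(z))
  barrier <- max(v[cen]) - bulk
  bpos <- z[cen][which.max(v[cen])]
  n <- length(v)
  ismin <- c(FALSE, v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n], FALSE)
  ismin <- ismin & (v < bulk)
  wells <- data.frame(position = z[ismin], depth = v[ismin] - bulk)
  list(barrier = barrier, barrier_position = bpos, bulk = bulk, wells = wells)
}

#' Ordered series of profile snapshots
#'
#' Holds PMF (or diffusivity) snapshots at increasing cumulative simulation
#' times, resampled onto a common grid, for convergence diagnostics.
#'
#' @param profiles list of \code{\link{profile1d}} of the same kind.
#' @param times numeric vector of cumulative time labels, same length.
#' @return object of class \code{"profile_series"}.
#' @export
profile_series <- function(profiles, times) {
  if (length(profiles) < 2L) stop("a series needs at least 2 snapshots")
  if (length(times) != length(profiles))
    stop("one time label per snapshot required")
  kinds <- vapply(profiles, `[[`, "", "kind")
  if (length(unique(kinds)) != 1L)
    stop("all snapshots must share the same kind")
  lo <- max(vapply(profiles, function(p) min(p$z), 0))
  hi <- min(vapply(profiles, function(p) max(p$z), 0))
  if (lo >= hi) stop("snapshot grids do not overlap; cannot resample")
  g <- profiles[[1L]]$z
  g <- g[g >= lo & g <= hi]
  if (length(g) < 3L) stop("common grid after resampling has fewer than 3 points")
  structure(list(profiles = lapply(profiles, resample_profile, grid = g),
                 times = times, grid = g),
            class = "profile_series")
}

#' Gradient-RMSD convergence diagnostic
#'
#' For each snapshot in a series, the root-mean-square deviation between its
#' finite-difference gradient and the gradient of the final snapshot.  A
#' decaying trace indicates converging free-energy estimates; the last entry
#' is exactly zero by construction.
#'
#' @param s a \code{\link{profile_series}}.
#' @return data.frame with columns \code{time} and \code{rmsd}
#'   (profile units per Angstrom).
#' @export
gradient_rmsd_convergence <- function(s) {
  stopifnot(inherits(s, "profile_series"))
  grads <- lapply(s$profiles, function(p) pracma::gradient(p$values, p$z))
  ref <- grads[[length(grads)]]
  rmsd <- vapply(grads, function(g) sqrt(mean((g - ref)^2)), 0)
  rmsd[length(rmsd)] <- 0
  data.frame(time = s$times, rmsd = rmsd)
}
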