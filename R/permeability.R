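#' Species input for effective-permeability protocols
#'
#' One ionization/tautomeric state of the permeant, described either by its
#' PMF and diffusivity profiles, by a precomputed specific permeability, or
#' as a proxy that borrows another state's permeability (and profiles).
#'
#' @param label state label matching the population labels.
#' @param pmf PMF \code{\link{profile1d}} (optional).
#' @param diffusivity diffusivity \code{\link{profile1d}} (optional).
#' @param specific_permeability specific permeability in cm/s (optional).
#' @param proxy_of label of the state whose permeability stands in for this
#'   one (optional).
#' @return object of class \code{"species_input"}.
#' @export
species_input <- function(label, pmf = NULL, diffusivity = NULL,
                          specific_permeability = NULL, proxy_of = NULL) {
  has_profiles <- !is.null(pmf) && !is.null(diffusivity)
  if (!has_profiles && is.null(specific_permeability) && is.null(proxy_of))
    stop("species '", label,
         "' needs (pmf and diffusivity), a specific permeability, or a proxy rule")
  if (!is.null(pmf)) stopifnot(inherits(pmf, "profile1d"), pmf$kind == "pmf")
  if (!is.null(diffusivity))
    stopifnot(inherits(diffusivity, "profile1d"), diffusivity$kind == "diffusivity")
  structure(list(label = label, pmf = pmf, diffusivity = diffusivity,
                 specific_permeability = specific_permeability,
                 proxy_of = proxy_of),
            class = "species_input")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> protocol = %s, P_eff = %.4g cm/s (pH %g)\n",
              x$protocol, x$p_eff, x$conditions$pH))
  if (length(x$contributions)) {
    sh <- x$contributions / sum(x$contributions)
    for (nm in names(x$contributions))
      cat(sprintf("  %-10s %.4g  (share %.3g)\n", nm, x$contributions[nm], sh[nm]))
  }
  invisible(x)
}

# trapezoidal ISD resistance integral on a merged grid, in ns/A
.isd_resistance <- function(pmf, d, tc, bounds) {
  g <- sort(unique(c(pmf$z, d$z)))
  g <- g[g >= bounds[1] & g <= bounds[2]]
  g <- sort(unique(c(bounds[1], g, bounds[2])))
  w <- resample_profile(pmf, g)$values
  dv <- resample_profile(d, g)$values
  if (any(dv <= 0)) stop("diffusivity must be positive over the integration range")
  pracma::trapz(g, exp(tc$beta * w) / dv)
}

#' Specific permeability from the inhomogeneous solubility-diffusion model
#'
#' The ISD model gives the permeability of a single ionization state as
#' \deqn{1/P = \int_{z_1}^{z_2} \frac{e^{+\beta w(z)}}{D(z)}\,dz,}
#' where \eqn{w(z)} is the PMF anchored to zero in bulk water and
#' \eqn{D(z)} the position-dependent diffusivity.  The integral is evaluated
#' by the composite trapezoid rule on the merged native grid of the two
#' profiles, and the result converted from Angstrom/ns to cm/s
#' (1 A/ns = 10 cm/s).
#'
#' @param pmf PMF \code{\link{profile1d}} (kcal/mol, bulk-anchored at 0).
#' @param d diffusivity \code{\link{profile1d}} (A^2/ns).
#' @param tc a \code{\link{thermo}} object.
#' @param bounds integration bounds (z1, z2) in Angstrom; default the common
#'   extent of the two profiles.
#' @return permeability in cm/s.
#' @export
isd_permeability <- function(pmf, d, tc = thermo(),
                             bounds = NULL) {
  stopifnot(inherits(pmf, "profile1d"), pmf$kind == "pmf",
            inherits(d, "profile1d"), d$kind == "diffusivity")
  lo <- max(min(pmf$z), min(d$z)); hi <- min(max(pmf$z), max(d$z))
  if (is.null(bounds)) bounds <- c(lo, hi)
  if (bounds[1] < lo - 1e-9 || bounds[2] > hi + 1e-9)
    stop(sprintf("bounds [%g, %g] outside the common profile range [%g, %g]",
                 bounds[1], bounds[2], lo, hi))
  R <- .isd_resistance(pmf, d, tc, bounds)   # ns/A
  10 / R                                     # cm/s
}

# resolve each species' specific permeability (cm/s), honouring proxy rules
.resolve_specific <- function(species, tc, bounds = NULL) {
  names(species) <- vapply(species, `[[`, "", "label")
  p <- stats::setNames(rep(NA_real_, length(species)), names(species))
  for (s in species) {
    if (!is.null(s$specific_permeability)) {
      p[s$label] <- s$specific_permeability
    } else if (!is.null(s$pmf) && !is.null(s$diffusivity)) {
      p[s$label] <- isd_permeability(s$pmf, s$diffusivity, tc, bounds)
    }
  }
  for (s in species) {
    if (is.na(p[s$label]) && !is.null(s$proxy_of)) {
      if (!s$proxy_of %in% names(p) || is.na(p[s$proxy_of]))
        stop("proxy donor '", s$proxy_of, "' of species '", s$label,
             "' has no resolvable permeability")
      p[s$label] <- p[s$proxy_of]
    }
  }
  if (anyNA(p)) stop("unresolvable species: ",
                     paste(names(p)[is.na(p)], collapse = ", "))
  p
}

# labels over which bulk fractions are combined: every microstate, plus the
# macrostates not represented by any microstate
.population_labels <- function(pops) {
  micro <- names(pops$by_microstate)
  split_macs <- unique(pops$macrostate_of[micro])
  c(micro, setdiff(names(pops$by_macrostate), split_macs))
}

#' Effective permeability by the pH-partitioning protocol
#'
#' Assumes protonation/deprotonation is slow compared with membrane
#' crossing: the bulk mixture of ionization states crosses independently, so
#' \deqn{P_\mathrm{eff} = \sum_s f_s P_s} with bulk fractions \eqn{f_s} and
#' specific permeabilities \eqn{P_s}.  States declared as proxies take the
#' donor state's permeability.
#'
#' @param species list of \code{\link{species_input}}.
#' @param pops \code{\link{populations}} at the target pH.
#' @param tc a \code{\link{thermo}} object.
#' @param bounds optional ISD integration bounds for profile-based species.
#' @return object of class \code{"permeability_result"} with fields
#'   \code{p_eff}, \code{protocol}, \code{contributions} (per-label
#'   \eqn{f_s P_s}), \code{p_specific}, \code{fractions}, \code{conditions}.
#' @export
effective_ph_partitioning <- function(species, pops, tc = thermo(),
                                      bounds = NULL) {
  tc$pH <- pops$pH
  p <- .resolve_specific(species, tc, bounds)
  labels <- .population_labels(pops)
  missing <- setdiff(labels, names(p))
  if (length(missing))
    stop("no species (or proxy rule) for population label(s): ",
         paste(missing, collapse = ", "))
  f <- vapply(labels, state_fraction, 0, pops = pops)
  contrib <- f * p[labels]
  structure(list(p_eff = sum(contrib), protocol = "ph-partitioning",
                 contributions = contrib, p_specific = p[labels],
                 fractions = f, conditions = tc),
            class = "permeability_result")
}

# effective bulk fraction of each profile-carrying species: its own fraction
# plus the fractions of profile-less states that proxy to it
.bwap_fractions <- function(species, pops) {
  names(species) <- vapply(species, `[[`, "", "label")
  has_prof <- vapply(species, function(s)
    !is.null(s$pmf) && !is.null(s$diffusivity), TRUE)
  if (!any(has_prof))
    stop("BWAP requires at least one species with PMF and diffusivity profiles")
  carriers <- names(species)[has_prof]
  f <- stats::setNames(numeric(length(carriers)), carriers)
  for (lab in .population_labels(pops)) {
    target <- lab
    seen <- character()
    while (!target %in% carriers) {
      seen <- c(seen, target)
      nxt <- if (target %in% names(species)) species[[target]]$proxy_of else NULL
      if (is.null(nxt) || nxt %in% seen)
        stop("population label '", lab, "' does not resolve to a species with profiles")
      target <- nxt
    }
    f[target] <- f[target] + state_fraction(pops, lab)
  }
  f
}

#' Boltzmann-weighted average potential (BWAP)
#'
#' Assumes protonation/deprotonation is fast compared with membrane
#' crossing, so the permeant diffuses on the population-weighted potential
#' \deqn{e^{-\beta w_m(z)} = \sum_s f_s e^{-\beta w_s(z)},}
#' computed with an overflow-safe log-sum-exp.  Bulk fractions of states
#' without their own profiles are folded into the state they proxy to.
#'
#' @param species list of \code{\link{species_input}} (those with profiles
#'   contribute terms).
#' @param pops \code{\link{populations}} at the target pH.
#' @param tc a \code{\link{thermo}} object.
#' @return the mixed PMF as a \code{\link{profile1d}} on the common grid.
#' @export
bwap_potential <- function(species, pops, tc = thermo()) {
  f <- .bwap_fractions(species, pops)
  names(species) <- vapply(species, `[[`, "", "label")
  grids <- lapply(names(f), function(l) species[[l]]$pmf$z)
  lo <- max(vapply(grids, min, 0)); hi <- min(vapply(grids, max, 0))
  if (lo >= hi) stop("species PMF grids do not overlap")
  g <- sort(unique(unlist(grids)))
  g <- g[g >= lo & g <= hi]
  # rows: species, cols: z;  log f_s - beta w_s(z)
  lg <- t(vapply(names(f), function(l) {
    w <- resample_profile(species[[l]]$pmf, g)$values
    log(f[l]) - tc$beta * w
  }, numeric(length(g))))
  m <- apply(lg, 2, max)
  lse <- m + log(colSums(exp(sweep(lg, 2, m))))
  profile1d(g, -lse / tc$beta, kind = "pmf", label = "BWAP")
}

#' Local-population-weighted effective diffusivity for BWAP
#'
#' At each position the fast-exchange mixture samples state \eqn{s} with the
#' local Boltzmann share
#' \eqn{\phi_s(z) = f_s e^{-\beta w_s(z)} / \sum_t f_t e^{-\beta w_t(z)}};
#' the effective diffusivity is \eqn{D_m(z) = \sum_s \phi_s(z) D_s(z)}.
#'
#' @inheritParams bwap_potential
#' @return the mixed diffusivity as a \code{\link{profile1d}}.
#' @export
bwap_effective_diffusivity <- function(species, pops, tc = thermo()) {
  f <- .bwap_fractions(species, pops)
  names(species) <- vapply(species, `[[`, "", "label")
  grids <- lapply(names(f), function(l)
    c(species[[l]]$pmf$z, species[[l]]$diffusivity$z))
  lo <- max(vapply(grids, min, 0)); hi <- min(vapply(grids, max, 0))
  g <- sort(unique(unlist(grids)))
  g <- g[g >= lo & g <= hi]
  lg <- t(vapply(names(f), function(l) {
    w <- resample_profile(species[[l]]$pmf, g)$values
    log(f[l]) - tc$beta * w
  }, numeric(length(g))))
  m <- apply(lg, 2, max)
  phi <- exp(sweep(lg, 2, m))
  phi <- sweep(phi, 2, colSums(phi), "/")
  dmat <- t(vapply(names(f), function(l)
    resample_profile(species[[l]]$diffusivity, g)$values, numeric(length(g))))
  profile1d(g, colSums(phi * dmat), kind = "diffusivity", label = "BWAP")
}

#' Effective permeability by the BWAP protocol
#'
#' Builds the Boltzmann-weighted average potential and the local-population-
#' weighted effective diffusivity, then integrates the ISD model on the
#' mixed profiles.
#'
#' @inheritParams bwap_potential
#' @param bounds optional integration bounds (z1, z2) in Angstrom.
#' @return object of class \code{"permeability_result"}; \code{contributions}
#'   records the effective bulk fraction carried by each profile species.
#' @export
effective_bwap <- function(species, pops, tc = thermo(), bounds = NULL) {
  tc$pH <- pops$pH
  wm <- bwap_potential(species, pops, tc)
  dm <- bwap_effective_diffusivity(species, pops, tc)
  p <- isd_permeability(wm, dm, tc, bounds)
  structure(list(p_eff = p, protocol = "bwap",
                 contributions = .bwap_fractions(species, pops),
                 p_specific = NULL, fractions = NULL, conditions = tc,
                 bwap_pmf = wm, bwap_diffusivity = dm),
            class = "permeability_result")
}

#' pH scan of the effective permeability
#'
#' Recomputes the microstate populations and the effective permeability on a
#' pH grid, reporting the dominant contributing state under the
#' pH-partitioning protocol (and the BWAP value when the species carry
#' profiles).
#'
#' @param species list of \code{\link{species_input}}.
#' @param model an \code{\link{ionization_model}} providing populations.
#' @param tc a \code{\link{thermo}} template (temperature).
#' @param ph_grid numeric vector of pH values.
#' @param bounds optional ISD bounds.
#' @param bwap also evaluate the BWAP protocol (default: TRUE when any
#'   species has profiles).
#' @return data.frame with columns \code{pH}, \code{p_eff} (pH-partitioning),
#'   \code{p_eff_bwap} (or NA), \code{dominant}, \code{dominant_share}.
#' @export
ph_scan <- function(species, model, tc = thermo(), ph_grid = 1:10,
                    bounds = NULL, bwap = NULL) {
  if (is.null(bwap))
    bwap <- any(vapply(species, function(s)
      !is.null(s$pmf) && !is.null(s$diffusivity), TRUE))
  rows <- lapply(ph_grid, function(ph) {
    tci <- thermo(tc$temperature, ph)
    pops <- microstate_fractions(model, tci)
    res <- effective_ph_partitioning(species, pops, tci, bounds)
    share <- res$contributions / res$p_eff
    pb <- if (bwap) effective_bwap(species, pops, tci, bounds)$p_eff else NA_real_
    data.frame(pH = ph, p_eff = res$p_eff, p_eff_bwap = pb,
               dominant = names(which.max(share)),
               dominant_share = max(share))
  })
  do.call(rbind, rows)
}

#' Sensitivity of the effective permeability to proxy-state permeabilities
#'
#' Proxy states (those declared with \code{proxy_of}) borrow another state's
#' specific permeability as an upper-bound stand-in.  This scan multiplies
#' only the proxy states' permeabilities by each factor (the donor state
#' itself is untouched) and recomputes the pH-partitioning sum.
#'
#' @param species list of \code{\link{species_input}}.
#' @param pops \code{\link{populations}} at the target pH.
#' @param tc a \code{\link{thermo}} object.
#' @param factors numeric vector of scale factors.
#' @param bounds optional ISD bounds.
#' @return data.frame with columns \code{factor}, \code{p_eff},
#'   \code{rel_change} (relative to the unscaled baseline) and \code{fold}.
#' @export
proxy_sensitivity_scan <- function(species, pops, tc = thermo(),
                                   factors = c(0, 1e3, 1e5), bounds = NULL) {
  tc$pH <- pops$pH
  p <- .resolve_specific(species, tc, bounds)
  labels <- .population_labels(pops)
  f <- vapply(labels, state_fraction, 0, pops = pops)
  names(species) <- vapply(species, `[[`, "", "label")
  is_proxy <- vapply(labels, function(l)
    l %in% names(species) && !is.null(species[[l]]$proxy_of), TRUE)
  base <- sum(f * p[labels])
  rows <- lapply(factors, function(fac) {
    ps <- p[labels]
    ps[is_proxy] <- ps[is_proxy] * fac
    pe <- sum(f * ps)
    data.frame(factor = fac, p_eff = pe,
               rel_change = pe / base - 1, fold = pe / base)
  })
  do.call(rbind, rows)
}
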