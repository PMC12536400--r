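#' Synthetic W-shaped permeation PMF
#'
#' Analytic stand-in for a membrane-permeation free-energy profile: a central
#' Gaussian barrier at z = 0 plus two mirrored Gaussian interfacial wells at
#' \code{+-well_position}, anchored to zero in bulk.  The two Gaussian
#' amplitudes are solved from a 2x2 linear system so that the profile passes
#' exactly through \code{barrier} at z = 0 and \code{well_depth} at the well
#' positions despite the overlap of the basis functions; with well-separated
#' landmarks the extrema then sit at those positions to high accuracy and
#' \code{\link{profile_features}} recovers the requested values.
#'
#' @param barrier barrier height at z = 0 (kcal/mol, >= 0).
#' @param well_depth well depth (kcal/mol, <= 0).
#' @param well_position position of the interfacial wells (Angstrom).
#' @param interface_width Gaussian width of the wells (Angstrom).
#' @param barrier_width Gaussian width of the central barrier (Angstrom).
#' @param bulk_extent half-extent of the grid (Angstrom).
#' @param grid_spacing grid spacing (Angstrom).
#' @param label profile label.
#' @return a PMF \code{\link{profile1d}}, symmetric by construction.
#' @export
make_w_pmf <- function(barrier = 4.5, well_depth = -4.9, well_position = 14,
                       interface_width = 3, barrier_width = 3.5,
                       bulk_extent = 40, grid_spacing = 0.2, label = "W-PMF") {
  if (barrier < 0) stop("barrier must be >= 0")
  if (well_depth > 0) stop("well_depth must be <= 0")
  if (bulk_extent <= well_position)
    stop("grid must extend beyond the wells: bulk_extent > well_position")
  z <- seq(-bulk_extent, bulk_extent, by = grid_spacing)
  gb <- function(x) exp(-x^2 / (2 * barrier_width^2))
  gw <- function(x) exp(-(x - well_position)^2 / (2 * interface_width^2)) +
                    exp(-(x + well_position)^2 / (2 * interface_width^2))
  # amplitudes solving value(0) = barrier, value(well_position) = well_depth
  M <- rbind(c(gb(0), gw(0)), c(gb(well_position), gw(well_position)))
  amp <- solve(M, c(barrier, well_depth))
  v <- amp[1] * gb(z) + amp[2] * gw(z)
  v <- v - .bulk_reference(z, v, 0.1)
  profile1d(z, v, kind = "pmf", label = label)
}

#' Synthetic diffusivity profile with a membrane dip
#'
#' Smooth positive profile interpolating bulk -> center -> bulk with a
#' Gaussian dip (or bump): \eqn{D(z) = D_b + (D_c - D_b) e^{-z^2/2\sigma^2}}.
#'
#' @param bulk_D bulk diffusivity (A^2/ns, > 0).
#' @param center_D diffusivity at z = 0 (A^2/ns, > 0).
#' @param width Gaussian width of the dip (Angstrom).
#' @param grid z grid (Angstrom).
#' @param label profile label.
#' @return a diffusivity \code{\link{profile1d}}.
#' @export
make_diffusivity <- function(bulk_D = 50, center_D = 25, width = 8,
                             grid = seq(-40, 40, by = 0.2), label = "D") {
  if (bulk_D <= 0 || center_D <= 0) stop("diffusivities must be positive")
  v <- bulk_D + (center_D - bulk_D) * exp(-grid^2 / (2 * width^2))
  profile1d(grid, v, kind = "diffusivity", label = label)
}

#' Overdamped Langevin trajectory under a known potential
#'
#' Brownian-dynamics surrogate for the MD free-diffusion protocol: the Ito
#' update
#' \deqn{z \leftarrow z + [-\beta D(z) U'(z) + D'(z)]\,dt + \sqrt{2 D(z) dt}\,\xi}
#' with reflecting boundaries.  The explicit \eqn{D'(z)} (spurious-drift)
#' term makes the stationary density Boltzmann in \eqn{U} even when the
#' diffusivity varies with position.  The integrator (compiled) linearly
#' interpolates drift and noise amplitude from a uniform internal grid.
#'
#' @param potential total potential \code{\link{profile1d}} (including any
#'   bias); NULL means flat.
#' @param diffusivity diffusivity \code{\link{profile1d}}, or a positive
#'   scalar for constant D.
#' @param dt time step in ns.
#' @param n_steps number of steps.
#' @param seed mandatory RNG seed (integer).
#' @param boundaries reflecting limits \code{c(lo, hi)} in Angstrom.
#' @param initial_z starting position (default mid-domain).
#' @param tc a \code{\link{thermo}} object (temperature).
#' @param grid_spacing internal interpolation grid spacing (Angstrom).
#' @return a \code{\link{trajectory1d}} (the bias field records the
#'   potential used).
#' @export
simulate_langevin <- function(potential, diffusivity, dt, n_steps, seed,
                              boundaries, initial_z = mean(boundaries),
                              tc = thermo(), grid_spacing = 0.1) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  lo <- boundaries[1]; hi <- boundaries[2]
  if (!(hi > lo)) stop("boundaries must satisfy lo < hi")
  g <- seq(lo, hi, by = grid_spacing)
  if (g[length(g)] < hi) g <- c(g, hi)
  if (is.numeric(diffusivity) && length(diffusivity) == 1L) {
    Dv <- rep(as.numeric(diffusivity), length(g))
    if (Dv[1] <= 0) stop("diffusivity must be positive")
    Dp <- rep(0, length(g))
  } else {
    stopifnot(inherits(diffusivity, "profile1d"),
              diffusivity$kind == "diffusivity")
    Dv <- stats::approx(diffusivity$z, diffusivity$values, xout = g,
                        rule = 2)$y
    Dp <- pracma::gradient(Dv, g)
  }
  if (is.null(potential)) {
    Fv <- rep(0, length(g))
  } else {
    stopifnot(inherits(potential, "profile1d"))
    Uv <- stats::approx(potential$z, potential$values, xout = g, rule = 2)$y
    Fv <- -pracma::gradient(Uv, g)
  }
  drift <- tc$beta * Dv * Fv + Dp
  max_step <- max(abs(drift)) * dt
  if (max_step > grid_spacing)
    stop(sprintf("dt too large: max drift step %.3g A exceeds the grid spacing; try dt <= %.3g ns",
                 max_step, grid_spacing / max(abs(drift))))
  set.seed(as.integer(seed))
  z <- langevin_path_cpp(initial_z, as.integer(n_steps), dt, g[1],
                         grid_spacing, drift, sqrt(2 * Dv), lo, hi)
  trajectory1d(z, dt, bias = potential, boundaries = boundaries)
}

#' Permeability from membrane-crossing counts
#'
#' Equilibrium-flux counting estimate, an independent cross-check of the ISD
#' integral: complete one-way traversals of the membrane slab per unit time,
#' divided by the bulk linear concentration (time fraction spent in the bulk
#' regions divided by their total length).  The standard error is obtained
#' by bootstrap over trajectories.
#'
#' @param trajs list of \code{\link{trajectory1d}} generated under the true
#'   (unbiased) potential.
#' @param membrane \code{c(z1, z2)}: the membrane slab (Angstrom).
#' @param bulk list of two intervals (each \code{c(lo, hi)}) defining the
#'   bulk regions outside the membrane.
#' @param n_boot bootstrap replicates (default 200).
#' @return list with \code{p} (cm/s), \code{se}, \code{n_crossings},
#'   \code{concentration} (1/Angstrom), \code{degenerate} (TRUE when no
#'   traversal was observed; \code{p} is then an upper bound based on one
#'   crossing).
#' @export
crossing_permeability <- function(trajs, membrane, bulk, n_boot = 200L) {
  if (inherits(trajs, "trajectory1d")) trajs <- list(trajs)
  stats_one <- function(tr) {
    side <- ifelse(tr$z < membrane[1], -1L, ifelse(tr$z > membrane[2], 1L, 0L))
    visits <- side[side != 0L]
    cross <- if (length(visits) > 1L) sum(diff(visits) != 0L) else 0L
    inbulk <- (tr$z >= bulk[[1]][1] & tr$z <= bulk[[1]][2]) |
              (tr$z >= bulk[[2]][1] & tr$z <= bulk[[2]][2])
    c(cross = cross, t_bulk = sum(inbulk) * tr$dt,
      t_tot = length(tr$z) * tr$dt)
  }
  st <- t(vapply(trajs, stats_one, c(cross = 0, t_bulk = 0, t_tot = 0)))
  Lb <- (bulk[[1]][2] - bulk[[1]][1]) + (bulk[[2]][2] - bulk[[2]][1])
  est <- function(m) {
    conc <- (sum(m[, "t_bulk"]) / sum(m[, "t_tot"])) / Lb   # 1/A
    # crossings counted in both directions; one-way flux = total / 2
    (sum(m[, "cross"]) / 2 / sum(m[, "t_tot"])) / conc      # A/ns
  }
  p_ans <- est(st)
  conc <- (sum(st[, "t_bulk"]) / sum(st[, "t_tot"])) / Lb
  n_cross <- sum(st[, "cross"])
  degenerate <- n_cross == 0
  if (degenerate)
    p_ans <- (1 / 2 / sum(st[, "t_tot"])) / conc            # <= 1 crossing
  se <- NA_real_
  if (nrow(st) > 1L && !degenerate) {
    boot <- vapply(seq_len(n_boot), function(b)
      est(st[sample.int(nrow(st), replace = TRUE), , drop = FALSE]), 0)
    se <- stats::sd(boot) * 10
  }
  list(p = p_ans * 10, se = se, n_crossings = n_cross,
       concentration = conc, degenerate = degenerate)
}

#' Random cycle-consistent ionization model
#'
#' Fixture generator: \code{n_sites} titratable sites of random type (acid:
#' 0/-1, base: +1/0) give \code{2^n_sites} microstates.  Microscopic pks are
#' assigned to a spanning tree of the protonation graph (uniform in
#' \code{pk_range}); all remaining protonation edges are completed by
#' thermodynamic-cycle closure, so the model is exactly consistent.  The
#' ground-truth log10 weights are attached as attribute \code{"gamma"} (as
#' for any \code{\link{ionization_model}}).
#'
#' @param n_sites number of sites (1 to 4).
#' @param pk_range range of tree-edge pks (default c(3, 10)).
#' @param seed RNG seed.
#' @return an \code{\link{ionization_model}}.
#' @export
make_tautomer_model <- function(n_sites, pk_range = c(3, 10), seed = 1L) {
  if (n_sites < 1L || n_sites > 4L) stop("n_sites must be between 1 and 4")
  set.seed(as.integer(seed))
  base_charge <- sample(c(0L, 1L), n_sites, replace = TRUE)  # protonated-site charge
  patterns <- as.matrix(expand.grid(rep(list(0:1), n_sites)))  # 1 = protonated
  lab <- apply(patterns, 1, function(p) paste0(
    LETTERS[1:n_sites],
    ifelse(p == 1, ifelse(base_charge == 1, "+", "0"),
           ifelse(base_charge == 1, "0", "-")), collapse = ""))
  net <- as.integer(patterns %*% base_charge - (1 - patterns) %*% (1 - base_charge))
  np <- rowSums(patterns)
  micro <- data.frame(label = lab, net_charge = net, n_protons = np,
                      stringsAsFactors = FALSE)
  # spanning tree: connect each state with k protons to a parent with k-1
  gamma <- stats::setNames(rep(NA_real_, nrow(micro)), lab)
  gamma[np == 0] <- 0
  for (k in seq_len(n_sites)) {
    for (i in which(np == k)) {
      js <- which(np == k - 1 &
                  colSums(abs(t(patterns) - patterns[i, ])) == 1L)
      parent <- js[1L]
      gamma[i] <- gamma[parent] + stats::runif(1, pk_range[1], pk_range[2])
    }
  }
  # all Hamming-distance-1 protonation edges, pks from the gamma differences
  pairs <- which(outer(np, np, `-`) == 1L, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(pairs)), function(r)
    sum(abs(patterns[pairs[r, 1], ] - patterns[pairs[r, 2], ])) == 1L, TRUE)
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(donor = lab[pairs[, 1]], acceptor = lab[pairs[, 2]],
                      pk = gamma[pairs[, 1]] - gamma[pairs[, 2]],
                      stringsAsFactors = FALSE)
  ionization_model(micro, edges, reference = lab[np == 0])
}

#' Calibrated tetracycline-like species fixture
#'
#' Builds the two zero-charge tautomer species with synthetic W-shaped PMFs
#' (central barriers 4.5 and 13.6 kcal/mol; interfacial wells -4.9 and -2.1
#' kcal/mol at +-14 Angstrom for the neutral and zwitterionic forms) and
#' dipped diffusivity profiles whose overall scale is calibrated by 1D
#' root-finding so that each tautomer's ISD specific permeability matches
#' its target value exactly.  The remaining ionization states are attached
#' as proxies of the zwitterion.
#'
#' @param tc a \code{\link{thermo}} object.
#' @param p_n target specific permeability of the neutral tautomer (cm/s).
#' @param p_z target specific permeability of the zwitterion (cm/s).
#' @param level \code{"lumped"} (charged macrostates as single proxy states,
#'   labels "+1", "-1", "-2") or \code{"microstate"} (proxy species for each
#'   microstate label of \code{\link{tc_microstate_model}}).
#' @param grid_spacing PMF grid spacing (Angstrom).
#' @return named list of \code{\link{species_input}}.
#' @export
tc_like_species <- function(tc = thermo(pH = 6), p_n = 2.22e-2, p_z = 1.63e-8,
                            level = c("lumped", "microstate"),
                            grid_spacing = 0.2) {
  level <- match.arg(level)
  calib <- function(pmf, target) {
    shape <- make_diffusivity(bulk_D = 1, center_D = 0.5, width = 8,
                              grid = pmf$z)
    fun <- function(log_s) {
      d <- profile1d(shape$z, exp(log_s) * shape$values, kind = "diffusivity")
      log(isd_permeability(pmf, d, tc)) - log(target)
    }
    root <- stats::uniroot(fun, c(-20, 20), tol = 1e-12)$root
    profile1d(shape$z, exp(root) * shape$values, kind = "diffusivity")
  }
  pmf_n <- make_w_pmf(4.5, -4.9, 14, grid_spacing = grid_spacing,
                      label = "TC_N")
  pmf_z <- make_w_pmf(13.6, -2.1, 14, grid_spacing = grid_spacing,
                      label = "TC_Z")
  sp <- list(
    TC_N = species_input("TC_N", pmf = pmf_n, diffusivity = calib(pmf_n, p_n)),
    TC_Z = species_input("TC_Z", pmf = pmf_z, diffusivity = calib(pmf_z, p_z)),
    TC_Zp = species_input("TC_Zp", proxy_of = "TC_Z"))
  proxies <- if (level == "lumped") c("+1", "-1", "-2")
             else c("A0B+C0", "A-B0C0", "A-B+C-", "A0B0C-", "A-B0C-")
  for (lab in proxies)
    sp[[lab]] <- species_input(lab, proxy_of = "TC_Z")
  sp
}
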