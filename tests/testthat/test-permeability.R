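test_that("ISD integral matches closed forms", {
  z <- seq(-40, 40, by = 0.2)
  flat <- profile1d(z, rep(0, length(z)), kind = "pmf")
  d40 <- constant_diffusivity(flat, 40)
  # w = 0, D = 40 A^2/ns over 80 A: P = 0.5 A/ns = 5 cm/s exactly
  expect_equal(isd_permeability(flat, d40), 5, tolerance = 1e-12)

  # constant barrier of height dW over the integration slab
  tc <- thermo()
  dW <- 3.7
  bar <- profile1d(z, rep(dW, length(z)), kind = "pmf")
  p <- isd_permeability(bar, d40, tc, bounds = c(-5, 5))
  expect_equal(p, 10 * 40 * exp(-tc$beta * dW) / 10, tolerance = 1e-3 * p)

  # trapezoid vs 10x-refined grid for the synthetic W-PMF: < 0.1%
  w <- make_w_pmf(4.5, -4.9, 14, grid_spacing = 0.1)
  d <- make_diffusivity(50, 25, grid = w$z)
  p0 <- isd_permeability(w, d, tc)
  zf <- seq(min(w$z), max(w$z), by = 0.01)
  pf <- isd_permeability(resample_profile(w, zf), resample_profile(d, zf), tc)
  expect_equal(p0, pf, tolerance = 1e-3)

  expect_error(isd_permeability(w, d, tc, bounds = c(-50, 50)), "outside")
})

test_that("a uniform PMF shift rescales P by exp(-beta dG) exactly", {
  tc <- thermo()
  w <- make_w_pmf(4.5, -4.9, 14)
  d <- make_diffusivity(50, 25, grid = w$z)
  p0 <- isd_permeability(w, d, tc)
  for (dg in c(-2, 0.7, 4.014)) {
    p1 <- isd_permeability(shift_profile(w, dg), d, tc)
    expect_equal(p1, p0 * exp(-tc$beta * dg), tolerance = 1e-12)
  }
})

test_that("pH-partitioning reproduces the published effective permeability", {
  tc6 <- thermo(pH = 6)
  pops <- tc_populations(tc6)
  res <- effective_ph_partitioning(tc_value_species(), pops, tc6)
  expect_equal(res$p_eff, 3.17e-5, tolerance = 0.02)
  # contributions are nonnegative and sum to P_eff
  expect_true(all(res$contributions >= 0))
  expect_equal(sum(res$contributions), res$p_eff, tolerance = 1e-12)
  # the neutral tautomer dominates
  expect_equal(names(which.max(res$contributions)), "TC_N")

  # single species with full fraction
  solo <- populations(by_macrostate = c(`0` = 1), pH = 7)
  r1 <- effective_ph_partitioning(
    list(species_input("0", specific_permeability = 1.2e-4)), solo, thermo())
  expect_equal(r1$p_eff, 1.2e-4)

  # a population label with no species and no proxy rule is an error
  expect_error(effective_ph_partitioning(tc_value_species()[1:2], pops, tc6),
               "proxy")
})

test_that("published specific permeabilities differ by over six orders of magnitude", {
  expect_gte(log10(2.22e-2 / 1.63e-8), 6)
})

test_that("proxy-state sensitivity matches the published scan", {
  tc6 <- thermo(pH = 6)
  pops <- tc_populations(tc6)
  scan <- proxy_sensitivity_scan(tc_value_species(), pops, tc6,
                                 factors = c(0, 1e3, 1e5))
  expect_lt(abs(scan$rel_change[scan$factor == 0]), 1e-3)     # negligible reduction
  expect_equal(scan$rel_change[scan$factor == 1e3], 0.017, tolerance = 0.1)
  expect_equal(scan$fold[scan$factor == 1e5], 2.7, tolerance = 0.05)
})

test_that("BWAP potential obeys its degenerate and bounding properties", {
  tc6 <- thermo(pH = 6)
  z <- seq(-30, 30, by = 0.2)
  w <- profile1d(z, 4 * exp(-z^2 / 30), kind = "pmf")
  dup <- list(species_input("a", pmf = w, diffusivity = constant_diffusivity(w, 40)),
              species_input("b", pmf = w, diffusivity = constant_diffusivity(w, 40)))
  pops2 <- populations(by_macrostate = c(a = 0.3, b = 0.7), pH = 6)
  wm <- bwap_potential(dup, pops2, tc6)
  expect_equal(wm$values, resample_profile(w, wm$z)$values, tolerance = 1e-9)

  # mixed potential never exceeds any single shifted state's potential
  w2 <- profile1d(z, 9 * exp(-z^2 / 50) - 2 * exp(-(abs(z) - 14)^2 / 9),
                  kind = "pmf")
  two <- list(species_input("a", pmf = w, diffusivity = constant_diffusivity(w, 40)),
              species_input("b", pmf = w2, diffusivity = constant_diffusivity(w2, 40)))
  popsm <- populations(by_macrostate = c(a = 0.2, b = 0.8), pH = 6)
  wmix <- bwap_potential(two, popsm, tc6)
  kT <- 1 / tc6$beta
  bound <- pmin(resample_profile(w, wmix$z)$values - kT * log(0.2),
                resample_profile(w2, wmix$z)$values - kT * log(0.8))
  expect_true(all(wmix$values <= bound + 1e-9))

  # local population shares sum to 1 => D_m is a convex combination
  dm <- bwap_effective_diffusivity(
    list(species_input("a", pmf = w, diffusivity = constant_diffusivity(w, 30)),
         species_input("b", pmf = w2, diffusivity = constant_diffusivity(w2, 60))),
    popsm, tc6)
  expect_true(all(dm$values >= 30 - 1e-9 & dm$values <= 60 + 1e-9))
})

test_that("BWAP reduces to the specific permeability for a single species", {
  tc6 <- thermo(pH = 6)
  w <- make_w_pmf(4.5, -4.9, 14)
  d <- make_diffusivity(50, 25, grid = w$z)
  solo <- list(species_input("only", pmf = w, diffusivity = d))
  pops <- populations(by_macrostate = c(only = 1), pH = 6)
  expect_equal(effective_bwap(solo, pops, tc6)$p_eff,
               isd_permeability(w, d, tc6), tolerance = 1e-9)
})

test_that("BWAP agrees with pH-partitioning when one state dominates", {
  tc6 <- thermo(pH = 6)
  set.seed(33)
  kT <- 1 / tc6$beta
  for (rep in 1:5) {
    b1 <- runif(1, 2, 5)
    f1 <- 10^runif(1, -3, -1)
    # choose the second barrier so that state 1's shifted PMF lies at least
    # 5 kcal/mol below state 2's across the barrier region
    b2 <- b1 - kT * log(f1) + 5 + runif(1, 0.5, 3)
    w1 <- make_w_pmf(b1, -runif(1, 1, 4), 14)
    w2 <- make_w_pmf(b2, -runif(1, 1, 4), 14)
    sp <- list(species_input("s1", pmf = w1,
                             diffusivity = constant_diffusivity(w1, 40)),
               species_input("s2", pmf = w2,
                             diffusivity = constant_diffusivity(w2, 40)))
    pops <- populations(by_macrostate = c(s1 = f1, s2 = 1 - f1), pH = 6)
    pb <- effective_bwap(sp, pops, tc6)$p_eff
    pp <- effective_ph_partitioning(sp, pops, tc6)$p_eff
    expect_equal(pb, pp, tolerance = 0.02)
  }
})

test_that("the calibrated tautomer fixture matches its permeability targets", {
  tc6 <- thermo(pH = 6)
  sp <- tc_like_species(tc6)
  expect_equal(isd_permeability(sp$TC_N$pmf, sp$TC_N$diffusivity, tc6),
               2.22e-2, tolerance = 1e-9)
  expect_equal(isd_permeability(sp$TC_Z$pmf, sp$TC_Z$diffusivity, tc6),
               1.63e-8, tolerance = 1e-9)
  f <- profile_features(sp$TC_Z$pmf)
  expect_equal(f$barrier, 13.6, tolerance = 0.02)
})

test_that("pH scan shows the neutral tautomer dominating from pH 1 to 10", {
  tc <- thermo()
  m <- tc_microstate_model()
  sp <- tc_value_species(level = "microstate")
  scan <- ph_scan(sp, m, tc, ph_grid = 1:10)
  expect_true(all(scan$dominant == "TC_N"))
  expect_true(all(scan$dominant_share > 0.5))
  # P_eff varies smoothly on a fine grid (no jumps beyond grid consistency)
  fine <- ph_scan(sp, m, tc, ph_grid = seq(5, 7, by = 0.1))
  steps <- abs(diff(log10(fine$p_eff)))
  expect_true(all(steps < 0.35))
  # far below every pKa the +1 macrostate takes over and P_eff -> its proxy P
  acid <- ph_scan(sp, m, tc, ph_grid = -5)
  expect_equal(acid$p_eff, 1.63e-8, tolerance = 1e-3)
})
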