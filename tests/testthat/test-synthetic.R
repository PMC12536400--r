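test_that("the W-PMF generator hits its landmarks and is symmetric", {
  p <- make_w_pmf(4.5, -4.9, 14)
  f <- profile_features(p)
  expect_equal(f$barrier, 4.5, tolerance = 0.02)
  expect_equal(min(f$wells$depth), -4.9, tolerance = 0.02)

  flat <- make_w_pmf(0, 0, 14)
  expect_true(all(abs(flat$values) < 1e-12))

  s <- symmetrize(p)
  expect_true(all(s$deviation$values < 1e-9))
  expect_error(make_w_pmf(4.5, -4.9, well_position = 14, bulk_extent = 10),
               "extend")
  expect_error(make_w_pmf(4.5, 2), "well_depth")
})

test_that("the diffusivity generator is positive with its dip at the centre", {
  g <- seq(-30, 30, by = 0.5)
  expect_equal(make_diffusivity(40, 40, grid = g)$values, rep(40, length(g)))
  dip <- make_diffusivity(50, 25, grid = g)
  expect_equal(min(dip$values), 25, tolerance = 1e-12)
  expect_equal(dip$z[which.min(dip$values)], 0)
  set.seed(19)
  for (i in 1:20) {
    d <- make_diffusivity(runif(1, 1, 100), runif(1, 1, 100),
                          width = runif(1, 2, 15), grid = g)
    expect_true(all(d$values > 0))
  }
  expect_error(make_diffusivity(-1, 5, grid = g), "positive")
})

test_that("the Langevin simulator is seed-deterministic and stability-checked", {
  a <- simulate_langevin(NULL, 50, dt = 1e-3, n_steps = 1e4, seed = 5,
                         boundaries = c(-10, 10))
  b <- simulate_langevin(NULL, 50, dt = 1e-3, n_steps = 1e4, seed = 5,
                         boundaries = c(-10, 10))
  expect_identical(a$z, b$z)
  cc <- simulate_langevin(NULL, 50, dt = 1e-3, n_steps = 1e4, seed = 6,
                          boundaries = c(-10, 10))
  expect_false(identical(a$z, cc$z))

  g <- seq(-10, 10, by = 0.1)
  steep <- profile1d(g, 30 * g^2, kind = "pmf")
  expect_error(simulate_langevin(steep, 50, dt = 1e-2, n_steps = 10, seed = 1,
                                 boundaries = c(-10, 10)), "dt")
  expect_error(simulate_langevin(NULL, 50, dt = 1e-3, n_steps = 10,
                                 seed = NULL, boundaries = c(-10, 10)), "seed")
})

test_that("free diffusion reproduces the diffusion law", {
  D0 <- 50; dt <- 1e-4
  tr <- simulate_langevin(NULL, D0, dt = dt, n_steps = 2e5, seed = 8,
                          boundaries = c(-50, 50), initial_z = 0)
  steps <- diff(tr$z)
  v <- stats::var(steps)
  se <- v * sqrt(2 / (length(steps) - 1))
  expect_lt(abs(v - 2 * D0 * dt), 3 * se)
})

test_that("a long run in a harmonic well reproduces Boltzmann occupancy", {
  g <- seq(-6, 6, by = 0.1)
  kspr <- 1.0
  U <- profile1d(g, 0.5 * kspr * g^2, kind = "pmf")
  tr <- simulate_langevin(U, 50, dt = 1e-4, n_steps = 2e5, seed = 3,
                          boundaries = c(-6, 6), initial_z = 0)
  zs <- tr$z[seq(1, length(tr$z), by = 200)]    # thin past the relaxation time
  br <- seq(-3, 3, by = 0.5)
  counts <- as.numeric(table(cut(zs[abs(zs) <= 3], br)))
  beta <- thermo()$beta
  p <- vapply(seq_len(length(br) - 1), function(i)
    stats::integrate(function(x) exp(-beta * 0.5 * kspr * x^2),
                     br[i], br[i + 1])$value, 0)
  expect_gt(suppressWarnings(stats::chisq.test(counts, p = p / sum(p)))$p.value,
            0.01)
})

test_that("an inverse-PMF bias flattens the sampled occupancy", {
  w <- make_w_pmf(4.5, -4.9, 14, bulk_extent = 20)
  total <- profile1d(w$z, w$values + inverse_bias(w)$values, kind = "pmf")
  expect_true(all(abs(total$values) < 1e-12))
  tr <- simulate_langevin(total, 50, dt = 2e-4, n_steps = 5e5, seed = 9,
                          boundaries = c(-20, 20))
  occ <- as.numeric(table(cut(tr$z, seq(-16, 16, by = 4))))
  expect_lt(max(occ) / min(occ), 2)
  # without the bias the occupancy is far from uniform (wells dominate)
  tru <- simulate_langevin(w, 50, dt = 2e-4, n_steps = 5e5, seed = 9,
                           boundaries = c(-20, 20))
  occ_u <- as.numeric(table(cut(tru$z, seq(-16, 16, by = 4))))
  expect_gt(max(occ_u) / min(occ_u), 2)
})

test_that("crossing counts vanish for an impassable barrier", {
  w <- make_w_pmf(13.6, -2.1, 14, bulk_extent = 20)
  trs <- lapply(1:2, function(s)
    simulate_langevin(w, 50, dt = 2e-4, n_steps = 5e4, seed = s,
                      boundaries = c(-20, 20), initial_z = -15))
  cp <- crossing_permeability(trs, membrane = c(-10, 10),
                              bulk = list(c(-20, -10), c(10, 20)))
  expect_true(cp$degenerate)
  expect_identical(cp$n_crossings, 0)
  expect_true(is.finite(cp$p))   # flagged upper bound
})

test_that("random ionization models are exactly cycle-consistent", {
  for (seed in 1:25) {
    n <- 1 + (seed %% 4)
    m <- make_tautomer_model(n, seed = seed)
    expect_equal(nrow(m$microstates), 2^n)
    v <- validate_cycles(m)
    if (nrow(v)) expect_lt(max(v$residual), 1e-10)
    # fractions from the model match direct enumeration via the ground-truth
    # log-weights attached by the constructor
    ph <- runif(1, 1, 13)
    tcp <- thermo(pH = ph)
    got <- microstate_fractions(m, tcp)$by_microstate
    gamma <- attr(m, "gamma")
    np <- stats::setNames(m$microstates$n_protons, m$microstates$label)
    lw <- gamma - np[names(gamma)] * ph
    want <- 10^(lw - max(lw)); want <- want / sum(want)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("a one-site model reduces to Henderson-Hasselbalch", {
  m <- make_tautomer_model(1, seed = 4)
  pk <- m$edges$pk[1]
  tcp <- thermo(pH = pk)          # half-titration at pH = pk
  f <- microstate_fractions(m, tcp)$by_microstate
  expect_equal(unname(f), c(0.5, 0.5), tolerance = 1e-12)
})
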