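test_that("macrostate fractions follow Henderson-Hasselbalch", {
  half <- macrostate_fractions(7.4, thermo(pH = 7.4), fully_protonated_charge = 0L)
  expect_equal(unname(half$by_macrostate), c(0.5, 0.5), tolerance = 1e-12)

  # brute-force oracle: accumulate weights from the fully protonated end
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    pkas <- sort(runif(n, 2, 11))
    ph <- runif(1, 0, 14)
    got <- macrostate_fractions(pkas, thermo(pH = ph))
    # by_macrostate is named most-protonated first; oracle is j = 0..N protons
    expect_equal(unname(rev(got$by_macrostate)),
                 unname(oracle_macro_fractions(pkas, ph)), tolerance = 1e-12)
    expect_equal(sum(got$by_macrostate), 1, tolerance = 1e-12)
  }

  # extreme pH concentrates all mass on a terminal macrostate
  lo <- macrostate_fractions(c(3.33, 7.75, 9.61), thermo(pH = -20))
  expect_equal(unname(lo$by_macrostate["+1"]), 1, tolerance = 1e-9)
  hi <- macrostate_fractions(c(3.33, 7.75, 9.61), thermo(pH = 20))
  expect_equal(unname(hi$by_macrostate["-2"]), 1, tolerance = 1e-9)
  expect_error(macrostate_fractions(numeric(0)), "at least one")
})

test_that("tetracycline macrostates and tautomer split reproduce published fractions", {
  pops <- tc_populations(thermo(pH = 6))
  expect_equal(unname(pops$by_macrostate["+1"]), 2.10e-3, tolerance = 0.02)
  expect_equal(unname(pops$by_macrostate["-1"]), 1.74e-2, tolerance = 0.02)
  expect_equal(unname(pops$by_macrostate["-2"]), 4.30e-6, tolerance = 0.02)
  expect_equal(unname(pops$by_microstate["TC_Z"]), 9.65e-1, tolerance = 0.02)
  expect_equal(unname(pops$by_microstate["TC_Zp"]), 1.43e-2, tolerance = 0.02)
  # splitting conserves the macrostate fraction exactly
  expect_equal(sum(pops$by_microstate[c("TC_Z", "TC_N", "TC_Zp")]),
               unname(pops$by_macrostate["0"]), tolerance = 1e-15)
})

test_that("tautomer splitting validates its ratios", {
  mac <- macrostate_fractions(c(5, 9), thermo(pH = 7), fully_protonated_charge = 1L)
  one <- split_macrostate_by_ratios(mac, "0", c(only = 1))
  expect_equal(unname(one$by_microstate["only"]),
               unname(mac$by_macrostate["0"]))
  expect_error(split_macrostate_by_ratios(mac, "0", c(a = 2, b = 3)), "anchor")
  expect_error(split_macrostate_by_ratios(mac, "0", c(2, 3)), "named")
})

test_that("microstate weights are path-independent and reference-normalized", {
  tc6 <- thermo(pH = 6)
  m <- tc_microstate_model()
  expect_equal(microstate_weight(m, m$reference, tc6), 1)
  expect_equal(microstate_weight(m, m$reference, thermo(pH = 12)), 1)

  # ratio of neutral to zwitterion weights equals the printed tautomer ratio
  expect_equal(microstate_weight(m, "TC_N", tc6) / microstate_weight(m, "TC_Z", tc6),
               10^-2.83, tolerance = 1e-12)

  # exhaustive simple-path enumeration: every path gives the same pk sum
  for (lab in m$microstates$label) {
    sums <- oracle_path_sums(m, m$reference, lab)
    expect_true(length(sums) >= 1L)
    expect_lt(max(sums) - min(sums), 1e-9)
  }
  expect_error(microstate_weight(m, "nope", tc6), "unknown")
})

test_that("microstate fractions aggregate exactly to macrostates", {
  tc6 <- thermo(pH = 6)
  m <- tc_microstate_model()
  pm <- microstate_fractions(m, tc6)
  expect_equal(sum(pm$by_microstate), 1, tolerance = 1e-12)
  for (mac in names(pm$by_macrostate)) {
    members <- names(pm$macrostate_of)[pm$macrostate_of == mac]
    expect_equal(sum(pm$by_microstate[members]),
                 unname(pm$by_macrostate[mac]), tolerance = 1e-12)
  }
  # the full microstate model agrees with the macroscopic-pKa + ratio route
  pops <- tc_populations(tc6)
  expect_equal(unname(pm$by_microstate[c("TC_Z", "TC_N", "TC_Zp")]),
               unname(pops$by_microstate[c("TC_Z", "TC_N", "TC_Zp")]),
               tolerance = 1e-9)
  expect_equal(pm$by_macrostate[names(pops$by_macrostate)],
               pops$by_macrostate, tolerance = 1e-9)

  # degenerate scheme (one microstate per macrostate) reduces to the
  # macroscopic Henderson-Hasselbalch result
  micro <- data.frame(label = c("H2A", "HA", "A"),
                      net_charge = c(0L, -1L, -2L),
                      n_protons = c(2L, 1L, 0L))
  edges <- data.frame(donor = c("HA", "H2A"), acceptor = c("A", "HA"),
                      pk = c(9.0, 4.0))
  dm <- ionization_model(micro, edges)
  ph5 <- thermo(pH = 5)
  got <- microstate_fractions(dm, ph5)$by_macrostate
  want <- macrostate_fractions(c(4.0, 9.0), ph5,
                               fully_protonated_charge = 0L)$by_macrostate
  expect_equal(got[names(want)], want, tolerance = 1e-12)
})

test_that("thermodynamic cycle validation flags inconsistent edges", {
  # 4-state square: two sites, consistent by construction
  micro <- data.frame(label = c("00", "10", "01", "11"),
                      net_charge = c(-2L, -1L, -1L, 0L),
                      n_protons = c(0L, 1L, 1L, 2L))
  edges <- data.frame(donor = c("10", "01", "11", "11"),
                      acceptor = c("00", "00", "10", "01"),
                      pk = c(5, 7, 6, 4))
  sq <- ionization_model(micro, edges, reference = "00")
  v <- validate_cycles(sq)
  expect_true(all(v$residual < 1e-12))

  edges2 <- edges
  edges2$pk[4] <- edges2$pk[4] + 0.5   # closing edge of the only cycle
  sq2 <- ionization_model(micro, edges2, reference = "00")
  v2 <- validate_cycles(sq2)
  expect_equal(max(v2$residual), 0.5, tolerance = 1e-12)
  expect_false(all(v2$consistent))

  expect_true(all(validate_cycles(tc_microstate_model())$residual < 1e-6))
})

test_that("assignment variants are cycle-consistent and swap as expected", {
  vars <- assignment_variants()
  expect_named(vars, c("leeson", "stephens-like-swap",
                       "naive-forward", "naive-reverse"))
  tc6 <- thermo(pH = 6)
  for (v in vars)
    expect_true(all(validate_cycles(v)$residual < 1e-9))

  rat <- function(m) microstate_weight(m, "TC_N", tc6) /
                     microstate_weight(m, "TC_Z", tc6)
  expect_equal(rat(vars$leeson), 10^-2.83, tolerance = 1e-12)
  # swapping pKa2/pKa3 between the naive orders changes f_N/f_Z by 10^(pKa3-pKa2)
  expect_equal(rat(vars$`naive-forward`) / rat(vars$`naive-reverse`),
               10^(9.61 - 7.75), tolerance = 1e-9)
  expect_error(assignment_variants(scheme = "bogus"), "arg")
})
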