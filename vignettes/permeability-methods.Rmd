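---
title: "Effective membrane permeability of ionizable, multi-tautomer permeants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective membrane permeability of ionizable, multi-tautomer permeants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeakit)
```

## The problem

Passive membrane permeation of a drug-like molecule is commonly quantified
with the inhomogeneous solubility-diffusion (ISD) model: given the potential
of mean force $w(z)$ (the free-energy profile of the permeant's centre of
mass along the membrane normal, anchored to zero in bulk water) and a
position-dependent diffusivity $D(z)$, the permeability of one fixed
chemical state of the molecule is

$$\frac{1}{P} \;=\; \int_{z_1}^{z_2} \frac{e^{+\beta w(z)}}{D(z)}\,dz,
\qquad \beta = (k_B T)^{-1}.$$

For ionizable molecules this *specific* permeability is defined per
ionization state, and the experimentally relevant quantity is the
pH-dependent *effective* permeability over all states.  Two limiting
protocols exist:

* **pH-partitioning** (protonation much slower than crossing):
  $P_\mathrm{eff} = \sum_s f_s P_s$, with $f_s$ the bulk equilibrium
  fraction of state $s$;
* **BWAP** (protonation much faster than crossing): the permeant diffuses
  on the Boltzmann-weighted average potential
  $e^{-\beta w_m(z)} = \sum_s f_s\,e^{-\beta w_s(z)}$, and $P_\mathrm{eff}$
  is the ISD integral of $(w_m, D_m)$.

The package implements both protocols, the microstate thermodynamics that
produces the $f_s$, kinetic-regime checks for liposomal assays, a
position-dependent diffusivity estimator for 1D trajectories, and a
synthetic-data generator so the whole pipeline runs — and is tested — with
no molecular-dynamics data.

The worked case throughout is tetracycline (TC), an antibiotic with three
titratable sites — the tricarbonyl (A), the dimethylammonium (B) and the
phenolic diketone (C) — whose eight protonation microstates group into four
macrostates of net charge +1, 0, −1 and −2.  The zero-charge macrostate
contains three tautomers: the uncharged neutral form (TC$_N$), the
zwitterion (TC$_Z$) and an alternative zwitterion (TC$_{Z'}$).

## Microstate populations

Macrostate fractions follow from the macroscopic pKas (3.33, 7.75, 9.61 for
TC) by sequential Henderson–Hasselbalch weighting.  Tautomer ratios within a
macrostate are pH-independent and require *microscopic* dissociation
exponents (pk); they follow from thermodynamic cycles in the ionization
graph.  With the model-compound estimates pk$_{21}$ = 5.97, pk$_{12}$ = 8.8,
pk$_{13}$ = 7.80 and the assumption pk$_{31} \approx$ pk$_{21}$,

$$f_N/f_Z = 10^{\,\mathrm{pk}_{21}-\mathrm{pk}_{12}} = 10^{-2.83},
\qquad
f_{Z'}/f_Z = 10^{\,\mathrm{pk}_{31}-\mathrm{pk}_{13}} = 10^{-1.83}.$$

```{r populations}
pops <- tc_populations(thermo(pH = 6))
pops
```

`ionization_model()` represents a general microstate graph; every
protonation edge carries a pk, microstate weights are
$10^{\gamma - n_H\,\mathrm{pH}}$ with $\gamma$ the pk sum along any path
from the fully deprotonated reference, and `validate_cycles()` verifies path
independence edge by edge.

**Design choice — completing the TC graph.**  Only four microscopic pks are
available from model compounds.  `tc_microstate_model()` fixes the remaining
edges by requiring exact thermodynamic-cycle closure *and* exact agreement
of the macrostate weight sums with the three macroscopic pKas.  This choice
is not unique at the level of individual charged-state tautomers (which the
pipeline treats as lumped proxies anyway), but it is the minimal completion
consistent with all printed constants, and it makes the full graph
reproduce the macroscopic titration exactly.

**Assignment sensitivity.**  `assignment_variants()` builds the same graph
under alternative microscopic assignments (swapping the B/C sites, or
naively equating microscopic with macroscopic constants in either order),
for sensitivity scans of $P_\mathrm{eff}$; misassigning macroscopic pKas
changes $f_N$ — and hence $P_\mathrm{eff}$ — by orders of magnitude, which
is why the variants are exposed as first-class models.

## Effective permeability

With the published specific permeabilities $P_N = 2.22\times10^{-2}$ and
$P_Z = 1.63\times10^{-8}$ cm/s, and the zwitterion's value standing in as
an upper-bound proxy for all charged macrostates and TC$_{Z'}$,

```{r peff}
tc6 <- thermo(pH = 6)
species <- list(
  species_input("TC_N", specific_permeability = 2.22e-2),
  species_input("TC_Z", specific_permeability = 1.63e-8),
  species_input("TC_Zp", proxy_of = "TC_Z"),
  species_input("+1", proxy_of = "TC_Z"),
  species_input("-1", proxy_of = "TC_Z"),
  species_input("-2", proxy_of = "TC_Z"))
effective_ph_partitioning(species, pops, tc6)
```

The neutral tautomer dominates even though its bulk fraction is only about
$1.4\times10^{-3}$: its specific permeability is roughly six orders of
magnitude larger than the zwitterion's.  `proxy_sensitivity_scan()`
quantifies the robustness of that conclusion to the proxy approximation,
and `ph_scan()` repeats the calculation across a pH grid.

### BWAP numerics

`bwap_potential()` evaluates $w_m$ with a log-sum-exp, so mixtures of very
unequal weights never overflow.  The defining reference for the BWAP
*effective diffusivity* is not reproduced in the source literature we
follow, so the package adopts local-Boltzmann-population weighting,

$$D_m(z) = \sum_s \phi_s(z) D_s(z), \qquad
\phi_s(z) = \frac{f_s e^{-\beta w_s(z)}}{\sum_t f_t e^{-\beta w_t(z)}},$$

which satisfies the required limits (a single state returns its own $D$;
a locally dominant state imposes its $D$).  In strongly mixed regions other
weightings are conceivable; the choice is surfaced here and in the result
object rather than hidden.

### Integration choices

The ISD integral uses the composite trapezoid rule on the merged native
grid of the two profiles: permeation profiles arrive pre-binned (0.2 Å is
typical), and a refinement check in the test suite confirms grid
convergence (re-gridding a smooth PMF from 0.1 Å to 0.01 Å moves $P$ by
less than 0.1%).  Default bounds are the full common profile extent; pass
`bounds` to integrate a narrower slab.  One unit conversion, 1 Å/ns = 10
cm/s, is applied exactly once at result assembly.

## Profile handling

Profiles are validated on construction (strictly increasing grid, finite
values, positive diffusivities).  `symmetrize()` reflects about the bilayer
midplane (off-centre grids are recentred by their midpoint), averages with
the mirror image and — for PMFs — re-anchors so the mean over the outermost
10% of each tail is zero; the per-point deviation from the mirror average
is returned as a convergence diagnostic, mirroring the error bars used for
finite-sampling asymmetry.  Diffusivity profiles are mirror-averaged
arithmetically by default (harmonic averaging is available; the literature
we follow does not state which is used).  `gradient_rmsd_convergence()`
implements the gradient-RMSD-vs-final-snapshot diagnostic for series of
profiles at increasing simulation time.

## Diffusivity inference

`infer_diffusivity()` replaces an external inference code with an in-house
maximum-a-posteriori estimator for classical (non-fractional) diffusion.
The model is the short-lag Euler–Gaussian propagator of the Smoluchowski
equation with known total potential $U$:

$$\Delta z \mid z \;\sim\; N\!\big((-\beta D\,U'(z) + D')\,\tau,\; 2D\tau\big),$$

with $D$ piecewise-constant on 1 Å bins (log-parameterized for positivity),
a Gaussian smoothness prior on adjacent $\Delta\log D$, analytic gradients,
L-BFGS-B optimization and curvature-based uncertainties.  Displacements are
taken at non-overlapping lags; samples *starting* within four step standard
deviations of a reflecting wall are dropped, so reflections are (with
overwhelming probability) absent from the retained data and — because
endpoints are never used for trimming — no censoring bias is introduced.
Guidance on the lag: it must be long enough that the Markovian propagator
applies, yet short enough that steps rarely span a bin; the estimate's
diagnostics report the mean step size per bin width.

`msd_oracle()` provides an independent mean-squared-displacement estimate
for effectively unbiased trajectories, used as a cross-check in the tests.
The estimator protocol mirrors the inverse-PMF trick (`inverse_bias()`):
biasing with $-w(z)$ flattens the landscape so all bins are visited.

## Synthetic data: what it emulates and what it does not

`make_w_pmf()` builds "W-shaped" permeation PMFs — bulk plateaus,
interfacial wells, central barrier — from Gaussian basis functions whose
amplitudes are solved so the landmark values are hit exactly;
`make_diffusivity()` builds smooth positive profiles with a membrane dip;
`simulate_langevin()` integrates the overdamped Itô dynamics (with the
explicit $D'$ drift term, so the stationary density is Boltzmann even for
position-dependent $D$) with a compiled inner loop and reflecting
boundaries; `make_tautomer_model()` generates exactly cycle-consistent
random ionization schemes with known ground-truth weights; and
`crossing_permeability()` counts complete membrane traversals at
equilibrium as a flux-based cross-check of the ISD integral.

The default "tc-like" fixture (`tc_like_species()`) uses the published
landmark values — central barriers 4.5 and 13.6 kcal/mol, interfacial wells
−4.9 and −2.1 kcal/mol at ±14 Å — and calibrates the diffusivity scale of
each tautomer by 1D root-finding so its ISD permeability matches the
published specific value exactly.  The fixture therefore reproduces
*landmarks and integrated permeabilities*, not the unknown full curve
shapes between them; conclusions that depend on fine profile shape (e.g.
local flux decomposition) are outside what these fixtures can validate.
Likewise, the Langevin surrogate emulates 1D diffusive dynamics with known
$(w, D)$ — it contains none of the orientation, hydrogen-bonding or
membrane-deformation physics of real all-atom sampling, so passing tests
demonstrate the correctness of the estimators and protocols, not the
realism of any particular profile.

Problem sizes in the test suite were chosen so the estimators' stated
tolerances are comfortably resolved: $10^6$-step trajectories (lag 10, so
$10^5$ displacement samples) for parameter recovery within 10–15%, and
eight $10^6$-step trajectories for the crossing-count versus ISD agreement
within two standard errors at a 1 kcal/mol barrier.

## Kinetic-regime checks

For liposomal fluorescence assays, `classify_regime()` compares the
permeation rate implied by the apparent permeability, $k = 6P_\mathrm{app}/d$
(liposome diameter $d$), with order-of-magnitude protonation rates
$k_\mathrm{on} = k_0 10^{-\mathrm{pH}}$ and
$k_\mathrm{off} = k_0 10^{-\mathrm{p}K_a}$, $k_0 = 10^{10}$ M$^{-1}$s$^{-1}$.
Treating $10^{-\mathrm{pH}}$ as a molar concentration is deliberate and
standard for this estimate; the result is a regime classification (default
margin 10×), not a quantitative rate model.

```{r kinetics}
classify_regime(pH = 6, pka = 7.75, p_app = 10^-5.86, diameter = 167.7)
```

## Known limitations

* Tautomer structure of the charged macrostates is lumped unless the user
  supplies it; the proxy mechanism bounds, but does not resolve, their
  individual contributions.
* The BWAP effective diffusivity weighting is a documented choice, exact in
  the single-state and local-dominance limits only.
* The diffusivity estimator is classical; anomalous (fractional) diffusion
  is out of scope.
* Profiles are one-dimensional; multidimensional reaction coordinates and
  membrane finite-size effects are not modelled.
* pH is treated as exact (no activity corrections).
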