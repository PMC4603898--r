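---
title: "The charge-space competition model of cation-channel selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The charge-space competition model of cation-channel selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscmc)
```

## The model

Biological cation channels discriminate between Na⁺, K⁺ and Ca²⁺ in a
short, narrow stretch of the conduction pore, the *selectivity filter*
(SF).  `cscmc` implements a charge–space competition (CSC) model of this
region: selectivity emerges from the competition between electrostatic
attraction to the charge sites lining the filter and hard-sphere volume
exclusion in the confined pore, with no attractive non-electrostatic terms
and no parameters tuned against measured selectivities.

The configurational energy is

$$H = U_C + U_{IC} + U_{mob} + U_{cp} + U_{overlap}$$

* **U_C** — pairwise Coulomb energy of all point charges (mobile ions and
  pore-wall atoms) in a uniform aqueous dielectric (relative permittivity
  80 at 298.15 K; the Bjerrum length is `bjerrum_length(80)` ≈ 7.0 Å).
* **U_IC** — the energy of the polarization charge induced on the sharp
  dielectric boundary between the aqueous region (ε = 80) and the protein
  body (ε = 10), solved by boundary-element collocation (see below).
* **U_mob** — harmonic localization of the wall atoms about their
  crystallographic positions, with per-axis spring constants
  `k = 8π²/B` kT/Ų from the X-ray B-factor (so an equilibrated atom
  reproduces the experimental mean-square displacement).
* **U_overlap** — hard-body exclusion: no two spheres may overlap, and no
  sphere may penetrate the protein body, the membrane or the cell wall.
  Touching (centre distance exactly equal to the radius sum) is allowed;
  the contrary convention would distinguish a measure-zero set and invites
  floating-point equality traps.
* **U_cp** — the chemical-potential term of the grand-canonical (μVT)
  ensemble.  Only μN differences are observable in μVT sampling, so this
  term is book-kept inside the Monte Carlo acceptance ratios rather than
  in the stored energy.

### Geometry

The simulation cell is a cylinder split by a virtual membrane at z = 0;
the protein is a flattened toroid embedded in the membrane whose narrow
central section (radius `sf_radius`, half-length `sf_half_length`)
surrounds the SF, and whose surface is the dielectric boundary.  Circular
arcs of configurable radius (`arc_radius`, default 5 Å) join the SF
cylinder smoothly to the flat membrane faces; published sensitivity work
found the exact boundary dimensions to have little influence, so the arc
radius is exposed in the configuration rather than fitted.  The SF
boundary-cylinder radius follows a sizing rule: maximal radial wall-atom
extent + hard radius + 0.1 Å, which maximizes wall-atom freedom while
keeping solutes from slipping between the wall spheres and the surface.
The pore through the toroid is the only aqueous connection between the two
half-cells; the axis convention is z along the pore with the extracellular
side at z > 0.

### Induced-charge electrostatics

With all free charges in the ε = 80 region, the polarization surface
density h on the boundary satisfies the collocation equations

$$h_j = \chi\Big[\sum_i \tfrac{q_i}{\varepsilon_w}
  \tfrac{\mathbf n_j\cdot(\mathbf s_j-\mathbf r_i)}{|\mathbf s_j-\mathbf r_i|^3}
  + \sum_{k\ne j} h_k a_k
  \tfrac{\mathbf n_j\cdot(\mathbf s_j-\mathbf s_k)}{|\mathbf s_j-\mathbf s_k|^3}\Big],
  \qquad \chi = \frac{\varepsilon_p-\varepsilon_w}
  {2\pi(\varepsilon_w+\varepsilon_p)}$$

with flat-patch self-terms omitted, and
$U_{IC} = \tfrac12\sum_i q_i\,\phi_{ind}(\mathbf r_i)$.  The
patch–patch influence matrix depends only on the geometry, so its dense
inverse is built once per run (`assemble_icc_operator()`) and every Monte
Carlo move re-solves with an O(patches²) matrix–vector product on
incrementally updated right-hand sides.  The solver is validated against
the closed-form image-charge energy of a charge above a planar ε = 80/10
interface (`planar_image_energy()`): the default meshes agree to better
than 1% for separations of two patch lengths and more, and the error
decreases monotonically under refinement.  Mesh rings are graded — fine
near the SF, growing geometrically outwards but capped at ~12% of the
local radius, because wide outer rings under centroid quadrature leave a
systematic energy bias.

### The hydration model

Each cation species is split into discrete hydration states x = 0..6
(retained first-shell waters).  Three ingredients:

1. **Populations.**  The bulk fraction of state x is the Boltzmann factor
   of the experimental stepwise dehydration free energy,
   `factor(x) = exp(-ΔG_x)`, normalized to 1 at full hydration.  The
   packaged table (`default_species_table()`, shipped as
   `extdata/hydration_states.tsv`) carries K⁺, Na⁺ and Ca²⁺.
2. **Gate sizes.**  Each state is a hard sphere whose diameter is the
   cross-section the ion-plus-waters cluster occludes moving along the
   pore axis (a "gate size", not a hydrodynamic diameter).  Two waters are
   assumed to sit on the pore axis and leave last; the other four occupy a
   perpendicular plane.  Hence d(x=6) = 2(r_MO + r_OO/2) from solution
   radial-distribution distances, d(x=5) = d(x=6) (removing one planar
   water does not shrink the circumcircle), and d(x≤2) is the bare ion
   diameter.  The x = 4, 3 circumcircle values are shipped as data rather
   than recomputed: the printed values are not reproduced by the naive
   hard-disc enclosing-circle construction, and the exact construction is
   not derivable from the available description, so recomputing them would
   amount to guessing.
3. **State selection and rescaling.**  Only states that fit through the SF
   bottleneck (`sf_min_accessible_diameter()`) can contribute inside the
   filter.  The largest fitting x is admitted together with consecutively
   lower states whose populations lie within three orders of magnitude
   (`select_states()`; the window and its reference — the admitted maximum
   or the cumulative sum — are configuration choices, and explicit state
   lists are supported).  Because the simulated bulk then carries only a
   sub-population, selectivities are corrected by the rescaling factor
   `rescaling_factor()` = (sum of included factors)/(sum of all factors).

The hydration-swap Monte Carlo move exchanges a cation's state in place —
a grand-canonical deletion concatenated with an insertion at the same
location, accepted with probability `min(1, exp(Δμ − ΔH))`; volume and
count factors cancel.  Because the charge and position are unchanged, ΔH
reduces to the hard-core test of the new diameter.

### Grand-canonical sampling

`csc_run()` performs Metropolis μVT sampling with displacement,
insertion, deletion and swap moves (default mix 80/5/5/10; the published
description does not state a move mix, so these are logged defaults, and
the displacement step is tuned towards ~40% acceptance during the first
part of equilibration, then frozen so detailed balance is exact).
Chemical potentials use the Λ-free convention μ = ln(ρ·Å³) for an ideal
gas; only μ differences and μ − ln ρ are observable, so the convention is
internal.  Within a species, state chemical potentials differ by
ln(factor ratios), which enforces the bulk population table by
construction.  `calibrate_mu()` adjusts the per-species offsets until the
concentrations measured in an interior bulk sampling region (away from
hard walls, where layering artefacts live) match their targets within 2%.
Counter-ions (default: 3.6 Å monovalent hard spheres, a configuration
default since no anion parameters are published) make the nominal
composition electroneutral; the instantaneous cell charge fluctuates as
usual in μVT and its mean is reported per run.

Insertion positions are drawn uniformly over the cell with rejection at
the hard walls.  Optionally a fraction `sf_bias` of insertion/deletion
proposals is restricted to a cylindrical window around the SF; the
acceptance ratio uses the exact mixture proposal density, so detailed
balance holds for any bias (verified by an ideal-gas equation-of-state
test with the bias on).  The bias is off by default and exists because
admitted partial-hydration states can have bulk concentrations of order
10⁻⁶ mol/L: unbiased insertions would essentially never place them in the
filter on accessible run lengths.

Every run is reproducible from (system, arguments, seed); accumulators
(axial histograms per species and state, particle-number samples,
bulk-region counts) carry block structure for Monte-Carlo standard
errors, and RDS checkpoints restore bit-identically.  A periodic
consistency check recomputes all cached energy components from scratch;
the maximum relative deviation is reported with the run (typically
~10⁻¹⁵, asserted < 10⁻⁸ in the tests).

### Selectivity estimation

Axial concentration profiles (`density_profile()`) are counts per sample
divided by the accessible aqueous slab volume of each 0.1 Å bin — the
ratio estimators below cancel the volume convention, but absolute profiles
need a declared one.  Profiles are smoothed by a 2 Å moving average
(`smooth_profile()`), and the rate-determining barrier of each ion is the
profile minimum inside a per-channel window (`profile_min()`).  Under a
single-barrier passage model the predicted selectivity of ion A (the
channel-selected ion, listed first) over B is

$$\hat\alpha_{sim}
  = \frac{[A\!\cdot\!X]_{min}/[A^{\lceil n\rceil}]_{bulk}}
         {[B\!\cdot\!X]_{min}/[B^{\lceil m\rceil}]_{bulk}},\qquad
  \alpha_{hyd} = \frac{\mathrm{rescale}(A)}{\mathrm{rescale}(B)},\qquad
  \alpha_{sim} = \alpha_{hyd}\,\hat\alpha_{sim},$$

the barrier enrichment ratio corrected for the bulk sub-populations.  The
orientation is fixed so that the selected ion scores α > 1 (e.g.
α_hyd(Na⁺ vs K⁺, states {4,3}) ≈ 0.3 and the Na channel overcomes it with
α̂ > 1/0.3).  Bulk terms default to the configured targets; measuring
them from the far field is a configuration switch, appropriate when the
far field is well sampled.  A window with no counts reports the 95%
Poisson upper limit instead of zero, turning the selectivity into an
explicit one-sided bound rather than an infinity.  Replicate runs are
combined by inverse-variance weighting of their profiles
(`aggregate_runs()`), with between-replicate spread as the uncertainty.

## What the synthetic channels emulate

`build_toy_channel()` generates fully synthetic test channels:

* `neutral-pore` — a KcsA-like carbonyl-lined pore (3 rings of 4 oxygens,
  charge −0.1 e each, 3.1 Å bottleneck): only dehydrated cations fit.
* `charged-pore` — a NavAb-like filter: an EEEE-like ring of four
  carboxylate oxygens (−1 e) above two carbonyl rings, 5.6 Å bottleneck.
  The carbonyl rings sit slightly wider than the charged ring so that the
  high-field locus alone gates the pore; this keeps the rate-determining
  barrier below the site sterically open enough to accumulate counts on
  short runs.  Under the state-selection rule Na⁺ passes as Na·4H₂O
  (5.44 Å) while K⁺ must strip to K·3H₂O (5.54 Å) — K·4H₂O (6.21 Å) does
  not fit, which is the partial-dehydration mechanism of bacterial Na⁺
  channel selectivity.
* `wide-pore` — a CavAb-like filter: a carboxylate ring in a 9.2 Å pore
  where every species remains fully hydrated and selectivity is pure
  charge–space competition (divalents win the charged site).

These toys reproduce mechanisms, not published channels: the published
per-channel SF coordinates are not packaged, so the quantitative
selectivities of real structures (which additionally require long,
aggregated runs to converge the rare-state density minima) are out of
reach of the test suite.  What the passing smoke tests show is the sign
and ordering of selectivity on desk-scale runs — Na⁺ over K⁺ in the
charged pore, Ca²⁺ over Na⁺ in the wide pore — with the full pipeline
(geometry, ICC, hydration states, GCMC, density analysis) engaged.  The
smoke runs use 2 mol/L (Na/K toy) and 0.1 mol/L (Ca/Na toy) baths; the
high concentration in the first case is the condition under which the
barrier region of a rare-state simulation accumulates measurable
statistics at 3×10⁵ steps.  Real data differ in ways the generator does
not emulate: non-axisymmetric pore walls, anisotropic B-factors (the
isotropic conversion is implemented; anisotropy is an extension),
structural water, and attractive non-electrostatic interactions — whose
absence is a model limitation that published work found decisive for
quantitative K⁺-channel selectivity.

## Numerical choices

* Patch meshes: exact band areas of the surface of revolution (total mesh
  area matches the closed form), azimuthal count scaled with the patch
  scale, dense LU-inverted influence matrix, solver residual checked
  against a 10⁻⁸ tolerance.
* Energy bookkeeping: single-particle Coulomb updates, full ICC re-solve
  per move from cached right-hand sides; caches refreshed (and audited)
  every 5000 steps.
* Degenerate inputs: occluded pores return a zero bottleneck with a
  warning; species whose states all fail to fit are excluded from the SF
  but warned about, not dropped silently; coincident point charges are an
  error because the hard-core terms should have prevented them.
* Problem sizes in the test-suite: sampling checks use 4×10⁴–1.5×10⁵
  steps in small cells (chosen so three Monte-Carlo standard errors
  resolve the tested effects), the image-charge oracle ~900 patches, and
  the two smoke runs 3×10⁵ and 1.2×10⁵ steps.

## Known limitations

* No attractive non-electrostatic interactions: K⁺-channel selectivity
  orders (Tl⁺, Rb⁺, NH₄⁺) are outside the model's scope by design.
* No membrane voltage, no explicit water, spherical non-polar hydrated
  clusters, isotropic tethers.
* Finite-size effects: with only rare partial-hydration states admitted,
  a charged filter is not fully screened and the cell carries a net
  monopole; bulk terms taken from configured targets avoid the resulting
  far-field bias, and the mean cell charge is logged per run.
* The collocation ICC solver loses accuracy for charges closer than about
  one patch length to the boundary; the sizing rule keeps mobile ions
  farther than that except at hard contact.
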