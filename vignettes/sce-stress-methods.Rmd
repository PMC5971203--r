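---
title: "Estimating membrane stored curvature elastic stress from lipidomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating membrane stored curvature elastic stress from lipidomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsce)
library(dplyr)
```

## Scope and model

`lipidsce` turns species-level lipid quantification tables into two
estimates of membrane stored curvature elastic (SCE) stress:

1. **τ, the lipid contribution.** Lipid monolayers have a spontaneous
   curvature `C0 = 1/R0`, measured at the pivotal plane (the point along
   the molecule whose area is unchanged on bending). Under ideal additive
   mixing, a mixture's curvature is the mole-fraction-weighted mean of its
   components' `C0`, and the stress stored by flattening that monolayer
   into a bilayer leaflet is `τ = −2 K_M C0,mix`. We treat the monolayer
   bending modulus as a single average constant, `K_M = 5.0e-20` J,
   because `K_M` varies far less across lipids than `C0` does; per-species
   moduli are out of scope.

2. **P_SCE, a proxy of total cellular SCE stress.** τ ignores proteins.
   P_SCE instead weights each lipid with a coarse-grained factor `w`
   absorbing, in a data-driven way, both lipid and protein contributions:
   `w = head_term(class) + unsat_increment × double bonds`. Species are
   partitioned against a pivot lipid — PE 34:1, with weight `w_Lp` — into
   *type II* (`w > w_Lp`, stress-raising) and *type 0* (`w ≤ w_Lp`), and

   `P_SCE = Σ_n w_n [L_II,n] / Σ_m (1/w_m) [L_0,m]`.

   The ratio is homogeneous of degree zero in the amounts, so
   concentrations may be supplied in nmol or mol% interchangeably — the
   package exploits and tests this.

Both metrics sit downstream of a standard internal-standard quantification
step (`areas_to_amounts()`): a single-point, one-standard-per-class
response model, `amount = area / area(standard) × spiked amount`, which is
all that class-matched deuterated spikes support. Calibration curves and
per-species response factors are deliberately not modelled.

## Parameters that matter

* **The C0 table** (`default_c0_table()`), in inverse meters (readers
  accept inverse nanometers with a unit tag). Each row carries a
  provenance note. The shipped values are rounded literature-scale numbers
  for the dioleoyl / palmitoyl-oleoyl series — e.g. PE(16:0/18:1) at
  −0.316 nm⁻¹, PC(16:0/18:1) at −0.022 nm⁻¹, DAG(18:1/18:1) at −0.99 nm⁻¹
  — plus analogy estimates (marked "estimate" in their provenance) for
  anionic-lipid chain variants that lack measurements. None of these are
  canonical: the table is an editable parameter file
  (`read_c0_table()`/`write_c0_table()`), and every τ result records which
  entry served each species and whether the match was exact, a fallback,
  or speculative.

* **Fallback lookup.** Measured lipidomes always contain species without a
  measured `C0`. The rule: among same-class entries with the identical
  per-chain double-bond multiset, use the one with the smallest absolute
  difference in total carbons; break remaining ties toward the shorter
  chain so the choice is deterministic. PI has no measured curvatures at
  all; it is excluded from the default variant and only enters sensitivity
  runs through an explicitly speculative class-level default (−0.05 nm⁻¹,
  near the middle of the phospholipid entries).

* **Class-inclusion variants** (`sce_variant()`). Default τ classes:
  {PC, PE, PS, PA, PG}. PI is excluded for lack of parameters; DAG and TAG
  because they predominantly reside in lipid droplets rather than bilayer
  membranes. `sensitivity_analysis()` recomputes the τ series under named
  alternates and flags whether the sign pattern of successive differences
  (the reported trend) is preserved.

* **The w model** (`psce_params()`). Constraints taken as fixed:
  unsaturation increases `w`; the small PE head group outweighs PC's; the
  pivot is PE 34:1; TAG is excluded (droplets) and PG excluded (no
  parameters); default classes {PC, PE, PS, PA, PI, DAG}. Within those
  constraints the shipped coefficients were chosen once, a priori, so that
  (i) one double bond crosses the pivot boundary — making mono- vs
  di-unsaturated species the operative distinction in yeast membranes,
  where 32:1/34:1 vs 32:2/34:2 shifts are the dominant acyl remodelling —
  and (ii) the absolute scale of `w` puts P_SCE of a typical yeast
  membrane composition in the 0.1–0.2 window reported for this metric.
  The scale matters because P_SCE ∝ w² under a uniform rescaling of all
  coefficients, so the published range pins the coefficient magnitude
  (≈0.2–0.5) rather than any individual value. The coefficients are
  flagged non-canonical; `calibrate_w()` implements the published
  selection principle (minimum P_SCE variance across cell populations
  over a finite grid, ties to the first row).

* **Denominator reading.** Printed renderings of the ratio control
  function are typographically ambiguous between `Σ (1/w_m)[L_0,m]` and
  `Σ w_m [L_0,m]`. We default to the inverse-weight reading — it makes
  strongly type-0 lipids count more in the stabilizing pool — but retain
  `denominator_mode = "direct_weight"` as a switch rather than hard-coding
  an interpretation.

* **Chain assignment.** Both the fallback lookup and the w model need
  per-chain unsaturation, while measured species are sum compositions
  (e.g. "PE 34:2"). A configurable `ChainAssignmentTable`
  (`default_chain_table()`) resolves this with the common yeast acyl pairs
  (16:0, 16:1, 18:0, 18:1): 32:1 → 16:0/16:1, 34:1 → 16:0/18:1,
  34:2 → 16:1/18:1, and an even-split rule for entries outside the table.
  This is an implementer convention — no lipidomics method of this type
  resolves sn-positions — and is documented as such; users with
  chain-resolved data can supply species in the per-chain grammar
  (`"PC(16:0/18:1)"`) and bypass it entirely.

* **Internal standards.** The spiked amount per standard is a required
  experimental configuration (`standard_config(spike_nmol = ...)`):
  protocols state standard concentrations in mass units and the µg→nmol
  conversion depends on the exact compound, so no constant is built in.
  Classes without a spiked standard (PS, PI, PA, PG, DAG in the default
  panel) are quantified against a configurable surrogate map (PC for the
  anionic phospholipids, TAG for DAG) and the standard used is recorded in
  the output.

## The synthetic generator

Choline-rescue lipidome datasets of the kind this pipeline targets are
rarely deposited in public repositories (values typically appear only as
figure bars), so validation runs on a synthetic generator that emulates
the experiment's statistical structure: PC near zero at t = 0 rising after
choline addition; PE elevated then falling; PS slightly depressed then
rising; TAG elevated then falling; PI, PA and DAG flat and low; PE 32:1
and PS 32:1 near 30 mol% of their class at t = 0, falling with a
compensatory 34:2 rise. Defaults: time points {0, 2, 4, 8, 24} h (figure
axes of such experiments are typically on this kind of grid; the grid is
configurable), 3 replicates, total lipid 400 nmol per 50 mg biomass.

Design choices:

* **Kinetics.** Saturating single-exponential approach to the post-rescue
  steady state (half-time 4 h for every class by default). This is the
  simplest shape consistent with the gradual recovery such experiments
  show, not a mechanistic claim about the CDP-choline pathway. Class
  targets sum to 100 mol% at both endpoints; interpolated compositions are
  renormalized so expectations sum to 100 at every time.

* **Noise.** Multiplicative lognormal with mean 1 (CV 0.15 by default):
  amounts are positive and replicate scatter grows with the mean, matching
  mean ± SD error bars in this kind of data. The mean-one construction
  makes noisy samples unbiased for the ground-truth expectations, which
  the Monte-Carlo tests rely on.

* **Peak simulation.** `generate_peak_table()` inverts the quantification
  model with per-class response factors and optional response noise, so
  quantification round-trips exactly at zero noise. Because analytes of a
  class share their standard's noise draw, recovered amounts have a small
  positive bias of `exp(s²) − 1` (≈1% at CV 0.1) from the `1/noise` term —
  the tests budget for this rather than pretend it away.

What passing tests on this generator do **not** show: correctness on real
chromatography (no drift, adducts, in-source fragmentation, or missing
species are simulated), on lipidomes whose acyl pairing deviates from the
default chain table, or on organisms whose lipid classes fall outside the
closed class enumeration.

## Numerical choices and degenerate inputs

* Classification at the pivot boundary is `w > w_Lp` strictly: equality —
  including the pivot itself — is type 0. Tests construct the boundary
  through the same floating-point expression to keep the check exact.
* Compositions with no positive included amount, a zero class total in
  within-class mol%, zero total PE in the PC/PE ratio, a missing or zero
  internal-standard area, and a P_SCE denominator of zero are all loud
  errors naming the sample/class — never silent NA or drops. Unknown
  class codes fail parsing for the same reason: silently dropping species
  would bias every mol% denominator.
* mol% outputs are guaranteed to sum to 100 within 1e-9; the mixing rule
  is exact weighted-mean arithmetic, bounded by the min/max of the used
  `C0` values, and `τ = −2 K_M C0,mix` is computed as that literal
  expression so the identity holds bit-for-bit.
* `calibrate_w()` evaluates a finite user grid in order and takes the
  first variance minimum — no stochastic optimizer, so results are
  reproducible by construction.

## Statistics

Group comparisons follow the conventions of this experimental literature:
mean ± SD summaries; two-tailed pooled-variance (Student) two-sample
t tests; one-way ANOVA with Bonferroni-corrected pairwise comparisons
(`p_adj = min(1, p × m)` over all `m` pairs — no contrast subset is
assumed), significance at p < 0.05 with the usual star tiers. With two
groups the ANOVA omnibus p equals the pooled t test p and no correction is
applied. `run_report()` tests each metric across the full time series with
per-pair adjustment (rather than per time point), and documents that
choice in its output; with fewer than two replicates per time point the
statistics section is empty rather than approximate.

## Problem sizes

The shipped tests and the acceptance script use the default scenario (5
time points × 3 replicates × 21 species), 200-replicate Monte-Carlo checks
for generator calibration and quantification bias, 1000 random mixtures
for the mixing-rule oracle, 300 randomized tables for the fallback oracle,
and 1000 null simulations for the type-I-error check — sizes chosen so the
whole suite characterizes every stage while remaining quick to run on a
laptop.

## Known limitations

* Ideal additive mixing is first-order: no curvature–composition coupling,
  leaflet asymmetry, or electrostatic corrections for charged head groups
  beyond whatever the tabulated `C0` values embed.
* The w model is linear in double bonds and head-group identity only;
  chain length, branching and cholesterol context are not terms.
* Shipped C0 values and w coefficients are defensible defaults, not
  measurements; conclusions about absolute stress magnitudes should be
  drawn only after substituting values appropriate to the system at hand.
* The species grammar covers sum compositions and simple per-chain
  notation with isotope suffixes; ether lipids, sphingoid-base detail and
  sn-stereochemistry are out of scope.
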