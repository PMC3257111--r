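---
title: "Molecular-field QSAR in qsar3d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-field QSAR in qsar3d: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar3d)
```

# The modelling problem

`qsar3d` implements ligand-based 3D-QSAR for congeneric small-molecule
series: a set of compounds sharing a scaffold, each with a measured
binding affinity Ki, from which one learns a spatial model of where
steric bulk, charge, lipophilicity or hydrogen-bonding capability around
the scaffold raises or lowers potency. The motivating application is a
series of N-substituted spiropiperidine agonists of the NOP receptor
(103 compounds, affinities spanning roughly 0.3–824 nM, i.e. about
3.4 pKi units), but nothing in the code is series-specific.

The method rests on three assumptions worth stating explicitly:

* **a common binding mode** — all compounds are assumed to bind the same
  site the same way, so that a single rigid superposition onto a template
  makes their surroundings comparable;
* **field–activity linearity** — pKi is modelled as a linear function of
  probe-field values sampled on a lattice around the aligned set;
* **conformational adequacy** — the supplied 3D structures are taken as
  given. The package performs no geometry optimisation or conformer
  search; if the input poses are poor, the fields and everything
  downstream inherit that error.

# Activities

Affinities enter as Ki in nM (the unit is fixed by the file format) and
are converted to `pKi = -log10(Ki * 1e-9)`. The train/test split
(`split_train_test()`) keeps a requested number of training compounds and
draws the test compounds one per equal-frequency pKi bin, so test
activities cover the whole observed range — a split that is "random but
uniform over the activity range". The bin rule is a design choice; any
assignment satisfying the partition and coverage properties would do. A
4:1 split (81 of 103 in the motivating series) is the default.

# Charges

Where the input carries no partial charges, `assign_charges()` computes
classic PEOE (partial equalization of orbital electronegativities,
Gasteiger–Marsili) sigma charges: per-atom electronegativity
χ(q) = a + bq + cq², with charge flowing across each bond from the less
to the more electronegative atom, scaled by the donor's cation
electronegativity (20.02 for hydrogen) and damped by 2⁻ⁿ at iteration n.
Twelve iterations leave the damped series converged far below the 10⁻³ e
documentation tolerance. The historical "Gasteiger–Hückel" variant adds a
Hückel π-charge correction; that correction is small for mostly saturated
scaffolds and its exact published form is not reproducible, so the
package implements the PEOE part only and says so here. Parameters cover
H, C, N, O (by hybridisation state inferred from bond orders), S, P and
the halogens; an element outside the table is a hard error naming the
element.

# Alignment

`kabsch_superpose()` solves the least-squares rigid superposition via the
singular value decomposition of the mapped-atom cross-covariance, with
the usual determinant correction to exclude reflections. Atom maps are
explicit input (two-column text files, 0-based), which keeps the
alignment deterministic and auditable; automatic maximum-common-
substructure detection is deliberately out of scope. Fitting is rigid —
no torsional relaxation. Maps need at least three non-collinear reference
atoms; collinearity is detected when the second singular value falls
below 1e-8 of the first. Externally produced poses (e.g. docked ones) can
bypass alignment entirely by supplying already-aligned coordinates.

# Lattice and fields

`build_grid()` spans the aligned set with an axis-aligned lattice:
origin at `min(coord) − margin`, `ceiling(span/spacing) + 1` points per
axis. Defaults: spacing 2 Å (the standard coarse CoMFA/CoMSIA lattice)
and margin 4 Å. Points are enumerated x-fastest, then y, then z, which
fixes descriptor column order bit-reproducibly.

**CoMSIA** (`comsia_field()`): the Gaussian similarity index
A = −Σᵢ ω_probe ω_ik exp(−α γ²) with attenuation factor α = 0.3 Å⁻² and
probe weights +1 for every property. No cutoff is applied — the Gaussian
decays smoothly, which is the method's point. The probe "radius" of
1 Å is recorded as metadata only; the formula does not use it. Per-atom
property weights ω_ik follow the conventional choices: steric = van der
Waals volume relative to carbon, electrostatic = partial charge,
hydrophobic = element-based increments, donor/acceptor = 0/1 by rule
(N/O with H for donors; N/O with a lone pair for acceptors, excluding
four-coordinate N). The element tables ship as editable CSVs under
`inst/extdata/`; the hydrophobic increments are deliberately coarse
(element-level, not atom-type-level) — adequate for field topology, not
for logP prediction.

**CoMFA** (`comfa_fields()`): Lennard-Jones 6-12 steric energies of an
sp³-carbon probe (Tripos-style vdW table, Lorentz radius combination,
geometric-mean well depth) and Coulomb electrostatics
332·q·q_probe/(D(r)·r) with D(r) = r by default (constant dielectric is a
switch). Both fields clamp at ±30 kcal/mol. At lattice points where the
steric term saturates the positive cutoff — i.e. inside the molecular
core — the raw Coulomb value is meaningless, and `field_block()` replaces
it with the column mean over the molecules not at cutoff (zero if none),
preventing PLS from fitting in-core noise.

**Descriptor assembly** (`assemble_descriptor_matrix()`): columns with
standard deviation below the block's minimum-sigma threshold are dropped
(2.0 kcal/mol for CoMFA blocks, 0 for CoMSIA blocks; exactly constant
columns are always dropped since they carry no information), then each
retained block is rescaled to unit total variance so no field dominates
by units alone — block-level standardisation in the spirit of
"CoMFA standard scaling". With a train/test split, filtering and scaling
statistics come from the training rows only (`fit_rows`), avoiding
information leakage into test predictions.

# PLS modelling and validation

`pls_fit()` implements single-response NIPALS: weights from the
covariance X'y, scores, loadings, and deflation, on column-centred X and
centred y. y is never rescaled and X columns are not individually
autoscaled — variance information is what stdev\*coeff maps display, so
only the block-level scaling above is applied. Coefficients are recovered
as B = W(PᵀW)⁻¹q. Numerical guards: a weight or score norm below
1e-12 of the data scale means the requested component count exceeds the
effective rank and is a hard error; a constant response is rejected.

Validation statistics follow the standard QSAR definitions:

* **Q²** = 1 − PRESS/SD, with PRESS from genuine leave-one-out refits
  (centering recomputed per fold) and SD about the full training mean.
  The multi-component form extracts predictions for every component count
  from one sequential fit per fold, which equals per-count refitting
  exactly because NIPALS components are nested — a property the tests
  assert bit-for-bit.
* **R²_ncv** = 1 − RSS/SD, **SEE** = √(RSS/(n − c − 1)).
* **F** is reported in its degrees-of-freedom form
  (R²/c)/((1 − R²)/(n − c − 1)); the dimensionless ratio R²/(1 − R²) is
  also emitted (`f_ratio`) for comparability with tables that print it
  without degrees of freedom.
* **SEP** = √(PRESS/(n − c − 1)), the cross-validated analogue of SEE.
* **R²_pred** = (SD − PRESS)/SD on a test set, SD about the *training*
  mean — the external predictivity statistic.
* **Field contributions**: Σ|bⱼ|·sd(xⱼ) per field, normalised to 1.

`model_search()` evaluates every non-empty subset of the supplied CoMSIA
blocks (31 combinations for five fields) plus the CoMFA steric+
electrostatic pair, choosing for each the component count that maximises
LOO Q² up to `max_components` (default 10), with ties broken toward fewer
components. Results are ranked by Q². Everything is deterministic.

# Contour maps

`stdev_coeff_field()` maps a model back to the lattice as
sd(column)·coefficient — the conventional quantity for CoMFA/CoMSIA
contours, since it weights a coefficient by how much that lattice point
actually varies across the series. `extract_contours()` applies the
"greater than 80% favored / less than 20% disfavored" levels. The exact
accounting behind commercial contour levels is proprietary, so the
convention here is explicit and configurable: the default min–max mode
rescales values to [0, 1] and applies strict thresholds (so a positively
skewed field maps its near-zero background into the disfavored set — a
known property of the convention, visible in the README example);
`mode = "percentile"` thresholds at the 80th/20th quantiles instead.
Levels are applied per field, not over the joint coefficient vector. A
constant field yields empty sets plus a degeneracy flag rather than an
error. Maps export as labelled CSV point lists and OpenDX grids.

# The synthetic-data generator

Public machine-readable structures for series like the motivating one do
not exist, so `generate_dataset()` provides a fully controlled stand-in
that emulates the *statistical* structure of an R-group series:

* a fixed scaffold cloud shared by all molecules (plus two fixed anchor
  atoms that pin the bounding box, hence the default lattice, to a common
  frame), making identity atom maps valid;
* ten fixed substituent attachment sites on a shell of radius ≈4.5 Å,
  positioned on even-integer coordinates so they coincide with default
  lattice points; each site is independently occupied (p = 0.5) by a
  substituent of 3–5 atoms jittered 0.4 Å around the site, with random
  property weights — mimicking how a medicinal-chemistry series varies
  substituents at numbered positions;
* activities from a planted sparse linear model: eight "hotspot" lattice
  points (each at a distinct site) of one property kind (steric by
  default) carry equal positive weights w, and
  pKi = intercept + Σ w·A + ε with ε ~ N(0, noise_sd²).

Defaults mirror the motivating study's scale: 103 molecules, signal
standard deviation 0.8 pKi units around a centre of 7.8, and noise
0.25 pKi units (the order of the fit standard errors such models print).
The weights are scaled so the noiseless signal has exactly the requested
spread, and the generator writes Ki = 10^(9−pKi) nM back to the activity
CSV, exercising the conversion round trip.

The geometry is a deliberate design for identifiability: with α = 0.3
and 2 Å spacing, a Gaussian field smears any point source onto the
neighbouring lattice columns with cross-talk exp(−1.2) ≈ 0.30, so a
planted single-point weight can only be resolved if per-site occupancy
contrast dominates the field variance and neighbouring columns
decorrelate through positional jitter. Sites on lattice points and
multi-atom substituents achieve both.

`recovery_report()` scores recovery in two parts. Predictive statistics
(Q², R²_pred) come from the field-combination search on a 4:1
activity-stratified split, exactly as the pipeline would run. Map
recovery — cosine similarity of fitted coefficients (mapped to the
lattice, block scaling undone) with the planted weights, and Jaccard
overlap of the favored contour with the planted support — is fitted on
the *full* dataset: the target there is the generative map, not held-out
prediction, so withholding a fifth of the data would only blur the
estimate. The map-recovery fit selects components by LOO Q² up to 20
rather than 10, because resolving correlated neighbour columns requires
more latent directions than prediction does; Q² is monotone-flat across
that extension, so the choice is consistent with the Q²-maximisation rule.
`permutation_q2()` provides the y-scrambling null: Q² recomputed under
random permutations of the activities at the real model's component
count.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: chemistry (atoms are weighted points;
elements are a formality), conformational flexibility and alignment
error, activity cliffs, correlated property weights within a substituent
(real substituents couple size, lipophilicity and charge), inter-site
correlation from synthetic accessibility, and any receptor. Recovery
results certify the statistical machinery, not chemical validity.

# Numerical conventions and degenerate inputs

* Lattice enumeration order is fixed (x fastest) and documented; exports
  reorder explicitly for formats with other conventions (OpenDX).
* SDF coordinates round-trip at the format's 1e-4 Å precision; partial
  charges and property weights persist in `PARTIAL_CHARGES` /
  `COMSIA_<KIND>` data fields.
* Records with zero atoms are collected in an error report, not fatal;
  duplicate compound ids are fatal.
* Rank-deficient PLS requests, constant responses, collinear alignment
  references, all-at-cutoff electrostatic columns, and constant contour
  fields each have a defined behaviour (error or flagged-empty result)
  asserted by tests.
* All stochastic procedures (split, generator, permutation null) take
  explicit integer seeds and restore the caller's RNG state.

# Problem sizes

The test suite and the acceptance script run the full machinery at
reduced but non-trivial sizes chosen as the package's own benchmark
conditions: the recovery study uses 60 molecules on an 11×11×11 lattice
(1331 points per field, five fields, 31-combination search with full LOO
inside), the permutation null uses 20 permutations, and the study-scale
run uses the generator's 103-compound defaults. These sizes exercise
every code path at meaningful multicollinearity (p ≫ n) while keeping a
complete run in the minutes range on one CPU.

# Known limitations

* Single-conformer, rigid-alignment fields; no region focusing or
  Boltzmann-weighted multi-conformer variants.
* PLS1 only (one response); no SAMPLS acceleration, bootstrap intervals,
  or progressive scrambling.
* The hydrophobic weight table is element-coarse, and the donor/acceptor
  rules are pattern-based, not electronic-structure-based.
* MOL2 reading covers the MOLECULE/ATOM/BOND sections (sufficient for
  charges, coordinates and connectivity), not the full format.
* Contour "percent" levels are a documented convention, not a
  reproduction of any vendor's proprietary accounting.
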