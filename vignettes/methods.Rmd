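---
title: "Models and methods: discriminating inter-holoenzyme phosphorylation from subunit exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holophos)
```

# The scientific question

CaMKII holoenzymes are dodecamers of kinase subunits held together by a
central hub domain. Autonomous kinase activity, established by
trans-autophosphorylation of T286, can spread between holoenzymes. Two
mechanisms have been proposed: exchange of subunits between holoenzymes, and
direct trans-autophosphorylation between intact holoenzymes (IHP). They are
hard to tell apart with any single measurement, but they make distinct
quantitative predictions across four assays, and this package implements
those four read-outs plus generators for synthetic data with known ground
truth. Everything below is about the *analysis layer*: the inputs are
quantified tables and image arrays, never raw spectra or movies.

# Kinetics: the two-component autophosphorylation model

Phosphorylation of an excess of substrate (kinase-dead) holoenzymes by an
enzyme (active) holoenzyme at concentration $c$ is modeled as

$$f(t) = 1 - A_1 e^{-r_1 t} - (1 - A_1)\, e^{-c\, k_2 t},$$

with $A_1 \in [0,1]$, $r_1 > 0$ in 1/min, $k_2 > 0$ in 1/(nM·min). The two
components encode the mechanistic dichotomy: a rate independent of enzyme
concentration (everything needed is inside one holoenzyme) and a rate
proportional to it (a second holoenzyme is a limiting reagent, as in IHP).
Constraining the amplitudes to sum to one makes $f(0)=0$ and
$f(\infty)=1$ on the normalized scale.

`fit_global()` shares $(A_1, r_1, k_2)$ across all concentrations and
minimizes the SD-weighted squared residuals. Choices that matter:

* **Weights.** Each (concentration, time) point is weighted $1/\mathrm{SD}$
  across replicates. An SD of zero (or a single replicate) is replaced by
  the median replicate SD of that curve; without such a floor, noiseless
  points would receive infinite weight.
* **Saturating concentrations.** At a concentration where the reaction
  saturates before the first sample (100 nM in the emulated design), the two
  components are not separable; listing it in `saturating` fixes $A_1 = 0$
  for that curve, reducing it to a single exponential with rate $c\,k_2$.
  Note that applying this to synthetic data generated from the full model is
  deliberate model mismatch; parameter-recovery checks therefore fit the
  matching (non-saturating) model.
* **Multistart.** Two-exponential least squares is multimodal. The
  optimizer (`minpack.lm::nls.lm`, Levenberg–Marquardt on transformed
  parameters $\mathrm{logit}\,A_1$, $\log r_1$, $\log k_2$) restarts from 5
  deterministic starts with $A_1 \in \{0.1,\dots,0.9\}$ and log-spaced
  rates; the best weighted residual wins.
* **Normalization.** Raw blot ratios arrive in arbitrary units. Each data
  set is first fitted with one- and two-exponential saturation curves and
  the AICc-preferred fit's plateau becomes the per-dataset normalization
  maximum (`estimate_curve_max()`, `normalize_curve()`), putting all curves
  on a common 0–1 scale before the global fit.

Simple saturation time courses (autoradiography-style read-outs) use the
Langmuir form $y(t) = y_{max}\, t/(t_{1/2} + t)$, whose half-time is a
parameter. For the two-component model, `half_time()` brackets by doubling
and bisects to $10^{-6}$ min; $A_1 = 1$ uses the closed form $\ln 2 / r_1$.
Degenerate parameter sets whose plateau never reaches one half raise a
domain error rather than returning an extrapolation.

# Crosslinking MS: the mixing ratio and domain heatmaps

Mixing light (¹⁴N) and heavy (¹⁵N, metabolically labeled) holoenzymes before
DSS crosslinking makes the isotope composition of each crosslinked peptide
pair report *which* holoenzymes touched: uni-isotopic (homotypic) pairs are
contacts within one preparation — overwhelmingly within one holoenzyme —
while mixed-isotope (heterotypic) pairs are contacts between differently
labeled holoenzymes. Each record carries four MS1 channel intensities, and
the per-crosslink mixing ratio is

$$R = \frac{I_{14N:15N} + I_{15N:14N}}{I_{14N:14N} + I_{15N:15N}}.$$

The denominator deserves a note: the equation as originally typeset reads
$I_{14N:14N} + I_{14N:15N}$, which contradicts the accompanying definition
of homotypic crosslinks as the two uni-isotopic channels. We default to the
prose-consistent homotypic sum and ship the typeset variant as
`denominator = "as_printed"`, so either convention is reproducible exactly.
$R$ is invariant to uniform intensity rescaling and, under the default
denominator, to swapping the light/heavy labels of both peptides at once.

Channel masses are pure arithmetic: the light–light pair weighs the two
peptides plus the DSS linker (138.068 Da), and each peptide's heavy shift is
0.997035 Da per nitrogen atom (`nitrogen_count()`, from residue elemental
composition). Complete ¹⁵N incorporation is assumed; real incorporation of
~97% broadens envelopes but does not move this bookkeeping.

Domain classification uses residue ranges for the kinase (1–274), regulatory
(275–314), linker (315–343) and hub (344–478) domains — boundaries chosen so
that the frequently crosslinked lysines 344/347 fall in the hub, and fully
overridable since published heatmaps rarely state their exact boundaries.
`build_heatmap()` counts *unique residue-position pairs* (so missed-cleavage
peptide variants collapse), optionally intersecting exactly two replicates —
a crosslink counts only if seen in both. A crosslink is heterotypic when
either mixed channel exceeds a configurable floor (default 0; raise it for
noisy data). The discriminating signatures: subunit exchange predicts
heterotypic counts across all domain pairs in proportion to sampling
weights; IHP predicts them confined to kinase–kinase.

`map_to_structure()` reduces each crosslink to the minimal Cα–Cα distance
over allowed chain pairings (same chain, distinct chains, or chains of
distinct assemblies via an explicit chain-to-assembly grouping) and flags
satisfaction at a configurable threshold, 30 Å by default — the common Cα
criterion for the 11.4 Å DSS spacer; the underlying chemistry constrains
lysine amines to ~10 Å, but Cα positions add side-chain and dynamics slack.
Unmappable residues are flagged, never dropped silently. A numbering offset
reconciles construct numbering (e.g. constructs lacking the first residues)
with structure numbering.

# Mass photometry: mixture decomposition and monomer bookkeeping

Mass photometry yields one mass per landing particle. `fit_mixture()`
estimates a smooth density (Gaussian kernel, Silverman's rule on the
windowed events) and fits a sum of Gaussians to that curve by least squares,
seeding components at local density maxima. Two numerical choices:

* **Prominence pruning.** Sampling noise puts shoulder wiggles on broad
  peaks; a local maximum only seeds a component if it is separated from
  every taller accepted maximum by a valley below half its own height.
* **Bandwidth deconvolution.** Kernel smoothing inflates component widths
  by the bandwidth ($s_{obs}^2 \approx s^2 + bw^2$); reported SDs are
  deconvolved so generator round-trips recover the truth SD. Means and
  component areas are bandwidth-invariant, and areas are what downstream
  bookkeeping uses.

`assign_oligomer()` picks the subunit count $n$ from a candidate grid
minimizing $|m_{peak} - n\,(m_{monomer} + m_{ligand})|$ (ties toward smaller
$n$); under activating conditions calmodulin (16.7 kDa) is bound per
subunit. With monomer 55 kDa this reproduces the canonical peak labels:
592 kDa → dodecamer, 1442 kDa (with CaM) → 24-mer.

Peak areas are percentages of *particles*; `monomer_fractions()` converts to
percentages of *subunits* by weighting each area by its subunit count and
renormalizing. For areas 4.7/85.9/9.4 with $n$ = 2/12/24 the weighted values
are 9.4/1030.8/225.6 (total 1265.8), i.e. 0.74%, 81.43% and 17.82% of
monomers. Full precision sums to 100 exactly; the conventional one-decimal
report (0.7/81.4/17.8) is carried alongside. (Rounding each value
independently need not preserve a sum of 100, which is why published
one-decimal triplets can differ from the recomputed values in the last
digit.)

# TIRF colocalization

`threshold_mask()` keeps the brightest `ceiling(f·n)` pixels ("top 1% of
signal" read as the brightest 1% of *pixels*, nearest-rank; not 1% of the
intensity range, which would be noise-level dependent). Ties at the cutoff
are all kept and the realized count reported. Constant images are rejected
as degenerate. `pearson_coloc()` applies each channel's mask to its own
channel and correlates the two masked channels over a support set. The
support convention materially changes what anti-colocalized signal scores:

* `"union"` (default): disjoint bright spots drive $r$ toward −1 — a
  sensitive discriminator between shared and unshared spot populations;
* `"intersection"`: only doubly-masked pixels, undefined when masks are
  disjoint;
* `"all"`: the full frame, under which two independent sparse channels give
  $r \approx 0$ (the usual full-frame plugin behaviour).

The original plugin's convention is not recoverable from its description,
so all three are implemented and the choice is recorded in every result.
Condition groups are compared against a control with Dunnett many-to-one
contrasts (`multcomp::glht` on a one-way fit), controlling familywise error
at $\alpha$ = 0.05; replication structure (ROIs from different slides) is
treated as metadata, not modeled.

# The synthetic-data generators

The generators define the study conditions under which the analyses are
validated; their defaults are fixed once and are not tuning knobs.

* **Time courses** (`gen_timecourse()`): enzyme at 0.5/2/10/100 nM, samples
  at 1, 2, 5, 10, 15, 30, 60 min, triplicates — the emulated titration
  design — with additive Gaussian noise (SD 0.05) on the normalized
  fraction, clipped to [0, 1.5]. The error model of blot densitometry is
  not published; additive Gaussian is the assumption that matches
  SD-weighted fitting, and it is an assumption.
* **Crosslink tables** (`gen_xl_table()`): residue pairs sampled uniformly
  from lysines (DSS is amine-reactive) of a *synthetic* CaMKII-α-like
  sequence — length 478 and per-domain lysine placement (including K42,
  K344, K347) mimic the real subunit, but it is not the curated database
  sequence, and no numerical result here depends on the true sequence.
  Homotypic intensities are log-normal (MS intensities are positive and
  multiplicative-noise dominated; CV 0.2) around a common scale. The three
  scenarios differ only in where heterotypic intensity appears: nowhere
  (basal), kinase–kinase with mean $R$ = 0.25 (IHP), or everywhere with flat
  mean $R$ (exchange). Ground-truth labels and sampling weights ride along
  for recovery tests.
* **Mass events** (`gen_mass_events()`): draws from a stated Gaussian
  mixture; the reference three-component truth (110/592/1320 kDa, weights
  0.05/0.85/0.10, 10⁴ events) mimics a dimer/dodecamer/24-mer field.
* **Spot images** (`gen_spot_images()`): 256² fields, 150 Gaussian-PSF spots
  per channel (σ 1.5 px), a controllable shared-center fraction, additive
  background noise.

One global seed drives everything; per-replicate noise uses derived
sub-streams, so tables are invariant to replicate ordering, and generators
restore the session RNG state (pure functions of their truth objects).

What the generators do *not* emulate — and hence what passing tests cannot
show about real data: chromatographic and envelope-level MS effects,
incomplete ¹⁵N incorporation, identification bias of the search engine,
ring-resolved phosphorylation stochastics, camera physics and drift,
landing-rate kinetics, and any systematic (non-random) blot error.
Parameter-recovery results certify the estimators, not the instruments.

# Problem sizes and numerical tolerances

The test suite and examples run at deliberately modest sizes chosen to make
the statistical checks sharp without waste: 50-seed recovery sweeps for the
global kinetic fit (triplicates, 7 timepoints, noise SD 0.05; ±20% recovery
in ≥90% of seeds, exact to 1e-4 without noise), 200–400 synthetic
crosslinks (mean $R$ within ±0.03; χ² uniformity at p > 0.01), 10⁴ mass
events (means within ±2 kDa, area fractions within ±2 points), 1000-run
null simulations for the Dunnett familywise error (observed ≤ 0.07 at
α = 0.05). Bisection tolerances are 1e-6 min for half-times; distance
mapping is exact to floating point and checked under rigid-body motion at
1e-6 Å.

# Known limitations

* Fitted kinetic parameters for the real titration data were never
  published, so the kinetics module is validated by synthetic recovery, not
  by reproducing published estimates; the same holds for the real crosslink
  counts, which depend on raw MS data.
* The replicate-intersection rule assumes exactly two replicates, matching
  the emulated design; other designs need the non-intersected mode.
* `fit_mixture()` fits the smoothed density, not the event likelihood; for
  heavily overlapping components a mixture EM on raw events would be more
  efficient, but peak positions here are separated by factors of ~2 in
  mass.
* The whole-subunit domain map is a single-chain abstraction: crosslinks
  between residues of the same domain on *different* subunits and within
  one subunit are distinguished only via structure mapping, not in the
  heatmaps.
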