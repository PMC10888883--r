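---
title: "metquilt methods: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metquilt methods: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, and the choices made where the design was genuinely open. It states
no empirical result that the test suite does not itself compute.

Units everywhere: masses in Da, retention times in seconds, ppm defined as
$10^6\,\Delta m / m$ and always computed against the reference mass.

# Data model

The unit of preprocessing output is the **feature**: an aligned cross-sample
signal with m/z, retention time and per-sample intensities. Missing
intensities are stored as zeros, never `NA` — imputation is an explicit,
auditable step, not a side effect of reading a file.

The unit of annotation is the **empirical compound**: a group of degenerate
features attributed to one tentative metabolite, organized as a grid whose
rows are isotopologues (M0, ¹³C/¹²C, ¹³C/¹²C·2, ¹³C/¹²C·3 at
$1.0033548/z$ Da spacing) and whose columns are adducts. The grid is the
right abstraction because isotopologue and adduct relations are
*independent*: any occupied cell's m/z is determined by the neutral mass,
its column's adduct contribution and its row index. Annotations from
different sources chain onto the same empirical compound, ordered by
confidence, and the whole set serializes to a byte-stable JSON array (fixed
key order; schema in `inst/extdata/empirical_compound.schema.json`).

An **experiment** is a directory: a JSON manifest binding acquisitions,
named feature tables and empirical-compound sets (all plain text on disk),
plus an append-only command log. Store operations refuse to overwrite an
existing name (copy-on-write naming), so no step can mutate a
predecessor's output and a recorded sequence replays to identical bytes.

# Pre-annotation: grouping features into grids

Inputs: a feature table, a relation table (isotope and adduct deltas), an
m/z tolerance in ppm and a co-elution window in seconds.

Defaults: **5 ppm, 2 s**. These are *within-table* co-elution tolerances —
aligned features from one preprocessing run agree much more tightly than
spectra acquired in a separate MS² run, which is why the MS²-mapping
defaults below are looser (10 ppm, 30 s).

The default relation tables, from standard atomic masses:

| mode | anchor | others (Δ vs neutral) |
|---|---|---|
| pos | M+H[1+] (+1.0072765) | M+NH4[1+], M+Na[1+], M+K[1+], M+2H[2+] |
| neg | M−H[−] (−1.0072765) | M+Na−2H[−], M+Cl[−], M+HCOO[−], M−2H[2−] |

The algorithm:

1. **Candidate edges.** Two features are linked when their retention-time
   difference is within the window and their m/z difference matches any
   single relation delta *or difference of two deltas* (any adduct-pair
   difference combined with −3…+3 isotope steps; plus the z = 2 isotope
   spacing 0.5016774) within the ppm tolerance of the larger m/z.
2. **Connected components** of the edge graph. Components larger than
   2·(max isotopes + 1)·(number of adducts) are split by repeatedly
   removing the worst-ppm edge — a guard against chaining artifacts in
   dense regions.
3. **Grid resolution.** Within a component, every (member, adduct, charge)
   combination is tried as a root hypothesis fixing a neutral mass
   $M = z\cdot mz - \Delta_{adduct}$. Every co-eluting member is placed in
   its best-fitting cell; when two features contend for one cell the
   smaller ppm error wins, ties go to the higher total intensity, and the
   loser is released. The hypothesis grouping the most features (ties: the
   smallest summed ppm error) is accepted, its features removed, and the
   search repeats until fewer than two features remain — so a component
   chaining two co-eluting compounds still yields two grids rather than
   one grid plus singletons. Everything unplaced is a singleton; the
   output is a partition (each input feature appears exactly once).
4. **Neutral mass**: mean of $z\cdot mz - \Delta_{adduct}$ over the
   adduct-resolved M0 members. Compounds with only isotope-tagged members
   are flagged unresolved (`NA` mass) rather than guessed.

Charge state 2 is supported as the doubly-protonated (or deprotonated)
anchor only; multimers, in-source fragments and higher charges are out of
scope for this version. Isotope-pattern abundance ratios are *not* used as
a grouping filter; grouping is on mass and retention time only, and
intensity enters only as a deterministic tie-break.

The greedy resolver is validated against an exhaustive oracle in the test
suite: for instances of ≤ 12 features, a brute-force search over all
relation-consistent partitions (maximizing grouped features, then
within-group pairs) must produce the same grouping.

# Annotation

Level semantics (the package's convention, in the spirit of the Schymanski
confidence scheme): **1a** MS² similarity to an authentic-standard library;
**1b** m/z + retention-time match to an authentic standard; **2** MS²
similarity to an external library; **4** neutral-mass-only match. Each
level carries mandatory evidence — 1b requires the rt error, 1a/2 require
the similarity score, 4 requires the mass/formula record — and the
constructors enforce this, so an invalid annotation cannot enter the data
model through any code path.

**Level 4** attaches *every* compound whose neutral monoisotopic mass lies
within the ppm window: mass alone cannot resolve isomers, and pretending
otherwise would overstate confidence. **Level 1b** gates on both ppm and
rt error, records both, and ranks multiple in-window standards by the
combined normalized error $(ppm/ppm_{tol})^2 + (rt/rt_{tol})^2$.

**Spectral similarity** is the square-root-intensity cosine: candidate
peak pairs within `frag_tol_da` (default 0.01 Da, optionally also after a
precursor-difference shift) are taken greedily in descending
intensity-product order, each peak used once; the score is
$(\sum\sqrt{I_aI_b})^2 / (\sum I_a \sum I_b)$ over matched pairs. Greedy
pairing matches common practice; a brute-force optimal-assignment oracle
runs in the tests and the agreement rate is asserted (≥ 95% on random
small spectra) with disagreements reported via `message()`, not hidden.
Greedy can only under-score, never over-score, relative to the optimum —
also asserted.

**Candidate retrieval** uses a precursor-m/z index over the library:
references sorted by precursor with closed ppm windows, point queries by
binary search (`findInterval`), construction O(n log n). Because every
window is proportional to its precursor, both window edges are sorted and
a query resolves to a contiguous run — the behavioral contract (results
identical to an exhaustive linear scan, boundaries included) is asserted
against a scan oracle on every tested query set.

**MS² mapping** attaches an experimental spectrum to the empirical
compound with a member feature within 10 ppm / 30 s of the precursor —
deliberately looser than grouping tolerances because MS¹ and MS² runs are
commonly acquired separately. Contested spectra go to the compound with
the smallest combined normalized distance; remaining ties break by interim
id so output is deterministic. Defaults for accepting a match:
`min_score = 0.60`, `min_matched = 3`. Re-annotating with the same source
is idempotent: duplicates are suppressed by (source, compound, level),
keeping the best score.

# Quality control

All QC operations are pure transforms with provenance tags; correlations
and PCA run on $\log_{10}(x+1)$ (raw intensities are never transformed in
place). Specific models and defaults:

- **Acquisition metrics**: per-acquisition feature count (nonzero cells),
  TIC, and median Pearson correlation to all other acquisitions, each with
  a z-score across acquisitions. **Failed-injection detection** flags
  feature-count z < −2: a failed injection loses most features and is an
  extreme negative outlier; −2 is this package's default (configurable)
  since no canonical threshold exists.
- **TIC normalization**: factor $\mathrm{median}(TIC)/TIC_s$; the median
  of an even count is the mean of the two central values. Idempotent by
  construction; zero-TIC samples are an error directing the user to remove
  failed injections first.
- **Blank masking**: drop a feature iff mean (or max) study intensity
  < k × the blank aggregate, default k = 3 — the conventional
  "3-fold over blank" rule. Blanks leave the surviving table.
- **Rare features**: keep iff nonzero in ≥ ⌈fraction · n⌉ samples,
  default 0.25.
- **Imputation**: half the feature's minimum nonzero value — the standard
  left-censored-missingness heuristic for LC-MS.
- **Batch correction**: parametric empirical-Bayes location/scale
  adjustment (the ComBat model), implemented in-package so the artifact is
  self-contained: standardize each feature against the batch-design fit,
  estimate per-batch location γ and scale δ², shrink toward normal /
  inverse-gamma priors fitted by method of moments, solve the coupled
  estimates iteratively, adjust and de-standardize, back-transform.
  Constant features pass through with a warning. Requires ≥ 2 batches of
  ≥ 2 samples.
- **Ordination**: PCA on feature-centered log intensities with a
  deterministic sign convention (largest-magnitude loading positive);
  correlation clustermaps use average-linkage clustering on 1 − r.

# Synthetic data: what a green test establishes

The generators emulate the *output* of preprocessing — aligned features
with exact relation deltas, log-normal intensities, co-elution — plus
controlled corruptions: 1 ppm m/z noise, 0.5 s rt jitter, 5% MS² intensity
jitter with one dropped peak, 5%-carryover blanks, failed injections with
90% feature dropout, per-batch log-scale effects. These magnitudes are
realistic for orbitrap-class data and are all overridable; each dataset
ships its ground truth for exact scoring.

They do **not** emulate: raw scans or chromatographic peak shapes,
alignment errors, correlated (non-independent) noise, intensity-dependent
mass error, real isotope abundance patterns, retention-time drift within a
batch, or matrix effects. A green recovery test therefore establishes
algorithmic correctness under the stated noise model — not performance on
any particular instrument's data.

One generator parameter deserves its rationale. The batch-effect
simulation plants per-feature location shifts drawn from N(1.0, 0.5) on
the log₁₀ scale rather than a constant +1.0 shift: recovery is scored by
the correlation between estimated and planted per-feature effects, which
is undefined for a constant and, for a spread much smaller than the
batch-mean estimator's standard error (≈ 0.17 log units at 10 samples per
batch with feature sds 0.2–0.5), would measure sampling noise rather than
the method even for a perfect estimator. The 0.5 spread puts the
theoretical ceiling near 0.95 so the > 0.9 requirement genuinely tests
recovery. This was fixed from the estimator-variance argument before the
test was run.

# Numerical conventions

- Table writers format numbers with `%.12g`: round-trips agree well below
  1e-9 relative, and repeated exports are byte-identical.
- Empirical-compound JSON uses a fixed key order and full-precision
  numbers; serialize∘parse and parse∘serialize are identities and equal
  inputs serialize to identical bytes.
- All ppm windows are closed intervals; ppm is computed against the
  reference (library/standard) mass.
- Ties anywhere resolve deterministically (ppm error, then intensity, then
  names/ids); output ordering of empirical compounds follows the first
  member's position in the input table.
- Generators save and restore the global RNG state, so seeded generation
  does not perturb a caller's random stream.

# Known limitations

- Grouping beyond z = 2, multimers, and in-source fragments are not
  modeled; such features end up as singletons or (rarely) mis-tagged
  cells.
- Only the parametric ComBat variant exists; heavy-tailed batch effects
  would favor the non-parametric variant.
- The mzML reader supports centroided spectra with 32/64-bit, optionally
  zlib-compressed arrays — the common case — not the full PSI vocabulary
  (no numpress, no profile mode).
- MSP is the only library format (MGF is not read); retention-time
  prediction, spectral networking and formula generation are out of scope.
- The report is markdown, not PDF; rendering is left to the user's
  toolchain.
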