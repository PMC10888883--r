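# metquilt

Post-processing, annotation and quality control for LC–MS metabolomics
feature tables.

## The problem

Untargeted LC–MS metabolomics preprocessing (peak picking and alignment)
ends with an aligned *feature table*: one row per feature — an m/z,
retention-time pair with per-sample intensities. That table is still far
from biology: a single metabolite typically appears as many degenerate
features (isotopologues, adducts such as [M+H]⁺ and [M+Na]⁺), most features
have no identity, and the table carries technical artifacts — contamination
visible in process blanks, failed injections, batch effects.

`metquilt` takes a feature table (plus sample metadata, and optionally MS²
spectra and reference resources) through to analysis-ready, annotated
output. It is aimed at mass-spectrometry and bioinformatics practitioners
who want each post-processing decision to be an explicit, replayable,
chainable step.

The core ideas:

- **Empirical compound** — the operational annotation unit: a grid of
  degenerate features, rows = isotopologues (M0, ¹³C/¹²C, … at
  1.0033548/z Da spacing), columns = adducts. Grouping features into grids
  *before* database search means one search per tentative metabolite
  instead of one per feature, and unresolved isomers stay honestly grouped.
  The neutral monoisotopic mass is inferred as the mean of `z·(m/z) − Δ_adduct`
  over adduct-resolved M0 members.
- **Chained, leveled annotation** — confidence tiers in the spirit of the
  Schymanski scheme: **1a** MS² match to authentic standards, **1b**
  m/z + retention-time match to authentic standards, **2** MS² match to an
  external library, **4** neutral-mass-only match (isomers not resolved).
  All annotations accumulate on the empirical compound in a lossless JSON
  format, so tools can be chained.
- **MS² similarity** — square-root intensity cosine with greedy peak
  pairing at `frag_tol_da` (default 0.01 Da); candidate references are
  retrieved through a sorted precursor-m/z index whose results are provably
  identical to a linear scan.
- **QC as pure transforms** — TIC normalization to the median sample TIC,
  blank masking (drop feature if mean study signal < k × mean blank
  signal), rare-feature removal, half-minimum imputation, failed-injection
  detection by feature-count z-score, parametric empirical-Bayes (ComBat)
  batch correction, PCA and correlation-clustermap summaries — each a
  table→table function with provenance tags, driven from a CLI over an
  on-disk experiment with an append-only command log.
- **Three-table output** — feature table (id, m/z, rt, intensities),
  annotation table (one row per feature–annotation pair), sample metadata
  table; referential integrity checked on every export.

## Worked example

```r
library(metquilt)

# synthetic experiment with known ground truth (12 planted compounds here: 3)
g   <- generate_feature_experiment(n_compounds = 3, n_samples = 4,
                                   seed = 42, noise = FALSE)
res <- build_empirical_compounds(g$table, default_relation_table("pos"))
res$empcpds[[1]]
#> EmpiricalCompound ec_00001: 2 features, 0 MS2 spectra, 0 annotations, neutral mass 830.140956
res$empcpds[[1]]$ms1_features
#>   feature_id       mz    rtime isotope modification
#> 1      F0001 831.1482 1126.378      M0      M+H[1+]
#> 2      F0002 832.1516 1126.378 13C/12C      M+H[1+]
```

The two features, 1.0033 Da apart and co-eluting at 1126.4 s, are the
monoisotopic and one-¹³C isotopologues of a single protonated molecule; the
neutral mass 830.1409557 Da is the feature m/z minus the proton mass
1.0072765 Da. QC metrics per acquisition:

```r
head(acquisition_metrics(g$table)[, 1:4], 3)
#>   acquisition feature_count     tic median_correlation
#> 1         S01            12 2375684          0.9769593
#> 2         S02            12 2484351          0.9706940
#> 3         S03            12 4636819          0.9794564
```

A full analysis is a chain of named steps over an on-disk workspace (each
also available as a CLI subcommand via `inst/cli/metquilt`):

```r
assemble_experiment("meta.csv", "wk")
run_step("wk", "ingest-table",  list(path = "raw.tsv", dialect = "asari", out = "raw"))
run_step("wk", "blank-mask",    list(table = "raw",    out = "masked"))
run_step("wk", "normalize",     list(table = "masked", out = "norm"))
run_step("wk", "impute",        list(table = "norm",   out = "imputed"))
run_step("wk", "build-empcpds", list(table = "imputed", out = "ecs"))
run_step("wk", "annotate-l4",   list(set = "ecs", compounds = "compounds.csv", out = "ecs_l4"))
run_step("wk", "export",        list(table = "imputed", set = "ecs_l4", out_dir = "wk/export"))
run_step("wk", "report",        list())
```

`wk/report.md` summarizes acquisitions, per-stage feature counts, QC
metrics, annotation counts by level, and the full command timeline; the
export directory holds the three tables, byte-identical across reruns.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the grouping
algorithm and its conflict-resolution rules, the annotation levels and
similarity scoring, every QC model with defaults and units, what the
synthetic generators do and do not emulate, and known limitations.
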