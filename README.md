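# foldphase

Tools for the quantitative analysis that links the folding stability of
globular proteins to their intracellular phase separation through the
unfolded state. Destabilised variants of a well-folded protein can demix
into liquid-like deposits; the analysis here asks whether a single critical
concentration of the *unfolded* species explains when that happens, and what
sequence chemistry drives it.

The package is aimed at groups analysing optoDroplet-style imaging assays,
unfolded-state simulation ensembles, and proteomics of insoluble fractions —
or at anyone who wants a fully synthetic, ground-truthed testbed for these
methods.

## The models at the core

**Polyphasic linkage.** A two-state folder with unfolding free energy
ΔG°U has unfolded fraction

    p_U = exp(-(ΔG°U + ΔG°S)/RT) / (1 + exp(-(ΔG°U + ΔG°S)/RT))

with ΔG°S a constant offset capturing reduced stability in cells. If phase
separation is driven by the unfolded species alone, the apparent saturation
concentration obeys `c_sat = c*/p_U`, i.e. `c* = p_U × c_sat` is invariant
across variants. `fit_cstar_shift()` estimates (c*, ΔG°S) from a variant
table by nonlinear least squares on log c_sat.

**c_sat extraction.** Per-cell pixel intensities before/after activation are
screened for uniformity, fit with single-Gaussian (before) and constrained
two-Gaussian (after) histogram models, pruned by Cook's distance, and the
saturation concentration is read off as the split point where the
before/after relation leaves the one-to-one line, with a 50-trial bootstrap
(`extract_csat()`).

**Stickers.** Per-residue mean contact probability (5 Å cutoff, nearest and
second-nearest neighbours excluded) is compared to the maximum observed in a
matched Flory-random-coil-style reference ensemble; residues above that
maximum are strong stickers (`call_stickers()`).

**Sequence grammar.** 36 NARDINI-style patterning z-scores (blockiness vs
1000 composition-preserving scrambles, window sizes 5 and 6 averaged) plus
55 composition features (amino-acid and residue-set fractions, charge
descriptors, patch coverages) give 91 sequence features; with an abundance
z-score, 92 z-scores per protein. Enrichment between protein sets uses
two-sample Kolmogorov–Smirnov tests with signed log p-values
(`grammar_feature_matrix()`, `ks_feature_enrichment()`), downstream of
one-way ANOVA + Fisher LSD enrichment sets (`anova_lsd()`).

Every stage has a synthetic generator with planted ground truth
(`gen_optodroplet_cells()`, `gen_variant_table()`, `gen_ensemble()`,
`gen_proteome_and_abundance()`), so the full chain runs and validates
without any external data.

## Worked example

Recover the linkage parameters from a noisy synthetic variant table, and a
planted saturation concentration from synthetic optoDroplet pixels:

```r
library(foldphase)

v   <- gen_variant_table(c_star_true = 10.83, dG_shift_true = -12.9,
                         noise_cv = 0.05, seed = 42)
fit <- fit_cstar_shift(v)
fit
#> Two-state polyphasic-linkage fit
#>   c*       = 11.04 a.u. (se 0.169)
#>   offset   = -12.74 kJ/mol (se 0.0895)
#>   R2 (log c_sat) = 0.997 on 12 variants

px  <- gen_optodroplet_cells(n_cells = 200, csat_true = 1000, seed = 42)
res <- extract_csat(px, seed = 42)
res
#> c_sat = 998.0 +/- 3.8 a.u. (191 cells, 50 bootstrap trials)
```

With 5% measurement noise on twelve variants, the fitted critical unfolded
concentration (11.04 a.u.) and stability offset (−12.74 kJ/mol) land within
about 2% and 0.2 kJ/mol of the planted truth (10.83 a.u., −12.9 kJ/mol), and
the extracted saturation concentration recovers the planted 1000 a.u.
threshold within its bootstrap SD. `run_demo_pipeline(outdir)` runs all four
stages end to end on synthetic inputs and writes plain-text outputs plus a
reproducibility manifest.

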