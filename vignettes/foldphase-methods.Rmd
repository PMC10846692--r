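---
title: "Methods: linking folding stability to intracellular phase separation"
author: "foldphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking folding stability to intracellular phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`foldphase` implements a quantitative analysis chain for the hypothesis that
destabilised globular proteins phase-separate through their unfolded state:

1. extraction of saturation concentrations (`c_sat`) from per-cell
   optoDroplet pixel intensities before and after light activation;
2. a two-state polyphasic-linkage fit of measured `c_sat` against folding
   stability, yielding the critical unfolded concentration `c*` and a
   constant cellular stability offset;
3. identification of sticker residues in unfolded-state conformational
   ensembles against a Flory-random-coil (FRC) style reference;
4. a 91-feature sequence-grammar engine with abundance z-scores and
   Kolmogorov–Smirnov enrichment profiling of proteins recruited into
   unfolded-protein deposits, on top of standard proteomics statistics
   (total-abundance normalisation, presence filtering, one-way ANOVA with
   Fisher LSD sets).

Every input the chain consumes can be generated synthetically with known
ground truth, so the whole pipeline is testable end to end without any
external data.

# The two-state linkage model

A two-state folder with standard free energy of unfolding $\Delta G^\circ_U$
has an unfolded fraction

$$p_U = \frac{e^{-(\Delta G^\circ_U + \Delta G^\circ_S)/RT}}
             {1 + e^{-(\Delta G^\circ_U + \Delta G^\circ_S)/RT}},$$

where $\Delta G^\circ_S$ is a constant offset that absorbs the reduced
stability of the protein in cells relative to in vitro measurements (crowding,
fusion partners, quality-control engagement). If phase separation is driven by
the unfolded species alone, demixing occurs when the unfolded subpopulation
reaches a critical concentration $c^*$, so the apparent saturation
concentration obeys

$$c_\mathrm{sat} = c^* / p_U, \qquad c^* = p_U \, c_\mathrm{sat}.$$

`fit_cstar_shift()` fits $(c^*, \Delta G^\circ_S)$ by nonlinear least squares
with residuals on $\log c_\mathrm{sat}$. The log scale is essential: the
$1/p_U$ branch diverges for stable variants and would otherwise dominate the
objective. It also makes the fit exactly equivariant under a rescaling of
intensity units ($c^*$ rescales, the offset is untouched). $c^*$ is
parameterised on the log scale so positivity is structural, and a coarse grid
of starting offsets (−40 to 40 kJ/mol) guards against local minima. The gas
constant defaults to 8.314 J/(mol K) at T = 293 K; `thermo_config(R = 8.131)`
reproduces analyses run with that alternative printed value — at the
precision that matters here (e.g. >99% folded at +13 kJ/mol) the two are
indistinguishable.

The bootstrap confidence procedure (`cstar_confidence_interval()`) resamples
variants with picking weights $(10 - b)/10$, floored at 0.05, where $b$ is the
blob-change score of the variant's sequence against the reference: the total
decrease in hydrophobic blob size plus the increase in hydrophilic blob size,
in residues (`detect_blobs()`, `blob_change()`). Blobs are runs of at least 4
overlapping 3-residue windows of scaled Kyte–Doolittle hydropathy, with the
linear map $(KD + 4.5)/9$ onto $[0, 1]$ and threshold 0.37. Note a
consequence of that published scale: serine (0.411) falls on the hydrophobic
side of the threshold, so "hydrophilic" test sequences are built from
strongly polar residues such as Asn (0.111). Each of 1000 trials draws 10
variants by weight with replacement and refits; the envelope pairs
mean($c^*$)+SD with mean($\Delta G^\circ_S$)−SD and vice versa, which brackets
the predicted $c_\mathrm{sat}$–$\Delta G^\circ_U$ curve. The envelope is
computed from fits on log residuals throughout; computing it on natural-scale
residuals instead shifts the envelope slightly but not the coverage behaviour
seen in simulation.

# Extraction of c_sat from optoDroplet pixel data

Input is a table of paired per-cell pixel intensities before and after
activation. The algorithm:

1. **Saturation filter** (`filter_cells()`): screening in natural-log space,
   cells with more than 25% of pixels at the detector maximum are removed.
   The rule is strictly "greater than" — a cell at exactly 25% is kept.
2. **Uniform-pixel screen** (`select_uniform_pixels()`): cells are
   approximately uniform before activation, so the log-intensity histogram is
   fit to a single Gaussian and only pixels inside the first bins whose
   frequency drops below 20% of the fitted peak (on either side of the mean)
   are kept; pixels saturated before activation are excluded. The retained
   positions index both channels.
3. **Dilute/dense fits** (`fit_dilute_dense()`): raw-intensity histograms of
   the screened pixels; a single Gaussian before activation
   ($I_\mathrm{dil,before}$, proportional to total concentration) and a
   two-Gaussian mixture after activation with the dilute mean constrained to
   $I_\mathrm{dil,after} \le I_\mathrm{dil,before}$. Cells with fewer than
   100 screened pixels, histograms occupying ≤ 5 bins, negative fitted
   means, or mixture $R^2 < 0.85$ are discarded with a recorded reason.
4. **Outlier pruning** (`remove_outlier_cells()`): three sequential steps —
   off-diagonal cells inside intensity regimes whose neighbours behave
   one-to-one; then Cook's-distance pruning (threshold 5× the mean Cook's
   distance) on the cells below, and then at or above, the split value
   $m = 0.9\,\mathrm{mean}(\mathrm{deviation} > x_\mathrm{1to1})$, with
   $x_\mathrm{1to1} = 1000$ a.u.
5. **Bootstrap split scan** (`estimate_csat()`): with at least 3 off-diagonal
   cells, 50 bootstrap trials each resample 90% of the off-diagonal cells
   with replacement and, together with the one-to-one-regime cells, scan
   candidate split values; the split minimising the min–max-normalised sum of
   SSE and $1 - R^2$ is the trial's `c_sat`, reported as mean ± SD over
   trials. Fewer than 3 off-diagonal cells means no phase separation at the
   concentrations sampled.

Numerical choices that the verbal description leaves open, and how they were
settled:

- **Histogram binning**: Freedman–Diaconis width with a floor of 10 bins on
  the before-activation histogram, chosen for scale-free robustness on
  right-skewed intensities. The after-activation histogram reuses the
  before-channel bin width: FD applied directly to a bimodal distribution
  spans the inter-mode gap and washes out the components, while the
  pre-activation noise scale is exactly the resolution needed to separate
  them.
- **Split model**: cells below the candidate split follow the one-to-one line
  $y = x$; cells at or above it follow the dilute-phase plateau $y = s$ — the
  zero-slope line crossing the one-to-one line at $(s, s)$. Above the
  saturation threshold the dilute-phase concentration is pinned at `c_sat`
  (tie-line flatness), so the plateau is the physical model of the upper
  branch. A free-slope variant was implemented and rejected by parameter
  recovery: the extra slope lets the split slide below the corner and biased
  recovered `c_sat` low by 4–7% on planted data, while the plateau model
  recovers within ~1%.
- **Candidate grid**: 400 evenly spaced split values between the 5th and 95th
  percentiles of observed $I_\mathrm{dil,before}$. Scanning only observed
  intensity values was tried first and proved degenerate: all 50 bootstrap
  trials snap to the same observed value, collapsing the bootstrap SD to
  exactly zero and voiding the method's own uncertainty estimate.
- **Trial composition**: "bootstrap" is taken literally (resampling with
  replacement). Cells in the intermediate deviation band
  ($x_\mathrm{1to1} < d < m$) participate in outlier pruning but not in the
  split scan.
- **Mixture initialisation**: component means start at the 25th and 90th
  percentiles; a mixture whose smaller component carries < 1% of the larger
  amplitude is treated as effectively single-Gaussian (one-to-one regime, no
  resolved dense phase), as is a cell where the mixture optimiser fails but a
  single Gaussian fits.

On synthetic populations of 200 cells with a planted
$c_\mathrm{sat} = 1000$ a.u., the estimator recovers the threshold to ~0.5%
with a bootstrap SD of the same order, and the SD matches the observed
across-simulation scatter — i.e. it is well calibrated, which also means an
"error within one SD" check is inherently a ~68% event.

# Sticker identification from conformational ensembles

For each conformation, residues $i, j$ with $|i - j| > 2$ are in contact when
their representative points lie within 5 Å (`contact_matrix()`). The mean
contact probability (mcp) of a residue averages the contact indicator jointly
over eligible partners and conformations (`mean_contact_probability()`); it
is invariant to rigid-body motion and the averaging order is immaterial for
the mean. A residue is a strong sticker when its mcp exceeds the maximum mcp
anywhere in a matched reference ensemble (`call_stickers()`); six residue
categories (aliphatic AILMV, aromatic FWY, unique CP, acidic DE, basic HKR,
polar GNQST) summarise which chemistry carries the contacts, compared
against the fraction expected from residue counts alone
(`group_contact_fractions()`). Replicate ensembles are pooled with equal
per-conformation weight (`pool_ensembles()`).

The synthetic ensemble generator (`gen_ensemble()`) is a bead-per-residue
model chosen as the simplest chain that makes planted stickers detectable by
this statistic:

- **Target chains** are semiflexible (successive bond vectors confined to a
  forward hemisphere, emulating backbone stiffness), self-avoiding
  (hard-sphere diameter 3.5 Å), with a square-well attraction of depth
  `attraction_strength` kT and range equal to the 5 Å contact cutoff between
  planted sticker pairs, sampled by Metropolis pivot moves with incremental
  cross-pair energy evaluation.
- **Reference chains** (`reference = TRUE`) emulate the FRC null — chain–chain
  and chain–solvent interactions counterbalanced — as semiflexible *ideal*
  walks with no nonlocal interactions, sampled directly.

The asymmetry is deliberate and mirrors the role the FRC plays in the
analysis it emulates: an ideal chain is more contact-rich than a
self-avoiding one, so the reference maximum is a *conservative* threshold.
Attraction-free targets sit far below it (zero sticker calls across seeds),
spacers dragged along by a bound sticker cluster stay below it because
excluded volume caps how much of the cluster they can touch, and strongly
bound stickers clear it severalfold. Designs without this margin were
implemented and rejected by recovery tests: matching self-avoiding reference
(threshold at the target's own baseline; Monte-Carlo flicker flags 4–15% of
spacers), floppy ideal reference (threshold geometrically unreachable), and
attraction on an ideal background (global collapse; most of the chain flags).
The packaged study conditions — a 40-mer with stickers at positions 8, 14,
20, 26, well depth 5 kT, pools of 6 × 250 conformations — recover all
planted stickers with zero false positives among residues at least three
positions away from any sticker; residues within two positions ride along
with every contact their sticker makes (the 5 Å well spans about 1.3 virtual
bonds) and are treated as boundary, not spacer.

# The sequence-grammar engine

**Patterning (36 z-scores).** Eight residue groups — pol (S,T,N,Q,C,H), hyd
(I,L,M,V), pos (K,R), neg (E,D), aro (F,W,Y), ala, pro, gly — give 36
unordered pairs including self-pairs. For a pair $(x, y)$ the window
statistic at window size $g$ is $\sigma = (f_x - f_y)^2 / (f_x + f_y)$ (0
where both are absent), reducing to $f_x$ for a self pair; blockiness is the
mean squared deviation of $\sigma$ over sliding windows from its
whole-sequence value — a windowed compositional variance. The statistic is
computed at $g = 5$ and $g = 6$, z-scored against 1000 composition-preserving
scrambles (no parametric fit to the null), and the two z-scores averaged.
Negative z means more well-mixed than the scrambles, positive means blockier.
Pairs involving a group absent from the sequence are reported as 0, since
scrambling cannot change an absent group's patterning.

**Composition (55 features).** 20 amino-acid fractions; 9 set fractions
(positive RK, negative DE, polar STNQCHG, aliphatic AILMV, aromatic FWY,
charged RKDE, chain-expanding EDRKP, disorder-promoting AGRDHQKSEP, and R+Y);
R/K and E/D ratios; net charge per residue, mean scaled Kyte–Doolittle
hydropathy, isoelectric point (bisection on the Henderson–Hasselbalch charge
equation with an EMBOSS-style pKa set), polyproline-II propensity (a pinned
experimental per-residue scale), and the R+Y count; plus 19 patch-coverage
fractions. A patch needs at least 4 occurrences of a residue (2 for the RG
dipeptide) with at most 2 non-target positions between consecutive
occurrences; coverage is patch residues over sequence length. The retained
patch set drops Met and Trp (none occur in the reference proteome — the
synthetic generator scrubs them accordingly), leaving 19 of 21 tracked
targets and hence exactly 55 composition features, 91 sequence features, and
92 z-scores once the abundance z-score is appended. The definitional sets and
scales are package constants, overridable and documented, since the composition
conventions are inherited from standard sequence-analysis tooling rather than
restated in print; the cardinalities are what the panel is tested against.
A ratio with zero denominator is reported as the numerator count with a
sentinel flag, keeping downstream z-scores finite.

**Z-scoring and enrichment.** Features are z-scored against the full mapped
protein set (`reference_zscores()`; zero-variance features are dropped, not
NaN'd). The abundance z-score compares a protein's mean abundance across all
groups and replicates to the distribution of those means over all proteins.
Per-feature enrichment between a protein set and the remaining background
uses the two-sample Kolmogorov–Smirnov test; features with $p < 0.05$ are
recorded as $|\log_{10} p|$ signed by whether the set's median z exceeds the
background's (`ks_feature_enrichment()`).

# Proteomics enrichment statistics

`normalize_and_filter()` divides each sample by its total abundance (columns
sum to one; idempotent), applies the presence rule, and mean-fills single
missing replicates within a group. The literal presence wording ("identified
in three or fewer replicates of any group excluded", i.e. all four required)
contradicts the subsequent fill rule for one-of-four missing values, which it
would make unreachable; the default `"reachable"` rule retains proteins
detected in at least $n - 1$ replicates of every group, and the `"literal"`
reading is selectable. `anova_lsd()` runs a one-way ANOVA per protein with
Fisher LSD pairwise comparisons (t-tests on the pooled ANOVA mean square,
exact ties floored at $10^{-12}$); significant proteins get the smallest
leading block of group means whose members are all significantly higher than
every group outside the block, or `"ambiguous"`. The ranked significant set
can be capped with `top_n`; the cap is data-specific reporting, not part of
the statistics. `smooth_zscores()` is a display-only transform: mean
replicate z times $(1 - p)$ from a one-sample t-test against zero, passed
through unscaled (and flagged) for single replicates.

# Synthetic data: what it emulates, and what it does not

`gen_optodroplet_cells()` draws per-cell totals uniformly over an expression
range (the distribution of expression across cells is a free knob; uniform is
assumed), gives pixels median-centred lognormal noise, and applies a per-cell
lognormal acquisition-gain factor (cv 0.05, identical in both channels) for
optical path and illumination variability. Above the planted threshold the
after-activation channel is a two-component mixture with the dilute component
at `csat_true` and the dense component at `dense_fold ×` total; the dense
pixel fraction is not a free parameter but solves within-cell intensity
conservation exactly, so the planted threshold is the single ground-truth
knob. Median-centring matters: the extraction fits histogram peaks, and an
ideal estimator of the measured data should land on the planted value rather
than a skew-shifted peak. Not emulated: camera point-spread functions,
segmentation errors, droplet-size effects, photobleaching.

`gen_variant_table()` applies the linkage law exactly (to machine precision
at zero noise) with mean-zero relative noise, and attaches point-mutated
sequences to a fixed base so the blob-weighted bootstrap has material.
`gen_proteome_and_abundance()` draws sequences from proteome-average residue
frequencies, shifts planted proteins' composition by an absolute frequency
bias, multiplies their abundance by a fold change in their group, and scrubs
Met/Trp patches unless asked not to. TMT ratio compression and
peptide-to-protein inference noise are not emulated. Passing tests on these
generators demonstrate that the algorithms recover the structure they assume;
they do not certify behaviour on features of real data the generators omit.

# Problem sizes and runtime

The shipped tests and the acceptance script run on deliberately modest
problem sizes — 100–400 cells of 400 pixels, 12-variant tables with 100 noise
repeats, ensemble pools of 6 × 250 conformations of a 40-mer, proteomes of
60–1000 proteins with 4 replicates in 3 groups, 200–1000 scrambles — chosen
so the full chain, including its property-based oracles, completes in a few
minutes while every recovery margin reported above still holds with room to
spare.

# Known limitations

- The split-scan `c_sat` estimator resolves the threshold no finer than the
  local density of cells near the kink; its bootstrap SD reflects off-diagonal
  resampling only, which matches across-simulation scatter in our conditions
  but is not guaranteed to for very sparse populations.
- The sticker threshold (reference maximum) is a point estimate; residues
  whose true contact enrichment is comparable to the reference profile's own
  Monte-Carlo error will flicker. The synthetic conditions are engineered for
  margin; real ensembles need enough sampling for the same reason.
- The bead-per-residue chain is a caricature: it demonstrates that the
  statistic identifies planted cohesive residues, not that any particular
  protein's stickers are correct.
- Composition conventions (polar set, disorder-promoting set, pI/PPII scales)
  are pinned, documented defaults; analyses comparing against other tools
  should align these constants first.
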