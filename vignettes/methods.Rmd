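---
title: "Methods: redox stoichiometry and differential abundance from isobaric labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redox stoichiometry and differential abundance from isobaric labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxtmt)
```

# Scope

`redoxtmt` implements the quantitative core of a two-strain comparative
proteomics study design built on isobaric labeling. Two strains of a
toxin-producing dinoflagellate — a high-toxin producer (HT) and a
low-toxin producer (LT) — are compared on two axes:

1. **Cysteine redox state** via differential iodoTMT labeling: free
   (reduced) cysteines are tagged with a light label, the remaining
   (oxidized) cysteines are reduced with TCEP and tagged with a heavy
   label. The fraction of in-vivo-reduced cysteines per protein, its
   *redox stoichiometry*, is then a ratio of reporter-ion intensities.
2. **Protein abundance** via an 11-plex TMT experiment with five samples
   per strain plus a pooled reference channel.

Everything downstream of the database search is implemented here: PSM
roll-up, channel quality control, scaling and normalization, the
moderated-statistic permutation FDR, strain-level tests, and categorical
enrichment statistics. Upstream steps (culturing, labeling chemistry,
LC-MS/MS acquisition, spectral search, sequence annotation) are out of
scope; their outputs — PSM-level reporter intensity tables and an
annotation catalog — are this package's inputs. Because raw
mass-spectrometry data are impractical to ship or reprocess at desk
scale, a synthetic PSM generator with complete ground truth stands in
for the instrument, and validation is by parameter recovery.

# Redox stoichiometry

For protein $i$, strain $g$ and replicate $r$, reporter intensities of
all matched PSMs are summed per channel, and

$$ s_{igr} \;=\; \frac{I^{\text{light}}_{igr}}
      {I^{\text{light}}_{igr} + I^{\text{heavy}}_{igr}} \in [0, 1], $$

the summed light intensity over the summed intensity of both labels
(reduced over total cysteines). Lower values mean a more oxidized
protein. The ratio is formed **within** a replicate (ratio of sums) and
then averaged **across** replicates (mean of ratios); this order makes
the per-strain mean robust to run-to-run intensity scale differences,
which cancel inside each ratio. A value is missing when both label
channels are missing or the total is zero; when exactly one label has no
observed PSM its sum is taken as 0, so "no light signal, clear heavy
signal" correctly yields a stoichiometry of 0 rather than a missing
value.

Per-protein fold changes HT/LT are reported in two forms: `fc`, the mean
of per-replicate ratios $s_{\mathrm{HT},r}/s_{\mathrm{LT},r}$ (the
default, since the two strains are multiplexed in the same run and the
per-run ratio cancels run effects), and `fc_of_means`, the ratio of
strain means. With four replicates the two rarely differ by much; both
are emitted so either convention can be compared against.

Strain-level statistics (in `redox_comparison()`):

* a **global paired t-test** across proteins on the (HT mean, LT mean)
  pairs. With thousands of proteins even a modest shift drives the
  p-value below double precision; underflow is reported as the floor
  label `"< 2.2e-16"`, never as a literal zero.
* **per-protein two-tailed homoscedastic t-tests** on the replicate
  stoichiometries, Benjamini–Hochberg adjusted. With four replicates
  per strain these are low-powered by design — a global shift can be
  overwhelming while no single protein reaches significance, and the
  package reports exactly that pattern when it occurs.
* distribution summaries: per-strain mean ± sd, fold-change mean,
  median, sd, the fraction of proteins with FC < 1, and histogram bin
  counts (default bin width 0.1) for plotting.

The replicate-presence filter (`filter_by_replicate_presence()`, default
at least 3 of 4 replicates per strain) trades coverage for estimate
stability. Both the full and the filtered tables are carried through and
summarized, since headline counts are conventionally reported on both.

# Differential abundance

Stages, in order, on the protein × channel matrix:

1. **Group merging** (`merge_protein_groups()`): families whose members
   cannot be distinguished meaningfully by quantification (e.g. the many
   near-identical chlorophyll a/b-binding light-harvesting antenna
   entries) are summed to a single row before analysis.
2. **Channel QC** (`qc_channels()`): a channel is dropped when the
   median of the other channels' totals is at least `ratio_threshold`
   (default 100, i.e. two orders of magnitude) times its own, or when
   more than `missing_frac` (default 0.5) of its values are missing.
   Both rules are configurable; a failed labeling typically trips both.
3. **Global scaling** (`scale_channels()`): each channel is multiplied
   by (grand mean of totals)/(own total) so all channel totals are
   equal; the grand-mean target makes the operation idempotent.
4. **Normalization** (`log2_and_center()`): log2 transform (zeros
   become missing first) and per-channel centering by the mean.
   Median centering is available and gives closely similar results on
   log-scale intensity data; mean centering is the default. Centering
   per channel, together with scaling, makes the group-mean difference
   exactly invariant to any per-channel multiplicative factor.
5. **Testing** (`differential_abundance()`): for each protein,
   $\mathrm{diff} = \bar{x}_{\mathrm{HT}} - \bar{x}_{\mathrm{LT}}$ in
   log2 units, the pooled (homoscedastic) standard error $s$, the plain
   Student t and p, and the SAM-style moderated statistic

   $$ d = \frac{\mathrm{diff}}{s + S_0}, \qquad S_0 = 1 \text{ by default.} $$

   The fudge factor $S_0$ damps the significance of proteins whose tiny
   standard errors would otherwise make negligible fold changes look
   extreme — the familiar volcano-plot "significance curve" behavior.
   The reference channel is carried through scaling but excluded from
   the two-group test.
6. **Permutation FDR**: group labels are permuted over the columns
   (all distinct assignments when there are at most `n_perm`, which at
   4 vs 5 samples means all 126; otherwise `n_perm` distinct draws).
   For each candidate threshold $c$ on the observed $|d|$,

   $$ \widehat{\mathrm{FDR}}(c) = \frac{\mathrm{mean}_{\pi}\,\#\{|d_\pi| \ge c\}}
        {\#\{|d_{\mathrm{obs}}| \ge c\}}, $$

   clipped to 1 and made monotone non-increasing in $c$ before
   thresholding; proteins are flagged at the smallest $c$ with smoothed
   FDR at or below `target_fdr` (default 0.02). A symmetric threshold
   on $|d|$ is used rather than separate up/down cut curves — simpler,
   and adequate when the up/down split is not extreme. Plain-t BH
   q-values are reported alongside as a cross-check. Proteins with
   fewer than two observations in either group are excluded and
   counted.
7. **Clustering** (`hierarchical_cluster()`): rows are Z-scored
   (mean 0, sd 1; constant rows dropped with a warning), Euclidean
   distance, average linkage, and the column tree cut at $k = 2$ to
   compare against the expected strain partition. The Z-scored matrix
   is the natural heat-map input.

# Enrichment statistics

* `fisher_enrichment()`: per annotation term, a 2×2 table of
  (flagged × member) counts over the universe; two-sided exact p by
  hypergeometric point-probability summation (via `stats::fisher.test`)
  and an observed/expected enrichment factor
  $a \,/\, [(a{+}b)(a{+}c)/N]$. The universe defaults to **annotated
  proteins only**: when only a minority of a non-model proteome can be
  annotated, including the unannotated bulk in the background inflates
  apparent enrichment. The `"all"` option exists because the background
  choice is a genuine judgment call and materially shifts p-values.
* `one_d_annotation_enrichment()`: the rank-based (Mann–Whitney) test of
  whether a term's proteins sit high or low in a numeric ranking —
  per-sample normalized intensity or the log2 fold change. With
  $U = \sum_{\text{members}} \mathrm{rank} - n_1(n_1{+}1)/2$, the
  position score $s = 2U/(n_1 n_2) - 1 \in [-1, 1]$ is $+1$ when
  members hold the top ranks, $-1$ at the bottom and 0 at rank parity.
  Two-sided p-values use the tie-corrected normal approximation
  (no continuity correction), BH-adjusted across terms within each
  sample.
* `bh_adjust()`: the Benjamini–Hochberg step-up rule, exposed because
  every stage above uses it.

# The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline is
validated against; they are fixed properties of the validation design,
not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `redox_mean_ht`, `redox_sd_ht` | 0.28, 0.15 | Beta moments of true HT reduced fractions |
| `redox_mean_lt`, `redox_sd_lt` | 0.37, 0.19 | Beta moments of true LT reduced fractions |
| `fc_pairing_median`, `fc_pairing_sigma` | 0.78, 0.1 | paired-mode HT/LT ratio: log-normal median and spread |
| `dap_fraction`, `dap_up_fraction` | 0.2, 0.45 | fraction of truly differential proteins; fraction of those up in HT |
| `log2fc_range` | (log2 1.7, log2 18) | magnitude range of true log2 fold changes |
| `n_replicates_redox` / `n_replicates_abundance` | 4 / 5 | replicates per strain |
| `psm_mean`, `psm_dispersion` | 4, 2 | negative-binomial peptide/PSM counts per protein (≥ 1) |
| `peptide_factor_sd` | 0.5 | log-normal per-peptide ionization factor |
| `noise_cv` | 0.1 | CV of multiplicative log-normal measurement noise |
| `missing_rate` | 0.05 | PSM × channel missing-completely-at-random rate |
| `channel_loading_sd` | 0.2 | log-normal per-channel loading factors (TMT) |
| `degenerate_channel` | 129N, ×0.01, +0.5 missing | one failed channel for the QC stage to catch |

Choices where the emulated design is silent: Beta laws are parameterized
by (mean, sd) because those are the natural reported moments of a
bounded fraction; negative-binomial PSM counts and log-normal peptide
factors give the over-dispersed, heterogeneous roll-up weights seen in
real bottom-up data; `psm_mean = 4`, `peptide_factor_sd = 0.5`,
`noise_cv = 0.1` and `missing_rate = 0.05` are typical of a
well-behaved TMT experiment at the protein-roll-up scale;
`channel_loading_sd = 0.2` produces the ±50% channel-total spread that
global scaling exists to remove; `dap_fraction = 0.2` and
`dap_up_fraction = 0.45` give a signal-rich but not degenerate
differential landscape. The iodoTMT experiment is simulated as one
4-channel plex per replicate — with four reagent roles and two strains
per run, one run per biological replicate is the natural multiplexing —
and channel ids are flattened to `i126_r1` … so that one design table
describes all runs.

In paired redox mode the LT fraction is drawn from its Beta law and
HT $= r \cdot$ LT with $\log r$ normal, truncated to $(0, 1]$; this
produces the strongly correlated per-protein pairing (and hence an
overwhelming global paired test with null-looking per-protein tests)
that the independent-strains mode cannot.

What the generator deliberately does **not** emulate: spectrum-level
effects (isotope impurity, co-isolation interference, m/z), retention
time and chromatography, intensity-dependent missingness, shared
peptides between proteins, and annotation errors. Tests passing on
these simulations therefore validate the statistical pipeline
(formulas, error control, invariances, recovery of configured truth),
not robustness to those instrument-level artifacts.

# Numerical choices and degenerate inputs

* Log-normal noise uses $\sigma^2 = \log(1 + \mathrm{CV}^2)$ with mean
  exactly 1, so noise never biases expected intensities.
* `beta_shapes()` rejects infeasible moments
  ($\mathrm{sd}^2 \ge m(1-m)$) with a parameter error.
* p-value underflow is floored at 2.2e-16 in all reported labels.
* Zero variance in both groups of a per-protein test yields a missing p
  (not 0 or 1); all-tied ranks yield $s = 0$, $p = 1$.
* A channel totaling zero is a pipeline error in `scale_channels()` —
  QC should have dropped it.
* The permutation set always includes the observed labeling (standard
  for this estimator, slightly conservative); sampled permutation sets
  are deduplicated and seeded, so every run is reproducible.
* Ties at the |d| threshold are included (`>=` comparisons throughout).
* Seed layout: ground truth uses `seed`, the iodoTMT tables `seed + 1`,
  the TMT tables `seed + 2`; one seed therefore fixes the entire
  simulated experiment byte-for-byte.

# Problem sizes

Validation runs use 2000 proteins × 4 replicates for redox recovery
(per-strain mean stoichiometry recovered within ±0.02, median fold
change within ±0.03), twenty 1000-protein null simulations plus five
signal simulations for FDR-control checks (flagged fraction and
empirical FDR at most twice the nominal 0.02; sensitivity at least 0.9
for |log2 FC| ≥ 2), and exhaustive enumeration on 6-sample toys for the
permutation oracle. These sizes make the whole suite run in well under
a minute per criterion while leaving Monte-Carlo error comfortably
inside the tolerances.

# Known limitations

* Site-level (per-cysteine) stoichiometry is not computed; roll-up is
  per protein, and the type of cysteine oxidation is not identifiable
  from differential labeling alone.
* No imputation of missing values and no isotope-impurity correction.
* Protein inference from shared peptides is out of scope; the PSM table
  is taken at its word.
* The homoscedastic per-protein t-test with four replicates has limited
  power; the moderated permutation procedure is the intended
  significance call, and the plain-t BH q-values are a cross-check, not
  a substitute.
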