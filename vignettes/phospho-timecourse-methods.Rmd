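---
title: "Models and methods behind phosflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phosflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
library(dplyr)
```

`phosflow` implements the quantitative chain of a multiplexed (TMT)
phosphoproteomics time-course analysis: from reporter-ion intensities to
normalized per-stage trajectories, a reproducible analyzable site set,
temporal clusters, and motif-resolved dephosphorylation statistics. This
vignette explains the models, the tunable parameters and their defaults,
the synthetic-data generator used for validation, and the numerical and
design choices that were genuinely open.

## The measurement model and the normalization chain

One *multiplex* is a set of isobarically labelled samples quantified
together: here, one biological replicate of an ordered stage series
(default `Pro, GVBD, MI, MII, 2-PN, FC` — prophase-I arrest through first
cleavage) plus one channel carrying a pooled *internal standard* (a
mixture of all stages). The observed intensity of feature $i$ in stage
channel $c$ of multiplex $m$ is modelled as

$$ y_{imc} \;=\; \beta_i \, \theta_{i,s(c)} \, L_{mc} \, M_m \,
   \varepsilon_{imc}, $$

where $\beta_i$ is the feature's base abundance, $\theta_{i,s}$ its
biological occupancy at stage $s$, $L_{mc}$ a per-channel loading factor,
$M_m$ a per-multiplex scale, and $\varepsilon$ multiplicative lognormal
noise. The normalization chain removes the technical terms in order:

1. **Rollup** (`rollup_proteins()`): protein intensity is the sum of its
   peptides' intensities per (multiplex, channel); missing cells are
   skipped and a cell with no observed contribution stays missing.
2. **Internal-standard normalization** (`normalize_multiplexes()`):
   per feature, each multiplex is rescaled so its reference-channel value
   equals the across-multiplex mean reference value. This removes $M_m$
   feature-wise. The reference is a pooled mixture, so a *feature-wise*
   ratio is the appropriate comparison; a per-multiplex global-median
   variant is available (`method = "global_median"`). Features missing the
   reference in some multiplex are flagged (`ref_missing`), not scaled.
3. **Loading adjustment** (`adjust_channel_loading()`): protein tables are
   divided by their per-channel column totals (and rescaled to the mean
   total), equalizing totals exactly. Phospho tables are divided by the
   *protein-table* channel totals — the protein input of each channel —
   then rescaled by the median total. Using protein input (not phospho
   totals) matters because global phosphorylation genuinely rises at
   meiotic entry; dividing by phospho totals would erase the biology. The
   pipeline therefore passes the **raw** protein rollup (not the
   already-equalized adjusted table) as the input reference.
4. **Replicate mean and 0–1 scaling** (`stage_means()`,
   `scale_unit_interval()`): channels are mapped to stages via the design,
   averaged across multiplexes (sd retained), and each trajectory is
   scaled $(x-\min)/(\max-\min)$. Scaling is idempotent and invariant to
   positive affine maps, so the occupancy floor and any residual
   per-feature constants drop out. Degenerate trajectories
   ($\max=\min$, or fewer than `min_stages = 4` observed stages) are
   flagged, set to 0 and excluded from clustering.

## The analyzable site set

Two filters define it (`apply_site_filters()`), both inclusive at their
boundary:

* **Localization**: every declared site on a record must have localization
  probability ≥ 0.9 (the field's convention for a "localized" site).
* **Reproducibility**: the combined cross-replicate Pearson correlation of
  the per-multiplex stage trajectories must be ≥ 0.8. With two replicates
  this is the single pairwise r; with three it is the *mean of the three
  pairwise r values* — a symmetric, reproducible choice where the original
  "multiple correlations" computation is under-specified. The alternative
  (multiple correlation of one replicate on the others) is available via
  `method = "multiple"`. A p-value is attached via the t transform
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$; note that at $n = 6$ stages $r = 0.8$
  gives a two-sided $p \approx 0.056$, so gating on $r \ge 0.8$ and gating
  on $p \le 0.05$ are *not* identical — the package gates on r by default
  and exposes `p_threshold` separately.

Filters are conjunctive, so their order is immaterial; an attrition table
records counts after each criterion.

## Temporal clustering and the cut rule

Clustering is agglomerative with Euclidean distance and average (UPGMA)
linkage on complete, scaled trajectories (no imputation; incomplete rows
are excluded and logged). The default cut produces exactly `k` flat
clusters. For the MI-peak analysis the pipeline instead uses a
*minimum-size* cut (`min_cluster_size`, default 1% of rows): the tree is
cut at increasing granularity until `k` clusters of at least that size
exist, and members of smaller branches are left unassigned. An exact-`k`
cut of an average-linkage tree is brittle: a single outlying trajectory
merges last and claims a whole flat cluster, collapsing two genuine
classes into one. Reading the `k` substantive branches off the dendrogram
— which is what one does by eye — is robust to this and leaves only a
handful of outliers unassigned (4 of ~3,650 in the reference simulation).

Peak stages are the argmax of the replicate-mean scaled trajectory with
ties broken to the earliest stage; peak assignment deliberately uses the
mean rather than per-replicate peaks, as the mean is less noise-sensitive.

## Motif-resolved dephosphorylation

Site windows are ±7 residues around the phosphoacceptor, gap-padded at
termini. Classification is a pure function of the window: acceptor (S/T/Y
at offset 0), +1 proline (proline-directed sites), +2 class — basic
(K/R/H), acidic (D/E), small nonpolar (A/G), proline, other — and a
downstream basic patch flag (≥ 2 of offsets +2..+6 in K/R).

Enrichment logos (`logo_enrichment()`) compare per-(offset, residue)
frequencies of an experimental set against a reference set:
percent difference $100(p_e - p_r)$ and a one-sample binomial z score
$z = (p_e - p_r)/\sqrt{p_r(1-p_r)/n_e}$, treating the reference as fixed
(the reference is typically an order of magnitude larger; a two-proportion
variant exists). Gaps are excluded from denominators. "Selected" /
"deselected" calls are made at `alpha = 0.05` two-sided. The original
iceLogo sampling scheme is not re-implemented.

Dephosphorylation is quantified as $\delta = x_{\mathrm{MI}} -
x_{\mathrm{MII}}$ on scaled replicate-mean trajectories, so deltas are
comparable across sites (raw-intensity deltas are available). Group CDFs
are contrasted with the two-sided two-sample Kolmogorov–Smirnov test
(exact small-sample p where available), with Bonferroni adjustment within
each contrast family (acceptor contrasts; +2-class contrasts) — a
correction had to be chosen since the source analysis reports only
significance stars. Ratios of scaled values are distorted by the min
subtraction, so the ≥3-fold prophase→GVBD criterion of the kinase
consensus split uses normalized *unscaled* intensities (a flag can change
this).

Two short-linear-motif scanners are included:

* **RVxF** (PP1-docking): `[KRL][KRSTAMVHN][VI][^FIMYDP][FW]`, overlapping
  matches all reported. The canonical "x" is the 4th pattern position
  (motif start + 3) — stated explicitly because the "RVxF" name counts
  only four positions while the definition has five. A hit is
  phospho-flagged when a quantified phospho-S/T sits at x or within two
  residues of either motif boundary; occupancy traces average the linked
  sites' scaled trajectories.
* **RxRxxS/T** (basophilic kinase consensus): anchored as R at −5 and R at
  −3 relative to the acceptor, the standard convention that makes the
  discriminating "−4 position" the second x. Sites are split by early
  (prophase→GVBD) fold change ≥ 3 and the −4 basophilic (K/R/H) frequency
  compared: AKT-like consensus is −4-basophilic, SGK-like is not.

## Condition comparisons

`welch_t()` is the two-tailed unequal-variance t with Welch–Satterthwaite
df; noiseless limits are defined explicitly (equal constants → p = 1,
unequal constants → p = 0). Calibration: with six replicates per group the
empirical type-I error under equal-mean lognormal noise is within 1% of
nominal; at two to three replicates the Satterthwaite approximation is
measurably *conservative* (≈ 0.034 at n = 3), and with two replicates the
df collapse toward 1 means even enormous effects stall near p ≈ 0.05.
Per-site response classification should therefore run on complete cases
(sites quantified in all multiplexes), which is what the reproduction
script does.

Fisher tests (2×2 and 2×3) use the probability-based two-sided definition
— the sum of probabilities of margin-preserving tables no more probable
than the observed — which is the common convention but not the only one;
they are verified against full enumeration in the tests.

`classify_treatment_response()` classifies each site over an ordered
treatment axis: `increased_high` requires a scaled final value at or above
`high_threshold` (default 0.5 — the 0–1 scale has no canonical "high"
cut, so the midpoint is used) *and* a significant Welch increase over
baseline; `decreased` a significant decrease; otherwise `unchanged`. With
a single replicate the significance gate is dropped and flagged.

## Cross-dataset stage alignment

`align_timepoints()` aligns two time courses through marker phosphosites
(conserved inhibitory sites on cell-cycle kinases/phosphatases are the
intended markers; the site pairing is user-supplied, not inferred). Each
marker is 0–1 scaled within its dataset, making the alignment invariant to
per-dataset affine rescaling, and each query timepoint is assigned a
reference stage by dynamic programming over monotone (order-preserving)
assignments minimizing total Euclidean distance, ties to the earliest
stage. Decreasing sites between the aligned MI-like and MII-like points
(default drop ≥ 0.3 scaled units; no canonical value exists) are then
tested for the TP-basic / SP-acidic signature against a background set.

## The synthetic-data generator

The generator is the package's validation instrument: it emulates the
study design and plants known structure, and its defaults *are* the study
conditions.

* **Design**: 3 replicate multiplexes × 6 ordered stages + 1 reference
  channel; S/T/Y acceptor proportions 0.793/0.196/0.011; localization
  probabilities massed near 1 with a configurable tail below 0.9
  (default 15%); per-(site, multiplex) dropout (default 10%); 5% of
  records carry a second site; 99% of proteins have a noiseless maximum
  fold change below 2, the rest get a cyclin-like degradation/resynthesis
  profile.
* **Temporal classes** with piecewise noiseless templates: three MI-peak
  classes differing in their MI→MII drop (`dephos_delta`: fast 0.6,
  intermediate 0.35, stable 0.1), plus stable, prophase-peak and
  FC-peak classes. MI-peak templates are anchored at 0 (Pro) and 1 (MI),
  so unit scaling is the identity on the truth and the planted drop
  survives the full pipeline *exactly* in the noiseless limit — the basis
  of the exactness tests.
* **Sequence context**: windows drawn from a uniform residue background
  with class-conditional enforcement: MI-peak classes are
  proline-directed; the fast class gets a basic +2, the stable (SP) class
  an acidic +2. Acceptor draws are class-conditional (the fast class is
  tilted to threonine, the SP class to serine) with the conditional
  distributions solved so the configured S/T/Y *marginal* is preserved
  exactly — both the SP/TP contrast and the global acceptor composition
  can therefore be tested on the same dataset. RxRxxS/T consensus context
  is planted on a configurable fraction of sites with −4 basophilicity
  depending on whether the class rises early (SGK-like) or not
  (AKT-like); RVxF motifs are planted with the phosphosite at x on
  intermediate-class sites so their occupancy rises into MI.
* **Noise and technical factors**: multiplicative lognormal noise with
  unit mean (`noise_cv`, default 0.1 — a typical reporter-ion CV);
  per-channel loading factors (CV 0.05) and per-multiplex scales (CV 0.2)
  that the normalization chain must remove. Intensities are occupancies
  times a lognormal base intensity plus a 5% occupancy floor, keeping
  intensities positive without affecting scaled trajectories.
* **Determinism**: each table draws from its own stream derived from the
  master seed, so identical configurations are byte-identical and
  resizing one table does not perturb another's draws.

What the generator does **not** emulate: spectrum-level effects (isolation
interference, co-isolation compression), peptide-level missingness
correlated with abundance, shared peptides between proteins, PTM types
other than phospho-S/T/Y, and within-class biological heterogeneity of
trajectory shapes. Passing recovery tests therefore demonstrates
correctness of the computations under a faithful but idealized error
model, not robustness to every artifact of real data.

## Problem sizes and numerical choices

The validation suite runs the full chain at 10,000 sites × 3 multiplexes
(noise CV 0.1) for recovery checks — adjusted Rand index of the three
MI-peak classes, SP-vs-TP KS separation, +2 logo calls — and 25,228 sites
for composition checks; KS null calibration uses 1,000 replicates of 60
deltas per group, where the exact two-sample KS attains a rejection rate
of 0.047 at a nominal 0.05 (the statistic is discrete; 60-per-group is the
size at which the attainable level is closest to nominal). Oracle tests
compare KS, Fisher, Welch and motif scans against brute-force
enumeration/ECDF implementations on all inputs up to 30 observations.
Ties in peak assignment and cluster merges follow documented
earliest-index rules; thresholds are inclusive.

## Known limitations

* The correlation filter needs ≥ 2 multiplexes and ≥ 3 common stages;
  singly observed features are never "evaluable" and are dropped by the
  default filter.
* The logo z test treats the reference set as fixed; for small reference
  sets use `method = "two_proportion"`.
* `fisher.test`'s exact network algorithm is used for 2×3 tables; very
  large totals may be slow (the tests verify totals ≤ 30 against
  enumeration).
* Welch-based response classification is underpowered below three
  complete replicates (see above); the package does not moderate
  variances across sites.
* Cross-species alignment assumes the marker sites are truly homologous
  and co-regulated; it will happily align unrelated datasets if given
  unrelated markers.
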