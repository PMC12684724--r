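---
title: "Detecting, correcting and contextualizing isotopologue labeling patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, correcting and contextualizing isotopologue labeling patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midcontext)
```

# The problem

In a stable-isotope labeling experiment a tracer substrate (e.g.
U-13C-glucose) is fed to a biological system; metabolites downstream of the
tracer incorporate heavy atoms, and their **mass isotopomer distribution**
(MID) — the fraction vector $M_0, M_1, \dots, M_k$ of molecules carrying
$0, 1, \dots, k$ heavy atoms — encodes which pathways produced them. Two
obstacles stand between an untargeted LC-MS feature table and usable MIDs:

1. isotopologues must be *found* among thousands of features without a
   target list, and
2. the measured distribution must be *corrected* for naturally occurring
   heavy isotopes (13C alone contributes ~1.07% per carbon), which are
   present with or without tracer.

`midcontext` takes feature-intensity tables and sample metadata — it is
deliberately instrument-agnostic and starts after peak picking, alignment
and feature grouping — and carries them to corrected MIDs and to a
similarity network that places unannotated metabolites next to annotated
ones with related labeling.

# Isotopologue-group detection

For each labeled condition, candidate base features are scanned in
descending mean unlabeled intensity. For a base at $(m/z_0, t_0)$ and
tracer mass difference $\Delta$ (13C$-$12C $= 1.0033548$ Da), the candidate
member at isotopologue index $n$ is the feature closest in $m/z$ to
$m/z_0 + n\Delta/z$ within a relative window (`ppm_tol`, default 5 ppm of
the target $m/z$) and within `rt_window` (default 10 s) of $t_0$. The n = 0
entry is the base itself.

Detection then asks whether the *pattern* of the group differs between
labeled and unlabeled samples. Each sample's member intensities are
normalized to sum 1 (missing intensities count as 0; a sample where all
members are absent is dropped), and for every position $n \ge 1$ the
labeled and unlabeled relative intensities are compared with a Welch
two-sample t-test. A group is retained when at least one position has
$p \le \alpha$ (default 0.05) and — with the default
`require_enrichment_direction` — the labeled mean at that position exceeds
the unlabeled mean, i.e. the shift looks like enrichment rather than
depletion. Members of retained groups are consumed, so no feature belongs
to two groups and iteration order is deterministic.

Choices worth knowing:

* **Relative, not absolute, intensities.** Detection is invariant to
  rescaling any single sample, so it tolerates injection-volume and
  ionization drifts.
* **Degenerate Welch branches.** Zero variance on both sides with equal
  means yields $t = 0, p = 1$; with unequal means, the $p \to 0$ limit,
  flagged degenerate. These branches matter in noise-free simulations and
  in saturated detectors.
* **Multiplicity.** The retention rule is a minimum over positions at level
  $\alpha$; it controls the error rate per tested position, not per run.
  The `fdr` flag re-filters retained groups after Benjamini–Hochberg
  adjustment of all tested positions when a run-level guarantee is wanted.
* **Charge** is a single user-supplied value per run (default 1); there is
  no per-feature charge inference.
* **Gaps.** A member missing at some $n$ below the highest observed keeps
  its position with zero intensity; the group is not truncated.
* The unlabeled counterpart of a labeled condition is resolved as: unlabeled
  samples of the same condition, else of the same experiment, else all
  unlabeled samples.

# MID correction against the unlabeled condition

The unlabeled condition's measured MID $u$ serves as the natural-abundance
kernel. Writing $C(u)$ for the $L \times L$ matrix whose $j$-th column is
$u$ shifted down by $j$ positions and truncated at $L$, the labeled MID $m$
is modeled as the convolution $C(u)\,f$ of the tracer-incorporation
distribution $f$ with the kernel, and recovered by non-negative least
squares:

$$\hat f = \arg\min_{f \ge 0} \lVert C(u) f - m \rVert_2, \qquad
\text{corrected MID} = \hat f / \textstyle\sum_i \hat f_i .$$

Truncated columns are **not** renormalized: mass lost beyond $M_k$ shows up
in the reported residual instead of being silently redistributed, so model
misfit stays visible. Vectors of unequal length are zero-padded to the
longer everywhere. Per-replicate correction of each labeled sample gives
the element-wise standard deviation reported as the corrected MID's
dispersion — an assumption-light alternative to error propagation,
documented as approximate. Enrichment is $1 - \hat f_0$; quantification is
the mean total member intensity over labeled replicates.

Two identities anchor the implementation and are enforced by tests: a MID
corrected against itself returns $(1, 0, \dots)$, and a noise-free forward
convolution is inverted exactly (the truncated kernel matrix is exactly the
forward operator of the truncated convolution, so truncation does not break
the inversion).

## Labeling filters

Estimates pass, in order: minimum labeled enrichment (default 0.05),
maximum unlabeled labeling ($1 - u_0$, default cap 0.05), minimum
quantification, maximum residual (default 0.05), minimum replicate
presence. The first failing rule is recorded per rejection. Because a
12-carbon compound shows $1 - u_0 \approx 0.12$ from natural 13C alone, the
unlabeled-labeling cap can optionally be raised by the binomial expectation
$1 - (1 - p)^{n_E}$ when the base feature carries a formula annotation
($p$ = natural heavy fraction, $n_E$ = tracer-element count) — without
this allowance the filter would systematically reject large molecules.

# Annotation

MS1 annotation matches each feature's accurate mass against every
(compound, adduct) pair of a user-supplied compound table:
$m/z = (n_{mult} M + \delta)/|z|$, two-sided ppm window applied on $m/z$.
The electron mass is neglected (proton constant 1.00727646 Da), a
$< 0.5$ mDa effect below the tolerances used. Annotation is candidate
generation — all hits per feature are kept, ordered by absolute ppm error.
Reference standards require joint $m/z$ and retention-time windows, ties
broken by the combined normalized distance. MS2 spectra are aligned to
features by precursor ppm and RT, then scored against a library with a
square-root-intensity cosine over greedily (closest-$\Delta m/z$ first)
one-to-one paired peaks; unpaired peaks remain in the vectors so extra
peaks lower the score.

# Contextualization

Metabolites in the same pathway acquire related labeling patterns, so MID
similarity links unknowns to annotated compounds. Node pairs are scored per
shared (experiment, condition) record — cosine by default, or
$1 - \lVert a - b\rVert_2/\sqrt 2$ (Euclidean distance normalized by the
simplex diameter) — and combined across conditions by mean (default) or
minimum. Edges at or above the threshold (default 0.9) are kept; isolated
nodes remain visible. The defaults are deliberate interpretations surfaced
as flags: no single similarity score is canonical, and cosine with a high
threshold favors precision of edges over recall, which suits a
neighbor-suggestion tool. Networks export as Cytoscape JSON; reference
pathways in the same format can be overlaid by exact identifier match
(attribute configurable, case-insensitive by default), and each pathway
metabolite's nearest unannotated neighbors are ranked by edge similarity
with lexicographic tie-breaking.

# The simulator and what passing tests mean

`simulate_experiment()` forward-simulates the whole measurement: per
compound a tracer-incorporation distribution is convolved with the
binomial natural-abundance distribution of the tracer element, one feature
is emitted per isotopologue, and per-sample intensities get multiplicative
lognormal noise (default CV 5%, matching the multiplicative behavior of MS
intensities), optional dropout below a threshold, plus unrelated decoy
features. The benchmark conditions are 20 metabolite-like compounds in 4
pathway groups of 5 (same-group incorporation distributions are small
perturbations of a shared archetype; pairwise cosine $\ge 0.95$ within and
$< 0.8$ across groups, asserted at construction), 3+3 replicates, 50
decoys, 13C tracer.

**Mass-error model.** Feature $m/z$ error is a shared calibration component
per co-eluting isotopologue envelope (sd `mz_jitter_ppm`, default 2 ppm)
plus an independent centroid component (sd `mz_jitter_ppm`/4). This mirrors
real instruments, where absolute calibration error dominates and is locally
correlated while isotopologue *spacing* is measured much more precisely; a
fully independent per-feature error would make the member-vs-base
difference absorb two full jitters and is not how profile data behaves.

**Type-I evaluation.** The null configuration is a single one-carbon
compound whose "labeled" samples carry no tracer, so detection faces
exactly one Welch test per condition and the per-condition false-positive
rate measures the per-test level that $\alpha$ actually controls. With many
compounds the "any detection" rate would be a familywise quantity the
min-over-positions rule never claims to bound; that regime is what the
`fdr` flag is for.

**What the simulator does not emulate** — and hence what green tests do not
show about real data: chromatographic peak shapes and integration error,
adduct and in-source-fragment cross-talk between features, natural
isotopes of non-tracer elements (O, S fine structure), tracer impurity,
and retention-time drift between samples. The correction step never sees
theory — only the simulated unlabeled measurement — so the pipeline test
is self-consistent, but real unlabeled MIDs carry the full fine structure.

Test problem sizes (the package's own choices): 1000 random MIDs of length
2–12 for the self-correction identity; 200 random deconvolution problems of
length $\le 4$ checked against an exhaustive simplex grid search (full
0.001 grid for $L \le 3$; for $L = 4$ a full 0.01 grid refined by the full
0.001 grid on the surrounding box — the objective is convex in the
direction/scale parameterization, so the refinement contains the global
0.001-grid optimum); 200 null simulations; the 20-compound benchmark for
recall, precision, MID accuracy, annotation coverage and network purity.

# Numerical conventions

* CSV dialect: comma, UTF-8, "." decimal, mandatory header; `sep` admits
  ";" and tab; text fields that may contain the separator are quoted.
* Numerics are written with 15 significant digits; round trips are tested
  to 12.
* Retention time is seconds internally; a reader flag converts minutes.
* Third-party MID files are renormalized when their sum is within 2% of 1
  and rejected beyond that (rounded exports are common; larger deviations
  signal a broken file).
* Missing intensities are absent (`NA`), never zero; zero-filling would
  bias MIDs and replicate counts.
* Candidate ties (two features in one isotopologue window) resolve to the
  closer $m/z$ and are counted; annotation ties order by |ppm|; neighbor
  ties order lexicographically.

# Known limitations

Single charge state per run; no deisotoping of unlabeled data, no adduct
grouping, no charge deconvolution; no purely theoretical natural-abundance
correction when no unlabeled measurement exists; no flux estimation; nodes
are keyed by the MID table's `node_id` with no cross-experiment m/z–RT
re-matching; graph layout and interactive visualization are left to
Cytoscape-compatible consumers of the exported JSON.
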