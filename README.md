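# midcontext

Non-targeted isotopologue detection, mass isotopomer distribution (MID)
correction and labeling-similarity networks for stable-isotope labeling
metabolomics — instrument-agnostic, starting from feature-intensity tables.

## Who this is for

In a tracer experiment (e.g. U-13C-glucose feeding), metabolites downstream
of the tracer incorporate heavy atoms. Their MID — the fraction vector
M0..Mk of molecules carrying 0..k heavy atoms — is the readout of pathway
activity. Targeted tools quantify MIDs for a predefined compound list;
`midcontext` instead scans an untargeted LC-MS (or GC-MS) feature table for
isotopologue groups, corrects their MIDs with the unlabeled condition, and
then *contextualizes* unknowns: metabolites in the same pathway acquire
related labeling patterns, so a similarity network over MIDs places
unannotated features next to annotated compounds.

The package starts after peak picking / alignment / feature grouping: its
inputs are CSV tables (features × samples, sample metadata, optional
compound databases and annotations, optional externally produced MID
tables) and Cytoscape JSON pathway graphs.

## The core computations

**Detection.** For each base feature, candidate isotopologues sit at
m/z₀ + nΔ/z (Δ = 1.0033548 Da for 13C) within a ppm and an RT window.
Per-sample member intensities are normalized to relative intensities, and
each position n ≥ 1 is tested labeled-vs-unlabeled with a Welch t-test;
groups with a significant, enrichment-directed shift are kept and their
features consumed.

**Correction.** With u the unlabeled condition's measured MID and C(u) the
matrix whose j-th column is u shifted down by j (truncated, never
renormalized), the tracer-incorporation distribution f is recovered by
non-negative least squares

    min ||C(u) f − m||₂  subject to f ≥ 0,   corrected MID = f / Σf,

with the reconstruction residual reported. Labeling filters (minimum
labeled enrichment, maximum unlabeled labeling with an optional
formula-aware natural-tail allowance, quantification, residual, replicate
presence) prune the estimates.

**Contextualization.** All node pairs of an MID table are scored (cosine by
default, or simplex-normalized Euclidean), combined across shared
experiments/conditions, thresholded into a network, exportable as
Cytoscape JSON, overlaid on reference pathways by identifier, with
nearest-unknown-neighbor ranking per pathway metabolite.

A forward simulator (`simulate_experiment()`) generates feature tables,
sample sheets and ground truth from tracer-incorporation distributions
convolved with binomial natural abundance, so the whole pipeline is
testable without instrument data. See the methods vignette
(`vignettes/isotope-contextualization.Rmd`) for models, assumptions and
design decisions.

## Worked example

Simulate a small labeling experiment (6 compounds, 3+3 replicates, 5%
intensity CV, 10 decoy features), detect groups, correct MIDs, annotate and
build the network:

```r
library(midcontext)

cfg <- benchmark_config(seed = 1, n_compounds = 6, n_decoys = 10)
sim <- simulate_experiment(cfg)
dim(sim$features)
#> [1] 52  9        # 52 features (42 isotopologues + 10 decoys), 6 samples

groups <- detect_groups(sim$features, sim$samples, tracer_def("13C"),
                        detection_params(ppm_tol = 5, rt_window = 10,
                                         n_max = 12), condition = "A")
length(unique(groups$group_id))
#> [1] 6            # one group per simulated compound, no decoy groups

est <- estimate_mids(groups, sim$features, sim$samples)
cf <- sim$truth$compound_features          # ground truth: feature "F0001" is
e <- est[[which(vapply(est, `[[`, "", "base_feature_id") == "F0001")]]  # glucose M0
round(e$corrected[1:4], 4)
#> [1] 0.4857 0.2946 0.2197 0.0000
sim$truth$label_dists[["glucose"]]
#> [1] 0.4793879 0.3099846 0.2106275
round(e$enrichment, 4);  round(e$residual, 6)
#> [1] 0.5143
#> [1] 0.000721
```

The corrected MID recovers the true incorporation distribution to ~0.015
despite 5% intensity noise; enrichment (1 − M0) says 51% of glucose
molecules carry at least one tracer atom; the small residual says the
convolution model fits. Annotation and contextualization:

```r
ann <- annotate_ms1(sim$features, sim$truth$compounds, ppm_tol = 5)
subset(ann, feature_id == "F0001")
#>   feature_id compound_name formula adduct ppm_error source score
#> 1      F0001       glucose C6H12O6 [M+H]+ -1.161086    ms1    NA

mids <- as_mid_table(est, sim$samples, annotations = ann)
net <- build_network(mids, threshold = 0.9)
head(net$edges[, c("node_a", "node_b", "similarity")], 2)
#>   node_a node_b similarity
#> 1 A_G001 A_G005  0.9956566
#> 2 A_G002 A_G006  0.9996710
write_network_cyjs(net, "network.cyjs")   # open in Cytoscape
```

Both edges connect compounds simulated in the same pathway group — the
similarity network recovers the pathway structure from labeling alone.

### Command line

A thin wrapper exposes the stages as subcommands:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "midcontext.R", package = "midcontext"))')
Rscript $CLI simulate --out-dir data --seed 5
Rscript $CLI pipeline --features data/features.csv --samples data/samples.csv \
    --compounds data/compounds.csv --threshold 0.9 --out-dir run
```

Each stage writes its CSV/JSON outputs plus a run manifest (version,
parameters, input digests, outputs, seed).

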