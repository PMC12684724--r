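# Forward simulation of stable-isotope labeling experiments. Each simulated
# compound carries a tracer-incorporation distribution; the measured MID of
# the labeled state is its convolution with the binomial natural-abundance
# distribution of the tracer element, and the unlabeled state sees the
# natural distribution alone. Features (one per isotopologue) get multiplicative
# lognormal intensity noise, m/z and RT jitter, and optional dropout; decoy
# features without isotopologue partners emulate unrelated background.
# Mass error is modeled the way it behaves on real instruments: a shared
# calibration component per co-eluting isotopologue envelope (sd =
# mz_jitter_ppm) plus a small independent centroid component per feature
# (sd = mz_jitter_ppm / 4) — absolute mass error dominates, while the
# spacing within an envelope is measured far more precisely. Only
# the tracer element contributes natural isotopes (no O/S fine structure):
# the correction step never sees theory, only simulated unlabeled data, so
# the pipeline remains self-consistent.

# linear discrete convolution of two non-negative vectors
.convolve_vec <- function(a, b) {
  L <- length(a) + length(b) - 1L
  out <- numeric(L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' Natural-abundance MID of the tracer element
#'
#' Binomial distribution over the heavy-isotope count of the tracer element
#' (natural heavy fractions: 13C 0.0107, 15N 0.00364, 2H 0.000115),
#' truncated at `n_max` and renormalized.
#'
#' @param formula Formula string or parsed composition.
#' @param tracer A [tracer_def()] (or tracer name).
#' @param n_max Optional truncation index (defaults to the element count).
#' @return Fraction vector M0..Mk.
#' @export
natural_mid <- function(formula, tracer = tracer_def("13C"), n_max = NULL) {
  if (is.character(tracer)) tracer <- tracer_def(tracer)
  comp <- if (is.character(formula)) parse_formula(formula) else formula
  if (!(tracer$element %in% names(comp)))
    stop("formula lacks tracer element '", tracer$element, "'",
         call. = FALSE)
  nE <- comp[[tracer$element]]
  v <- stats::dbinom(0:nE, nE, tracer$natural_fraction)
  if (!is.null(n_max) && n_max < nE) v <- v[1:(n_max + 1L)]
  v / sum(v)
}

#' Simulated compound
#'
#' @param name Compound name.
#' @param formula Formula string.
#' @param rt Retention time in seconds.
#' @param base_abundance Total intensity scale (arbitrary units).
#' @param true_label_dist Tracer-incorporation distribution (simplex vector
#'   over heavy-atom count; its support must fit in the formula's
#'   tracer-element count).
#' @param pathway_group Group label tying compounds with correlated labeling.
#' @param adduct Adduct definition (default `[M+H]+`).
#' @return A `sim_compound` list.
#' @export
sim_compound <- function(name, formula, rt, base_abundance, true_label_dist,
                         pathway_group = "g1",
                         adduct = default_adducts()[1, ]) {
  stopifnot(all(true_label_dist >= 0),
            abs(sum(true_label_dist) - 1) < 1e-9)
  comp <- parse_formula(formula)
  structure(list(name = name, formula = formula, composition = comp,
                 adduct = as.list(adduct), rt = rt,
                 base_abundance = base_abundance,
                 true_label_dist = true_label_dist,
                 pathway_group = pathway_group),
            class = "sim_compound")
}

#' Expected measured MID of a simulated compound
#'
#' Discrete convolution of the tracer-incorporation distribution with the
#' natural-abundance MID, truncated to (tracer-atom count + 1) and
#' renormalized; the unlabeled state uses the point distribution at zero
#' incorporated atoms, so its measured MID is the natural MID exactly.
#'
#' @param compound A [sim_compound()].
#' @param tracer A [tracer_def()].
#' @param labeled Simulate the labeled (`TRUE`) or unlabeled state.
#' @return Fraction vector with attribute `truncated_tail` (mass lost to
#'   truncation before renormalization).
#' @export
true_measured_mid <- function(compound, tracer = tracer_def("13C"),
                              labeled = TRUE) {
  nE <- compound$composition[[tracer$element]]
  if (is.null(nE))
    stop("compound lacks tracer element '", tracer$element, "'",
         call. = FALSE)
  if (max(which(compound$true_label_dist > 0)) - 1L > nE)
    stop("label distribution support exceeds tracer-element count",
         call. = FALSE)
  lab <- if (labeled) compound$true_label_dist else 1
  u <- natural_mid(compound$composition, tracer)
  conv <- .convolve_vec(lab, u)
  keep <- conv[seq_len(min(length(conv), nE + 1L))]
  tail_mass <- sum(conv) - sum(keep)
  out <- keep / sum(keep)
  attr(out, "truncated_tail") <- tail_mass
  out
}

#' Simulation configuration
#'
#' @param compounds List of [sim_compound()] objects.
#' @param n_replicates Replicates per tracer state.
#' @param intensity_cv Relative sd of multiplicative lognormal intensity
#'   noise.
#' @param dropout_intensity Intensities below this become absent (`NA`).
#' @param mz_jitter_ppm Gaussian m/z calibration jitter sd in ppm, shared by
#'   a compound's isotopologue envelope; each feature additionally gets an
#'   independent centroid jitter of sd `mz_jitter_ppm / 4`.
#' @param rt_jitter_s Gaussian RT jitter sd in seconds (per feature).
#' @param n_decoys Number of unrelated decoy features.
#' @param seed RNG seed; the simulation is a pure function of the config.
#' @param tracer Tracer name or [tracer_def()].
#' @param condition,experiment Labels written to the sample sheet.
#' @return A `sim_config` list.
#' @export
sim_config <- function(compounds, n_replicates = 3, intensity_cv = 0.05,
                       dropout_intensity = 0, mz_jitter_ppm = 2,
                       rt_jitter_s = 1, n_decoys = 0, seed = 1,
                       tracer = "13C", condition = "A", experiment = "E1") {
  stopifnot(length(compounds) >= 1, n_replicates >= 1, intensity_cv >= 0,
            dropout_intensity >= 0, mz_jitter_ppm >= 0, rt_jitter_s >= 0,
            n_decoys >= 0)
  if (is.character(tracer)) tracer <- tracer_def(tracer)
  structure(list(compounds = compounds,
                 n_replicates = as.integer(n_replicates),
                 intensity_cv = intensity_cv,
                 dropout_intensity = dropout_intensity,
                 mz_jitter_ppm = mz_jitter_ppm, rt_jitter_s = rt_jitter_s,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 tracer = tracer, condition = condition,
                 experiment = experiment),
            class = "sim_config")
}

#' Simulate a labeling experiment
#'
#' Generates a feature table, a sample sheet and ground-truth tables from a
#' [sim_config()]. One feature is emitted per compound and isotopologue
#' index 0..nE, at `adduct_mz + n * delta_mass / |charge|` with Gaussian ppm
#' jitter; per-sample intensity is `base_abundance * expected_fraction *
#' lognormal(cv)`, with values below the dropout threshold recorded absent.
#' Decoy features are drawn uniformly over the observed m/z and RT ranges
#' with no isotopologue partners and identical expected intensity in both
#' tracer states. All randomness derives from the config seed; the caller's
#' RNG state is restored on exit.
#'
#' @param config A [sim_config()].
#' @return List `features` (`feature_table`), `samples` (`sample_sheet`),
#'   `truth` (list: `compound_features`, `label_dists`, `measured_mids`,
#'   `pathway_groups`, `compounds` data frame of name/formula).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  tracer <- config$tracer
  nrep <- config$n_replicates
  lab_ids <- sprintf("L%d", seq_len(nrep))
  unl_ids <- sprintf("U%d", seq_len(nrep))
  samples <- sample_sheet(data.frame(
    sample_id = c(lab_ids, unl_ids),
    experiment = config$experiment, condition = config$condition,
    tracer_state = rep(c("labeled", "unlabeled"), each = nrep),
    replicate = c(seq_len(nrep), seq_len(nrep)),
    stringsAsFactors = FALSE))
  sdlog <- sqrt(log(1 + config$intensity_cv^2))
  noise <- function(k) stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  rows <- list(); truth_rows <- list(); measured <- list()
  for (cpd in config$compounds) {
    nE <- cpd$composition[[tracer$element]]
    mid_l <- as.numeric(true_measured_mid(cpd, tracer, labeled = TRUE))
    mid_u <- as.numeric(true_measured_mid(cpd, tracer, labeled = FALSE))
    base_mz <- adduct_mz(monoisotopic_mass(cpd$composition), cpd$adduct)
    zch <- abs(cpd$adduct$charge)
    cal_ppm <- stats::rnorm(1, 0, config$mz_jitter_ppm)
    for (n in 0:nE) {
      theo <- base_mz + n * tracer$delta_mass / zch
      mz <- theo * (1 + (cal_ppm +
                           stats::rnorm(1, 0, config$mz_jitter_ppm / 4)) * 1e-6)
      rt <- max(0, cpd$rt + stats::rnorm(1, 0, config$rt_jitter_s))
      ints <- c(cpd$base_abundance * mid_l[n + 1] * noise(nrep),
                cpd$base_abundance * mid_u[n + 1] * noise(nrep))
      rows[[length(rows) + 1L]] <- c(mz = mz, rt = rt, ints)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        compound = cpd$name, n = n, mz_theoretical = theo,
        stringsAsFactors = FALSE)
    }
    measured[[cpd$name]] <- list(labeled = mid_l, unlabeled = mid_u)
  }
  n_real <- length(rows)
  mz_range <- range(vapply(rows, `[[`, numeric(1), "mz"))
  rt_range <- range(vapply(rows, `[[`, numeric(1), "rt"))
  ab_range <- log10(range(vapply(config$compounds, `[[`, numeric(1),
                                 "base_abundance")))
  for (d in seq_len(config$n_decoys)) {
    mz <- stats::runif(1, mz_range[1], mz_range[2])
    rt <- stats::runif(1, rt_range[1], rt_range[2])
    ab <- 10^stats::runif(1, ab_range[1], ab_range[2])
    rows[[length(rows) + 1L]] <- c(mz = mz, rt = rt, ab * noise(2 * nrep))
  }
  mat <- do.call(rbind, rows)
  ids <- sprintf("F%04d", seq_len(nrow(mat)))
  ft <- data.frame(feature_id = ids, mz = mat[, "mz"], rt = mat[, "rt"],
                   stringsAsFactors = FALSE)
  for (k in seq_along(c(lab_ids, unl_ids))) {
    v <- mat[, 2 + k]
    if (config$dropout_intensity > 0) v[v < config$dropout_intensity] <- NA
    ft[[c(lab_ids, unl_ids)[k]]] <- v
  }
  features <- feature_table(ft)
  compound_features <- do.call(rbind, truth_rows)
  compound_features$feature_id <- ids[seq_len(n_real)]
  truth <- list(
    compound_features = compound_features,
    label_dists = stats::setNames(
      lapply(config$compounds, `[[`, "true_label_dist"),
      vapply(config$compounds, `[[`, character(1), "name")),
    measured_mids = measured,
    pathway_groups = data.frame(
      compound = vapply(config$compounds, `[[`, character(1), "name"),
      pathway_group = vapply(config$compounds, `[[`, character(1),
                             "pathway_group"),
      stringsAsFactors = FALSE),
    compounds = data.frame(
      name = vapply(config$compounds, `[[`, character(1), "name"),
      formula = vapply(config$compounds, `[[`, character(1), "formula"),
      stringsAsFactors = FALSE),
    decoy_feature_ids = if (config$n_decoys > 0)
      ids[(n_real + 1L):length(ids)] else character(0))
  list(features = features, samples = samples, truth = truth)
}

# 20 metabolite-like compounds (all with >= 6 tracer carbons) used by the
# benchmark; RTs spaced 38 s so isotopologue windows never collide.
.benchmark_formulas <- data.frame(
  name = c("glucose", "glucose-6-phosphate", "fructose-1,6-bisphosphate",
           "citrate", "cis-aconitate", "gluconate", "N-acetylglucosamine",
           "tryptophan", "phenylalanine", "tyrosine", "histidine", "leucine",
           "lysine", "arginine", "sucrose", "riboflavin", "adenosine",
           "inosine", "pantothenate", "shikimate"),
  formula = c("C6H12O6", "C6H13O9P", "C6H14O12P2", "C6H8O7", "C6H6O6",
              "C6H12O7", "C8H15NO6", "C11H12N2O2", "C9H11NO2", "C9H11NO3",
              "C6H9N3O2", "C6H13NO2", "C6H14N2O2", "C6H14N4O2", "C12H22O11",
              "C17H20N4O6", "C10H13N5O4", "C10H12N4O5", "C9H17NO5",
              "C7H10O5"),
  stringsAsFactors = FALSE)

# archetype tracer-incorporation distributions per pathway group; supports
# are disjoint enough that cross-group cosine stays below 0.8
.group_archetypes <- list(
  g1 = c(0.50, 0.30, 0.20),
  g2 = c(0.20, 0.00, 0.50, 0.30),
  g3 = c(0.10, 0.00, 0.00, 0.00, 0.40, 0.50),
  g4 = c(0.35, 0.05, 0.00, 0.00, 0.00, 0.00, 0.60))

#' Benchmark simulation configuration
#'
#' The study conditions used throughout the test suite and the acceptance
#' script: 20 compounds in 4 pathway groups of 5 (same-group
#' tracer-incorporation distributions are small perturbations of a shared
#' archetype), 3 labeled + 3 unlabeled replicates, 5% intensity CV, 2 ppm
#' m/z jitter, 50 decoy features, 13C tracer. Same-group label distributions
#' have pairwise cosine >= 0.95 and cross-group < 0.8; both are asserted at
#' construction.
#'
#' @param seed RNG seed for the perturbations and the simulation.
#' @param n_compounds Number of compounds (<= 20), mainly for the noise-free
#'   identifiability check.
#' @param intensity_cv,n_decoys,mz_jitter_ppm,rt_jitter_s,n_replicates
#'   Overrides of the benchmark defaults.
#' @return A [sim_config()].
#' @export
benchmark_config <- function(seed = 42, n_compounds = 20,
                             intensity_cv = 0.05, n_decoys = 50,
                             mz_jitter_ppm = 2, rt_jitter_s = 1,
                             n_replicates = 3) {
  stopifnot(n_compounds >= 1, n_compounds <= nrow(.benchmark_formulas))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed + 1L)  # perturbation stream distinct from the sim stream
  groups <- rep(names(.group_archetypes), length.out = n_compounds)
  compounds <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    arch <- .group_archetypes[[groups[i]]]
    support <- arch > 0
    d <- arch
    d[support] <- d[support] + stats::runif(sum(support), 0, 0.04)
    d <- d / sum(d)
    compounds[[i]] <- sim_compound(
      name = .benchmark_formulas$name[i],
      formula = .benchmark_formulas$formula[i],
      rt = 60 + 38 * (i - 1),
      base_abundance = 10^(5 + 0.04 * i),
      true_label_dist = d, pathway_group = groups[i])
  }
  # assert the pathway-group structure the contextualization tests rely on
  L <- max(vapply(compounds, function(cp) length(cp$true_label_dist),
                  integer(1)))
  dists <- t(vapply(compounds, function(cp) .pad(cp$true_label_dist, L),
                    numeric(L)))
  for (i in seq_len(n_compounds)) for (j in seq_len(n_compounds)) {
    if (j <= i) next
    cs <- mid_similarity(dists[i, ], dists[j, ], "cosine")
    if (groups[i] == groups[j] && cs < 0.95)
      stop("benchmark invariant violated: within-group cosine ", cs)
    if (groups[i] != groups[j] && cs >= 0.8)
      stop("benchmark invariant violated: cross-group cosine ", cs)
  }
  sim_config(compounds, n_replicates = n_replicates,
             intensity_cv = intensity_cv, mz_jitter_ppm = mz_jitter_ppm,
             rt_jitter_s = rt_jitter_s, n_decoys = n_decoys, seed = seed)
}

#' Null (no-labeling) simulation configuration
#'
#' One single-carbon compound whose "labeled" samples carry no tracer
#' (incorporation distribution concentrated at zero), so detection faces
#' exactly one Welch test per condition and the per-condition false-positive
#' rate equals the per-test level.
#'
#' @param seed RNG seed.
#' @param intensity_cv Intensity CV.
#' @return A [sim_config()].
#' @export
null_config <- function(seed, intensity_cv = 0.05) {
  cpd <- sim_compound("methanol", "CH4O", rt = 100, base_abundance = 1e5,
                      true_label_dist = 1, pathway_group = "null")
  sim_config(list(cpd), n_replicates = 3, intensity_cv = intensity_cv,
             mz_jitter_ppm = 0.5, rt_jitter_s = 0.2, n_decoys = 0,
             seed = seed)
}
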