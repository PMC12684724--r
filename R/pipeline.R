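# Pipeline entry points behind the command-line interface: one function per
# subcommand, a composed pipeline, and a machine-readable run manifest (tool
# version, parameters verbatim, input digests, outputs, timestamps, seed)
# written beside the outputs so every run is reconstructible.

.pkg_version <- function() as.character(utils::packageVersion("midcontext"))

write_manifest <- function(out_dir, subcommand, params, inputs, outputs,
                           seed = NULL) {
  digest1 <- function(p) if (file.exists(p)) unname(tools::md5sum(p))
                         else NA_character_
  manifest <- list(
    tool = "midcontext", version = .pkg_version(), subcommand = subcommand,
    parameters = params,
    inputs = lapply(stats::setNames(inputs, inputs), digest1),
    outputs = outputs, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest invariant violated: output(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  path <- file.path(out_dir, sprintf("manifest_%s.json", subcommand))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.as_num <- function(x, default) if (is.null(x)) default else as.numeric(x)
.as_chr <- function(x, default) if (is.null(x)) default else as.character(x)
.as_lgl <- function(x, default) if (is.null(x)) default else
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")

cmd_simulate <- function(args) {
  out_dir <- .as_chr(args[["out_dir"]], ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.as_num(args[["seed"]], 42))
  preset <- .as_chr(args[["preset"]], "benchmark")
  config <- switch(preset,
    benchmark = benchmark_config(
      seed = seed,
      n_compounds = as.integer(.as_num(args[["n_compounds"]], 20)),
      intensity_cv = .as_num(args[["cv"]], 0.05),
      n_decoys = as.integer(.as_num(args[["decoys"]], 50))),
    null = null_config(seed),
    stop("unknown simulate preset '", preset, "'", call. = FALSE))
  sim <- simulate_experiment(config)
  fp <- file.path(out_dir, "features.csv")
  sp <- file.path(out_dir, "samples.csv")
  cp <- file.path(out_dir, "compounds.csv")
  tp <- file.path(out_dir, "truth_compound_features.csv")
  write_feature_table(sim$features, fp)
  write_sample_sheet(sim$samples, sp)
  .write_csv(sim$truth$compounds, cp,
             quote_cols = .text_cols(sim$truth$compounds))
  .write_csv(sim$truth$compound_features, tp,
             quote_cols = .text_cols(sim$truth$compound_features))
  write_manifest(out_dir, "simulate", args, character(0),
                 c(fp, sp, cp, tp), seed = seed)
  list(features = fp, samples = sp, compounds = cp)
}

cmd_annotate <- function(args) {
  features <- read_feature_table(args[["features"]])
  compounds <- .read_csv_raw(args[["compounds"]])
  adducts <- if (!is.null(args[["adducts"]])) {
    a <- .read_csv_raw(args[["adducts"]])
    a$multimer <- as.integer(a$multimer)
    a$delta_mass <- as.numeric(a$delta_mass)
    a$charge <- as.integer(a$charge)
    a
  } else default_adducts()
  ann <- annotate_ms1(features, compounds, adducts,
                      ppm_tol = .as_num(args[["ppm_tol"]], 5))
  out <- .as_chr(args[["out"]], "annotations.csv")
  write_annotation_table(ann, out)
  write_manifest(dirname(out), "annotate", args,
                 c(args[["features"]], args[["compounds"]]), out)
  out
}

cmd_detect <- function(args) {
  features <- read_feature_table(args[["features"]])
  samples <- read_sample_sheet(args[["samples"]])
  params <- detection_params(
    ppm_tol = .as_num(args[["ppm_tol"]], 5),
    rt_window = .as_num(args[["rt_window"]], 10),
    n_max = as.integer(.as_num(args[["n_max"]], 10)),
    charge = as.integer(.as_num(args[["charge"]], 1)),
    alpha = .as_num(args[["alpha"]], 0.05),
    noise_floor = .as_num(args[["noise_floor"]], 0),
    fdr = .as_lgl(args[["fdr"]], FALSE))
  groups <- detect_all_groups(features, samples,
                              tracer_def(.as_chr(args[["tracer"]], "13C")), params)
  out <- .as_chr(args[["out"]], "groups.csv")
  write_groups_csv(groups, out)
  write_manifest(dirname(out), "detect", args,
                 c(args[["features"]], args[["samples"]]), out)
  out
}

cmd_mids <- function(args) {
  features <- read_feature_table(args[["features"]])
  samples <- read_sample_sheet(args[["samples"]])
  groups <- read_groups_csv(args[["groups"]])
  annotations <- if (!is.null(args[["annotations"]]))
    read_annotation_table(args[["annotations"]]) else NULL
  est <- estimate_mids(groups, features, samples)
  fp <- mid_filter_params(
    min_labeled_enrichment = .as_num(args[["min_enrichment"]], 0.05),
    max_unlabeled_labeling = .as_num(args[["max_unlabeled"]], 0.05),
    min_quantification = .as_num(args[["min_quant"]], 0),
    max_residual = .as_num(args[["max_residual"]], 0.05))
  filt <- filter_mids(est, fp, annotations = annotations,
                      tracer = tracer_def(.as_chr(args[["tracer"]], "13C")))
  if (!length(filt$kept))
    stop("all MID estimates were rejected by the labeling filters",
         call. = FALSE)
  mids <- as_mid_table(filt$kept, samples, annotations = annotations)
  out <- .as_chr(args[["out"]], "mids.csv")
  write_mid_table(mids, out)
  rej <- sub("\\.csv$", "_rejected.csv", out)
  .write_csv(filt$rejected, rej, quote_cols = .text_cols(filt$rejected))
  write_manifest(dirname(out), "mids", args,
                 c(args[["features"]], args[["samples"]], args[["groups"]]), c(out, rej))
  out
}

cmd_contextualize <- function(args) {
  mids <- read_mid_table(args[["mids"]])
  net <- build_network(mids,
                       threshold = .as_num(args[["threshold"]], 0.9),
                       metric = .as_chr(args[["metric"]], "cosine"),
                       combine = .as_chr(args[["combine"]], "mean"))
  out <- .as_chr(args[["out"]], "network.cyjs")
  write_network_cyjs(net, out)
  outputs <- out
  edge_csv <- sub("\\.cyjs$", "_edges.csv", out)
  edf <- net$edges
  txt <- .text_cols(edf)
  edf$similarity <- .fmt_num(edf$similarity)
  .write_csv(edf, edge_csv, quote_cols = txt)
  outputs <- c(outputs, edge_csv)
  if (!is.null(args[["pathway"]])) {
    pw <- read_pathway_cyjs(args[["pathway"]],
                            id_attribute = .as_chr(args[["id_attribute"]], "id"))
    ov <- map_to_pathway(net, pw)
    match_csv <- sub("\\.cyjs$", "_pathway_matches.csv", out)
    .write_csv(ov$matches, match_csv, quote_cols = .text_cols(ov$matches))
    outputs <- c(outputs, match_csv)
  }
  write_manifest(dirname(out), "contextualize", args,
                 c(args[["mids"]], args[["pathway"]]), outputs)
  out
}

#' Run one pipeline subcommand
#'
#' Dispatches to the simulate / annotate / detect / mids / contextualize /
#' pipeline stage, validates arguments, and writes a JSON run manifest
#' (version, parameters, input digests, outputs, seed) beside the outputs.
#'
#' @param name Subcommand name.
#' @param args Named list of arguments (CLI flags with `-` mapped to `_`).
#' @return The primary output path(s), invisibly.
#' @export
run_subcommand <- function(name, args = list()) {
  fn <- switch(name,
               simulate = cmd_simulate, annotate = cmd_annotate,
               detect = cmd_detect, mids = cmd_mids,
               contextualize = cmd_contextualize, pipeline = run_pipeline,
               stop("unknown subcommand '", name, "'; valid: simulate, ",
                    "annotate, detect, mids, contextualize, pipeline",
                    call. = FALSE))
  invisible(fn(args))
}

#' Run the full table-to-network pipeline
#'
#' Chains annotate (optional) -> detect -> mids -> contextualize on feature
#' and sample tables, writing each stage's CSV and a final Cytoscape JSON
#' network; with `mids_only = TRUE` (or an `args[["mids"]]` input), only the
#' contextualization stage runs, starting from an MID CSV.
#'
#' @param args Named list: `features`, `samples`, optional `compounds`,
#'   `pathway`, `out_dir`, `mids` (+ the per-stage tuning flags).
#' @return Path of the final network file, invisibly.
#' @export
run_pipeline <- function(args) {
  out_dir <- .as_chr(args[["out_dir"]], ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (.as_lgl(args[["mids_only"]], FALSE) ||
      (!is.null(args[["mids"]]) && is.null(args[["features"]]))) {
    cargs <- args
    cargs$out <- .as_chr(args[["out"]], file.path(out_dir, "network.cyjs"))
    return(invisible(cmd_contextualize(cargs)))
  }
  if (is.null(args[["features"]]) || is.null(args[["samples"]]))
    stop("pipeline requires --features and --samples (or --mids for a ",
         "contextualization-only run)", call. = FALSE)
  ann_path <- NULL
  if (!is.null(args[["compounds"]]) && !.as_lgl(args[["skip_annotate"]], FALSE)) {
    aargs <- args
    aargs$out <- file.path(out_dir, "annotations.csv")
    ann_path <- cmd_annotate(aargs)
  }
  dargs <- args
  dargs$out <- file.path(out_dir, "groups.csv")
  groups_path <- cmd_detect(dargs)
  margs <- args
  margs$groups <- groups_path
  margs$annotations <- ann_path
  margs$out <- file.path(out_dir, "mids.csv")
  mids_path <- cmd_mids(margs)
  cargs <- args
  cargs$mids <- mids_path
  cargs$out <- file.path(out_dir, "network.cyjs")
  invisible(cmd_contextualize(cargs))
}
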