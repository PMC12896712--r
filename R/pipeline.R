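# YAML-configured end-to-end pipeline:
# simulate -> fst -> reference sets -> predict -> evaluate.

run_config_schema <- list(
  scale = "character", populations = "character",
  fst_threshold = "numeric", fractions = "numeric",
  aggregate = "character", models = "character", varcomp = "character",
  replicates = "numeric", master_seed = "numeric", baseline = "logical")

#' Read and validate a pipeline run configuration
#'
#' The YAML file may set: `scale` (desk/full), `populations`,
#' `fst_threshold`, `fractions`, `aggregate`, `models`, `varcomp`
#' (true/reml), `replicates`, `master_seed`, `baseline`. Unknown keys are
#' rejected by name; missing keys fall back to the shipped defaults. The
#' configuration round-trips losslessly through YAML.
#'
#' @param path YAML file path.
#' @return validated configuration list of class `run_config`, with
#'   attribute `md5` (hash of the file).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(run_config_schema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- list(scale = "desk", populations = c("A", "B", "C"),
                   fst_threshold = 0.1, fractions = c(0.10, 0.15, 0.20),
                   aggregate = "centroid",
                   models = c("gblup", "ssgblup", "wgblup"),
                   varcomp = "true", replicates = 2, master_seed = 1,
                   baseline = TRUE)
  cfg <- modifyList(defaults, cfg)
  for (k in names(run_config_schema)) {
    ok <- switch(run_config_schema[[k]],
                 character = is.character(cfg[[k]]),
                 numeric = is.numeric(cfg[[k]]),
                 logical = is.logical(cfg[[k]]))
    if (!ok) stop(sprintf("configuration key `%s` must be %s", k,
                          run_config_schema[[k]]), call. = FALSE)
  }
  if (!cfg$scale %in% c("desk", "full"))
    stop("scale must be \"desk\" or \"full\"", call. = FALSE)
  if (!cfg$varcomp %in% c("true", "reml"))
    stop("varcomp must be \"true\" or \"reml\"", call. = FALSE)
  structure(cfg, md5 = unname(tools::md5sum(path)), class = "run_config")
}

#' Run the full pipeline from a configuration file
#'
#' Executes simulate -> Fst -> reference-set construction -> prediction ->
#' evaluation for every replicate and writes the artefacts into `out_dir`:
#' per-population study tables and per-donor Fst/LD/PCA diagnostics for
#' the first replicate, a scenario manifest (JSON), the tidy
#' `results.tsv`, the per-cell `summary.tsv`, and a structured
#' `manifest.json` log (stage, seed, wall time, warnings). A schema
#' violation aborts before any computation.
#'
#' @param config path to a YAML configuration, or a `run_config`.
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @return invisibly, the [run_grid()] result.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  md5 <- attr(cfg, "md5") %||% NA
  if (!is.null(seed)) cfg$master_seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character()
    val <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    log[[length(log) + 1L]] <<- list(
      stage = name, seed = cfg$master_seed,
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
      warnings = warns)
    val
  }

  rep1_seed <- derive_seeds(cfg$master_seed, 1, stage = 17L)
  studies <- stage("simulate",
                   simulate_populations(rep1_seed, cfg$scale,
                                        pops = cfg$populations))
  for (p in cfg$populations)
    write_study(studies[[p]], file.path(out_dir, paste0("pop", p)),
                config_md5 = md5)

  for (dn in intersect(c("B", "C"), cfg$populations)) {
    fst <- stage(paste0("fst-A", dn), fst_per_snp(
      studies$A$genotypes[studies$A$reference_ids, , drop = FALSE],
      studies[[dn]]$genotypes[studies[[dn]]$reference_ids, , drop = FALSE]))
    write_tsv(cbind(studies$A$genome$markers, fst[c("fst", "undefined")]),
              file.path(out_dir, sprintf("fst_A_%s.tsv", dn)),
              paste0("fst-A", dn), rep1_seed, md5)
  }
  ld <- stage("ld-decay", ld_decay(
    studies$A$genotypes[studies$A$validation_ids, , drop = FALSE],
    studies$A$genome))
  write_tsv(ld, file.path(out_dir, "ld_decay_A.tsv"), "ld-decay",
            rep1_seed, md5)
  all_val <- do.call(rbind, lapply(cfg$populations, function(p)
    studies[[p]]$genotypes[studies[[p]]$validation_ids, , drop = FALSE]))
  pc <- stage("pca", pca_coords(all_val, 2))
  write_tsv(data.frame(id = rownames(pc), pc), file.path(out_dir, "pca.tsv"),
            "pca", rep1_seed, md5)

  scen <- stage("build-refsets", build_scenarios(
    studies$A, studies$B, studies$C, fst_threshold = cfg$fst_threshold,
    fractions = cfg$fractions, aggregate = cfg$aggregate,
    baseline = cfg$baseline))
  manifest <- lapply(scen, function(s)
    list(name = s$name, group = s$group, donor = s$donor,
         fraction = s$fraction, n_reference = length(s$reference_ids),
         n_validation = length(s$validation_ids),
         n_screened_snps = s$n_screened,
         aggregate = cfg$aggregate, fst_threshold = cfg$fst_threshold))
  jsonlite::write_json(manifest, file.path(out_dir, "scenarios.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  grid <- stage("grid", run_grid(
    replicates = cfg$replicates, master_seed = cfg$master_seed,
    scale = cfg$scale, models = cfg$models, fractions = cfg$fractions,
    fst_threshold = cfg$fst_threshold, baseline = cfg$baseline,
    varcomp = cfg$varcomp, aggregate = cfg$aggregate))
  write_tsv(grid$records, file.path(out_dir, "results.tsv"), "evaluate",
            cfg$master_seed, md5)
  write_tsv(grid$summary, file.path(out_dir, "summary.tsv"), "evaluate",
            cfg$master_seed, md5)
  jsonlite::write_json(
    list(config = unclass(cfg), config_md5 = md5, stages = log),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(grid)
}
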