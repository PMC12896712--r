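# Fit a prediction model to a reference scenario and score the target
# population's validation animals.

#' Predict validation breeding values under a reference scenario
#'
#' Assembles the training data defined by a [build_scenarios()] scenario,
#' fits the requested model with [gsblup()], and returns GEBVs for the
#' validation individuals (the target population's final generation, whose
#' phenotypes are never used).
#'
#' Training phenotypes are the scenario's reference individuals'. For
#' `"ssgblup"` and `"pblup"`, which carry information through the
#' pedigree, the non-genotyped earlier generations of the *target*
#' population additionally contribute phenotypes whenever the target's
#' reference generation is part of the reference set (the single-step
#' rationale: ungenotyped relatives' records enter through `H`); donor
#' populations contribute only their selected individuals' records, since
#' the donor herd's other data are not part of the constructed reference
#' set. Genotypes always cover reference plus validation individuals.
#'
#' @param model `"gblup"`, `"ssgblup"`, `"wgblup"` or `"pblup"`.
#' @param scenario a `ref_scenario`.
#' @param studies named list of `sim_study` objects (as returned by
#'   [simulate_populations()]): must contain every population contributing
#'   ids to the scenario.
#' @param varcomp `varcomp` object; `NULL` uses the true simulated
#'   components of the target study.
#' @param ... passed to [gsblup()] (e.g. `blend`, `window`).
#' @return list of class `scenario_prediction`: `gebv` (named vector over
#'   validation ids), `fit` (the `gsblup` object), `scenario`, `model`.
#' @export
predict_scenario <- function(model = c("gblup", "ssgblup", "wgblup", "pblup"),
                             scenario, studies, varcomp = NULL, ...) {
  model <- match.arg(model)
  pops <- Filter(function(s) inherits(s, "sim_study"), studies)
  target <- pops[[which(vapply(pops, function(s)
    all(scenario$validation_ids %in% s$pedigree$id), logical(1)))[1]]]
  if (is.null(varcomp))
    varcomp <- varcomp_true(target$architecture$sigma_a2,
                            target$architecture$sigma_e2)

  ref <- scenario$reference_ids
  val <- scenario$validation_ids
  involved <- pops[vapply(pops, function(s)
    any(c(ref, val) %in% s$pedigree$id), logical(1))]

  geno <- do.call(rbind, lapply(involved, function(s) {
    ids <- intersect(c(ref, val), s$pedigree$id)
    s$genotypes[ids, , drop = FALSE]
  }))
  miss <- setdiff(c(ref, val), rownames(geno))
  if (length(miss))
    stop("scenario ids not found in any study: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)

  train_ids <- ref
  if (model %in% c("ssgblup", "pblup")) {
    tgt_ref_gen <- min(target$reference_generations)
    if (all(target$reference_ids %in% ref)) {
      anc <- target$pedigree$id[target$pedigree$generation < tgt_ref_gen]
      train_ids <- c(anc, ref)
    }
  }
  y <- unlist(lapply(involved, function(s)
    s$phenotype[intersect(train_ids, s$pedigree$id)]), use.names = TRUE)
  names(y) <- sub("^[^.]*\\.", "", names(y))  # strip list-name prefixes
  dat <- data.frame(id = names(y), y = unname(y), stringsAsFactors = FALSE)

  ped <- if (model %in% c("ssgblup", "pblup"))
    do.call(rbind, c(lapply(involved, function(s) s$pedigree),
                     list(make.row.names = FALSE)))
  else NULL

  chrom <- target$genome$markers$chrom
  fit <- gsblup(y ~ 1, dat, genotypes = geno, pedigree = ped,
                method = model, varcomp = varcomp,
                marker_chrom = chrom, ...)
  structure(list(gebv = predict(fit, val), fit = fit,
                 scenario = scenario$name, model = model),
            class = "scenario_prediction")
}

#' @export
#' @method print scenario_prediction
print.scenario_prediction <- function(x, ...) {
  cat(sprintf("scenario_prediction: %s under %s, %d validation GEBVs\n",
              x$scenario, x$model, length(x$gebv)))
  invisible(x)
}
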