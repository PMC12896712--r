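# Reference-set construction: distance ranking over Fst-screened markers
# and stratified single-/cross-population scenarios.

#' Euclidean genetic distance of candidates to a target population
#'
#' The target population is summarised by its per-marker mean allele-count
#' vector over the screened marker subset (`aggregate = "centroid"`, the
#' default: O(n) per candidate, and under squared distance it ranks
#' candidates identically to the mean pairwise distance). Each candidate's
#' distance is the Euclidean norm of its genotype vector minus that
#' summary. `"mean_pair"` and `"min_pair"` aggregate over all pairwise
#' candidate-target distances instead.
#'
#' @param candidate_genotypes,target_genotypes allele-count matrices with
#'   rownames ids, covering at least the markers in `snp_subset`.
#' @param snp_subset non-empty integer vector of screened marker columns
#'   (from [screen_snps()]).
#' @param aggregate distance aggregation mode.
#' @return a data frame of class `distance_ranking` with columns `id`,
#'   `distance`, sorted ascending by distance (ties by id); attributes
#'   `snp_subset` and `aggregate`.
#' @export
distance_to_target <- function(candidate_genotypes, target_genotypes,
                               snp_subset,
                               aggregate = c("centroid", "mean_pair",
                                             "min_pair")) {
  aggregate <- match.arg(aggregate)
  if (!length(snp_subset))
    stop("empty marker subset: Fst screening selected no markers",
         call. = FALSE)
  Xc <- candidate_genotypes[, snp_subset, drop = FALSE]
  Xt <- target_genotypes[, snp_subset, drop = FALSE]
  if (aggregate == "centroid") {
    centroid <- colMeans(Xt)
    d <- sqrt(rowSums(sweep(Xc, 2, centroid)^2))
  } else {
    # squared pairwise distances candidates x target individuals
    D2 <- outer(rowSums(Xc^2), rowSums(Xt^2), "+") - 2 * tcrossprod(Xc, Xt)
    D2[D2 < 0] <- 0
    d <- if (aggregate == "mean_pair") rowMeans(sqrt(D2))
         else apply(sqrt(D2), 1, min)
  }
  ids <- rownames(candidate_genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Xc)))
  ord <- order(d, ids)
  structure(data.frame(id = ids[ord], distance = unname(d[ord]),
                       stringsAsFactors = FALSE),
            snp_subset = snp_subset, aggregate = aggregate,
            class = c("distance_ranking", "data.frame"))
}

#' Select the genetically most similar candidates
#'
#' Takes the `k = max(1, floor(fraction * n))` candidates with the smallest
#' distance; ties are broken by ascending candidate id.
#'
#' @param ranking a [distance_to_target()] ranking.
#' @param fraction fraction of candidates to keep, in (0, 1].
#' @return character vector of selected ids.
#' @export
select_similar <- function(ranking, fraction) {
  if (!nrow(ranking)) stop("empty ranking", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  k <- max(1L, floor(fraction * nrow(ranking)))
  ranking$id[seq_len(k)]
}

#' Build single- and cross-population reference scenarios
#'
#' For each donor population (B, C) and each fraction, markers differentiated
#' between the target and that donor are screened (`Fst > fst_threshold`),
#' donor reference-generation individuals are ranked by Euclidean distance to
#' the target's reference individuals over those markers, and the closest
#' fraction is selected. Each selection yields a *cross* scenario (target
#' reference plus selected donors, named e.g. `"A+10%B"`) and a *signal*
#' scenario (the selected donors alone, named e.g. `"signal-B-10"`).
#' Validation individuals are always the target population's final
#' generation and never enter any reference set. A `baseline` scenario
#' (`"A-only"`) with the target reference alone is included by default.
#'
#' @param popA_study,popB_study,popC_study `sim_study` objects on a shared
#'   genome with disjoint id spaces (donor studies may be `NULL` to skip).
#' @param fst_threshold screening threshold (strict `>`), default 0.1.
#' @param fractions donor fractions, default `c(0.10, 0.15, 0.20)`.
#' @param aggregate distance aggregation, see [distance_to_target()].
#' @param signal `"selected"` (default: the signal scenario uses the same
#'   selected donors alone) or `"full"` (the whole donor reference
#'   generation).
#' @param baseline include the target-only scenario?
#' @return list of `ref_scenario` objects: each has `name`, `group`
#'   (`"cross"`, `"signal"` or `"baseline"`), `donor`, `fraction`,
#'   `reference_ids`, `validation_ids`, `snp_subset`, `n_screened`.
#' @export
build_scenarios <- function(popA_study, popB_study = NULL, popC_study = NULL,
                            fst_threshold = 0.1,
                            fractions = c(0.10, 0.15, 0.20),
                            aggregate = "centroid",
                            signal = c("selected", "full"),
                            baseline = TRUE) {
  signal <- match.arg(signal)
  target_ref <- popA_study$reference_ids
  validation <- popA_study$validation_ids
  donors <- Filter(Negate(is.null),
                   list(B = popB_study, C = popC_study))
  all_ids <- c(popA_study$pedigree$id,
               unlist(lapply(donors, function(s) s$pedigree$id)))
  if (anyDuplicated(all_ids))
    stop("population id spaces overlap", call. = FALSE)

  scen <- list()
  add <- function(name, group, donor, fraction, reference, subset) {
    stopifnot(!any(reference %in% validation))
    scen[[length(scen) + 1L]] <<- structure(
      list(name = name, group = group, donor = donor, fraction = fraction,
           reference_ids = reference, validation_ids = validation,
           snp_subset = subset, n_screened = length(subset)),
      class = "ref_scenario")
  }
  if (baseline)
    add("A-only", "baseline", NA_character_, NA_real_, target_ref,
        integer())

  tgt_geno <- popA_study$genotypes[target_ref, , drop = FALSE]
  for (dn in names(donors)) {
    dstudy <- donors[[dn]]
    cand_ids <- dstudy$reference_ids
    fst <- fst_per_snp(tgt_geno,
                       dstudy$genotypes[cand_ids, , drop = FALSE])
    subset <- suppressWarnings(screen_snps(fst, fst_threshold))
    if (!length(subset)) {
      warning("no markers pass Fst screening for donor ", dn,
              "; its scenarios are skipped")
      next
    }
    ranking <- distance_to_target(
      dstudy$genotypes[cand_ids, , drop = FALSE], tgt_geno, subset,
      aggregate = aggregate)
    for (f in fractions) {
      sel <- select_similar(ranking, f)
      pct <- round(100 * f)
      add(sprintf("A+%d%%%s", pct, dn), "cross", dn, f,
          c(target_ref, sel), subset)
      sig_ids <- if (signal == "selected") sel else cand_ids
      add(sprintf("signal-%s-%d", dn, pct), "signal", dn, f,
          sig_ids, subset)
    }
  }
  scen
}

#' @export
#' @method print ref_scenario
print.ref_scenario <- function(x, ...) {
  cat(sprintf("ref_scenario %s [%s]: %d reference, %d validation, %d screened SNPs\n",
              x$name, x$group, length(x$reference_ids),
              length(x$validation_ids), x$n_screened))
  invisible(x)
}
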