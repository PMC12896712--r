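# Scoring (accuracy, dispersion bias) and the scenario x model x replicate
# evaluation grid.

#' Prediction accuracy
#'
#' Pearson correlation between predicted and true breeding values.
#'
#' @param gebv,tbv numeric vectors of equal length >= 3, both
#'   non-constant.
#' @return the correlation `r`.
#' @export
accuracy <- function(gebv, tbv) {
  check_score_input(gebv, tbv)
  cor(gebv, tbv)
}

#' Prediction dispersion bias
#'
#' `b = Cov(GEBV, TBV) / Var(GEBV)`, the slope of the regression of true
#' on predicted breeding values; `b = 1` indicates neither inflated nor
#' deflated predictions. The standard error is the ordinary least-squares
#' slope standard error of that regression.
#'
#' @param gebv,tbv numeric vectors of equal length >= 3; `Var(gebv) > 0`.
#' @return list with `b` and `se`.
#' @export
bias <- function(gebv, tbv) {
  check_score_input(gebv, tbv, check_tbv = FALSE)
  n <- length(gebv)
  sxx <- sum((gebv - mean(gebv))^2)
  b <- sum((gebv - mean(gebv)) * (tbv - mean(tbv))) / sxx
  a <- mean(tbv) - b * mean(gebv)
  rss <- sum((tbv - a - b * gebv)^2)
  list(b = b, se = sqrt(rss / (n - 2) / sxx))
}

check_score_input <- function(gebv, tbv, check_tbv = TRUE) {
  if (length(gebv) != length(tbv))
    stop("gebv and tbv must have equal length", call. = FALSE)
  if (length(gebv) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (var(gebv) == 0)
    stop("predictions are constant; score undefined", call. = FALSE)
  if (check_tbv && var(tbv) == 0)
    stop("true values are constant; score undefined", call. = FALSE)
  invisible(TRUE)
}

#' Run the full scenario x model x replicate evaluation grid
#'
#' For each replicate seed: simulate the three populations on a shared
#' genome, build the single-population (signal) and cross-population
#' reference scenarios, fit every requested model on each, and score
#' accuracy and bias on the target population's validation animals against
#' their true breeding values. A failing stage aborts that replicate with
#' a recorded reason; the grid completes the remaining replicates.
#'
#' @param replicates number of replicate simulations (the full design uses
#'   5).
#' @param master_seed master seed; replicate seeds are derived from it.
#' @param scale `"desk"` or `"full"`.
#' @param models models to fit.
#' @param fractions donor fractions.
#' @param fst_threshold Fst screening threshold.
#' @param baseline include the target-only scenario?
#' @param varcomp `"true"` (simulated components) or `"reml"`.
#' @param aggregate distance aggregation mode for [distance_to_target()].
#' @param ... passed to [gsblup()] via [predict_scenario()].
#' @return object of class `gs_grid`: list with `records` (tidy data frame:
#'   scenario, group, donor, model, fraction, replicate, accuracy, bias,
#'   bias_se, n_validation), `summary` (mean and SD per cell), `failures`.
#' @export
run_grid <- function(replicates = 5, master_seed = 1,
                     scale = c("desk", "full"),
                     models = c("gblup", "ssgblup", "wgblup"),
                     fractions = c(0.10, 0.15, 0.20),
                     fst_threshold = 0.1, baseline = TRUE,
                     varcomp = c("true", "reml"), aggregate = "centroid",
                     ...) {
  scale <- match.arg(scale)
  varcomp <- match.arg(varcomp)
  seeds <- derive_seeds(master_seed, replicates, stage = 17L)
  rec <- list(); failures <- list()
  for (r in seq_len(replicates)) {
    res <- tryCatch(
      grid_replicate(seeds[r], r, scale, models, fractions, fst_threshold,
                     baseline, varcomp, aggregate, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(res)))
      failures[[length(failures) + 1L]] <-
        data.frame(replicate = r, reason = conditionMessage(res))
    } else {
      rec[[length(rec) + 1L]] <- res
    }
  }
  records <- do.call(rbind, c(rec, list(make.row.names = FALSE)))
  out <- list(records = records, summary = summarise_grid(records),
              failures = do.call(rbind, failures),
              master_seed = master_seed, scale = scale)
  class(out) <- "gs_grid"
  out
}

grid_replicate <- function(seed, replicate, scale, models, fractions,
                           fst_threshold, baseline, varcomp,
                           aggregate = "centroid", ...) {
  studies <- simulate_populations(seed, scale)
  scen <- build_scenarios(studies$A, studies$B, studies$C,
                          fst_threshold = fst_threshold,
                          fractions = fractions, baseline = baseline,
                          aggregate = aggregate)
  tbv_val <- studies$A$tbv[studies$A$validation_ids]
  vc <- if (varcomp == "true")
    varcomp_true(studies$A$architecture$sigma_a2,
                 studies$A$architecture$sigma_e2)
  else NULL
  rows <- list()
  for (sc in scen) for (m in models) {
    pred <- predict_scenario(m, sc, studies, varcomp = vc, ...)
    bb <- bias(pred$gebv, tbv_val)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc$name, group = sc$group, donor = sc$donor, model = m,
      fraction = sc$fraction, replicate = replicate,
      accuracy = accuracy(pred$gebv, tbv_val),
      bias = bb$b, bias_se = bb$se,
      n_validation = length(pred$gebv), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

summarise_grid <- function(records) {
  if (is.null(records) || !nrow(records)) return(NULL)
  agg <- aggregate(cbind(accuracy, bias) ~ group + donor + fraction + model,
                   data = records, FUN = mean, na.action = na.omit)
  sdv <- aggregate(cbind(accuracy, bias) ~ group + donor + fraction + model,
                   data = records, FUN = sd, na.action = na.omit)
  names(agg)[names(agg) == "accuracy"] <- "mean_accuracy"
  names(agg)[names(agg) == "bias"] <- "mean_bias"
  agg$sd_accuracy <- sdv$accuracy
  agg$sd_bias <- sdv$bias
  agg[order(agg$group, agg$donor, agg$fraction, agg$model), ]
}

#' @export
#' @method print gs_grid
print.gs_grid <- function(x, ...) {
  nrep <- length(unique(x$records$replicate))
  cat(sprintf("gs_grid [%s scale]: %d records over %d replicates\n",
              x$scale, nrow(x$records), nrep))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$failures) && nrow(x$failures))
    cat(sprintf("%d failed replicates\n", nrow(x$failures)))
  invisible(x)
}

#' Accuracy profile of an evaluation grid
#'
#' Mean accuracy per donor fraction, one line per group x model, drawn
#' with base graphics.
#'
#' @param x a [run_grid()] result.
#' @param ... unused.
#' @export
plot.gs_grid <- function(x, ...) {
  s <- x$summary[x$summary$group %in% c("signal", "cross"), ]
  if (is.null(s) || !nrow(s)) return(invisible(x))
  cells <- unique(s[, c("group", "model", "donor")])
  graphics::plot(range(s$fraction), range(s$mean_accuracy), type = "n",
                 xlab = "donor fraction", ylab = "mean accuracy", ...)
  for (i in seq_len(nrow(cells))) {
    sel <- s$group == cells$group[i] & s$model == cells$model[i] &
      s$donor == cells$donor[i]
    d <- s[sel, ]
    graphics::lines(d$fraction, d$mean_accuracy,
                    lty = if (cells$group[i] == "cross") 1 else 2,
                    col = match(cells$model[i], unique(s$model)))
  }
  graphics::legend("bottomright", bty = "n", cex = 0.8,
                   legend = c("cross (solid) / signal (dashed)",
                              unique(s$model)),
                   col = c(NA, seq_along(unique(s$model))),
                   lty = c(NA, rep(1, length(unique(s$model)))))
  invisible(x)
}
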