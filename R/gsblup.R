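#' Fit a genomic / pedigree BLUP animal model
#'
#' Central fitting function for the four prediction machineries:
#' \describe{
#'   \item{`"pblup"`}{pedigree BLUP: random effects over all pedigree ids
#'     with the sparse inverse numerator relationship matrix.}
#'   \item{`"gblup"`}{GBLUP: random effects over the genotyped ids with the
#'     blended VanRaden genomic relationship matrix `G*`.}
#'   \item{`"ssgblup"`}{single-step GBLUP: random effects over all pedigree
#'     ids with `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`, combining
#'     genotyped and non-genotyped animals.}
#'   \item{`"wgblup"`}{two-step SNP-window-weighted GBLUP: a first fit with
#'     unit SNP weights yields back-solved SNP effects, window-averaged
#'     squared effects become variance weights (mean 1), and the model is
#'     refit once with the weighted genomic matrix.}
#' }
#' All methods solve Henderson's mixed-model equations at
#' `lambda = sigma_e2 / sigma_a2`. Records with missing response are
#' dropped; individuals without records still receive breeding values
#' through the relationship structure.
#'
#' @param formula model formula for the response and fixed effects, e.g.
#'   `y ~ 1` (an overall mean).
#' @param data data frame with an `id` column plus the model variables;
#'   one row per phenotypic record.
#' @param genotypes allele-count matrix (individuals x markers, rownames
#'   ids) for the genotyped set; required by all methods except `"pblup"`.
#' @param pedigree pedigree data frame (`id`, `sire`, `dam`; parents before
#'   offspring); required by `"pblup"` and `"ssgblup"`.
#' @param method one of `"gblup"`, `"pblup"`, `"ssgblup"`, `"wgblup"`.
#' @param varcomp a `varcomp` object ([varcomp_true()] or [em_reml()]
#'   output); `NULL` estimates the components by EM-REML on the fitted
#'   relationship structure.
#' @param blend identity blending weight for `G*` (default 0.05).
#' @param center centre allele counts by `2p` when building `G` (default
#'   `TRUE`).
#' @param allele_freq optional allele frequencies for `G` (default:
#'   computed from `genotypes`).
#' @param snp_weights optional fixed SNP variance weights for `"wgblup"`;
#'   skips the first step (unit weights reproduce GBLUP exactly).
#' @param window window half-width `S` for [window_weights()] (default 20).
#' @param marker_chrom optional chromosome id per marker so that weight
#'   windows do not span chromosome boundaries.
#' @return an object of class `gsblup` with components `b` (fixed
#'   effects), `u` (breeding values for every random-effect id), `varcomp`,
#'   `lambda`, `method`, `fitted`, `residuals`, `alpha` and `snp_weights`
#'   (wgblup), `mme_residual`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`.
#' @examples
#' set.seed(1)
#' M <- matrix(rbinom(50 * 80, 2, 0.5), 50,
#'             dimnames = list(paste0("id", 1:50), NULL))
#' u <- drop(scale(M) %*% rnorm(80)) * 0.1
#' d <- data.frame(id = rownames(M), y = u + rnorm(50, 0, 0.7))
#' fit <- gsblup(y ~ 1, d, genotypes = M, varcomp = varcomp_true(0.3, 0.7))
#' fit
#' cor(u, predict(fit))
#' @export
gsblup <- function(formula, data, genotypes = NULL, pedigree = NULL,
                   method = c("gblup", "pblup", "ssgblup", "wgblup"),
                   varcomp = NULL, blend = 0.05, center = TRUE,
                   allele_freq = NULL, snp_weights = NULL, window = 20,
                   marker_chrom = NULL) {
  method <- match.arg(method)
  cl <- match.call()
  if (!"id" %in% names(data)) stop("`data` needs an `id` column", call. = FALSE)
  if (method != "pblup" && is.null(genotypes))
    stop(sprintf("method \"%s\" needs `genotypes`", method), call. = FALSE)
  if (method %in% c("pblup", "ssgblup") && is.null(pedigree))
    stop(sprintf("method \"%s\" needs `pedigree`", method), call. = FALSE)

  mf <- model.frame(formula, data, na.action = na.pass)
  y_all <- model.response(mf)
  keep <- !is.na(y_all)
  if (sum(keep) < 3) stop("fewer than 3 phenotyped records", call. = FALSE)
  y <- y_all[keep]
  X <- model.matrix(attr(mf, "terms"), mf[keep, , drop = FALSE])
  ids_train <- as.character(data$id[keep])

  rand_ids <- switch(method,
    pblup = , ssgblup = as.character(pedigree$id),
    gblup = , wgblup = rownames(genotypes))
  j <- match(ids_train, rand_ids)
  if (anyNA(j))
    stop("phenotyped ids missing from the relationship structure: ",
         paste(head(ids_train[is.na(j)], 3), collapse = ", "), call. = FALSE)
  Z <- Matrix::sparseMatrix(i = seq_along(j), j = j, x = 1,
                            dims = c(length(j), length(rand_ids)))

  grm <- function(w = NULL) {
    p <- if (is.null(allele_freq)) colMeans(genotypes) / 2 else allele_freq
    if (is.null(w)) vanraden_grm(genotypes, p = p, blend = blend,
                                 center = center)
    else weighted_grm(genotypes, w, p = p, blend = blend, center = center)
  }
  Kinv <- switch(method,
    pblup = ainverse(pedigree),
    gblup = inv_pd(grm(), "G*"),
    ssgblup = h_inverse_ped(pedigree, grm(), rownames(genotypes)),
    wgblup = NULL)

  alpha <- weights_out <- NULL
  if (method == "wgblup") {
    if (is.null(snp_weights)) {
      step1 <- grm()
      Kinv1 <- inv_pd(step1, "G*")
      vc1 <- varcomp %||% em_reml(y, X, as.matrix(Z), Kinv1)
      fit1 <- solve_mme(y, X, Z, Kinv1, vc1$lambda, tag = "wGBLUP-step1")
      alpha <- backsolve_snp_effects(genotypes, fit1$u, Kinv1,
                                     allele_freq = allele_freq,
                                     center = center)
      weights_out <- window_weights(alpha, S = window, chrom = marker_chrom)
    } else {
      weights_out <- snp_weights
    }
    Kinv <- inv_pd(grm(weights_out), "G*w")
  }

  if (is.null(varcomp))
    varcomp <- em_reml(y, X, as.matrix(Z), as.matrix(Kinv))
  if (!inherits(varcomp, "varcomp"))
    stop("`varcomp` must be a varcomp object (see varcomp_true, em_reml)",
         call. = FALSE)

  tag <- c(pblup = "PBLUP", gblup = "GBLUP", ssgblup = "ssGBLUP",
           wgblup = "wGBLUP")[[method]]
  sol <- solve_mme(y, X, Z, Kinv, varcomp$lambda, tag = tag)
  u <- setNames(sol$u, rand_ids)
  if (method == "wgblup" && is.null(alpha))
    alpha <- backsolve_snp_effects(genotypes, u, Kinv,
                                   allele_freq = allele_freq,
                                   center = center, weights = weights_out)
  fitted <- drop(X %*% sol$b) + as.numeric(Z %*% sol$u)
  structure(list(call = cl, method = method, b = sol$b, u = u,
                 varcomp = varcomp, lambda = varcomp$lambda,
                 alpha = alpha, snp_weights = weights_out,
                 fitted = setNames(fitted, ids_train),
                 residuals = setNames(y - fitted, ids_train),
                 y = setNames(y, ids_train), X = X,
                 ids_train = ids_train, K_inverse = Kinv,
                 mme_residual = sol$residual_norm),
            class = "gsblup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# VanRaden G with per-SNP variance weights: Z diag(W) Z' / sum(2p(1-p)).
weighted_grm <- function(M, weights, p = NULL, blend = 0.05, center = TRUE) {
  if (is.null(p)) p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic; G undefined", call. = FALSE)
  Mk <- M[, keep, drop = FALSE]
  pk <- p[keep]
  Z <- if (center) sweep(Mk, 2, 2 * pk) else Mk
  G <- tcrossprod(sweep(Z, 2, weights[keep], "*"), Z) /
    sum(2 * pk * (1 - pk))
  G <- (G + t(G)) / 2
  Gs <- (1 - blend) * G + blend * diag(nrow(G))
  dimnames(Gs) <- list(rownames(M), rownames(M))
  structure(Gs, p = pk, blend = blend, n_dropped = sum(!keep), kind = "Gw")
}

# Back-solve SNP effect BLUPs from genomic breeding values:
# alpha-hat = W Z' G^-1 u-hat / sum(2p(1-p)).
backsolve_snp_effects <- function(M, u, G_inverse, allele_freq = NULL,
                                  center = TRUE, weights = NULL) {
  p <- if (is.null(allele_freq)) colMeans(M) / 2 else allele_freq
  keep <- p > 0 & p < 1
  Z <- M[, keep, drop = FALSE]
  if (center) Z <- sweep(Z, 2, 2 * p[keep])
  k <- sum(2 * p[keep] * (1 - p[keep]))
  a <- drop(crossprod(Z, G_inverse %*% u)) / k
  if (!is.null(weights)) a <- a * weights[keep]
  alpha <- numeric(ncol(M))
  alpha[keep] <- a
  names(alpha) <- colnames(M)
  alpha
}

#' @export
#' @method print gsblup
print.gsblup <- function(x, ...) {
  cat(sprintf("gsblup fit [%s]: %d records, %d random effects\n",
              x$method, length(x$y), length(x$u)))
  cat(sprintf("  varcomp [%s]: sigma_a2 = %.4f, sigma_e2 = %.4f (lambda = %.3f)\n",
              x$varcomp$source, x$varcomp$sigma_a2, x$varcomp$sigma_e2,
              x$lambda))
  cat(sprintf("  MME relative residual: %.2e\n", x$mme_residual))
  invisible(x)
}

#' @export
#' @method summary gsblup
summary.gsblup <- function(object, ...) {
  s <- list(method = object$method, n_records = length(object$y),
            n_random = length(object$u), varcomp = object$varcomp,
            fixed = object$b, gebv_summary = summary(unname(object$u)),
            accuracy_fitted = cor(object$fitted, object$y),
            mme_residual = object$mme_residual)
  class(s) <- "summary.gsblup"
  s
}

#' @export
#' @method print summary.gsblup
print.summary.gsblup <- function(x, ...) {
  cat(sprintf("gsblup [%s]: %d records, %d random effects\n",
              x$method, x$n_records, x$n_random))
  print(x$varcomp)
  cat("fixed effects:\n"); print(x$fixed)
  cat("breeding values:\n"); print(x$gebv_summary)
  cat(sprintf("cor(fitted, observed) = %.3f\n", x$accuracy_fitted))
  invisible(x)
}

#' @export
coef.gsblup <- function(object, ...) object$b

#' Breeding-value predictions from a fitted gsblup model
#'
#' @param object a [gsblup()] fit.
#' @param ids ids to predict; default all random-effect ids.
#' @param ... unused.
#' @return named numeric vector of (G)EBVs.
#' @export
predict.gsblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$u)
  out <- object$u[ids]
  if (anyNA(out))
    stop("ids absent from the fitted relationship structure: ",
         paste(head(ids[is.na(match(ids, names(object$u)))], 3),
               collapse = ", "), call. = FALSE)
  out
}

#' @export
fitted.gsblup <- function(object, ...) object$fitted

#' @export
residuals.gsblup <- function(object, ...) object$residuals

#' Simulate responses from a fitted gsblup model
#'
#' Draws `u* ~ N(0, sigma_a2 K)` (via the stored `K^-1`) and
#' `e* ~ N(0, sigma_e2 I)` and returns `X b-hat + Z u* + e*` for the
#' training records, one column per simulation.
#'
#' @param object a [gsblup()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame (`n_records x nsim`).
#' @export
simulate.gsblup <- function(object, nsim = 1, seed = NULL, ...) {
  local_seed(seed)
  Kinv <- as.matrix(object$K_inverse)
  R <- chol(Kinv)  # K = R^-1 R^-T
  q <- ncol(Kinv)
  ids <- names(object$u)
  n <- length(object$y)
  j <- match(object$ids_train, ids)
  xb <- drop(object$X %*% object$b)
  out <- replicate(nsim, {
    ustar <- backsolve(R, rnorm(q)) * sqrt(object$varcomp$sigma_a2)
    xb + ustar[j] + rnorm(n, 0, sqrt(object$varcomp$sigma_e2))
  })
  as.data.frame(out, row.names = object$ids_train)
}

#' Diagnostic plot of a gsblup fit
#'
#' Observed phenotypes against fitted values for the training records,
#' with the identity line.
#'
#' @param x a [gsblup()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gsblup <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "fitted", ylab = "observed",
                 main = sprintf("gsblup [%s]", x$method), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
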