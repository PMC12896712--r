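# SNP-effect ridge model and window-based SNP weighting (the two-step
# weighted-GBLUP machinery).

#' BLUP of SNP effects under a weighted ridge model
#'
#' Fits `y = X b + Z_s alpha + e` with `alpha ~ N(0, W sigma_alpha2)` and
#' `e ~ N(0, I sigma_e2)` (`W` diagonal, `R = I`), solving the mixed-model
#' equations in SNP dimension. SNPs with zero weight are fixed at effect
#' zero. With `W = I` and a genomic relationship built from the same
#' centred genotype matrix, the implied breeding values `Z_s alpha-hat`
#' are identical to GBLUP's (equivalent-model identity).
#'
#' @param y phenotypes (no missing values).
#' @param X fixed-effect design matrix.
#' @param Z_s centred genotype matrix (records x SNPs).
#' @param weights non-negative SNP variance weights (default all 1).
#' @param sigma_alpha2 per-SNP effect variance.
#' @param sigma_e2 residual variance.
#' @return list with `alpha` (SNP effect BLUPs, zero-weight SNPs included
#'   as 0), `b` (fixed effects), `gebv_train` (`Z_s alpha` for the
#'   records).
#' @export
snp_ridge <- function(y, X, Z_s, weights = NULL, sigma_alpha2, sigma_e2) {
  m <- ncol(Z_s)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be finite, non-negative, one per SNP", call. = FALSE)
  if (all(weights == 0))
    stop("all SNP weights are zero: degenerate model", call. = FALSE)
  active <- which(weights > 0)
  Za <- Z_s[, active, drop = FALSE]
  lambda_w <- (sigma_e2 / sigma_alpha2) / weights[active]
  X <- as.matrix(X)
  C <- rbind(cbind(crossprod(X), crossprod(X, Za)),
             cbind(crossprod(Za, X), crossprod(Za) + diag(lambda_w,
                                                          length(active))))
  rhs <- c(crossprod(X, y), crossprod(Za, y))
  sol <- drop(solve(C, rhs))
  p <- ncol(X)
  alpha <- numeric(m)
  alpha[active] <- sol[-seq_len(p)]
  names(alpha) <- colnames(Z_s)
  list(alpha = alpha, b = sol[seq_len(p)],
       gebv_train = drop(Z_s %*% alpha))
}

#' Window-averaged SNP variance weights
#'
#' The raw weight of SNP `j` is the mean squared estimated effect over the
#' window of `2S + 1` SNPs centred on `j` (truncated at chromosome ends,
#' with the divisor equal to the SNPs actually available), rescaled by one
#' constant `C` so that the mean weight equals 1. Neighbouring SNPs in
#' linkage disequilibrium with a QTL share its signal, so window averaging
#' stabilises the per-SNP variance estimates before the second model fit.
#'
#' @param alpha_hat estimated SNP effects from a pre-fit with `W = I`.
#' @param S window half-width in SNPs (`S = 0` gives `W_j` proportional to
#'   `alpha_hat_j^2`).
#' @param chrom optional chromosome id per SNP; windows never span
#'   chromosome boundaries. Default: one chromosome.
#' @return numeric weight vector with mean 1 and attributes `S` and
#'   `scaling_C`; if all effects are zero, uniform weights with a warning.
#' @export
window_weights <- function(alpha_hat, S = 20, chrom = NULL) {
  if (S < 0) stop("S must be >= 0", call. = FALSE)
  m <- length(alpha_hat)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (length(chrom) != m)
    stop("chrom must have one entry per SNP", call. = FALSE)
  a2 <- alpha_hat^2
  raw <- numeric(m)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    x <- a2[idx]
    n <- length(x)
    cs <- cumsum(c(0, x))
    j <- seq_len(n)
    lo <- pmax(j - S, 1L)
    hi <- pmin(j + S, n)
    raw[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (all(raw == 0)) {
    warning("all estimated SNP effects are zero; uniform weights returned")
    return(structure(rep(1, m), S = S, scaling_C = NA_real_))
  }
  C <- 1 / mean(raw)
  structure(C * raw, S = S, scaling_C = C)
}
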