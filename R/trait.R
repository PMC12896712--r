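# Trait architecture: gamma-distributed QTL effects scaled to a target
# heritability, true breeding values, and phenotype generation.

#' Draw raw QTL effect magnitudes
#'
#' Magnitudes of additive QTL effects follow a gamma distribution with the
#' given shape (scale fixed at 1; the overall scale is set later when the
#' effects are standardised to the target genetic variance).
#'
#' @param n number of magnitudes.
#' @param shape gamma shape parameter (default 0.4, a strongly leptokurtic
#'   effect-size distribution typical of production traits).
#' @return numeric vector of non-negative magnitudes.
#' @export
rqtl_effects <- function(n, shape = 0.4) {
  if (shape <= 0) stop("gamma shape must be positive", call. = FALSE)
  rgamma(n, shape = shape, scale = 1)
}

#' Assign a trait architecture over founder QTL genotypes
#'
#' QTL effect magnitudes are drawn from a gamma distribution
#' (`|beta_j| ~ Gamma(shape, scale = 1)`), signs are assigned by fair coin,
#' and all effects are rescaled by one constant so that the variance of the
#' true breeding values over the founder cohort equals
#' `h2 * phenotypic_variance`. The genetic variance is thus fully explained
#' by the combined QTL effects; markers are neutral and never enter the
#' breeding value.
#'
#' @param founder_qtl individuals x QTL allele-count matrix (0/1/2) of the
#'   founder cohort; at least one QTL must be segregating.
#' @param gamma_shape shape of the effect-magnitude distribution.
#' @param h2 narrow-sense heritability in (0, 1); default 0.42.
#' @param phenotypic_variance total phenotypic variance; default 1.0.
#' @param mu fixed overall mean of the phenotype; default 0.
#' @return an object of class `trait_architecture`: list with `beta`
#'   (signed, scaled QTL effects), `gamma_shape`, `h2`,
#'   `phenotypic_variance`, `mu`, `sigma_a2`, `sigma_e2`.
#' @export
assign_trait <- function(founder_qtl, gamma_shape = 0.4, h2 = 0.42,
                         phenotypic_variance = 1.0, mu = 0) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)", call. = FALSE)
  if (phenotypic_variance <= 0)
    stop("phenotypic variance must be positive", call. = FALSE)
  nq <- ncol(founder_qtl)
  beta <- rqtl_effects(nq, gamma_shape) *
    sample(c(-1, 1), nq, replace = TRUE)
  raw <- drop(founder_qtl %*% beta)
  v <- var(raw)
  if (!is.finite(v) || v <= 0)
    stop("all QTL monomorphic in founders; cannot scale effects",
         call. = FALSE)
  sigma_a2 <- h2 * phenotypic_variance
  beta <- beta * sqrt(sigma_a2 / v)
  structure(list(beta = beta, gamma_shape = gamma_shape, h2 = h2,
                 phenotypic_variance = phenotypic_variance, mu = mu,
                 sigma_a2 = sigma_a2,
                 sigma_e2 = (1 - h2) * phenotypic_variance),
            class = "trait_architecture")
}

#' @export
#' @method print trait_architecture
print.trait_architecture <- function(x, ...) {
  cat(sprintf(paste0("trait_architecture: %d QTL, h2 = %.3f, ",
                     "sigma_a2 = %.3f, sigma_e2 = %.3f\n"),
              length(x$beta), x$h2, x$sigma_a2, x$sigma_e2))
  invisible(x)
}

#' True breeding values from QTL genotypes
#'
#' `TBV_k = sum_j beta_j Q_kj`: the sum of additive QTL effects weighted by
#' the individual's allele counts.
#'
#' @param qtl_genotypes individuals x QTL allele-count matrix.
#' @param beta QTL effect vector (length = number of QTL columns).
#' @return numeric vector of breeding values (named by rownames).
#' @export
compute_tbv <- function(qtl_genotypes, beta) {
  if (ncol(qtl_genotypes) != length(beta))
    stop(sprintf("dimension mismatch: %d QTL columns vs %d effects",
                 ncol(qtl_genotypes), length(beta)), call. = FALSE)
  drop(qtl_genotypes %*% beta)
}

#' Simulate phenotypes with missing records
#'
#' `y_i = mu + TBV_i + e_i` with `e_i ~ N(0, sigma_e2)`; each record is then
#' independently set missing with probability `missing_rate` (the default 5%
#' mimics routine recording gaps in livestock herds).
#'
#' @param tbv vector of true breeding values.
#' @param architecture a [assign_trait()] object (supplies `mu` and
#'   `sigma_e2`).
#' @param missing_rate probability a record is missing; default 0.05.
#' @return numeric vector with `NA` at missing records.
#' @export
simulate_phenotypes <- function(tbv, architecture, missing_rate = 0.05) {
  if (architecture$sigma_e2 < 0)
    stop("residual variance must be non-negative", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing rate must lie in [0, 1]", call. = FALSE)
  n <- length(tbv)
  y <- architecture$mu + tbv +
    rnorm(n, 0, sqrt(architecture$sigma_e2))
  if (missing_rate > 0) y[runif(n) < missing_rate] <- NA
  names(y) <- names(tbv)
  y
}
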