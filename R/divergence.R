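# Population differentiation and structure diagnostics.

#' Per-SNP fixation index between two populations
#'
#' Default estimator is the Weir & Cockerham (1984) two-population
#' variance-components form `a / (a + b + c)` for diploids (no
#' within-individual inbreeding correction), computed from allele and
#' heterozygote frequencies. The Hudson estimator (as formulated by Bhatia
#' et al. 2013) is available behind `estimator = "hudson"`. Loci
#' monomorphic in both populations have an undefined Fst and are reported
#' as 0 with `undefined = TRUE`; negative estimates (sampling noise around
#' zero differentiation) are not clamped.
#'
#' @param genotypes_a,genotypes_b individuals x markers allele-count
#'   matrices (0/1/2) over the same marker set, each with >= 2 individuals.
#' @param estimator `"wc"` (Weir & Cockerham, default) or `"hudson"`.
#' @return a data frame of class `fst_result` with columns `snp`, `fst`,
#'   `p_a`, `p_b`, `undefined`; attributes `estimator`, `n_a`, `n_b`.
#' @export
fst_per_snp <- function(genotypes_a, genotypes_b,
                        estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  if (ncol(genotypes_a) != ncol(genotypes_b))
    stop("marker sets differ between populations", call. = FALSE)
  na <- nrow(genotypes_a); nb <- nrow(genotypes_b)
  if (na < 2 || nb < 2)
    stop("each population needs at least 2 individuals", call. = FALSE)
  pa <- colMeans(genotypes_a) / 2
  pb <- colMeans(genotypes_b) / 2
  undefined <- (pa == 0 & pb == 0) | (pa == 1 & pb == 1)
  if (estimator == "wc") {
    ha <- colMeans(genotypes_a == 1)
    hb <- colMeans(genotypes_b == 1)
    r <- 2
    nbar <- (na + nb) / 2
    nc <- (r * nbar - (na^2 + nb^2) / (r * nbar)) / (r - 1)
    pbar <- (na * pa + nb * pb) / (r * nbar)
    s2 <- (na * (pa - pbar)^2 + nb * (pb - pbar)^2) / ((r - 1) * nbar)
    hbar <- (na * ha + nb * hb) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    fst <- a / (a + b + cc)
  } else {
    ca <- 2 * na; cb <- 2 * nb  # allele sample sizes
    num <- (pa - pb)^2 - pa * (1 - pa) / (ca - 1) - pb * (1 - pb) / (cb - 1)
    den <- pa * (1 - pb) + pb * (1 - pa)
    fst <- num / den
  }
  fst[undefined | !is.finite(fst)] <- 0
  undefined <- undefined | !is.finite(fst)
  out <- data.frame(snp = seq_along(fst), fst = unname(fst),
                    p_a = unname(pa), p_b = unname(pb),
                    undefined = unname(undefined))
  structure(out, estimator = estimator, n_a = na, n_b = nb,
            class = c("fst_result", "data.frame"))
}

#' Screen markers exceeding an Fst threshold
#'
#' Returns the (ascending) indices of markers whose Fst strictly exceeds
#' `threshold`; the default 0.1 selects the highly differentiated loci used
#' to measure cross-population genetic distance.
#'
#' @param fst_result a [fst_per_snp()] result (or a numeric Fst vector).
#' @param threshold finite screening threshold; strict `>` is applied.
#' @return integer vector of marker indices (possibly empty, with a
#'   warning).
#' @export
screen_snps <- function(fst_result, threshold = 0.1) {
  if (!is.finite(threshold)) {
    if (is.infinite(threshold) && threshold < 0) {
      n <- if (is.data.frame(fst_result)) nrow(fst_result) else length(fst_result)
      return(seq_len(n))
    }
    stop("threshold must be finite (or -Inf to keep all markers)",
         call. = FALSE)
  }
  fst <- if (is.data.frame(fst_result)) fst_result$fst else fst_result
  idx <- which(fst > threshold)
  if (!length(idx))
    warning("no markers exceed the Fst threshold ", threshold)
  idx
}

#' Linkage-disequilibrium decay profile
#'
#' For all intra-chromosomal marker pairs within `max_distance_kb`
#' (distances follow the 1 cM = 1 Mb convention), computes the squared
#' Pearson correlation of allele counts and averages it within distance
#' bins. Pairs involving a zero-variance marker are skipped and counted.
#'
#' @param genotypes individuals x markers allele-count matrix.
#' @param genome the [build_genome()] map the markers live on.
#' @param max_distance_kb maximum pair distance in kb.
#' @param n_bins number of equal-width distance bins.
#' @return data frame of class `ld_decay` with columns `bin`, `dist_lo_kb`,
#'   `dist_hi_kb`, `mean_r2`, `n_pairs`; attribute `n_skipped`.
#' @export
ld_decay <- function(genotypes, genome, max_distance_kb = 10000,
                     n_bins = 10) {
  mk <- genome$markers
  if (ncol(genotypes) != nrow(mk))
    stop("genotype columns must match the genome's markers", call. = FALSE)
  breaks <- seq(0, max_distance_kb, length.out = n_bins + 1)
  sums <- counts <- numeric(n_bins)
  skipped <- 0L
  for (c in unique(mk$chrom)) {
    cols <- which(mk$chrom == c)
    if (length(cols) < 2) next
    pos_kb <- mk$pos_cM[cols] * 1000  # 1 cM = 1 Mb = 1000 kb
    Gc <- genotypes[, cols, drop = FALSE]
    v <- apply(Gc, 2, var)
    ok <- v > 0
    D <- abs(outer(pos_kb, pos_kb, "-"))
    pair <- which(upper.tri(D) & D <= max_distance_kb, arr.ind = TRUE)
    if (!nrow(pair)) next
    usable <- ok[pair[, 1]] & ok[pair[, 2]]
    skipped <- skipped + sum(!usable)
    pair <- pair[usable, , drop = FALSE]
    if (!nrow(pair)) next
    R <- suppressWarnings(cor(Gc[, ok, drop = FALSE]))
    map <- cumsum(ok)
    r2 <- R[cbind(map[pair[, 1]], map[pair[, 2]])]^2
    bin <- pmin(findInterval(D[pair], breaks, left.open = TRUE,
                             rightmost.closed = TRUE), n_bins)
    bin[bin == 0] <- 1L
    for (b in unique(bin)) {
      sel <- bin == b
      sums[b] <- sums[b] + sum(r2[sel])
      counts[b] <- counts[b] + sum(sel)
    }
  }
  out <- data.frame(bin = seq_len(n_bins),
                    dist_lo_kb = breaks[-(n_bins + 1)],
                    dist_hi_kb = breaks[-1],
                    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                    n_pairs = as.integer(counts))
  structure(out, n_skipped = skipped, class = c("ld_decay", "data.frame"))
}

#' Principal-component coordinates of genotyped individuals
#'
#' Columns are centred by twice the allele frequency and scaled by
#' `sqrt(2 p (1 - p))`; monomorphic markers are dropped. The leading
#' component scores are returned; score vectors are mutually orthogonal.
#'
#' @param genotypes individuals x markers allele-count matrix (>= 2 rows).
#' @param n_components number of leading components to return.
#' @return numeric matrix (individuals x components) with rownames from
#'   `genotypes` and columns `PC1`, `PC2`, ...; attribute `sdev` holds the
#'   component standard deviations.
#' @export
pca_coords <- function(genotypes, n_components = 2) {
  if (nrow(genotypes) < 2)
    stop("need at least 2 individuals", call. = FALSE)
  p <- colMeans(genotypes) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) {  # no polymorphism: every score is zero
    scores <- matrix(0, nrow(genotypes), n_components,
                     dimnames = list(rownames(genotypes),
                                     paste0("PC", seq_len(n_components))))
    return(structure(scores, sdev = rep(0, n_components)))
  }
  Z <- sweep(genotypes[, keep, drop = FALSE], 2, 2 * p[keep])
  Z <- sweep(Z, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  rank <- min(dim(Z)) - 1L  # centring removes one dimension
  if (n_components > rank) {
    warning("n_components exceeds the matrix rank; truncated to ", rank)
    n_components <- rank
  }
  sv <- svd(scale(Z, scale = FALSE), nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(genotypes),
                           paste0("PC", seq_len(n_components)))
  structure(scores, sdev = sv$d[seq_len(n_components)] / sqrt(nrow(Z) - 1))
}
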