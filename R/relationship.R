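# Pedigree and genomic relationship matrices.

# Convert a pedigree data frame (id, sire, dam; NA/0/"" = unknown) into
# 1-based parent indices, checking topological order.
ped_indices <- function(pedigree) {
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) stop("duplicated ids in pedigree", call. = FALSE)
  lookup <- function(parent) {
    p <- as.character(parent)
    p[is.na(p) | p %in% c("0", "")] <- NA
    i <- match(p, id)
    if (any(!is.na(p) & is.na(i)))
      stop("pedigree parent not listed as an individual: ",
           paste(unique(p[!is.na(p) & is.na(i)]), collapse = ", "),
           call. = FALSE)
    ifelse(is.na(i), 0L, i)
  }
  s <- lookup(pedigree$sire)
  d <- lookup(pedigree$dam)
  bad <- which(s >= seq_along(id) | d >= seq_along(id))
  if (length(bad))
    stop("pedigree not topologically ordered (or individual is its own ",
         "ancestor) at id ", id[bad[1]], call. = FALSE)
  list(id = id, sire = s, dam = d)
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular-method recursion; unknown parents are treated as unrelated,
#' non-inbred founders. The pedigree must list parents before offspring.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam` (`NA` or `0`
#'   for unknown parents), parents before offspring.
#' @return dense symmetric matrix `A` with ids as dimnames; diagonal
#'   `1 + F_i` where `F_i` is the inbreeding coefficient.
#' @examples
#' ped <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'                   dam = c(NA, NA, "d"))
#' numerator_relationship(ped)
#' @export
numerator_relationship <- function(pedigree) {
  px <- ped_indices(pedigree)
  A <- cpp_tabular_a(px$sire, px$dam)
  dimnames(A) <- list(px$id, px$id)
  attr(A, "kind") <- "A"
  A
}

# Henderson's rules for the sparse inverse of A, with inbreeding taken from
# the tabular diagonal. Returns a dsCMatrix over the pedigree ids.
ainverse <- function(pedigree, Fcoef = NULL) {
  px <- ped_indices(pedigree)
  n <- length(px$id)
  if (is.null(Fcoef)) Fcoef <- diag(cpp_tabular_a(px$sire, px$dam)) - 1
  s <- px$sire; d <- px$dam
  Fs <- ifelse(s > 0, Fcoef[pmax(s, 1)], 0)
  Fd <- ifelse(d > 0, Fcoef[pmax(d, 1)], 0)
  # Mendelian sampling variance given known-parent pattern
  dm <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
        ifelse(s > 0 | d > 0, 0.75 - 0.25 * (Fs + Fd), 1))
  alpha <- 1 / dm
  i <- seq_len(n)
  ii <- c(i, s[s > 0], i[s > 0], d[d > 0], i[d > 0],
          s[s > 0 & d > 0], d[s > 0 & d > 0],
          s[s > 0], d[d > 0])
  jj <- c(i, i[s > 0], s[s > 0], i[d > 0], d[d > 0],
          d[s > 0 & d > 0], s[s > 0 & d > 0],
          s[s > 0], d[d > 0])
  xx <- c(alpha,
          rep(-alpha[s > 0] / 2, 2), rep(-alpha[d > 0] / 2, 2),
          rep(alpha[s > 0 & d > 0] / 4, 2),
          alpha[s > 0] / 4, alpha[d > 0] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(px$id, px$id))
  Matrix::forceSymmetric(M)
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / sum(2 p_i (1 - p_i))` where `Z` is the allele-count matrix
#' column-centered by twice the allele frequency. Monomorphic markers carry
#' no information and are dropped (their count is recorded). To guarantee a
#' positive-definite, invertible matrix the result is blended with the
#' identity: `G* = (1 - blend) G + blend I`.
#'
#' @param M individuals x markers allele-count matrix (0/1/2), rownames ids.
#' @param p optional allele frequencies; computed from `M` when `NULL`.
#' @param blend weight on the identity in `[0, 1)`; default 0.05.
#' @param center centre columns by `2 p`? `FALSE` reproduces the uncentered
#'   cross-product (for comparison only).
#' @return symmetric matrix with attributes `p` (frequencies used),
#'   `blend`, `n_dropped` (monomorphic markers removed) and `kind = "G"`.
#' @export
vanraden_grm <- function(M, p = NULL, blend = 0.05, center = TRUE) {
  if (is.null(p)) p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic; G undefined", call. = FALSE)
  Mk <- M[, keep, drop = FALSE]
  pk <- p[keep]
  Z <- if (center) sweep(Mk, 2, 2 * pk) else Mk
  G <- tcrossprod(Z) / sum(2 * pk * (1 - pk))
  Gs <- (1 - blend) * G + blend * diag(nrow(G))
  dimnames(Gs) <- list(rownames(M), rownames(M))
  structure(Gs, p = pk, blend = blend, n_dropped = sum(!keep), kind = "G")
}

#' Inverse of the single-step (H) relationship matrix
#'
#' Combines pedigree and genomic information:
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]` with the non-zero block placed on
#' the genotyped individuals. With an empty genotyped set `H^-1 = A^-1`; with
#' `G*` equal to `A22` the genomic block cancels exactly.
#'
#' @param A numerator relationship matrix over all ids (dimnames required),
#'   or a pedigree data frame from which it is built.
#' @param G_star blended genomic relationship matrix over the genotyped ids.
#' @param genotyped_ids character ids of genotyped individuals (subset of
#'   the ids of `A`).
#' @return dense symmetric matrix `H^-1` with attribute
#'   `genotyped = genotyped_ids`.
#' @export
h_inverse <- function(A, G_star, genotyped_ids = rownames(G_star)) {
  if (is.data.frame(A)) A <- numerator_relationship(A)
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry ids as dimnames", call. = FALSE)
  Hinv <- inv_pd(A, "A")
  if (length(genotyped_ids)) {
    g <- match(genotyped_ids, ids)
    if (anyNA(g)) stop("genotyped ids missing from A", call. = FALSE)
    G_star <- G_star[genotyped_ids, genotyped_ids, drop = FALSE]
    Hinv[g, g] <- Hinv[g, g] +
      inv_pd(G_star, "G*") - inv_pd(A[g, g, drop = FALSE], "A22")
  }
  dimnames(Hinv) <- list(ids, ids)
  structure(Hinv, kind = "Hinv", genotyped = genotyped_ids)
}

# Cholesky-based inverse with an error naming the offending matrix.
inv_pd <- function(X, label) {
  R <- tryCatch(chol(X),
                error = function(e) stop(sprintf(
                  "matrix %s is singular or not positive definite", label),
                  call. = FALSE))
  chol2inv(R)
}

# Sparse H^-1 over a pedigree: Henderson A^-1 plus the dense genomic block.
# Used by the ssGBLUP fitting path where pedigrees are large but sparse.
h_inverse_ped <- function(pedigree, G_star, genotyped_ids) {
  A <- numerator_relationship(pedigree)
  Ainv <- ainverse(pedigree, Fcoef = diag(A) - 1)
  ids <- rownames(Ainv)
  g <- match(genotyped_ids, ids)
  if (anyNA(g)) stop("genotyped ids missing from pedigree", call. = FALSE)
  if (!length(g)) return(Ainv)
  block <- inv_pd(G_star[genotyped_ids, genotyped_ids, drop = FALSE], "G*") -
    inv_pd(A[g, g, drop = FALSE], "A22")
  k <- length(g)
  Hb <- Matrix::sparseMatrix(i = rep(g, times = k), j = rep(g, each = k),
                             x = as.numeric(block), dims = dim(Ainv),
                             dimnames = dimnames(Ainv))
  Matrix::forceSymmetric(Ainv + Hb)
}
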