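#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{\left[\begin{array}{cc} X'X & X'Z \\ Z'X & Z'Z + \lambda K^{-1}
#' \end{array}\right] \left[\begin{array}{c}\hat b \\ \hat u\end{array}\right]
#' = \left[\begin{array}{c}X'y \\ Z'y\end{array}\right]}
#' for the fixed effects and the BLUP of the random effects, where
#' `lambda = sigma_e2 / sigma_a2` and `K` is the relationship matrix of the
#' random effects (A, G* or H). A rank-deficient fixed-effect design is
#' handled by the Moore-Penrose pseudo-inverse with a warning (individual
#' fixed effects are then not estimable, though `X b-hat` is).
#'
#' @param y phenotype vector (no missing values; drop missing records and
#'   their design rows before calling).
#' @param X fixed-effect design matrix (`n x p`).
#' @param Z random-effect incidence matrix (`n x q`).
#' @param K_inverse inverse relationship matrix of the random effects
#'   (`q x q`, dense or a sparse `Matrix`).
#' @param lambda variance ratio `sigma_e2 / sigma_a2` (> 0).
#' @param tag label stored with the solution (e.g. `"GBLUP"`).
#' @return an object of class `mme_solution`: list with `b` (fixed-effect
#'   estimates), `u` (random-effect predictions, named from the columns of
#'   `Z` or rows of `K_inverse`), `residual_norm` (relative residual of the
#'   normal equations) and `tag`.
#' @export
solve_mme <- function(y, X, Z, K_inverse, lambda, tag = "BLUP") {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive variance ratio", call. = FALSE)
  if (anyNA(y)) stop("y contains missing values; drop them first", call. = FALSE)
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n)
    stop("X and Z must have one row per record", call. = FALSE)
  sparse <- is(K_inverse, "Matrix")
  X <- as.matrix(X)
  if (sparse) {
    Z <- as(Z, "CsparseMatrix")
    Xs <- Matrix::Matrix(X, sparse = TRUE)
    C12 <- as(Matrix::crossprod(Xs, Z), "CsparseMatrix")
    C22 <- Matrix::crossprod(Z) + lambda * K_inverse
    C <- rbind(cbind(Matrix::Matrix(crossprod(X), sparse = TRUE), C12),
               cbind(Matrix::t(C12), C22))
    rhs <- c(crossprod(X, y), as.numeric(Matrix::crossprod(Z, y)))
    sol <- as.numeric(Matrix::solve(C, rhs))
  } else {
    Z <- as.matrix(Z)
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lambda * K_inverse))
    rhs <- c(crossprod(X, y), crossprod(Z, y))
    if (qr(X)$rank < ncol(X)) {
      warning("rank-deficient fixed-effect design; ",
              "pseudo-inverse solution, fixed effects not estimable")
      sol <- drop(MASS::ginv(C) %*% rhs)
    } else {
      sol <- drop(solve(C, rhs))
    }
  }
  p <- ncol(X)
  b <- sol[seq_len(p)]
  u <- sol[-seq_len(p)]
  names(b) <- colnames(X)
  names(u) <- if (!is.null(colnames(Z))) colnames(Z) else rownames(K_inverse)
  res <- if (sparse) sqrt(sum((as.numeric(C %*% sol) - rhs)^2))
         else sqrt(sum((drop(C %*% sol) - rhs)^2))
  structure(list(b = b, u = u,
                 residual_norm = res / max(sqrt(sum(rhs^2)), .Machine$double.eps),
                 tag = tag),
            class = "mme_solution")
}

#' @export
#' @method print mme_solution
print.mme_solution <- function(x, ...) {
  cat(sprintf("mme_solution [%s]: %d fixed, %d random; rel. residual %.2e\n",
              x$tag, length(x$b), length(x$u), x$residual_norm))
  invisible(x)
}
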