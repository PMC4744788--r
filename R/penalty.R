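#' Sparse tensor difference penalty
#'
#' Builds the stacked difference operator `D` acting on the tensor-product
#' coefficient array: for each of the three dimensions the order-`order`
#' difference matrix along that dimension is expanded with identities on the
#' other two (Kronecker products) and the three blocks are stacked vertically.
#' The quadratic roughness penalty is then `lambda * ||D alpha||^2` with a
#' single global smoothing parameter.
#'
#' The returned object also carries an orthonormal basis of the null space of
#' `D` (the coefficient arrays that attract no penalty): constants for
#' `order = 1`; all products of per-dimension constant/linear-in-index vectors
#' for `order = 2`. The null-space dimension is `(order)^3` in that tensor
#' sense, i.e. 1 and 8 respectively. Precomputed penalty-side factors used by
#' the fitting decomposition (`Z`, orthonormal complement `X`, Cholesky factor
#' of `X' D'D X`) are attached so they are shared across refits on the same
#' basis (e.g. cross-validation folds).
#'
#' @param spec a [basis_spec()] giving the marginal sizes.
#' @param order difference order, 1 or 2 (default 1).
#' @param precompute also compute the dense complement/Cholesky factors used
#'   by [fit_context()] (default `TRUE`; involves an `m` by `m` dense QR).
#' @return object of class `"stps_penalty"` with elements `D`, `DtD`, `order`,
#'   `null_basis`, `rank` (= `m - ncol(null_basis)`), and (if `precompute`)
#'   `X`, `R`.
#' @export
difference_penalty <- function(spec, order = 1L, precompute = TRUE) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("'order' must be 1 or 2")
  nb <- spec$n_basis
  if (any(nb <= order))
    stop("difference order ", order, " needs more than ", order,
         " basis functions in every dimension")
  Dmarg <- lapply(nb, function(p) {
    methods::as(methods::as(Matrix::Matrix(
      diff(diag(p), differences = order)), "generalMatrix"), "CsparseMatrix")
  })
  Id <- lapply(nb, function(p) Matrix::Diagonal(p))
  # column order: easting slowest, time fastest (matches tensor_design)
  D1 <- Dmarg[[1]] %x% Id[[2]] %x% Id[[3]]
  D2 <- Id[[1]] %x% Dmarg[[2]] %x% Id[[3]]
  D3 <- Id[[1]] %x% Id[[2]] %x% Dmarg[[3]]
  D <- rbind(D1, D2, D3)
  DtD <- Matrix::forceSymmetric(Matrix::crossprod(D))
  m <- prod(nb)
  # tensor null space: products of per-dimension polynomial-in-index vectors
  # of degree < order (order 1: constants; order 2: constants and linears)
  polys <- lapply(nb, function(p) {
    v <- outer(seq_len(p), seq_len(order) - 1L, `^`)
    v
  })
  Zraw <- matrix(0, m, order^3)
  cidx <- 0L
  for (a in seq_len(order)) for (b in seq_len(order)) for (cc in seq_len(order)) {
    cidx <- cidx + 1L
    Zraw[, cidx] <- as.vector(polys[[1]][, a] %x% polys[[2]][, b] %x%
                                polys[[3]][, cc])
  }
  Z <- qr.Q(qr(Zraw))
  resid <- max(abs(as.matrix(D %*% Z)))
  if (resid > 1e-8)
    stop("internal error: constructed null basis fails D Z = 0 (", resid, ")")
  pen <- structure(list(D = D, DtD = DtD, order = order, spec = spec,
                        null_basis = Z, m = m, rank = m - ncol(Z)),
                   class = "stps_penalty")
  if (precompute) {
    Qfull <- qr.Q(qr(Z), complete = TRUE)
    X <- Qfull[, (ncol(Z) + 1L):m, drop = FALSE]
    K1 <- crossprod(X, as.matrix(DtD %*% X))
    K1 <- (K1 + t(K1)) / 2
    pen$X <- X
    pen$R <- chol(K1)
  }
  pen
}

#' Orthonormal basis of the penalty null space
#'
#' @param penalty an object from [difference_penalty()].
#' @return matrix whose orthonormal columns span `{alpha : D alpha = 0}`.
#' @export
null_space <- function(penalty) {
  stopifnot(inherits(penalty, "stps_penalty"))
  penalty$null_basis
}
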