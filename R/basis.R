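#' Specify a tensor-product B-spline basis
#'
#' Collects the marginal basis sizes, spline degree and per-dimension domains
#' for a spatiotemporal (easting, northing, time) tensor-product basis. All
#' marginal bases use equally spaced knots so that simple difference penalties
#' on adjacent coefficients correspond to roughness of the fitted surface.
#'
#' @param n_basis integer vector of length 3: number of basis functions for
#'   easting, northing and time. Each must be at least `degree + 1`.
#' @param degree polynomial degree of the B-splines (default 2, i.e.
#'   piecewise-quadratic "second-order" basis functions).
#' @param domains list of 3 numeric intervals `c(lower, upper)`, one per
#'   dimension, or `NULL` to take them from the data when the design is built.
#' @return An object of class `"stps_basis_spec"`.
#' @export
basis_spec <- function(n_basis = c(14L, 8L, 5L), degree = 2L, domains = NULL) {
  n_basis <- as.integer(n_basis)
  if (length(n_basis) != 3L || any(is.na(n_basis)))
    stop("'n_basis' must be three integers (easting, northing, time)")
  degree <- as.integer(degree)
  if (degree < 1L) stop("'degree' must be >= 1")
  if (any(n_basis < degree + 1L))
    stop("each marginal basis needs at least degree + 1 = ", degree + 1L,
         " functions")
  if (!is.null(domains)) {
    stopifnot(is.list(domains), length(domains) == 3L)
    for (d in domains) {
      if (length(d) != 2L || !all(is.finite(d)) || d[1] >= d[2])
        stop("each domain must be a finite interval c(lower, upper)")
    }
  }
  structure(list(n_basis = n_basis, degree = degree, domains = domains),
            class = "stps_basis_spec")
}

# Equally spaced open-uniform knot vector: interior knots span the domain,
# boundary knots are extended outside it so that exactly n_basis functions
# have support on the domain.
equal_knots <- function(n_basis, degree, domain) {
  h <- diff(domain) / (n_basis - degree)
  seq(domain[1] - degree * h, domain[2] + degree * h, by = h)
}

#' Evaluate a marginal B-spline basis on equally spaced knots
#'
#' Returns the `length(x)` by `n_basis` matrix of B-spline basis functions
#' evaluated at `x`. Knots are equally spaced over `domain` and extended past
#' its ends so that exactly `n_basis` functions are supported on it; inside the
#' domain the basis is a partition of unity (rows sum to 1).
#'
#' @param x numeric vector of evaluation points.
#' @param n_basis number of basis functions (>= degree + 1).
#' @param degree spline degree (default 2).
#' @param domain interval `c(lower, upper)`; defaults to `range(x)`.
#' @param extrapolate if `FALSE` (default) points outside `domain` are an
#'   error; if `TRUE` they are evaluated on the extended knot sequence.
#' @param sparse return a sparse `Matrix` (default) or a dense matrix.
#' @return matrix (or `dgCMatrix`) of basis values; attribute `"knots"` holds
#'   the full knot vector.
#' @export
marginal_basis <- function(x, n_basis, degree = 2L, domain = range(x),
                           extrapolate = FALSE, sparse = TRUE) {
  if (!all(is.finite(x))) stop("evaluation points must be finite")
  n_basis <- as.integer(n_basis); degree <- as.integer(degree)
  if (n_basis < degree + 1L)
    stop("'n_basis' must be at least degree + 1 = ", degree + 1L)
  if (domain[1] >= domain[2]) stop("domain must have lower < upper")
  eps <- 1e-8 * max(1, diff(domain))
  out <- x < domain[1] - eps | x > domain[2] + eps
  if (any(out) && !extrapolate)
    stop(sum(out), " point(s) outside the basis domain [", domain[1], ", ",
         domain[2], "]; set extrapolate = TRUE to allow this")
  knots <- equal_knots(n_basis, degree, domain)
  # clamp roundoff-level boundary excursions of in-domain points to the
  # support interval implied by the (floating-point) knot values
  lo <- knots[degree + 1L]; hi <- knots[length(knots) - degree]
  xe <- if (extrapolate) x else pmin(pmax(x, lo), hi)
  M <- splines::splineDesign(knots, xe, ord = degree + 1L,
                             outer.ok = extrapolate)
  if (sparse) M <- methods::as(methods::as(Matrix::Matrix(M), "generalMatrix"),
                               "CsparseMatrix")
  attr(M, "knots") <- knots
  M
}

# Row-wise Kronecker (face-splitting) product of two matrices with equal row
# counts; row i of the result is kron(A[i, ], B[i, ]).
row_kronecker <- function(A, B) {
  n <- nrow(A)
  stopifnot(nrow(B) == n)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  B <- methods::as(methods::as(B, "generalMatrix"), "CsparseMatrix")
  Ta <- Matrix::mat2triplet(A)
  Tb <- Matrix::mat2triplet(B)
  ord_a <- order(Ta$i); ord_b <- order(Tb$i)
  ia <- Ta$i[ord_a]; ja <- Ta$j[ord_a]; xa <- Ta$x[ord_a]
  ib <- Tb$i[ord_b]; jb <- Tb$j[ord_b]; xb <- Tb$x[ord_b]
  cb <- tabulate(ib, n)
  # pair each nonzero of A in row i with every nonzero of B in row i
  reps <- cb[ia]
  idx_a <- rep.int(seq_along(ia), reps)
  off_b <- cumsum(c(0L, cb))  # nonzeros of B before each row
  pos_b <- sequence(reps) + off_b[ia[idx_a]]
  i_new <- ia[idx_a]
  j_new <- (ja[idx_a] - 1L) * ncol(B) + jb[pos_b]
  x_new <- xa[idx_a] * xb[pos_b]
  Matrix::sparseMatrix(i = i_new, j = j_new, x = x_new,
                       dims = c(n, ncol(A) * ncol(B)))
}

#' Build the sparse spatiotemporal tensor-product design matrix
#'
#' Each row is the Kronecker product of the three marginal B-spline rows at an
#' observation's (easting, northing, time) coordinates, so the full design is
#' assembled without ever forming the dense tensor basis. Column `c` holds the
#' coefficient with easting index `j`, northing index `k` and time index `l`
#' where `c = (j - 1) * n2 * n3 + (k - 1) * n3 + l` (time index fastest).
#'
#' @param s1,s2,t numeric coordinate vectors of equal length.
#' @param spec a [basis_spec()]; if its `domains` are `NULL` the coordinate
#'   ranges are used and stored in the returned design.
#' @param extrapolate allow points outside the domains (default `FALSE`).
#' @return An object of class `"stps_design"`: list with the sparse matrix `B`
#'   (`n` by `m`), the completed `spec`, marginal knot vectors, and `dim_order`
#'   metadata.
#' @export
tensor_design <- function(s1, s2, t, spec = basis_spec(),
                          extrapolate = FALSE) {
  n <- length(s1)
  if (n == 0L) stop("empty dataset: no observations to build a design from")
  if (length(s2) != n || length(t) != n)
    stop("coordinate vectors must have equal length")
  doms <- spec$domains
  if (is.null(doms)) doms <- list(range(s1), range(s2), range(t))
  for (d in seq_len(3)) {
    if (doms[[d]][1] >= doms[[d]][2]) {
      # degenerate range (e.g. single time point): widen symmetrically
      doms[[d]] <- doms[[d]] + c(-0.5, 0.5)
    }
  }
  B1 <- marginal_basis(s1, spec$n_basis[1], spec$degree, doms[[1]], extrapolate)
  B2 <- marginal_basis(s2, spec$n_basis[2], spec$degree, doms[[2]], extrapolate)
  B3 <- marginal_basis(t,  spec$n_basis[3], spec$degree, doms[[3]], extrapolate)
  B <- row_kronecker(row_kronecker(B1, B2), B3)
  spec$domains <- doms
  structure(list(B = B, spec = spec,
                 knots = list(attr(B1, "knots"), attr(B2, "knots"),
                              attr(B3, "knots")),
                 m = prod(spec$n_basis), n = n),
            class = "stps_design")
}

# Evaluate design rows for new points on an existing design's bases.
design_rows <- function(design, s1, s2, t, extrapolate = FALSE) {
  spec <- design$spec
  doms <- spec$domains
  B1 <- marginal_basis(s1, spec$n_basis[1], spec$degree, doms[[1]], extrapolate)
  B2 <- marginal_basis(s2, spec$n_basis[2], spec$degree, doms[[2]], extrapolate)
  B3 <- marginal_basis(t,  spec$n_basis[3], spec$degree, doms[[3]], extrapolate)
  row_kronecker(row_kronecker(B1, B2), B3)
}
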