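#' Normal-inverse-gamma prior hyperparameters
#'
#' Joint conjugate prior for the spline coefficients and error variance:
#' `alpha, sigma^2 ~ NIG(0, (lambda D'D)^{-1}, a, b)`, with the rank-deficient
#' precision handled by a flat improper prior on the penalty null space.
#' The weakly informative default `a = b = 1e-4` reflects vague prior
#' information on `sigma^2`.
#'
#' @param a,b inverse-gamma shape and scale, both > 0.
#' @return list of class `"stps_prior"`.
#' @export
nig_prior <- function(a = 1e-4, b = 1e-4) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "stps_prior")
}

#' Default smoothing-parameter grid
#'
#' 81 log-spaced values spanning `[1e-6, 1e8]`: wide enough that the posterior
#' mode is interior for typical monitoring data while keeping per-value cost
#' trivial after the one-time decomposition.
#'
#' @param lower,upper grid end points (> 0).
#' @param length number of grid points.
#' @return numeric vector, increasing.
#' @export
lambda_grid <- function(lower = 1e-6, upper = 1e8, length = 81L) {
  stopifnot(lower > 0, upper > lower, length >= 1L)
  exp(seq(log(lower), log(upper), length.out = length))
}

#' One-time decomposition for cheap smoothing-parameter profiling
#'
#' Performs all expensive linear algebra once so that, afterwards, the
#' penalized residual quadratic form, residual sum of squares, generalized
#' log-determinant, effective degrees of freedom, coefficient estimate and the
#' marginal log-posterior of `lambda` each cost O(m) arithmetic per `lambda`.
#'
#' The coefficient space is split into the penalty null space (flat prior,
#' spanned by `Z`) and its orthogonal complement, on which the cross-product
#' `B'B` (after projecting out the null-space fit) and the penalty `D'D` are
#' simultaneously diagonalized through a Cholesky factor of the reduced
#' penalty and a final dense symmetric eigendecomposition. Sparse matrices are
#' used for the design and penalty assembly; only that final step is dense.
#'
#' @param design an `"stps_design"` from [tensor_design()].
#' @param penalty an `"stps_penalty"` from [difference_penalty()] on the same
#'   basis spec.
#' @param y numeric response vector (already on the modelling scale),
#'   length `nrow(design$B)`.
#' @param max_coef guardrail: refuse models with more than this many
#'   coefficients (default `1e4`) unless `allow_large = TRUE`. With 25 basis
#'   functions per dimension the cross-product matrix is already
#'   15,625 x 15,625, beyond routine desk-scale use.
#' @param allow_large override the guardrail.
#' @return object of class `"stps_ctx"` (list): spectrum `s`, rotated data
#'   `c`, null-space dimension `q`, ranks, norms, and the factor matrices
#'   needed to materialize coefficients and predictions.
#' @export
fit_context <- function(design, penalty, y, max_coef = 1e4,
                        allow_large = FALSE) {
  stopifnot(inherits(design, "stps_design"), inherits(penalty, "stps_penalty"))
  B <- design$B
  n <- nrow(B); m <- ncol(B)
  if (length(y) != n) stop("length(y) must equal nrow(design$B)")
  if (!all(is.finite(y))) stop("response contains non-finite values")
  if (m != penalty$m) stop("design and penalty have different coefficient counts")
  if (m > max_coef && !allow_large)
    stop("model has m = ", m, " coefficients (> max_coef = ", max_coef,
         "); the cross-product matrix would be ", m, " x ", m,
         ". Reduce the basis sizes or set allow_large = TRUE.")
  Z <- penalty$null_basis
  q <- ncol(Z)
  if (is.null(penalty$X))
    penalty <- difference_penalty(penalty$spec, penalty$order)
  X <- penalty$X
  R <- penalty$R
  C <- as.matrix(Matrix::forceSymmetric(Matrix::crossprod(B)))
  by <- as.numeric(Matrix::crossprod(B, y))
  A00 <- crossprod(Z, C %*% Z)
  A00 <- (A00 + t(A00)) / 2
  cholA <- tryCatch(chol(A00), error = function(e) NULL)
  if (is.null(cholA)) {
    ev <- eigen(A00, symmetric = TRUE)
    bad <- which(ev$values < 1e-10 * max(ev$values, 1))
    stop("the design does not identify ", length(bad),
         " unpenalized (null-space) direction(s); the penalized system is ",
         "singular for every lambda. Deficient null-space directions: ",
         paste(bad, collapse = ", "))
  }
  C01 <- crossprod(Z, C %*% X)                       # q x (m-q)
  C11 <- crossprod(X, C %*% X)
  A00inv_C01 <- chol_solve(cholA, C01)
  C1 <- C11 - crossprod(C01, A00inv_C01)
  C1 <- (C1 + t(C1)) / 2
  # simultaneous diagonalization: K1 = R'R, G = R^{-T} C1 R^{-1}
  G <- backsolve(R, t(backsolve(R, t(C1), transpose = TRUE)), transpose = TRUE)
  G <- (G + t(G)) / 2
  eg <- eigen(G, symmetric = TRUE)
  s <- eg$values
  s[s < 1e-12 * max(s, 0)] <- 0        # explicit finite-precision rank floor
  s[s < 0] <- 0
  U <- eg$vectors
  Tmat <- X %*% backsolve(R, U)        # maps rotated coefficients to alpha
  C01T <- C01 %*% backsolve(R, U)      # q x (m-q) coupling block
  by0 <- as.numeric(crossprod(Z, by))
  by1 <- as.numeric(crossprod(X, by))
  b1r <- by1 - as.numeric(crossprod(A00inv_C01, by0))
  cvec <- as.numeric(crossprod(U, backsolve(R, b1r, transpose = TRUE)))
  ynorm2 <- sum(y^2)
  py2 <- sum(by0 * chol_solve(cholA, by0))
  r2 <- max(ynorm2 - py2, 0)
  logdet_const <- 2 * sum(log(diag(cholA))) + 2 * sum(log(diag(R)))
  structure(list(
    n = n, m = m, q = q, s = s, c = cvec,
    rank_B = q + sum(s > 0), rank_DtD = penalty$rank,
    r2 = r2, ynorm2 = ynorm2, logdet_const = logdet_const,
    Z = Z, Tmat = Tmat, cholA = cholA, C01T = C01T, by0 = by0,
    design = design, penalty_order = penalty$order, y = y,
    n_dense_decompositions = 1L
  ), class = "stps_ctx")
}

chol_solve <- function(cholA, b) {
  backsolve(cholA, backsolve(cholA, b, transpose = TRUE))
}

#' Profile quantities along the smoothing parameter
#'
#' Evaluates, for each `lambda`, the penalized residual quadratic form
#' `y'(I - B (B'B + lambda D'D)^{-1} B') y`, the residual sum of squares of
#' the fitted values, the effective degrees of freedom, and the full
#' log-determinant `log |B'B + lambda D'D|`, all in O(m) per value from the
#' stored spectrum.
#'
#' @param ctx an `"stps_ctx"` from [fit_context()].
#' @param lambda positive numeric vector.
#' @return data.frame with columns `lambda`, `qform`, `rss`, `edf`, `logdet`.
#' @export
lambda_profile <- function(ctx, lambda) {
  stopifnot(inherits(ctx, "stps_ctx"), all(lambda > 0))
  s <- ctx$s; c2 <- ctx$c^2
  out <- vapply(lambda, function(l) {
    d <- s + l
    c(qform = ctx$r2 - sum(c2 / d),
      rss = ctx$r2 - sum(c2 * (s + 2 * l) / d^2),
      edf = ctx$q + sum(s / d),
      logdet = ctx$logdet_const + sum(log(d)))
  }, numeric(4))
  data.frame(lambda = lambda, qform = pmax(out["qform", ], 0),
             rss = pmax(out["rss", ], 0), edf = out["edf", ],
             logdet = out["logdet", ])
}

#' Effective degrees of freedom of the smoother
#'
#' Trace of the hat matrix `B (B'B + lambda D'D)^{-1} B'`, computed from the
#' decomposition spectrum as `q + sum(s_i / (s_i + lambda))` where `q` is the
#' unpenalized null-space dimension. `lambda = 0` gives `rank(B)`;
#' `lambda = Inf` gives `dim null(D)`.
#'
#' @param ctx an `"stps_ctx"`.
#' @param lambda non-negative scalar (0 allowed; requires full support of the
#'   penalized spectrum only for the interpretation as an exact fit).
#' @return scalar effective degrees of freedom.
#' @export
effective_df <- function(ctx, lambda) {
  stopifnot(inherits(ctx, "stps_ctx"))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  s <- ctx$s
  if (is.infinite(lambda)) return(ctx$q)
  if (lambda == 0) return(ctx$q + sum(s > 0))
  ctx$q + sum(s / (s + lambda))
}

#' Marginal log-posterior of the smoothing parameter
#'
#' Up to one additive constant shared across `lambda`, returns
#' `rank(D'D)/2 * log(lambda) - 1/2 * log|B'B + lambda D'D|
#'  - (a + n/2) * log(2b + y'(I - B(B'B + lambda D'D)^{-1} B') y)
#'  + log prior(lambda)`,
#' the closed-form marginal posterior of the model indexed by `lambda` under
#' the conjugate normal-inverse-gamma prior with a flat improper prior on the
#' penalty null space. The default prior over `lambda` itself is flat
#' (improper uniform).
#'
#' @param ctx an `"stps_ctx"`.
#' @param lambda positive numeric vector.
#' @param prior an [nig_prior()].
#' @param lambda_prior optional function `lambda -> log prior density`
#'   (vectorized); `NULL` means flat.
#' @return numeric vector of log-posterior values (common constant dropped).
#' @export
log_lambda_posterior <- function(ctx, lambda, prior = nig_prior(),
                                 lambda_prior = NULL) {
  stopifnot(inherits(ctx, "stps_ctx"))
  if (any(lambda <= 0)) stop("'lambda' must be positive")
  prof <- lambda_profile(ctx, lambda)
  lp <- 0.5 * ctx$rank_DtD * log(lambda) - 0.5 * prof$logdet -
    (prior$a + ctx$n / 2) * log(2 * prior$b + prof$qform)
  if (!is.null(lambda_prior)) lp <- lp + lambda_prior(lambda)
  if (any(!is.finite(lp)))
    stop("non-finite log posterior at lambda = ",
         paste(signif(lambda[!is.finite(lp)], 4), collapse = ", "))
  lp
}

#' Posterior over a smoothing-parameter grid
#'
#' Evaluates the marginal log-posterior on a grid, normalizes discrete
#' posterior weights, and locates the MAP value.
#'
#' @inheritParams log_lambda_posterior
#' @param grid increasing positive grid of `lambda` values.
#' @param strict error (instead of warn) when the maximum sits on a grid
#'   boundary.
#' @return object of class `"stps_lambda_posterior"`: list with `grid`,
#'   `log_posterior`, `weights`, `map_index`, `map_lambda`, `boundary`.
#' @export
lambda_posterior <- function(ctx, grid = lambda_grid(), prior = nig_prior(),
                             lambda_prior = NULL, strict = FALSE) {
  if (length(grid) < 1L) stop("empty lambda grid")
  if (is.unsorted(grid)) stop("'grid' must be sorted increasing")
  lp <- log_lambda_posterior(ctx, grid, prior, lambda_prior)
  # ties broken toward the smallest lambda for deterministic output
  map_index <- which(lp >= max(lp) - 0)[1L]
  boundary <- length(grid) > 1L && map_index %in% c(1L, length(grid))
  if (boundary || length(grid) == 1L) {
    msg <- "posterior maximum at the grid boundary; consider extending the grid"
    if (strict && length(grid) > 1L) stop(msg) else warning(msg)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  structure(list(grid = grid, log_posterior = lp, weights = w,
                 map_index = map_index, map_lambda = grid[map_index],
                 boundary = boundary),
            class = "stps_lambda_posterior")
}

#' MAP smoothing parameter
#'
#' @inheritParams lambda_posterior
#' @return the grid value maximizing the marginal posterior.
#' @export
select_map <- function(ctx, grid = lambda_grid(), prior = nig_prior(),
                       lambda_prior = NULL, strict = FALSE) {
  lambda_posterior(ctx, grid, prior, lambda_prior, strict)$map_lambda
}

# Coefficient estimate at one lambda: posterior mean of alpha (equivalently
# the penalized least-squares solution).
coef_at_lambda <- function(ctx, lambda) {
  stopifnot(lambda > 0)
  gamma <- ctx$c / (ctx$s + lambda)
  beta0 <- chol_solve(ctx$cholA, ctx$by0 - as.numeric(ctx$C01T %*% gamma))
  as.numeric(ctx$Z %*% beta0 + ctx$Tmat %*% gamma)
}

# Rotated-coordinate prediction pieces for a set of target design rows Bt
# (sparse nt x m). Everything here is lambda-free.
target_pieces <- function(ctx, Bt) {
  U0 <- as.matrix(Bt %*% ctx$Z)          # nt x q
  U1 <- as.matrix(Bt %*% ctx$Tmat)       # nt x (m-q)
  V0 <- t(chol_solve(ctx$cholA, t(U0)))  # nt x q, = U0 A00^{-1}
  W <- V0 %*% ctx$C01T - U1              # nt x (m-q)
  list(U0 = U0, U1 = U1, V0 = V0, W = W, term0 = rowSums(U0 * V0))
}

# Posterior mean and posterior quadratic form b'(B'B+lambda D'D)^{-1}b of the
# target means at one lambda, from precomputed pieces.
predict_at_lambda <- function(ctx, pieces, lambda) {
  d <- ctx$s + lambda
  gamma <- ctx$c / d
  beta0 <- chol_solve(ctx$cholA, ctx$by0 - as.numeric(ctx$C01T %*% gamma))
  mean <- as.numeric(pieces$U0 %*% beta0) + as.numeric(pieces$U1 %*% gamma)
  quad <- pieces$term0 + as.numeric((pieces$W^2) %*% (1 / d))
  list(mean = mean, quad = pmax(quad, 0))
}

# Posterior NIG parameters at one lambda.
posterior_nig <- function(ctx, lambda, prior = nig_prior()) {
  prof <- lambda_profile(ctx, lambda)
  list(a_n = prior$a + ctx$n / 2, b_n = prior$b + prof$qform / 2)
}
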