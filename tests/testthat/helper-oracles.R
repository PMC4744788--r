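# Independent oracles used across the test files. These deliberately use
# plain dense linear algebra / textbook recursions, not the package's
# decomposition-based fast path.

# de Boor recursion for a single B-spline basis function B_{j,d}(x) on a
# given knot vector (0-based j over seq_len(length(knots) - d - 1)).
deboor_bspline <- function(x, knots, j, d) {
  if (d == 0) {
    return(as.numeric(x >= knots[j] & x < knots[j + 1]))
  }
  den1 <- knots[j + d] - knots[j]
  den2 <- knots[j + d + 1] - knots[j + 1]
  w1 <- if (den1 > 0) (x - knots[j]) / den1 else 0
  w2 <- if (den2 > 0) (knots[j + d + 1] - x) / den2 else 0
  w1 * deboor_bspline(x, knots, j, d - 1) +
    w2 * deboor_bspline(x, knots, j + 1, d - 1)
}

deboor_row <- function(x, knots, d) {
  vapply(seq_len(length(knots) - d - 1),
         function(j) deboor_bspline(x, knots, j, d), numeric(1))
}

# Small random fitting instance: irregular coordinates, a smooth signal plus
# noise, and the matching design/penalty pair.
random_instance <- function(seed, n_basis = c(4L, 4L, 3L), n = 200L,
                            order = 1L, degree = 2L) {
  set.seed(seed)
  s1 <- runif(n); s2 <- runif(n); tt <- runif(n)
  spec <- basis_spec(n_basis, degree, domains = list(c(0, 1), c(0, 1), c(0, 1)))
  design <- tensor_design(s1, s2, tt, spec)
  penalty <- difference_penalty(spec, order)
  y <- sin(4 * s1) + cos(3 * s2) * tt + rnorm(n, 0, 0.3)
  list(design = design, penalty = penalty, y = y, spec = spec,
       s1 = s1, s2 = s2, t = tt)
}

# Dense brute-force evaluation of everything the fast path provides.
dense_oracle <- function(design, penalty, y, lambda, prior = nig_prior()) {
  B <- as.matrix(design$B)
  K <- as.matrix(penalty$DtD)
  n <- nrow(B)
  q <- ncol(penalty$null_basis)
  M <- crossprod(B) + lambda * K
  alpha <- solve(M, crossprod(B, y))
  Hy <- B %*% alpha
  edf <- sum(diag(B %*% solve(M, t(B))))
  qform <- sum(y^2) - sum(y * Hy)
  rss <- sum((y - Hy)^2)
  logdet <- as.numeric(determinant(M, logarithm = TRUE)$modulus)
  lp <- 0.5 * penalty$rank * log(lambda) - 0.5 * logdet -
    (prior$a + n / 2) * log(2 * prior$b + qform)
  list(alpha = as.numeric(alpha), edf = edf, qform = qform, rss = rss,
       logdet = logdet, lp = lp)
}

# Log posterior of lambda under an explicit ridge completion of the penalty
# (prior precision lambda * D'D + eps^2 * N with N projecting on null(D)),
# evaluated densely. As eps -> 0 this converges, up to a lambda-free
# constant, to the improper flat-prior (null-space) formulation.
dense_ridge_lp <- function(design, penalty, y, lambda, eps,
                           prior = nig_prior()) {
  B <- as.matrix(design$B)
  K <- as.matrix(penalty$DtD)
  Z <- penalty$null_basis
  N <- Z %*% t(Z)
  n <- nrow(B)
  P <- lambda * K + eps^2 * N
  M <- crossprod(B) + P
  alpha <- solve(M, crossprod(B, y))
  qform <- sum(y^2) - sum(y * (B %*% alpha))
  0.5 * as.numeric(determinant(P, logarithm = TRUE)$modulus) -
    0.5 * as.numeric(determinant(M, logarithm = TRUE)$modulus) -
    (prior$a + n / 2) * log(2 * prior$b + qform)
}

# Ray-casting point-in-polygon (works for any simple polygon); independent
# of the half-plane construction used by the package.
raycast_inside <- function(px, py, vx, vy, tol = 1e-12) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # on-edge check
    dx <- vx[i] - vx[j]; dy <- vy[i] - vy[j]
    cr <- dx * (py - vy[j]) - dy * (px - vx[j])
    dot <- (px - vx[j]) * dx + (py - vy[j]) * dy
    len2 <- dx^2 + dy^2
    if (abs(cr) < tol && dot >= -tol && dot <= len2 + tol) return(TRUE)
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Shared small plume truth for simulator-based tests (solved once per run).
test_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- solve_plume(grid = c(60L, 60L, 40L))
    cache
  }
})
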