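# Point-in-convex-hull test (closed hull; points on an edge count as inside).
in_convex_hull <- function(points, vertices, tol = 1e-10) {
  vertices <- unique(as.matrix(vertices))
  if (nrow(vertices) < 3L) stop("need at least 3 wells for a convex hull")
  hull <- grDevices::chull(vertices[, 1], vertices[, 2])
  if (length(hull) < 3L) stop("degenerate (collinear) well configuration")
  hv <- vertices[hull, , drop = FALSE]
  # orient counter-clockwise (positive signed area)
  n <- nrow(hv)
  nxt <- c(2:n, 1L)
  area2 <- sum(hv[, 1] * hv[nxt, 2] - hv[nxt, 1] * hv[, 2])
  if (area2 < 0) {
    hv <- hv[n:1, , drop = FALSE]
  }
  scale <- max(apply(hv, 2, function(z) diff(range(z))), 1e-12)
  inside <- rep(TRUE, nrow(points))
  for (e in seq_len(n)) {
    a <- hv[e, ]; b <- hv[if (e == n) 1L else e + 1L, ]
    cross <- (b[1] - a[1]) * (points[, 2] - a[2]) -
      (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & cross >= -tol * scale^2
  }
  inside
}

#' Convex-hull mask for a space-time evaluation grid
#'
#' Flags the nodes of a regular space-time grid whose spatial coordinates lie
#' inside the closed 2-D convex hull of the monitoring wells and whose time
#' lies within the sampled time range. This is the region over which fitted
#' surfaces are scored (predictions outside it are extrapolation).
#'
#' @param wells matrix or data frame of well coordinates (columns `s1`, `s2`).
#' @param t_range numeric interval of sampled times.
#' @param grid list with numeric vectors `s1`, `s2`, `t` defining the grid.
#' @return logical array of dimension `length(s1) x length(s2) x length(t)`.
#' @export
convex_hull_mask <- function(wells, t_range, grid) {
  wells <- as.matrix(as.data.frame(wells)[, c("s1", "s2")])
  sp <- expand.grid(s1 = grid$s1, s2 = grid$s2, KEEP.OUT.ATTRS = FALSE)
  sp_in <- in_convex_hull(as.matrix(sp), wells)
  t_in <- grid$t >= min(t_range) & grid$t <= max(t_range)
  array(as.logical(outer(sp_in, t_in)),
        dim = c(length(grid$s1), length(grid$s2), length(grid$t)))
}

#' Integrated squared error over a masked grid
#'
#' Numerical approximation of the integral of `(fit - truth)^2` over the
#' flagged region of a regular space-time grid (both surfaces on the
#' modelling, i.e. transformed, scale): a tensor-product trapezoidal rule,
#' i.e. a Riemann sum with boundary nodes down-weighted so a constant
#' integrand integrates exactly.
#'
#' @param fit,truth numeric arrays on the same grid.
#' @param mask logical array from [convex_hull_mask()] (default: everywhere).
#' @param grid list with grid vectors `s1`, `s2`, `t` giving the cell volume.
#' @return non-negative scalar.
#' @export
integrated_squared_error <- function(fit, truth, grid, mask = NULL) {
  fit <- as.array(fit); truth <- as.array(truth)
  same_dim <- function(a, b) length(dim(a)) == length(dim(b)) &&
    all(dim(a) == dim(b))
  if (!same_dim(fit, truth)) stop("'fit' and 'truth' grids do not match")
  if (is.null(mask)) mask <- array(TRUE, dim(fit))
  if (!same_dim(mask, fit)) stop("'mask' grid does not match")
  wt1 <- function(g) {
    k <- length(g)
    if (k == 1) return(1)
    w <- rep(1, k); w[c(1, k)] <- 0.5
    w * diff(range(g)) / (k - 1)
  }
  w <- outer(outer(wt1(grid$s1), wt1(grid$s2)), wt1(grid$t))
  sum(((fit - truth)^2 * w)[mask])
}

#' Replicate-level comparison of smoothing-parameter selectors
#'
#' Repeatedly samples noisy monitoring data from a simulated plume, fits the
#' P-spline model, selects the smoothing parameter with each requested
#' selector (all selectors score the identical dataset within a replicate,
#' sharing one decomposition), and scores the fitted surface against the
#' known truth by integrated squared error over the convex hull of the wells
#' and the sampled time range, on the `log(y + 1)` scale.
#'
#' @param truth an `"stps_plume"`; solved once and shared by all replicates.
#' @param scenario scenario id (1, 2 or 3). As in a designed monitoring
#'   study, the well network and sampling dates are drawn once (from the base
#'   seed) and held fixed across replicates; only the measurement noise is
#'   redrawn.
#' @param selectors character vector from `c("map", "average", "aicc", "gcv",
#'   "bic", "cv-obs", "cv-well")`.
#' @param n_replicates number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param n_basis,pen_order model settings passed to the fit.
#' @param lambda smoothing-parameter grid.
#' @param prior an [nig_prior()].
#' @param noise a [noise_model()].
#' @param eval_grid evaluation grid sizes `c(n_s1, n_s2, n_t)` (default
#'   `c(50, 50, 20)`).
#' @param cv_folds folds for the CV selectors.
#' @return object of class `"stps_comparison"`: list with `table` (selector,
#'   mean ISE, standard error), `ise` (replicate x selector matrix), `lambda`
#'   (selected values), and `failures`.
#' @export
compare_selectors <- function(truth, scenario = 1L,
                              selectors = c("map", "average", "aicc"),
                              n_replicates = 50L, seed = 1L,
                              n_basis = c(14L, 8L, 5L), pen_order = 1L,
                              lambda = lambda_grid(), prior = nig_prior(),
                              noise = noise_model(),
                              eval_grid = c(50L, 50L, 20L),
                              cv_folds = 10L) {
  all_sel <- c("map", "average", "aicc", "gcv", "bic", "cv-obs", "cv-well")
  if (!all(selectors %in% all_sel))
    stop("unknown selector(s): ",
         paste(setdiff(selectors, all_sel), collapse = ", "))
  ise <- matrix(NA_real_, n_replicates, length(selectors),
                dimnames = list(NULL, selectors))
  lam_sel <- ise
  failures <- character(0)
  g1 <- seq(0, 1, length.out = eval_grid[1])
  g2 <- seq(0, 1, length.out = eval_grid[2])
  gt <- seq(min(truth$t), max(truth$t), length.out = eval_grid[3])
  egrid <- list(s1 = g1, s2 = g2, t = gt)
  epts <- expand.grid(s1 = g1, s2 = g2, t = gt, KEEP.OUT.ATTRS = FALSE)
  truth_log <- array(log(interp_plume(truth, epts$s1, epts$s2, epts$t) + 1),
                     dim = eval_grid)
  des <- plume_scenario(scenario, seed = seed)
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r
    res <- tryCatch({
      dat <- sample_plume(truth, des, noise, seed = rep_seed)
      fit_selectors_ise(dat, selectors, truth_log, egrid, epts,
                        n_basis, pen_order, lambda, prior, cv_folds,
                        rep_seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    ise[r, ] <- res$ise
    lam_sel[r, ] <- res$lambda
  }
  tab <- data.frame(
    selector = selectors,
    mean = colMeans(ise, na.rm = TRUE),
    se = apply(ise, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    }))
  structure(list(table = tab, ise = ise, lambda = lam_sel,
                 failures = failures, scenario = scenario, seed = seed),
            class = "stps_comparison")
}

# One replicate: shared fit machinery, per-selector lambda + ISE.
fit_selectors_ise <- function(dat, selectors, truth_log, egrid, epts,
                              n_basis, pen_order, lambda, prior, cv_folds,
                              seed) {
  y <- log(dat$conc + 1)
  spec <- basis_spec(n_basis, 2L, domains = list(c(0, 1), c(0, 1), c(0, 1)))
  design <- tensor_design(dat$s1, dat$s2, dat$t, spec)
  penalty <- difference_penalty(spec, pen_order)
  ctx <- fit_context(design, penalty, y)
  Bt <- design_rows(design, epts$s1, epts$s2, epts$t, extrapolate = TRUE)
  mask <- convex_hull_mask(unique(dat[c("s1", "s2")]), range(dat$t), egrid)
  post <- NULL
  out_ise <- numeric(length(selectors))
  out_lam <- numeric(length(selectors))
  for (j in seq_along(selectors)) {
    sel <- selectors[j]
    if (sel %in% c("map", "average") && is.null(post))
      post <- lambda_posterior(ctx, lambda, prior)
    if (sel == "average") {
      keep <- which(post$weights > 1e-10)
      w <- post$weights[keep] / sum(post$weights[keep])
      alpha <- Reduce(`+`, Map(function(l, wi) wi * coef_at_lambda(ctx, l),
                               post$grid[keep], w))
      surf <- as.numeric(Bt %*% alpha)
      lam <- post$map_lambda  # reported value; prediction averages over grid
    } else {
      lam <- switch(sel,
        map = post$map_lambda,
        aicc = lambda[which.min(aicc(ctx, lambda))],
        gcv = lambda[which.min(gcv(ctx, lambda))],
        bic = lambda[which.min(bic(ctx, lambda))],
        `cv-obs` = cv_score(design, penalty, y, dat$well, lambda, cv_folds,
                            "observation", seed)$lambda_min,
        `cv-well` = cv_score(design, penalty, y, dat$well, lambda, cv_folds,
                             "well", seed)$lambda_min)
      surf <- as.numeric(Bt %*% coef_at_lambda(ctx, lam))
    }
    fitarr <- array(surf, dim = vapply(egrid, length, integer(1)))
    out_ise[j] <- integrated_squared_error(fitarr, truth_log, egrid, mask)
    out_lam[j] <- lam
  }
  list(ise = out_ise, lambda = out_lam)
}

#' @export
print.stps_comparison <- function(x, ...) {
  cat(sprintf("Selector comparison, scenario %d, %d replicate(s)\n",
              x$scenario, nrow(x$ise)))
  cat("Mean integrated squared error over the well hull (log scale):\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$failures))
    cat(length(x$failures), "replicate(s) failed\n")
  invisible(x)
}
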