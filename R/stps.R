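#' Fit a Bayesian spatiotemporal P-spline model
#'
#' Smooths irregular monitoring data `(s1, s2, t, conc)` with a tensor-product
#' B-spline surface and a single global difference penalty, under a conjugate
#' normal-inverse-gamma prior. The marginal posterior of the smoothing
#' parameter `lambda` is evaluated in closed form over a grid (after a
#' one-time decomposition, each grid value costs O(m) arithmetic), so the
#' smoothing parameter can be selected fully automatically: by its posterior
#' mode (`"map"`), by model averaging over the grid (`"average"`), or by the
#' classical selectors AICc, GCV, BIC and k-fold cross-validation with
#' observation- or well-based folds.
#'
#' Coordinates are affinely rescaled to the unit interval per dimension before
#' basis construction (for numerical conditioning); all reported surfaces are
#' in the original units. The response is modelled on a transformed scale,
#' by default `log(conc + 1)`, appropriate for concentration data with
#' multiplicative noise and exact zeros.
#'
#' @param data data frame with numeric columns `s1`, `s2`, `t` and a response
#'   column `conc` (raw concentration), plus optionally `well` (required for
#'   well-based cross-validation). Objects from [read_monitoring_csv()] work
#'   directly.
#' @param n_basis marginal basis sizes (easting, northing, time); default
#'   `c(14, 8, 5)` suits a study region wider in easting than northing with
#'   concentrations varying more quickly in space than in time.
#' @param degree B-spline degree (default 2).
#' @param pen_order difference-penalty order, 1 or 2 (default 1; first-order
#'   differences resist spurious off-data extrema better).
#' @param selector smoothing-parameter selector: one of `"map"`, `"average"`,
#'   `"aicc"`, `"gcv"`, `"bic"`, `"cv-obs"`, `"cv-well"`.
#' @param lambda smoothing-parameter grid (see [lambda_grid()]).
#' @param prior an [nig_prior()].
#' @param transform `"log1p"` (default, `log(conc + offset)`) or `"identity"`.
#' @param offset additive offset of the log transform (default 1).
#' @param cv_folds folds for the CV selectors (default 10).
#' @param seed seed used for CV fold shuffling.
#' @param max_coef,allow_large guardrail on the coefficient count, see
#'   [fit_context()].
#' @param domains optional list of 3 intervals (original units) overriding the
#'   data ranges as basis domains.
#' @return An object of class `"stps"` with `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `plot` and `simulate` methods.
#' @examples
#' truth <- solve_plume(grid = c(40, 40, 25))
#' dat <- sample_plume(truth, plume_scenario(3, seed = 1), seed = 1)
#' fit <- stps(dat, n_basis = c(8, 6, 4))
#' fit
#' @export
stps <- function(data,
                 n_basis = c(14L, 8L, 5L),
                 degree = 2L,
                 pen_order = 1L,
                 selector = c("map", "average", "aicc", "gcv", "bic",
                              "cv-obs", "cv-well"),
                 lambda = lambda_grid(),
                 prior = nig_prior(),
                 transform = c("log1p", "identity"),
                 offset = 1,
                 cv_folds = 10L,
                 seed = 1L,
                 max_coef = 1e4,
                 allow_large = FALSE,
                 domains = NULL) {
  selector <- match.arg(selector)
  transform <- match.arg(transform)
  cl <- match.call()
  data <- as.data.frame(data)
  need <- c("s1", "s2", "t", "conc")
  if (!all(need %in% names(data)))
    stop("'data' must contain columns ", paste(need, collapse = ", "))
  if (nrow(data) == 0L) stop("empty dataset")
  for (v in need) if (!all(is.finite(data[[v]])))
    stop("column '", v, "' contains non-finite values")
  if (transform == "log1p") {
    if (any(data$conc < 0)) stop("negative concentrations; cannot log-transform")
    if (offset <= 0) stop("'offset' must be positive")
    y <- log(data$conc + offset)
  } else {
    y <- data$conc
  }
  # rescale each coordinate to [0, 1]
  rngs <- if (is.null(domains)) {
    list(range(data$s1), range(data$s2), range(data$t))
  } else domains
  rngs <- lapply(rngs, function(r) if (diff(r) <= 0) r + c(-0.5, 0.5) else r)
  sc <- function(x, r) (x - r[1]) / (r[2] - r[1])
  u1 <- sc(data$s1, rngs[[1]]); u2 <- sc(data$s2, rngs[[2]])
  ut <- sc(data$t, rngs[[3]])
  spec <- basis_spec(n_basis, degree,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  design <- tensor_design(u1, u2, ut, spec)
  penalty <- difference_penalty(spec, pen_order)
  ctx <- fit_context(design, penalty, y, max_coef = max_coef,
                     allow_large = allow_large)
  posterior <- lambda_posterior(ctx, lambda, prior)
  sel <- select_lambda(selector, ctx, design, penalty, y, data$well,
                       lambda, prior, k = cv_folds, seed = seed)
  lam <- sel$lambda
  profile <- lambda_profile(ctx, lambda)
  nig <- posterior_nig(ctx, lam, prior)
  alpha <- coef_at_lambda(ctx, lam)
  fitted_tr <- as.numeric(design$B %*% alpha)
  out <- structure(list(
    call = cl, data = data, y = y, transform = transform, offset = offset,
    ranges = rngs, spec = spec, design = design, penalty = penalty,
    ctx = ctx, grid = lambda, prior = prior, posterior = posterior,
    profile = profile, selector = selector, selection = sel$detail,
    lambda = lam, weights = if (selector == "average") posterior$weights,
    edf = effective_df(ctx, lam), a_n = nig$a_n, b_n = nig$b_n,
    coefficients = alpha, fitted = fitted_tr, seed = seed
  ), class = "stps")
  out
}

# map original-unit coordinates into the scaled basis coordinates
scale_coords <- function(object, s1, s2, t) {
  r <- object$ranges
  list(u1 = (s1 - r[[1]][1]) / diff(r[[1]]),
       u2 = (s2 - r[[2]][1]) / diff(r[[2]]),
       ut = (t - r[[3]][1]) / diff(r[[3]]))
}

#' Predict from a fitted spatiotemporal P-spline model
#'
#' Posterior mean of the smooth surface with pointwise credible intervals at
#' new space-time locations. Under the conjugate model the marginal posterior
#' of each linear functional of the coefficients is a scaled Student-t with
#' `2 a_n` degrees of freedom; under model averaging (`average = TRUE`) the
#' interval is computed from the posterior-weighted mixture of those t
#' distributions by numerical quantile inversion.
#'
#' @param object an `"stps"` fit.
#' @param newdata data frame with columns `s1`, `s2`, `t` (original units);
#'   defaults to the observed locations.
#' @param level credible level (default 0.95; 0 gives a degenerate interval).
#' @param average integrate over the smoothing-parameter posterior instead of
#'   conditioning on the selected value. Defaults to `TRUE` when the fit used
#'   `selector = "average"`.
#' @param backtransform return results on the raw concentration scale by
#'   monotonically inverting the response transform (default `FALSE`:
#'   transformed/modelling scale).
#' @param extrapolate allow locations outside the basis domains.
#' @param in_hull also flag whether each location lies inside the convex hull
#'   of the observed wells and the sampled time range (default `TRUE` when
#'   `well` coordinates are available).
#' @param ... unused.
#' @return data frame with columns `s1`, `s2`, `t`, `mean`, `lower`, `upper`
#'   (and `in_hull`).
#' @export
predict.stps <- function(object, newdata = NULL, level = 0.95,
                         average = object$selector == "average",
                         backtransform = FALSE, extrapolate = FALSE,
                         in_hull = TRUE, ...) {
  if (level < 0 || level >= 1) stop("'level' must be in [0, 1)")
  if (is.null(newdata)) newdata <- object$data[c("s1", "s2", "t")]
  newdata <- as.data.frame(newdata)
  stopifnot(all(c("s1", "s2", "t") %in% names(newdata)))
  u <- scale_coords(object, newdata$s1, newdata$s2, newdata$t)
  Bt <- design_rows(object$design, u$u1, u$u2, u$ut, extrapolate = extrapolate)
  a_n <- object$prior$a + object$ctx$n / 2
  df <- 2 * a_n
  if (level == 0) {
    # posterior-mean surface only; skip the interval machinery
    alpha <- if (!average) {
      coef_at_lambda(object$ctx, object$lambda)
    } else {
      keep <- which(object$posterior$weights > 1e-10)
      w <- object$posterior$weights[keep] / sum(object$posterior$weights[keep])
      Reduce(`+`, Map(function(l, wi) wi * coef_at_lambda(object$ctx, l),
                      object$grid[keep], w))
    }
    mean <- as.numeric(Bt %*% alpha)
    lower <- upper <- mean
  } else if (!average) {
    pieces <- target_pieces(object$ctx, Bt)
    pr <- predict_at_lambda(object$ctx, pieces, object$lambda)
    b_n <- object$b_n
    scale <- sqrt(pmax(b_n / a_n * pr$quad, 0))
    tq <- stats::qt((1 + level) / 2, df)
    mean <- pr$mean; lower <- mean - tq * scale; upper <- mean + tq * scale
  } else {
    pieces <- target_pieces(object$ctx, Bt)
    keep <- which(object$posterior$weights > 1e-10)
    w <- object$posterior$weights[keep]
    w <- w / sum(w)
    lams <- object$grid[keep]
    prof <- lambda_profile(object$ctx, lams)
    nt <- nrow(pieces$U0)
    M <- matrix(0, nt, length(keep)); S <- matrix(0, nt, length(keep))
    for (j in seq_along(keep)) {
      pr <- predict_at_lambda(object$ctx, pieces, lams[j])
      b_nj <- object$prior$b + prof$qform[j] / 2
      M[, j] <- pr$mean
      S[, j] <- sqrt(pmax(b_nj / a_n * pr$quad, 0))
    }
    mean <- as.numeric(M %*% w)
    if (level > 0) {
      qs <- mixture_t_quantiles(M, S, df, w, c((1 - level) / 2,
                                               (1 + level) / 2))
      lower <- qs[, 1]; upper <- qs[, 2]
    } else {
      lower <- upper <- mean
    }
  }
  out <- data.frame(s1 = newdata$s1, s2 = newdata$s2, t = newdata$t,
                    mean = mean, lower = lower, upper = upper)
  if (backtransform && object$transform == "log1p") {
    inv <- function(z) pmax(exp(z) - object$offset, 0)
    out$mean <- inv(out$mean); out$lower <- inv(out$lower)
    out$upper <- inv(out$upper)
  }
  if (isTRUE(in_hull) && !is.null(object$data$well)) {
    wells <- unique(object$data[c("s1", "s2")])
    out$in_hull <- in_convex_hull(cbind(out$s1, out$s2), as.matrix(wells)) &
      out$t >= min(object$data$t) & out$t <= max(object$data$t)
  }
  out
}

# Quantiles of a row-wise mixture of t distributions: M, S are nt x L
# matrices of locations and scales, w the mixture weights.
mixture_t_quantiles <- function(M, S, df, w, probs) {
  nt <- nrow(M)
  out <- matrix(NA_real_, nt, length(probs))
  S <- pmax(S, 1e-300)
  for (i in seq_len(nt)) {
    mu <- M[i, ]; sc <- S[i, ]
    cdf <- function(x) sum(w * stats::pt((x - mu) / sc, df))
    lo0 <- min(mu - 12 * sc); hi0 <- max(mu + 12 * sc)
    for (j in seq_along(probs)) {
      p <- probs[j]
      out[i, j] <- stats::uniroot(function(x) cdf(x) - p, c(lo0, hi0),
                                  extendInt = "yes", tol = 1e-9)$root
    }
  }
  out
}

#' Predictions on a regular space-time grid
#'
#' Convenience wrapper building a regular grid over the fitted domains
#' (original units) and calling [predict.stps()].
#'
#' @param object an `"stps"` fit.
#' @param n grid sizes `c(n_s1, n_s2, n_t)` (default `c(40, 40, 10)`).
#' @param ... passed to [predict.stps()].
#' @return data frame as from [predict.stps()], with attribute `"grid"`
#'   holding the marginal grids.
#' @export
prediction_grid <- function(object, n = c(40L, 40L, 10L), ...) {
  r <- object$ranges
  g1 <- seq(r[[1]][1], r[[1]][2], length.out = n[1])
  g2 <- seq(r[[2]][1], r[[2]][2], length.out = n[2])
  gt <- seq(r[[3]][1], r[[3]][2], length.out = n[3])
  gr <- expand.grid(s1 = g1, s2 = g2, t = gt, KEEP.OUT.ATTRS = FALSE)
  out <- predict(object, gr, ...)
  attr(out, "grid") <- list(s1 = g1, s2 = g2, t = gt)
  out
}
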