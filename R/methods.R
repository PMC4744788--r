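#' @export
print.stps <- function(x, ...) {
  cat("Bayesian spatiotemporal P-spline fit\n")
  cat(sprintf("  %d observations%s, basis %s (degree %d), penalty order %d\n",
              x$ctx$n,
              if (!is.null(x$data$well))
                sprintf(" at %d wells", length(unique(x$data$well))) else "",
              paste(x$spec$n_basis, collapse = " x "), x$spec$degree,
              x$penalty$order))
  cat(sprintf("  selector: %s;  lambda = %.4g;  edf = %.2f\n",
              x$selector, x$lambda, x$edf))
  cat(sprintf("  MAP lambda = %.4g;  posterior sigma^2 (mean) = %.4g\n",
              x$posterior$map_lambda, x$b_n / (x$a_n - 1)))
  invisible(x)
}

#' Summarize a spatiotemporal P-spline fit
#'
#' Reports the smoothing parameter each selector would choose from the shared
#' profile, together with effective degrees of freedom and residual summaries
#' on the modelling scale. Cross-validation selectors are only reported if
#' they were used for the fit (they require refits).
#'
#' @param object an `"stps"` fit.
#' @param ... unused.
#' @export
summary.stps <- function(object, ...) {
  ctx <- object$ctx
  grid <- object$grid
  sel_tab <- data.frame(
    selector = c("map", "aicc", "gcv", "bic"),
    lambda = c(object$posterior$map_lambda,
               grid[which.min(aicc(ctx, grid))],
               grid[which.min(gcv(ctx, grid))],
               grid[which.min(bic(ctx, grid))]))
  sel_tab$edf <- vapply(sel_tab$lambda, function(l) effective_df(ctx, l),
                        numeric(1))
  if (inherits(object$selection, "stps_cv")) {
    sel_tab <- rbind(sel_tab,
                     data.frame(selector = object$selector,
                                lambda = object$lambda,
                                edf = object$edf))
  }
  out <- list(call = object$call, selectors = sel_tab,
              selector = object$selector, lambda = object$lambda,
              edf = object$edf, n = ctx$n, m = ctx$m,
              sigma2 = object$b_n / (object$a_n - 1),
              a_n = object$a_n, b_n = object$b_n,
              residuals = summary(object$y - object$fitted),
              boundary = object$posterior$boundary)
  class(out) <- "summary.stps"
  out
}

#' @export
print.summary.stps <- function(x, ...) {
  cat("Bayesian spatiotemporal P-spline fit\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nn = %d observations, m = %d coefficients\n", x$n, x$m))
  cat(sprintf("Selected by %s: lambda = %.4g (edf = %.2f)\n",
              x$selector, x$lambda, x$edf))
  cat(sprintf("Posterior error variance: E[sigma^2 | y] = %.4g (a_n = %.1f, b_n = %.4g)\n",
              x$sigma2, x$a_n, x$b_n))
  if (x$boundary)
    cat("Note: posterior maximum on the lambda-grid boundary.\n")
  cat("\nSmoothing parameter by selector:\n")
  print(x$selectors, row.names = FALSE, digits = 4)
  cat("\nResiduals (modelling scale):\n")
  print(x$residuals)
  invisible(x)
}

#' @export
coef.stps <- function(object, ...) {
  object$coefficients
}

#' @export
fitted.stps <- function(object, ...) {
  object$fitted
}

#' @export
residuals.stps <- function(object, ...) {
  object$y - object$fitted
}

#' Plot a fitted concentration surface at one time point
#'
#' Filled-contour image of the posterior-mean surface at a single time slice
#' with the well locations overlaid.
#'
#' @param x an `"stps"` fit.
#' @param t time (original units) of the slice; defaults to the median
#'   sampling time.
#' @param n spatial grid resolution `c(n_s1, n_s2)`.
#' @param backtransform plot on the raw concentration scale.
#' @param ... passed to [graphics::filled.contour()].
#' @export
plot.stps <- function(x, t = stats::median(x$data$t), n = c(60L, 60L),
                      backtransform = FALSE, ...) {
  r <- x$ranges
  g1 <- seq(r[[1]][1], r[[1]][2], length.out = n[1])
  g2 <- seq(r[[2]][1], r[[2]][2], length.out = n[2])
  gr <- expand.grid(s1 = g1, s2 = g2, t = t, KEEP.OUT.ATTRS = FALSE)
  pr <- predict(x, gr, level = 0, backtransform = backtransform,
                in_hull = FALSE)
  z <- matrix(pr$mean, length(g1), length(g2))
  graphics::filled.contour(
    g1, g2, z, xlab = "easting", ylab = "northing",
    main = sprintf("Predicted surface at t = %.3g", t),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::points(x$data$s1, x$data$s2, pch = 3, cex = 0.7)
    }, ...)
  invisible(pr)
}

#' Simulate from the posterior predictive at the observed design
#'
#' Draws replicate response vectors: `sigma^2` from its inverse-gamma
#' posterior, coefficients from their conditional Gaussian posterior at the
#' selected smoothing parameter, and observation noise on top.
#'
#' @param object an `"stps"` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix `n x nsim` of simulated responses on the modelling scale.
#' @export
simulate.stps <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- object$ctx
  lam <- object$lambda
  q <- ctx$q; mq <- length(ctx$s)
  # posterior precision of rotated coefficients (beta0, gamma), / sigma^2;
  # the gamma block carries the null-space coupling C01T' A00^{-1} C01T on
  # top of the diagonalized spectrum
  Fc <- backsolve(ctx$cholA, ctx$C01T, transpose = TRUE)
  M <- rbind(cbind(t(ctx$cholA) %*% ctx$cholA, ctx$C01T),
             cbind(t(ctx$C01T), diag(ctx$s + lam, mq) + crossprod(Fc)))
  M <- (M + t(M)) / 2
  cholM <- chol(M)
  gamma_hat <- ctx$c / (ctx$s + lam)
  beta0_hat <- chol_solve(ctx$cholA, ctx$by0 -
                            as.numeric(ctx$C01T %*% gamma_hat))
  center <- c(beta0_hat, gamma_hat)
  out <- matrix(NA_real_, ctx$n, nsim)
  for (k in seq_len(nsim)) {
    sig2 <- 1 / stats::rgamma(1, shape = object$a_n, rate = object$b_n)
    z <- stats::rnorm(q + mq)
    theta <- center + sqrt(sig2) * backsolve(cholM, z)
    alpha <- as.numeric(ctx$Z %*% theta[seq_len(q)]) +
      as.numeric(ctx$Tmat %*% theta[-seq_len(q)])
    mu <- as.numeric(object$design$B %*% alpha)
    out[, k] <- mu + stats::rnorm(ctx$n, 0, sqrt(sig2))
  }
  out
}
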