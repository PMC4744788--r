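#' Classical smoothing-parameter selection criteria
#'
#' Generalized cross-validation, corrected AIC and BIC in their Gaussian
#' profile-likelihood forms, all computed from the same `(RSS(lambda),
#' edf(lambda))` profile as the Bayesian machinery:
#' \describe{
#'   \item{GCV}{`n RSS / (n - edf)^2`}
#'   \item{AICc}{`n log(RSS/n) + 2 edf + 2 edf (edf + 1) / (n - edf - 1)`}
#'   \item{BIC}{`n log(RSS/n) + log(n) edf`}
#' }
#' `RSS` is the plain residual sum of squares of the fitted values. Undefined
#' denominators (`edf >= n`, or `edf >= n - 1` for AICc) return `Inf` with a
#' warning so grid minimization remains well defined.
#'
#' @param ctx an `"stps_ctx"` from [fit_context()].
#' @param lambda positive numeric vector.
#' @return numeric vector of criterion values.
#' @name selection_criteria
NULL

#' @rdname selection_criteria
#' @export
gcv <- function(ctx, lambda) {
  prof <- lambda_profile(ctx, lambda)
  denom <- (ctx$n - prof$edf)^2
  bad <- prof$edf >= ctx$n
  if (any(bad)) warning("edf >= n at some lambda; GCV set to Inf there")
  out <- ctx$n * prof$rss / denom
  out[bad] <- Inf
  out
}

#' @rdname selection_criteria
#' @export
aicc <- function(ctx, lambda) {
  prof <- lambda_profile(ctx, lambda)
  bad <- prof$edf >= ctx$n - 1
  if (any(bad)) warning("edf >= n - 1 at some lambda; AICc set to Inf there")
  out <- ctx$n * log(prof$rss / ctx$n) + 2 * prof$edf +
    2 * prof$edf * (prof$edf + 1) / (ctx$n - prof$edf - 1)
  out[bad] <- Inf
  out
}

#' @rdname selection_criteria
#' @export
bic <- function(ctx, lambda) {
  prof <- lambda_profile(ctx, lambda)
  ctx$n * log(prof$rss / ctx$n) + log(ctx$n) * prof$edf
}

#' k-fold cross-validation score along the smoothing-parameter grid
#'
#' Folds are formed by seeded shuffling either of individual observations or
#' of whole wells (grouped folds that respect the clustered monitoring
#' design). Each fold is refit with the shared penalty-side decomposition; the
#' score at each `lambda` is the mean squared held-out prediction error on the
#' modelling (transformed) scale. Held-out points are predicted from the
#' global bases even when they fall outside the training wells' hull.
#'
#' @param design an `"stps_design"` for the full dataset.
#' @param penalty matching `"stps_penalty"`.
#' @param y response vector on the modelling scale.
#' @param well well identifiers (required for `grouping = "well"`).
#' @param lambda positive grid of smoothing parameters.
#' @param k number of folds (default 10).
#' @param grouping `"observation"` or `"well"`.
#' @param seed integer seed controlling the fold shuffle.
#' @return object of class `"stps_cv"`: list with `lambda`, `score`,
#'   `lambda_min`, `grouping`, `folds` (assignment vector), `k`,
#'   `skipped_folds`.
#' @export
cv_score <- function(design, penalty, y, well = NULL, lambda = lambda_grid(),
                     k = 10L, grouping = c("observation", "well"),
                     seed = 1L) {
  grouping <- match.arg(grouping)
  k <- as.integer(k)
  n <- length(y)
  if (k < 2L) stop("'k' must be at least 2")
  set.seed(seed)
  if (grouping == "observation") {
    if (k > n) stop("more folds than observations")
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    if (is.null(well)) stop("well identifiers are required for well-based CV")
    uw <- unique(well)
    if (length(uw) < k) stop("well-based CV needs at least k = ", k, " wells")
    wf <- sample(rep_len(seq_len(k), length(uw)))
    fold <- wf[match(well, uw)]
  }
  B <- design$B
  sse <- numeric(length(lambda))
  nheld <- 0L
  skipped <- 0L
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    dtrain <- design
    dtrain$B <- B[train, , drop = FALSE]
    dtrain$n <- length(train)
    ctx <- tryCatch(
      fit_context(dtrain, penalty, y[train], allow_large = TRUE),
      error = function(e) NULL)
    if (is.null(ctx)) {
      skipped <- skipped + 1L
      next
    }
    pieces <- target_pieces(ctx, B[test, , drop = FALSE])
    for (j in seq_along(lambda)) {
      pr <- predict_at_lambda(ctx, pieces, lambda[j])
      sse[j] <- sse[j] + sum((y[test] - pr$mean)^2)
    }
    nheld <- nheld + length(test)
  }
  if (skipped > 0L)
    warning(skipped, " fold(s) skipped: training design singular for the ",
            "unpenalized directions")
  if (nheld == 0L) stop("all cross-validation folds failed")
  score <- sse / nheld
  structure(list(lambda = lambda, score = score,
                 lambda_min = lambda[which.min(score)],
                 grouping = grouping, folds = fold, k = k,
                 skipped_folds = skipped, seed = seed),
            class = "stps_cv")
}

# Unified selector dispatch used by stps(); returns list(lambda, detail).
select_lambda <- function(selector, ctx, design, penalty, y, well,
                          grid, prior, k = 10L, seed = 1L) {
  switch(selector,
    map = ,
    average = {
      post <- lambda_posterior(ctx, grid, prior)
      list(lambda = post$map_lambda, detail = post)
    },
    aicc = {
      v <- aicc(ctx, grid)
      list(lambda = grid[which.min(v)], detail = v)
    },
    gcv = {
      v <- gcv(ctx, grid)
      list(lambda = grid[which.min(v)], detail = v)
    },
    bic = {
      v <- bic(ctx, grid)
      list(lambda = grid[which.min(v)], detail = v)
    },
    `cv-obs` = {
      cv <- cv_score(design, penalty, y, well, grid, k, "observation", seed)
      list(lambda = cv$lambda_min, detail = cv)
    },
    `cv-well` = {
      cv <- cv_score(design, penalty, y, well, grid, k, "well", seed)
      list(lambda = cv$lambda_min, detail = cv)
    },
    stop("unknown selector '", selector, "'")
  )
}
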