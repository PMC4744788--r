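test_that("the decomposition reproduces direct penalized solves", {
  inst <- random_instance(10)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  for (lam in c(0.01, 1, 100)) {
    oracle <- dense_oracle(inst$design, inst$penalty, inst$y, lam)
    fast <- stpspline:::coef_at_lambda(ctx, lam)
    expect_lt(max(abs(fast - oracle$alpha)) / max(abs(oracle$alpha)), 1e-8)
    prof <- lambda_profile(ctx, lam)
    expect_equal(prof$edf, oracle$edf, tolerance = 1e-8)
    expect_equal(prof$qform, oracle$qform, tolerance = 1e-8)
    expect_equal(prof$rss, oracle$rss, tolerance = 1e-8)
    expect_equal(prof$logdet, oracle$logdet, tolerance = 1e-8)
  }
})

test_that("profiling the grid reuses the single dense decomposition", {
  inst <- random_instance(11)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  prof <- lambda_profile(ctx, lambda_grid(length = 100L))
  expect_equal(nrow(prof), 100L)
  expect_identical(ctx$n_dense_decompositions, 1L)
})

test_that("the coefficient-count guardrail refuses oversized models", {
  spec <- basis_spec(c(25L, 25L, 25L), 2L,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  des <- tensor_design(runif(5), runif(5), runif(5), spec)
  pen <- difference_penalty(spec, 1L, precompute = FALSE)
  expect_equal(des$m, 15625L)
  expect_error(fit_context(des, pen, rnorm(5)), "15625")
})

test_that("unidentified null-space directions raise an informative error", {
  # all observations at a single spatial location: the spatial null-space
  # cannot be separated from the penalized part... here instead use too few
  # observations to pin the (order-2) null space of dimension 8
  set.seed(12)
  spec <- basis_spec(c(4L, 4L, 3L), 2L,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  des <- tensor_design(rep(0.5, 3), rep(0.5, 3), c(0.2, 0.5, 0.8), spec)
  pen <- difference_penalty(spec, 2L)
  expect_error(fit_context(des, pen, rnorm(3)), "singular|identify")
})

test_that("effective degrees of freedom hit their closed-form limits", {
  inst <- random_instance(13, n = 300L)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  expect_equal(effective_df(ctx, Inf), 1)          # order-1 null space
  expect_equal(effective_df(ctx, 0), ctx$rank_B)
  expect_equal(ctx$rank_B, qr(as.matrix(inst$design$B))$rank)
  # strictly decreasing in lambda, matching the dense hat-matrix trace
  grid <- lambda_grid(1e-4, 1e4, 50L)
  edfs <- vapply(grid, function(l) effective_df(ctx, l), numeric(1))
  expect_true(all(diff(edfs) < 0))
  for (l in grid[c(1, 25, 50)]) {
    expect_equal(effective_df(ctx, l),
                 dense_oracle(inst$design, inst$penalty, inst$y, l)$edf,
                 tolerance = 1e-8)
  }
  expect_error(effective_df(ctx, -1), "non-negative")
})

test_that("profile monotonicity: RSS rises and edf falls with lambda", {
  inst <- random_instance(14)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  prof <- lambda_profile(ctx, lambda_grid(1e-6, 1e6, 60L))
  expect_true(all(diff(prof$rss) >= -1e-10))
  expect_true(all(diff(prof$edf) <= 1e-10))
  expect_true(all(diff(prof$qform) >= -1e-10))
})

test_that("log lambda-posterior matches the dense null-space evaluation", {
  for (seed in 20:22) {
    inst <- random_instance(seed, n_basis = c(3L, 3L, 3L), n = 50L)
    ctx <- fit_context(inst$design, inst$penalty, inst$y)
    grid <- 10^seq(-4, 4, by = 1)
    lp_fast <- log_lambda_posterior(ctx, grid)
    lp_dense <- vapply(grid, function(l)
      dense_oracle(inst$design, inst$penalty, inst$y, l)$lp, numeric(1))
    # equal up to one common additive constant
    d <- (lp_fast - lp_fast[5]) - (lp_dense - lp_dense[5])
    expect_lt(max(abs(d)), 1e-8 * max(1, max(abs(lp_dense - lp_dense[5]))))
  }
})

test_that("the ridge-limit posterior converges to the null-space form", {
  inst <- random_instance(23, n_basis = c(3L, 3L, 3L), n = 50L)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  grid <- 10^seq(-3, 3, by = 1)
  lp_fast <- log_lambda_posterior(ctx, grid)
  ref <- lp_fast - lp_fast[4]
  # eps below 1e-4 makes the dense reference itself unreliable: the eps^2
  # eigenvalue of the completed precision drowns in the determinant's
  # floating-point noise, so the comparison stops at the last trustworthy eps
  errs <- vapply(10^-(1:4), function(eps) {
    lp_r <- vapply(grid, function(l)
      dense_ridge_lp(inst$design, inst$penalty, inst$y, l, eps), numeric(1))
    max(abs((lp_r - lp_r[4]) - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))  # monotone decrease
  expect_lt(errs[length(errs)], 1e-5)
})

test_that("the posterior stays proper and finite across the default grid", {
  for (seed in 30:32) {
    inst <- random_instance(seed, n_basis = c(4L, 3L, 3L),
                            n = sample(5:50, 1), order = sample(1:2, 1))
    ctx <- fit_context(inst$design, inst$penalty, inst$y)
    lp <- log_lambda_posterior(ctx, lambda_grid())
    expect_true(all(is.finite(lp)))
  }
})

test_that("prior hyperparameters default to a = b = 1e-4", {
  pr <- nig_prior()
  expect_equal(pr$a, 1e-4)
  expect_equal(pr$b, 1e-4)
  expect_error(nig_prior(a = 0), "a > 0")
})

test_that("MAP selection returns the grid argmax with boundary handling", {
  inst <- random_instance(15)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  post <- lambda_posterior(ctx, lambda_grid())
  expect_equal(post$map_lambda, post$grid[which.max(post$log_posterior)])
  expect_false(post$boundary)
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
  expect_warning(p1 <- lambda_posterior(ctx, 1), "boundary")
  expect_equal(p1$map_lambda, 1)
  expect_error(lambda_posterior(ctx, c(1e9, 1e10), strict = TRUE),
               "boundary")
})

test_that("posterior NIG parameters follow their closed forms", {
  inst <- random_instance(16)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  nig <- stpspline:::posterior_nig(ctx, 1, nig_prior())
  expect_equal(nig$a_n, 1e-4 + length(inst$y) / 2)
  expect_gte(nig$b_n, 1e-4)
})

test_that("noise-free data from a spline in the span are reproduced", {
  set.seed(17)
  spec <- basis_spec(c(5L, 4L, 3L), 2L,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  n <- 500
  s1 <- runif(n); s2 <- runif(n); tt <- runif(n)
  des <- tensor_design(s1, s2, tt, spec)
  alpha0 <- rnorm(60)
  y <- as.numeric(des$B %*% alpha0)
  pen <- difference_penalty(spec, 1L)
  ctx <- fit_context(des, pen, y)
  pred <- as.numeric(des$B %*% stpspline:::coef_at_lambda(ctx, 1e-12))
  expect_lt(max(abs(pred - y)), 1e-8)
})

test_that("model averaging nests the single-lambda fit and widens intervals", {
  truth <- test_truth()
  dat <- sample_plume(truth, plume_scenario(3, seed = 5), seed = 5)
  fit <- stps(dat, n_basis = c(6L, 5L, 4L))
  newd <- data.frame(s1 = c(0.5, 0.6, 0.7), s2 = c(0.4, 0.45, 0.35),
                     t = c(0.5, 0.5, 0.5))
  # degenerate one-point grid: averaging equals conditioning
  suppressWarnings({
    fit1 <- stps(dat, n_basis = c(6L, 5L, 4L), lambda = fit$lambda,
                 selector = "average")
  })
  p_avg <- predict(fit1, newd, average = TRUE)
  p_map <- predict(fit1, newd, average = FALSE)
  expect_equal(p_avg$mean, p_map$mean, tolerance = 1e-9)
  expect_equal(p_avg$lower, p_map$lower, tolerance = 1e-6)
  # with the full grid the mixture interval is at least as wide
  pm <- predict(fit, newd, average = FALSE)
  pa <- predict(fit, newd, average = TRUE)
  expect_true(all(pa$upper - pa$lower >= pm$upper - pm$lower - 1e-8))
  # level 0 collapses the interval
  p0 <- predict(fit, newd, level = 0)
  expect_equal(p0$lower, p0$mean)
  expect_equal(p0$upper, p0$mean)
})
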