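test_that("GCV, AICc and BIC match their textbook dense forms", {
  inst <- random_instance(40)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  n <- length(inst$y)
  for (lam in c(0.05, 1, 50)) {
    o <- dense_oracle(inst$design, inst$penalty, inst$y, lam)
    expect_equal(gcv(ctx, lam), n * o$rss / (n - o$edf)^2, tolerance = 1e-10)
    expect_equal(aicc(ctx, lam),
                 n * log(o$rss / n) + 2 * o$edf +
                   2 * o$edf * (o$edf + 1) / (n - o$edf - 1),
                 tolerance = 1e-10)
    expect_equal(bic(ctx, lam), n * log(o$rss / n) + log(n) * o$edf,
                 tolerance = 1e-10)
  }
  expect_true(all(gcv(ctx, lambda_grid()) > 0))
})

test_that("the smoothed-out limit of GCV is the near-constant fit", {
  inst <- random_instance(41)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  n <- length(inst$y)
  rss_inf <- lambda_profile(ctx, 1e12)$rss
  # order-1 penalty: the lambda -> Inf fit is the basis-weighted grand mean
  expect_equal(rss_inf, sum((inst$y - mean(inst$y))^2), tolerance = 0.05)
  expect_equal(gcv(ctx, 1e12), n * rss_inf / (n - 1 - 0)^2,
               tolerance = 1e-6)
})

test_that("AICc exceeds AIC wherever both are defined", {
  inst <- random_instance(42)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  g <- lambda_grid(1e-4, 1e4, 30L)
  prof <- lambda_profile(ctx, g)
  aic <- length(inst$y) * log(prof$rss / length(inst$y)) + 2 * prof$edf
  expect_true(all(aicc(ctx, g) > aic))
})

test_that("interpolating fits push GCV to +Inf with a warning", {
  set.seed(43)
  spec <- basis_spec(c(4L, 4L, 3L), 1L,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  des <- tensor_design(runif(5), runif(5), runif(5), spec)
  pen <- difference_penalty(spec, 1L)
  ctx <- fit_context(des, pen, rnorm(5))
  expect_equal(ctx$rank_B, 5L)  # rank(B) = n: lambda -> 0 interpolates
  expect_warning(v <- gcv(ctx, 1e-300), "Inf")
  expect_true(is.infinite(v))
})

test_that("observation-based k = n cross-validation equals explicit LOO", {
  set.seed(44)
  n <- 40
  spec <- basis_spec(c(4L, 3L, 3L), 2L,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  s1 <- runif(n); s2 <- runif(n); tt <- runif(n)
  des <- tensor_design(s1, s2, tt, spec)
  pen <- difference_penalty(spec, 1L)
  y <- sin(3 * s1) + tt + rnorm(n, 0, 0.2)
  grid <- c(0.5, 5)
  cv <- cv_score(des, pen, y, well = NULL, lambda = grid, k = n,
                 grouping = "observation", seed = 7)
  loo <- numeric(length(grid))
  for (i in seq_len(n)) {
    B <- as.matrix(des$B)
    K <- as.matrix(pen$DtD)
    Btr <- B[-i, , drop = FALSE]
    for (j in seq_along(grid)) {
      a <- solve(crossprod(Btr) + grid[j] * K, crossprod(Btr, y[-i]))
      loo[j] <- loo[j] + (y[i] - sum(B[i, ] * a))^2
    }
  }
  expect_equal(cv$score, loo / n, tolerance = 1e-8)
})

test_that("cross-validation is deterministic given the seed", {
  truth <- test_truth()
  dat <- sample_plume(truth, plume_scenario(3, seed = 8), seed = 8)
  y <- log(dat$conc + 1)
  spec <- basis_spec(c(6L, 5L, 4L), 2L,
                     domains = list(c(0, 1), c(0, 1), c(0, 1)))
  des <- tensor_design(dat$s1, dat$s2, dat$t, spec)
  pen <- difference_penalty(spec, 1L)
  g <- lambda_grid(1e-4, 1e4, 17L)
  a <- cv_score(des, pen, y, dat$well, g, 5, "well", seed = 99)
  b <- cv_score(des, pen, y, dat$well, g, 5, "well", seed = 99)
  expect_identical(a$folds, b$folds)
  expect_identical(a$score, b$score)
  d <- cv_score(des, pen, y, dat$well, g, 5, "well", seed = 100)
  expect_false(identical(a$folds, d$folds))
  # well-based folds never split a well
  split_ok <- tapply(a$folds, dat$well, function(f) length(unique(f)) == 1L)
  expect_true(all(split_ok))
})

test_that("criterion curves are continuous (finite) along the grid", {
  inst <- random_instance(45)
  ctx <- fit_context(inst$design, inst$penalty, inst$y)
  g <- lambda_grid()
  expect_true(all(is.finite(gcv(ctx, g))))
  expect_true(all(is.finite(aicc(ctx, g))))
  expect_true(all(is.finite(bic(ctx, g))))
})

test_that("BIC selects at least as much smoothing as AICc on scenario-2 data", {
  truth <- test_truth()
  wins <- logical(20)
  for (r in seq_along(wins)) {
    dat <- sample_plume(truth, plume_scenario(2, seed = 300 + r),
                        seed = 300 + r)
    fit <- stps(dat, n_basis = c(8L, 8L, 4L))
    g <- fit$grid
    wins[r] <- g[which.min(bic(fit$ctx, g))] >= g[which.min(aicc(fit$ctx, g))]
  }
  expect_gte(mean(wins), 0.9)
})
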