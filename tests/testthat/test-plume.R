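test_that("pure diffusion conserves mass under zero-flux boundaries", {
  truth <- solve_plume(constant_flow(0, 0, diffusion = 0.01),
                       gaussian_plume_init(c(0.5, 0.5), 0.1, 50),
                       grid = c(60L, 60L, 20L))
  cell <- (truth$s1[2] - truth$s1[1]) * (truth$s2[2] - truth$s2[1])
  mass <- apply(truth$values, 3, sum) * cell
  expect_lt(max(abs(mass - mass[1])) / mass[1], 0.001)
})

test_that("pure diffusion reproduces the spreading Gaussian heat kernel", {
  D <- 0.002
  s0 <- 0.05
  truth <- solve_plume(constant_flow(0, 0, diffusion = D),
                       gaussian_plume_init(c(0.5, 0.5), s0, 1),
                       grid = c(100L, 100L, 11L), t_span = c(0, 0.5))
  # closed form: variance grows as s0^2 + 2 D t, peak scales accordingly
  for (k in c(6L, 11L)) {
    tt <- truth$t[k]
    v <- s0^2 + 2 * D * tt
    g <- expand.grid(s1 = truth$s1, s2 = truth$s2)
    closed <- s0^2 / v * exp(-((g$s1 - 0.5)^2 + (g$s2 - 0.5)^2) / (2 * v))
    interior <- g$s1 > 0.2 & g$s1 < 0.8 & g$s2 > 0.2 & g$s2 < 0.8
    err <- abs(as.vector(truth$values[, , k])[interior] - closed[interior])
    expect_lt(max(err) / max(closed), 0.01)
  }
})

test_that("with no diffusion the plume centroid advects at the drift speed", {
  u <- c(0.3, -0.2)
  truth <- solve_plume(constant_flow(u[1], u[2], diffusion = 0),
                       gaussian_plume_init(c(0.35, 0.6), 0.07, 10),
                       grid = c(120L, 120L, 11L), t_span = c(0, 0.8))
  centroid <- function(k) {
    w <- truth$values[, , k]
    c(sum(outer(truth$s1, rep(1, 120)) * w), sum(outer(rep(1, 120), truth$s2) * w)) / sum(w)
  }
  c0 <- centroid(1); c1 <- centroid(11)
  h <- truth$s1[2] - truth$s1[1]
  expect_lt(abs((c1[1] - c0[1]) - u[1] * 0.8), h)
  expect_lt(abs((c1[2] - c0[2]) - u[2] * 0.8), h)
})

test_that("unstable solver configurations are refused with guidance", {
  expect_error(
    solve_plume(constant_flow(0, 0, diffusion = 5),
                grid = c(100L, 100L, 5L), max_substeps = 10L),
    "sub-steps")
})

test_that("simulated concentrations are finite and non-negative", {
  truth <- test_truth()
  expect_true(all(is.finite(truth$values)))
  expect_true(all(truth$values >= 0))
  dat <- sample_plume(truth, plume_scenario(1, seed = 2), seed = 2)
  expect_true(all(dat$conc >= 0))
})

test_that("sampling is byte-deterministic under a fixed seed", {
  truth <- test_truth()
  a <- sample_plume(truth, plume_scenario(1, seed = 3), seed = 3)
  b <- sample_plume(truth, plume_scenario(1, seed = 3), seed = 3)
  expect_identical(a, b)
  d <- sample_plume(truth, plume_scenario(1, seed = 4), seed = 4)
  expect_false(identical(a$conc, d$conc))
})

test_that("scenarios deliver the prescribed design sizes", {
  s1 <- plume_scenario(1, seed = 1)
  expect_equal(nrow(s1), 1402L)
  expect_equal(nrow(attr(s1, "wells")), 29L)
  s2 <- plume_scenario(2, seed = 1)
  expect_equal(nrow(s2), 1402L)
  expect_equal(nrow(attr(s2, "wells")), 280L)
  s3 <- plume_scenario(3, seed = 1)
  expect_equal(nrow(s3), 100L)
  expect_equal(nrow(attr(s3, "wells")), 29L)
  # each well sampled about 3-4 times on average in the sparse scenario
  expect_equal(nrow(s3) / length(unique(s3$well)), 100 / 29, tolerance = 1e-12)
})

test_that("infinite signal-to-noise returns the interpolated truth exactly", {
  truth <- test_truth()
  des <- plume_scenario(3, seed = 6)
  dat <- sample_plume(truth, des, noise_model(snr = Inf), seed = 6)
  expect_equal(dat$conc, attr(dat, "signal"), tolerance = 1e-12)
})

test_that("within-well correlation of the log-scale noise matches rho", {
  # background concentration keeps the log signal well away from zero so the
  # non-negativity clamp never distorts the recovered noise
  truth <- solve_plume(init = function(s1, s2)
    20 + 100 * exp(-((s1 - 0.6)^2 + (s2 - 0.4)^2) / 0.08),
    grid = c(40L, 40L, 10L))
  des <- plume_scenario(3, seed = 7)
  rho_hat <- vapply(seq_len(200), function(r) {
    dat <- sample_plume(truth, des, seed = 1000 + r)
    eta <- log(dat$conc + 1) - log(attr(dat, "signal") + 1)
    s2 <- attr(dat, "log_noise_sd")^2
    # unbiased moment estimate of E[eta_i eta_j] over same-well pairs
    num <- 0; npairs <- 0
    for (w in split(eta, dat$well)) {
      k <- length(w)
      if (k < 2) next
      num <- num + (sum(w)^2 - sum(w^2)) / 2
      npairs <- npairs + k * (k - 1) / 2
    }
    num / npairs / s2
  }, numeric(1))
  expect_lt(abs(mean(rho_hat) - 0.05), 0.03)
})

test_that("wells outside the simulated domain are rejected", {
  truth <- test_truth()
  des <- plume_scenario(3, seed = 9)
  des$s1[1] <- 1.5
  expect_error(sample_plume(truth, des, seed = 9), "outside")
})
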