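#' Groundwater flow field for the plume simulator
#'
#' Smooth synthetic stand-in for an observed groundwater-level surface: the
#' drift velocity is the negative gradient of a two-bump potential (a high in
#' the south-east, a low in the north-west of the unit square), so the plume
#' drifts from south-east to north-west as is typical for a down-gradient
#' contaminant plume. The field is rescaled so that its maximum speed equals
#' `peak_speed` (domain lengths per unit time), which together with
#' `diffusion` sets the effective Peclet number of the transport.
#'
#' @param diffusion diffusion coefficient `D` of the transport equation
#'   (domain-length^2 per unit time).
#' @param peak_speed maximum drift speed (default 0.35).
#' @param high,low centres of the potential high and low.
#' @param width Gaussian width of the two potential bumps.
#' @return object of class `"stps_flow"`: list with vectorized velocity
#'   functions `u1(s1, s2)`, `u2(s1, s2)` and the `diffusion` constant.
#' @export
plume_flow <- function(diffusion = 0.0025, peak_speed = 0.35,
                       high = c(0.85, 0.15), low = c(0.15, 0.85),
                       width = 0.45) {
  stopifnot(diffusion >= 0, peak_speed >= 0)
  g <- function(s1, s2, c0) exp(-((s1 - c0[1])^2 + (s2 - c0[2])^2) /
                                  (2 * width^2))
  # velocity = -grad(potential), potential = bump(high) - bump(low)
  v1 <- function(s1, s2) {
    (s1 - high[1]) / width^2 * g(s1, s2, high) -
      (s1 - low[1]) / width^2 * g(s1, s2, low)
  }
  v2 <- function(s1, s2) {
    (s2 - high[2]) / width^2 * g(s1, s2, high) -
      (s2 - low[2]) / width^2 * g(s1, s2, low)
  }
  gg <- expand.grid(s1 = seq(0, 1, length.out = 51),
                    s2 = seq(0, 1, length.out = 51))
  sp <- sqrt(v1(gg$s1, gg$s2)^2 + v2(gg$s1, gg$s2)^2)
  scl <- if (max(sp) > 0) peak_speed / max(sp) else 0
  structure(list(u1 = function(s1, s2) scl * v1(s1, s2),
                 u2 = function(s1, s2) scl * v2(s1, s2),
                 diffusion = diffusion),
            class = "stps_flow")
}

#' Constant flow field
#'
#' Uniform drift velocity, mainly useful for verifying the solver against
#' method-of-characteristics solutions.
#'
#' @param u1,u2 drift velocity components.
#' @param diffusion diffusion coefficient.
#' @return an `"stps_flow"` object.
#' @export
constant_flow <- function(u1 = 0, u2 = 0, diffusion = 0.0025) {
  structure(list(u1 = function(s1, s2) rep_len(u1, length(s1)),
                 u2 = function(s1, s2) rep_len(u2, length(s1)),
                 diffusion = diffusion),
            class = "stps_flow")
}

#' Default initial plume
#'
#' Gaussian blob of peak concentration `peak` centred at `centre`.
#'
#' @param centre blob centre (unit-square coordinates).
#' @param sd spatial standard deviation.
#' @param peak peak concentration (e.g. micrograms per litre).
#' @return vectorized function `f(s1, s2)`.
#' @export
gaussian_plume_init <- function(centre = c(0.72, 0.28), sd = 0.06, peak = 1000) {
  function(s1, s2) peak * exp(-((s1 - centre[1])^2 + (s2 - centre[2])^2) /
                                (2 * sd^2))
}

#' Solve the advection-diffusion equation for a solute plume
#'
#' Finite-difference solution of
#' `dy/dt = D (d2y/ds1^2 + d2y/ds2^2) - u1 dy/ds1 - u2 dy/ds2`
#' on the unit square with zero-flux boundaries: conservative central
#' differences for diffusion, first-order upwinding for advection, and
#' explicit time stepping with automatic sub-stepping to satisfy the
#' stability (CFL) bound. `u = (u1, u2)` is the drift velocity of the plume;
#' written with advection coefficients `psi = -u` this is the usual
#' `+ psi . grad y` form of the transport equation.
#'
#' @param flow an `"stps_flow"` (default [plume_flow()]).
#' @param init initial concentration: a vectorized function `f(s1, s2)` or a
#'   matrix of values on the spatial grid.
#' @param grid output grid sizes `c(n_s1, n_s2, n_t)` (default
#'   `c(100, 100, 100)`).
#' @param t_span time interval (default `c(0, 1)`).
#' @param safety CFL safety factor in (0, 1].
#' @param max_substeps refuse configurations needing more internal sub-steps
#'   per output step than this.
#' @return object of class `"stps_plume"`: list with grid vectors `s1`, `s2`,
#'   `t`, the `values` array (`n_s1 x n_s2 x n_t`, non-negative), the `flow`,
#'   and solver metadata.
#' @export
solve_plume <- function(flow = plume_flow(), init = gaussian_plume_init(),
                        grid = c(100L, 100L, 100L), t_span = c(0, 1),
                        safety = 0.5, max_substeps = 20000L) {
  stopifnot(inherits(flow, "stps_flow"), length(grid) == 3L,
            all(grid >= 2L), t_span[2] > t_span[1])
  ns1 <- grid[1]; ns2 <- grid[2]; nt <- grid[3]
  s1 <- seq(0, 1, length.out = ns1); s2 <- seq(0, 1, length.out = ns2)
  tt <- seq(t_span[1], t_span[2], length.out = nt)
  h1 <- s1[2] - s1[1]; h2 <- s2[2] - s2[1]
  S1 <- matrix(s1, ns1, ns2); S2 <- matrix(s2, ns1, ns2, byrow = TRUE)
  U1 <- matrix(flow$u1(as.vector(S1), as.vector(S2)), ns1, ns2)
  U2 <- matrix(flow$u2(as.vector(S1), as.vector(S2)), ns1, ns2)
  if (!all(is.finite(U1)) || !all(is.finite(U2)))
    stop("flow velocities are not finite on the grid")
  D <- flow$diffusion
  Y <- if (is.function(init)) {
    matrix(init(as.vector(S1), as.vector(S2)), ns1, ns2)
  } else {
    stopifnot(identical(dim(init), c(ns1, ns2)))
    init
  }
  if (any(Y < 0)) stop("initial concentrations must be non-negative")
  dt_out <- tt[2] - tt[1]
  dt_diff <- if (D > 0) 1 / (2 * D * (1 / h1^2 + 1 / h2^2)) else Inf
  dt_adv <- min(
    if (max(abs(U1)) > 0) h1 / max(abs(U1)) else Inf,
    if (max(abs(U2)) > 0) h2 / max(abs(U2)) else Inf)
  dt_stable <- safety * min(dt_diff, dt_adv)
  substeps <- ceiling(dt_out / dt_stable)
  if (substeps > max_substeps)
    stop("stability requires ", substeps, " sub-steps per output step ",
         "(internal step <= ", signif(dt_stable, 3),
         "); coarsen the grid or reduce velocities/diffusion")
  dt <- dt_out / substeps
  up1p <- pmax(U1, 0); up1m <- pmin(U1, 0)
  up2p <- pmax(U2, 0); up2m <- pmin(U2, 0)
  vals <- array(0, dim = c(ns1, ns2, nt))
  vals[, , 1] <- Y
  for (k in 2:nt) {
    for (ss in seq_len(substeps)) {
      # zero-flux (reflected-ghost) Laplacian, conservative
      lap <- (Y[c(2:ns1, ns1), ] - 2 * Y + Y[c(1, 1:(ns1 - 1)), ]) / h1^2 +
        (Y[, c(2:ns2, ns2)] - 2 * Y + Y[, c(1, 1:(ns2 - 1))]) / h2^2
      # upwind one-sided gradients (edge-replicated ghosts)
      gb1 <- (Y - Y[c(1, 1:(ns1 - 1)), ]) / h1
      gf1 <- (Y[c(2:ns1, ns1), ] - Y) / h1
      gb2 <- (Y - Y[, c(1, 1:(ns2 - 1))]) / h2
      gf2 <- (Y[, c(2:ns2, ns2)] - Y) / h2
      adv <- up1p * gb1 + up1m * gf1 + up2p * gb2 + up2m * gf2
      Y <- Y + dt * (D * lap - adv)
    }
    vals[, , k] <- Y
  }
  vals[vals < 0] <- 0
  structure(list(s1 = s1, s2 = s2, t = tt, values = vals, flow = flow,
                 meta = list(substeps = substeps, dt = dt, safety = safety)),
            class = "stps_plume")
}

# Trilinear interpolation of the truth array at arbitrary points.
interp_plume <- function(truth, s1, s2, t) {
  stopifnot(inherits(truth, "stps_plume"))
  gi <- function(g, x) {
    i <- findInterval(x, g, rightmost.closed = TRUE, all.inside = TRUE)
    w <- (x - g[i]) / (g[i + 1] - g[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  a <- gi(truth$s1, s1); b <- gi(truth$s2, s2); d <- gi(truth$t, t)
  v <- truth$values
  idx <- function(i, j, k) v[cbind(i, j, k)]
  (1 - a$w) * ((1 - b$w) * ((1 - d$w) * idx(a$i, b$i, d$i) +
                              d$w * idx(a$i, b$i, d$i + 1)) +
                 b$w * ((1 - d$w) * idx(a$i, b$i + 1, d$i) +
                          d$w * idx(a$i, b$i + 1, d$i + 1))) +
    a$w * ((1 - b$w) * ((1 - d$w) * idx(a$i + 1, b$i, d$i) +
                          d$w * idx(a$i + 1, b$i, d$i + 1)) +
             b$w * ((1 - d$w) * idx(a$i + 1, b$i + 1, d$i) +
                      d$w * idx(a$i + 1, b$i + 1, d$i + 1)))
}

#' Monitoring designs for the simulation study
#'
#' Three sampling scenarios over the unit square and unit time interval:
#' \describe{
#'   \item{1}{29 wells (two spatial clusters plus scattered singletons,
#'     emulating a real monitoring network) sampled densely and irregularly in
#'     time; 1402 observations.}
#'   \item{2}{280 randomly placed wells sampled about five times each; 1402
#'     observations.}
#'   \item{3}{the same kind of 29-well network but only 100 observations, each
#'     well sampled about 3-4 times.}
#' }
#'
#' @param scenario 1, 2 or 3.
#' @param seed integer seed; the design (well positions, sampling times) is a
#'   deterministic function of it.
#' @return object of class `"stps_scenario"`: data frame with columns `well`,
#'   `s1`, `s2`, `t` plus attributes `scenario` and `wells`.
#' @export
plume_scenario <- function(scenario = 1L, seed = 1L) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop("'scenario' must be 1, 2 or 3")
  set.seed(seed)
  clamp <- function(x, lo = 0.05, hi = 0.95) pmin(pmax(x, lo), hi)
  if (scenario %in% c(1L, 3L)) {
    # monitoring-network geometry: a dense cluster around the source area,
    # a second cluster mid-gradient, and a ring of sentinel/compliance wells
    # around the site perimeter. The hull covers nearly the whole domain
    # while large parts of its interior (under site infrastructure, say)
    # carry no wells at all.
    ring <- cbind(c(0.08, 0.08, 0.92, 0.92, 0.50, 0.06, 0.50, 0.94),
                  c(0.08, 0.92, 0.92, 0.08, 0.06, 0.50, 0.94, 0.50))
    wells <- data.frame(
      s1 = clamp(c(stats::rnorm(12, 0.70, 0.05), stats::rnorm(9, 0.55, 0.05),
                   ring[, 1] + stats::runif(8, -0.03, 0.03))),
      s2 = clamp(c(stats::rnorm(12, 0.30, 0.05), stats::rnorm(9, 0.48, 0.05),
                   ring[, 2] + stats::runif(8, -0.03, 0.03))))
    n_obs <- if (scenario == 1L) 1402L else 100L
  } else {
    wells <- data.frame(s1 = stats::runif(280, 0.05, 0.95),
                        s2 = stats::runif(280, 0.05, 0.95))
    n_obs <- 1402L
  }
  nw <- nrow(wells)
  wells$well <- sprintf("W%03d", seq_len(nw))
  base <- n_obs %/% nw
  counts <- rep(base, nw)
  extra <- n_obs - base * nw
  if (extra > 0) {
    add <- sample.int(nw, extra)
    counts[add] <- counts[add] + 1L
  }
  idx <- rep(seq_len(nw), counts)
  # wells are installed and decommissioned at different times: each covers a
  # contiguous sub-window of the study period, sampled irregularly within it.
  # Perimeter/compliance wells (the last 8 in scenarios 1 and 3) keep records
  # over the whole period.
  win_len <- stats::runif(nw, 0.5, 1)
  if (scenario %in% c(1L, 3L)) win_len[(nw - 7L):nw] <- 1
  win_start <- stats::runif(nw, 0, 1 - win_len)
  tms <- unlist(lapply(seq_len(nw), function(w) {
    sort(stats::runif(counts[w], win_start[w], win_start[w] + win_len[w]))
  }), use.names = FALSE)
  out <- data.frame(well = wells$well[idx], s1 = wells$s1[idx],
                    s2 = wells$s2[idx], t = tms)
  structure(out, scenario = scenario, wells = wells, seed = seed,
            class = c("stps_scenario", "data.frame"))
}

#' Measurement-noise model
#'
#' Multiplicative noise specified on the log scale: the total log-scale noise
#' standard deviation is `sd(log signal) / snr`, split into an exchangeable
#' well-level effect (variance fraction `rho`, the within-well correlation)
#' and independent measurement error; between-well correlation is zero.
#'
#' @param snr log-scale signal-to-noise ratio (default 10; `Inf` = noise-free).
#' @param rho within-well correlation, in `[0, 1)` (default 0.05).
#' @return list of class `"stps_noise"`.
#' @export
noise_model <- function(snr = 10, rho = 0.05) {
  stopifnot(snr > 0, rho >= 0, rho < 1)
  structure(list(snr = snr, rho = rho), class = "stps_noise")
}

#' Sample noisy monitoring observations from a simulated plume
#'
#' Interpolates the plume truth at the scenario's well locations and sampling
#' times, then perturbs on the log scale with the noise model: with
#' `g = log(signal + 1)`, the observation is
#' `conc = max(exp(g + b_well + e) - 1, 0)` where `b_well` is a shared
#' Gaussian well effect and `e` independent Gaussian error. The returned data
#' frame is ready for [stps()].
#'
#' @param truth an `"stps_plume"` from [solve_plume()].
#' @param scenario an `"stps_scenario"` from [plume_scenario()].
#' @param noise a [noise_model()].
#' @param seed integer seed for the noise draws.
#' @return data frame `well, s1, s2, t, conc` with attributes `signal` (the
#'   noise-free interpolated truth) and `log_noise_sd`.
#' @export
sample_plume <- function(truth, scenario, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(truth, "stps_plume"),
            inherits(scenario, "stps_scenario"))
  if (any(scenario$s1 < min(truth$s1) | scenario$s1 > max(truth$s1) |
            scenario$s2 < min(truth$s2) | scenario$s2 > max(truth$s2)))
    stop("scenario wells fall outside the simulated domain")
  set.seed(seed)
  sig <- interp_plume(truth, scenario$s1, scenario$s2, scenario$t)
  g <- log(sig + 1)
  sd_tot <- if (is.finite(noise$snr)) stats::sd(g) / noise$snr else 0
  uw <- unique(scenario$well)
  bw <- stats::rnorm(length(uw), 0, sd_tot * sqrt(noise$rho))
  eta <- bw[match(scenario$well, uw)] +
    stats::rnorm(nrow(scenario), 0, sd_tot * sqrt(1 - noise$rho))
  conc <- pmax(exp(g + eta) - 1, 0)
  out <- data.frame(well = scenario$well, s1 = scenario$s1,
                    s2 = scenario$s2, t = scenario$t, conc = conc)
  attr(out, "signal") <- sig
  attr(out, "log_noise_sd") <- sd_tot
  out
}
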