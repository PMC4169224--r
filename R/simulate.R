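#' Simulation settings
#'
#' @param method `"direct"` (Gillespie direct method, one reaction per
#'   event), `"tauleap"` (explicit tau-leap, Poisson firing counts per fixed
#'   interval) or `"ode"` (deterministic reference integration).
#' @param tau leap interval in time units (tau-leap only; > 0).
#' @param t_end end time (> 0).
#' @param record_dt output grid spacing (> 0); states are recorded at
#'   `0, record_dt, ..., t_end`.
#' @param seed integer RNG seed. Replicate `i` of an ensemble uses
#'   `seed + i - 1`, so replicate 1 reproduces a single run at `seed`.
#' @param replicates number of ensemble replicates (>= 1).
#' @param omega system-size factor Omega, particles per concentration unit.
#'   Half-saturation constants are rescaled by Omega inside the propensity
#'   kernel; the published scaling convention corresponds to `omega = 5`.
#' @return list of class `ad_config`.
#' @export
sim_config <- function(method = c("direct", "tauleap", "ode"),
                       tau = 0.4, t_end = 20, record_dt = 0.5,
                       seed = 1L, replicates = 1L, omega = 1) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("direct", "tauleap", "ode")) {
    stop("unknown method '", method, "' (use direct, tauleap or ode)",
         call. = FALSE)
  }
  method <- match.arg(method)
  stopifnot(t_end > 0, record_dt > 0, replicates >= 1, omega > 0)
  if (method == "tauleap" && (!is.numeric(tau) || tau <= 0)) {
    stop("tau must be > 0 for the tau-leap method", call. = FALSE)
  }
  structure(list(method = method, tau = tau, t_end = t_end,
                 record_dt = record_dt, seed = as.integer(seed),
                 replicates = as.integer(replicates), omega = omega),
            class = "ad_config")
}

#' One event of the Gillespie direct method
#'
#' Draws the waiting time to the next reaction event, exponential with rate
#' `a0`, and the reaction index, categorical with probabilities `a_j/a0` by
#' cumulative-sum inversion (first index whose cumulative probability
#' exceeds a uniform draw). Consumes exactly one exponential and one uniform
#' variate from the current RNG stream, in that order.
#'
#' @param a numeric vector of per-reaction propensities (the total must be
#'   positive; a zero total means the system is exhausted and the caller
#'   should idle to the end time).
#' @return list with `waiting_time` and `reaction_index`.
#' @export
direct_step <- function(a) {
  a0 <- sum(a)
  if (a0 <= 0) stop("a0 = 0: system exhausted, no event to draw", call. = FALSE)
  wt <- stats::rexp(1L, rate = a0)
  u <- stats::runif(1L)
  j <- which(cumsum(a) / a0 > u)[1L]
  if (is.na(j)) j <- length(a)  # guard against u == 1 rounding
  list(waiting_time = wt, reaction_index = j)
}

#' One interval of the explicit tau-leap method
#'
#' Fires each reaction \eqn{k_j \sim Poisson(a_j \tau)} times independently
#' and applies the net update \eqn{\sum_j k_j \nu_j}. If the update would
#' drive a species negative, the firing counts of the reactions consuming
#' it are scaled down so the species lands exactly at zero; the incident is
#' counted. This clamps populations at zero while keeping total mass exactly
#' conserved (the update remains a combination of zero-sum columns).
#'
#' @param state named numeric vector of particle counts.
#' @param net an `ad_network`.
#' @param a per-reaction propensities at `state`.
#' @param tau leap interval (> 0).
#' @return list with `state` (updated), `k` (realised firing counts after
#'   any clamp scaling) and `clamps` (number of clamp incidents).
#' @export
tau_leap_step <- function(state, net, a, tau) {
  stopifnot(tau > 0)
  k <- stats::rpois(length(a), a * tau)
  res <- apply_firings(as.numeric(state[net$species$name]), net$stoich, k)
  list(state = stats::setNames(res$x, net$species$name), k = res$k,
       clamps = res$clamps)
}

# Apply k firings of each column of nu to x; where a species would go
# negative, scale down the firing counts of the reactions consuming it so it
# lands exactly at 0 (partial final firing), counting each incident. Scaling
# only ever reduces k, so the fixed-point loop terminates.
apply_firings <- function(x, nu, k, tol = 1e-9) {
  clamps <- 0L
  for (pass in seq_len(2L * length(x))) {
    xn <- x + as.numeric(nu %*% k)
    neg <- which(xn < -tol)
    if (!length(neg)) break
    s <- neg[which.min(xn[neg])]
    cons <- which(nu[s, ] < 0 & k > 0)
    if (!length(cons)) break
    consumed <- -sum(nu[s, cons] * k[cons])
    produced <- sum(nu[s, ] * k) + consumed
    avail <- x[s] + produced
    scale <- max(min(avail / consumed, 1), 0)
    k[cons] <- k[cons] * scale
    clamps <- clamps + 1L
  }
  xn <- x + as.numeric(nu %*% k)
  xn[xn < 0 & xn > -tol] <- 0
  list(x = xn, k = k, clamps = clamps)
}

#' Run one simulation
#'
#' Simulates the network from `t = 0` to `cfg$t_end` with the configured
#' engine, recording the state on the regular output grid. The direct and
#' tau-leap methods record the last state at or before each grid time
#' (states are piecewise constant between events/leaps); when all
#' propensities vanish before the end time the system is absorbed and the
#' final state is repeated. The ODE method integrates the shared rate
#' kernel with `lsoda` at relative tolerance 1e-8.
#'
#' Identical `(net, init, cfg)` including the seed reproduce the identical
#' trajectory. Per event the direct method draws one exponential then one
#' uniform; per leap the tau-leap method draws the Poisson counts in
#' reaction order.
#'
#' @param net an `ad_network`.
#' @param init named numeric vector of initial particle counts (>= 0),
#'   covering all network species (missing species default to 0).
#' @param cfg an [sim_config()].
#' @return object of class `ad_trajectory`: `times`, `state` (time x
#'   species matrix), `events` (cumulative per-reaction firing totals),
#'   `clamps` (clamp incident count), `method`, `cfg` and the network name.
#' @examples
#' net <- build_ad_network()
#' init <- ad_initial_state(omega = 1)
#' tr <- simulate_network(net, init, sim_config("direct", t_end = 5, seed = 1))
#' tr
#' @export
simulate_network <- function(net, init, cfg) {
  stopifnot(inherits(net, "ad_network"), inherits(cfg, "ad_config"))
  sp <- net$species$name
  x0 <- stats::setNames(numeric(length(sp)), sp)
  unknown <- setdiff(names(init), sp)
  if (length(unknown)) {
    stop("init has unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x0[names(init)] <- init
  if (any(x0 < 0)) stop("initial state must be >= 0", call. = FALSE)
  times <- seq(0, cfg$t_end, by = cfg$record_dt)
  k <- compile_kinetics(net)
  res <- switch(cfg$method,
    direct = run_direct(k, as.numeric(x0), times, cfg),
    tauleap = run_tauleap(k, as.numeric(x0), times, cfg),
    ode = run_ode(net, k, x0, times, cfg))
  dimnames(res$state) <- list(NULL, sp)
  structure(list(times = times, state = res$state,
                 events = stats::setNames(res$events, k$rnames),
                 clamps = res$clamps, method = cfg$method, cfg = cfg,
                 network = net$name),
            class = "ad_trajectory")
}

run_direct <- function(k, x, times, cfg) {
  set.seed(cfg$seed)
  nu <- k$nu
  out <- matrix(NA_real_, nrow = length(times), ncol = length(x))
  events <- numeric(length(k$rnames))
  t <- 0
  gi <- 1L
  repeat {
    a <- eval_propensities(k, x, cfg$omega)
    a0 <- sum(a)
    if (a0 <= 0) break                      # absorbed: idle to t_end
    dt <- stats::rexp(1L, rate = a0)
    u <- stats::runif(1L)
    t_new <- t + dt
    while (gi <= length(times) && times[gi] < t_new) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
    if (gi > length(times)) break
    j <- which(cumsum(a) / a0 > u)[1L]
    if (is.na(j)) j <- length(a)
    x <- x + nu[, j]
    x[x < 0 & x > -1e-12] <- 0
    events[j] <- events[j] + 1
    t <- t_new
  }
  while (gi <= length(times)) { out[gi, ] <- x; gi <- gi + 1L }
  list(state = out, events = events, clamps = 0L)
}

run_tauleap <- function(k, x, times, cfg) {
  set.seed(cfg$seed)
  nu <- k$nu
  out <- matrix(NA_real_, nrow = length(times), ncol = length(x))
  events <- numeric(length(k$rnames))
  clamps <- 0L
  t <- 0
  gi <- 1L
  nsteps <- ceiling(cfg$t_end / cfg$tau - 1e-9)
  for (step in seq_len(nsteps)) {
    a <- eval_propensities(k, x, cfg$omega)
    t_new <- min(t + cfg$tau, cfg$t_end)
    while (gi <= length(times) && times[gi] < t_new - 1e-12) {
      out[gi, ] <- x
      gi <- gi + 1L
    }
    if (sum(a) > 0) {
      kj <- stats::rpois(length(a), a * cfg$tau)
      res <- apply_firings(x, nu, kj)
      x <- res$x
      events <- events + res$k
      clamps <- clamps + res$clamps
    }
    t <- t_new
  }
  while (gi <= length(times)) { out[gi, ] <- x; gi <- gi + 1L }
  list(state = out, events = events, clamps = clamps)
}

run_ode <- function(net, k, x0, times, cfg) {
  rhs <- function(t, y, parms) {
    list(as.numeric(k$nu %*% eval_propensities(k, y, cfg$omega)))
  }
  sol <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  if (attr(sol, "istate")[1L] < 0) {
    stop("ODE integration failed (lsoda istate ",
         attr(sol, "istate")[1L], ")", call. = FALSE)
  }
  state <- unname(as.matrix(sol[, -1, drop = FALSE]))
  state[state < 0 & state > -1e-8] <- 0
  list(state = state, events = numeric(length(k$rnames)), clamps = 0L)
}

#' Deterministic reference integration
#'
#' Convenience wrapper running [simulate_network()] with `method = "ode"`.
#'
#' @inheritParams simulate_network
#' @return an `ad_trajectory` (events and clamps are zero).
#' @export
integrate_ode <- function(net, init, cfg) {
  cfg$method <- "ode"
  simulate_network(net, init, cfg)
}

#' Simulate an ensemble of replicates
#'
#' Runs `cfg$replicates` independent stochastic replicates, replicate `i`
#' seeded with `cfg$seed + i - 1`, and summarises the per-time, per-species
#' mean and variance (sample variance; 0 when `replicates = 1`).
#'
#' @inheritParams simulate_network
#' @return object of class `ad_ensemble`: `times`, `mean` and `variance`
#'   (time x species matrices), `n`, total `clamps` across replicates,
#'   summed `events`, `method` and `cfg`.
#' @export
simulate_ensemble <- function(net, init, cfg) {
  stopifnot(inherits(cfg, "ad_config"))
  if (cfg$method == "ode") {
    stop("ensembles are for the stochastic methods; use integrate_ode()",
         call. = FALSE)
  }
  n <- cfg$replicates
  s1 <- s2 <- NULL
  clamps <- 0L
  events <- NULL
  times <- NULL
  for (i in seq_len(n)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    cfg_i$replicates <- 1L
    tr <- simulate_network(net, init, cfg_i)
    if (is.null(s1)) {
      s1 <- tr$state * 0
      s2 <- tr$state * 0
      events <- tr$events * 0
      times <- tr$times
    }
    s1 <- s1 + tr$state
    s2 <- s2 + tr$state^2
    events <- events + tr$events
    clamps <- clamps + tr$clamps
  }
  m <- s1 / n
  v <- if (n > 1) pmax(s2 - n * m^2, 0) / (n - 1) else s2 * 0
  structure(list(times = times, mean = m, variance = v, n = n,
                 clamps = clamps, events = events,
                 method = cfg$method, cfg = cfg),
            class = "ad_ensemble")
}

#' Default initial state of the digestion network
#'
#' The documented convention for the shipped network: glucose 500 and each
#' degrader population 100 in concentration units, all intermediates and
#' methane 0, scaled by the system-size factor (so `omega = 5` gives 2500
#' glucose particles). The published model does not print its initial
#' conditions; this convention is chosen from the kinetic constants' own
#' scale (glucose starts at its half-saturation value).
#'
#' @param omega system-size factor.
#' @return named numeric vector over the 11 default species.
#' @export
ad_initial_state <- function(omega = 1) {
  conc <- c(glucose = 500, butyrate = 0, propionate = 0, acetate = 0,
            hydrogen = 0, methane = 0, sugar_degraders = 100,
            butyrate_degraders = 100, propionate_degraders = 100,
            acetate_degraders = 100, hydrogen_degraders = 100)
  concentration_to_particles(conc, omega)
}

#' @rdname simulate_network
#' @param object an `ad_network` (S3 method for [stats::simulate()]).
#' @param nsim number of replicates (overrides `cfg$replicates`).
#' @param seed optional seed (overrides `cfg$seed`).
#' @param init,cfg passed to [simulate_network()] / [simulate_ensemble()].
#' @param ... unused.
#' @export
simulate.ad_network <- function(object, nsim = 1, seed = NULL,
                                init = ad_initial_state(cfg$omega),
                                cfg = sim_config(), ...) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$replicates <- as.integer(nsim)
  if (nsim == 1L) simulate_network(object, init, cfg)
  else simulate_ensemble(object, init, cfg)
}

#' @export
print.ad_trajectory <- function(x, ...) {
  cat(sprintf("<ad_trajectory> %s method, %d grid points over [0, %g], network '%s'\n",
              x$method, length(x$times), max(x$times), x$network))
  cat(sprintf("  total firings %.6g, clamp incidents %d\n",
              sum(x$events), x$clamps))
  final <- x$state[nrow(x$state), ]
  cat("  final state:\n")
  print(round(final, 3))
  invisible(x)
}

#' @export
print.ad_ensemble <- function(x, ...) {
  cat(sprintf("<ad_ensemble> %d replicates, %s method, %d grid points over [0, %g]\n",
              x$n, x$method, length(x$times), max(x$times)))
  cat(sprintf("  clamp incidents (all replicates): %d\n", x$clamps))
  cat("  final mean state:\n")
  print(round(x$mean[nrow(x$mean), ], 3))
  invisible(x)
}

#' @export
summary.ad_trajectory <- function(object, ...) {
  rng <- apply(object$state, 2, range)
  df <- data.frame(species = colnames(object$state),
                   initial = object$state[1, ],
                   final = object$state[nrow(object$state), ],
                   min = rng[1, ], max = rng[2, ], row.names = NULL)
  cat(sprintf("Trajectory (%s), t in [0, %g], clamps %d\n",
              object$method, max(object$times), object$clamps))
  print(df, row.names = FALSE)
  invisible(df)
}

#' Plot a trajectory or ensemble mean
#'
#' Line plot of species trajectories over time (convenience only).
#'
#' @param x an `ad_trajectory` or `ad_ensemble`.
#' @param species character vector of species to draw (default all).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ad_trajectory <- function(x, species = colnames(x$state), ...) {
  y <- x$state[, species, drop = FALSE]
  graphics::matplot(x$times, y, type = "l", lty = 1,
                    col = grDevices::rainbow(ncol(y)),
                    xlab = "time (d)", ylab = "particle count", ...)
  graphics::legend("topright", legend = species, lty = 1, cex = 0.7,
                   col = grDevices::rainbow(ncol(y)))
  invisible(x)
}

#' @rdname plot.ad_trajectory
#' @export
plot.ad_ensemble <- function(x, species = colnames(x$mean), ...) {
  y <- x$mean[, species, drop = FALSE]
  graphics::matplot(x$times, y, type = "l", lty = 1,
                    col = grDevices::rainbow(ncol(y)),
                    xlab = "time (d)", ylab = "mean particle count", ...)
  graphics::legend("topright", legend = species, lty = 1, cex = 0.7,
                   col = grDevices::rainbow(ncol(y)))
  invisible(x)
}
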