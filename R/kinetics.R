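#' Monod propensity of a single reaction
#'
#' The rate of substrate-uptake events for one reaction:
#' \deqn{a = \mu_{max} \frac{S}{K\Omega + S} X}
#' with `S` the substrate particle count, `X` the degrader count and the
#' half-saturation constant rescaled to the particle axis. One event
#' consumes one substrate particle. Linear-kinetics reactions return
#' `mu_max * S`. Negative state entries are clamped to 0 inside the kernel
#' so the kernel stays usable by ODE integrators near depletion.
#'
#' @param reaction an [reaction()] object.
#' @param state named numeric vector of particle counts.
#' @param omega system-size factor used to rescale `K` (default 1).
#' @return a single non-negative rate (events per unit time).
#' @export
monod_propensity <- function(reaction, state, omega = 1) {
  S <- state_count(state, reaction$substrate)
  if (identical(reaction$kinetics, "linear")) {
    return(reaction$mu_max * S)
  }
  if (is.na(reaction$degrader)) {
    stop("monod reaction '", reaction$name, "' has no degrader", call. = FALSE)
  }
  X <- state_count(state, reaction$degrader)
  reaction$mu_max * S / (reaction$K * omega + S) * X
}

state_count <- function(state, species) {
  if (!species %in% names(state)) {
    stop("species '", species, "' not present in state", call. = FALSE)
  }
  max(state[[species]], 0)
}

#' Dual-substrate Monod propensity
#'
#' Multiplies the base Monod rate by a second saturation factor
#' \eqn{S_2/(K_2\Omega + S_2)}, the form used for hydrogenotrophic
#' methanogens when carbon dioxide limitation is modelled. Off by default in
#' the shipped network because CO2 is not a tracked species; available when
#' the user adds one.
#'
#' @inheritParams monod_propensity
#' @param second_substrate species name of the co-substrate.
#' @param K2 half-saturation constant of the co-substrate (> 0,
#'   concentration units).
#' @return a single non-negative rate.
#' @export
dual_monod_propensity <- function(reaction, state, second_substrate, K2,
                                  omega = 1) {
  if (!is.numeric(K2) || K2 <= 0) stop("K2 must be > 0", call. = FALSE)
  S2 <- state_count(state, second_substrate)
  monod_propensity(reaction, state, omega) * S2 / (K2 * omega + S2)
}

#' Non-competitive inhibition factor
#'
#' Returns \eqn{K_I\Omega / (K_I\Omega + I)} where `I` is the inhibitor
#' count: 1 with no inhibitor, 1/2 at the half-inhibition point, tending to
#' 0 as the inhibitor accumulates. Multiplies the base propensity when a
#' reaction carries an `inhibition` spec (hydrogen or free-ammonia
#' inhibition in digestion models; constants are system-specific and must
#' be supplied by the user).
#'
#' @param inh list with elements `inhibitor` (species name) and `K_I` (> 0).
#' @param state named numeric vector of particle counts.
#' @param omega system-size factor (default 1).
#' @return a factor in (0, 1].
#' @export
noncompetitive_factor <- function(inh, state, omega = 1) {
  if (!is.numeric(inh$K_I) || inh$K_I <= 0) {
    stop("inhibition constant K_I must be > 0", call. = FALSE)
  }
  I <- state_count(state, inh$inhibitor)
  KI <- inh$K_I * omega
  KI / (KI + I)
}

#' Propensity vector of a network
#'
#' Evaluates every reaction's rate at the given state: the base Monod (or
#' linear) rate times any configured inhibition and dual-substrate factors.
#'
#' @param net an `ad_network`.
#' @param state named numeric vector of particle counts (all network species).
#' @param omega system-size factor (default 1).
#' @return list with `a` (named per-reaction rates) and `a0` (their sum).
#' @export
propensity_vector <- function(net, state, omega = 1) {
  k <- compile_kinetics(net)
  x <- as.numeric(state[net$species$name])
  if (anyNA(x)) stop("state is missing species required by the network",
                     call. = FALSE)
  a <- eval_propensities(k, x, omega)
  names(a) <- k$rnames
  list(a = a, a0 = sum(a))
}

# Precompute index/parameter arrays so the simulation inner loops run on
# plain vectors. State vectors are addressed positionally in species order.
compile_kinetics <- function(net) {
  rx <- net$reactions
  sp <- net$species$name
  idx <- function(nm) if (is.null(nm) || is.na(nm)) 0L else match(nm, sp)
  list(
    rnames = vapply(rx, `[[`, "", "name"),
    sub = vapply(rx, function(r) idx(r$substrate), 0L),
    deg = vapply(rx, function(r) idx(r$degrader), 0L),
    mu = vapply(rx, `[[`, 0, "mu_max"),
    K = vapply(rx, `[[`, 0, "K"),
    linear = vapply(rx, function(r) identical(r$kinetics, "linear"), TRUE),
    inh = vapply(rx, function(r) idx(r$inhibition$inhibitor), 0L),
    KI = vapply(rx, function(r) if (is.null(r$inhibition)) NA_real_
                else r$inhibition$K_I, 0),
    sub2 = vapply(rx, function(r) idx(r$second_substrate$name), 0L),
    K2 = vapply(rx, function(r) if (is.null(r$second_substrate)) NA_real_
                else r$second_substrate$K2, 0),
    nu = net$stoich)
}

eval_propensities <- function(k, x, omega) {
  x <- pmax(x, 0)
  S <- x[k$sub]
  a <- ifelse(k$linear, k$mu * S,
              k$mu * S / (k$K * omega + S) * x[pmax(k$deg, 1L)])
  a[!k$linear & k$deg == 0L] <- 0   # monod without degrader: undefined, rate 0
  has_inh <- k$inh > 0L
  if (any(has_inh)) {
    KI <- k$KI * omega
    f <- ifelse(has_inh, KI / (KI + x[pmax(k$inh, 1L)]), 1)
    a <- a * f
  }
  has2 <- k$sub2 > 0L
  if (any(has2)) {
    K2 <- k$K2 * omega
    f2 <- ifelse(has2, x[pmax(k$sub2, 1L)] / (K2 + x[pmax(k$sub2, 1L)]), 1)
    a <- a * f2
  }
  a[!is.finite(a) | a < 0] <- 0
  a
}

#' Deterministic rate of change (ODE right-hand side)
#'
#' The mean-field twin of the stochastic model:
#' \eqn{dx/dt = \sum_j \nu_j a_j(x)}, sharing the propensity kernel and the
#' stoichiometry matrix with the simulators. Because every monod column of
#' the stoichiometry sums to zero, the derivatives sum to zero: total mass
#' is conserved.
#'
#' @inheritParams propensity_vector
#' @return named numeric vector of per-species derivatives.
#' @export
ode_rhs <- function(net, state, omega = 1) {
  k <- compile_kinetics(net)
  x <- as.numeric(state[net$species$name])
  a <- eval_propensities(k, x, omega)
  stats::setNames(as.numeric(k$nu %*% a), net$species$name)
}
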