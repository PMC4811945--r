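#' Boltzmann energy model
#'
#' Biases `b` and a symmetric zero-diagonal weight matrix `W` define the
#' second-order energy function
#' \deqn{E(x) = -\sum_k b_k x_k - \tfrac12 \sum_{k,l} x_k x_l w_{kl}}
#' whose Boltzmann distribution is the stationary distribution of a
#' symmetric spiking network over the same units.
#'
#' @param biases Numeric vector of biases.
#' @param weights Symmetric numeric matrix with zero diagonal (defaults to
#'   all-zero).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(biases, weights = NULL) {
  n <- length(biases)
  if (is.null(weights)) weights <- matrix(0, n, n)
  weights <- as.matrix(weights)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop("weight matrix must be symmetric")
  if (any(diag(weights) != 0)) stop("weight matrix must have zero diagonal")
  if (nrow(weights) != n) stop("dimension mismatch between biases and weights")
  structure(list(biases = as.numeric(biases), weights = weights),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> %d units, %d nonzero couplings\n",
              length(x$biases), sum(x$weights != 0) / 2))
  invisible(x)
}

#' Energy of a binary state
#' @param x Binary vector (same length as `model$biases`).
#' @param model An `energy_model`.
#' @return Numeric energy.
#' @export
energy <- function(x, model) {
  if (length(x) != length(model$biases)) stop("dimension mismatch")
  x <- as.numeric(x)
  -sum(model$biases * x) - 0.5 * drop(x %*% model$weights %*% x)
}

#' All binary states of n units
#'
#' @param n Number of units (<= 20).
#' @return A `2^n x n` 0/1 matrix; row order follows binary counting with
#'   unit 1 as the least significant bit.
#' @export
all_states <- function(n) {
  if (n > 20) stop("too many units to enumerate")
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

#' Exact Boltzmann distribution by enumeration
#'
#' @param model An `energy_model` with at most 20 units.
#' @return Named numeric vector of probabilities over all `2^n` states;
#'   names are state bitstrings (unit 1 first).
#' @export
boltzmann_exact <- function(model) {
  n <- length(model$biases)
  if (n > 20) stop("too many units to enumerate")
  S <- all_states(n)
  E <- apply(S, 1, energy, model = model)
  p <- exp(-(E - min(E)))
  p <- p / sum(p)
  names(p) <- apply(S, 1, paste, collapse = "")
  p
}

#' Rescale an energy model by a temperature
#'
#' Sampling at temperature `T` replaces `E(x)` by `E(x)/T`: biases and
#' weights are divided by `T`.  `T < 1` sharpens the distribution around its
#' modes, `T > 1` flattens it.
#'
#' @param model An `energy_model`.
#' @param T Positive temperature.
#' @return The rescaled `energy_model`.
#' @export
apply_temperature <- function(model, T) {
  if (T <= 0) stop("temperature must be positive")
  energy_model(model$biases / T, model$weights / T)
}

#' Membrane potential required by the neural computability condition
#'
#' The NCC requires neuron k's membrane potential to equal the log-odds
#' \eqn{\log p(x_k = 1 | x_{\setminus k}) / p(x_k = 0 | x_{\setminus k})},
#' i.e. the energy difference \eqn{E(x_k = 0, \cdot) - E(x_k = 1, \cdot)}.
#' For a second-order model this is \eqn{b_k + \sum_l w_{kl} x_l}.
#'
#' @param k Unit index.
#' @param x Binary state vector (value at position k is ignored).
#' @param model An `energy_model`.
#' @return Numeric membrane potential.
#' @export
ncc_membrane <- function(k, x, model) {
  x <- as.numeric(x)
  x[k] <- 0
  model$biases[k] + sum(model$weights[k, ] * x)
}

#' Mean state-change (event) rate of a spiking neuron
#'
#' A neuron at clamped membrane potential `u` waits on average
#' \eqn{m_{on} = \tau e^{-u}} in the off state and \eqn{m_{off} = \tau} in
#' the on state, giving event rate
#' \eqn{R(u) = 2/(m_{on}+m_{off}) = (2/\tau)\sigma(u)}: low for strongly
#' inhibited neurons and saturating at \eqn{2/\tau} for strongly driven ones.
#'
#' @param u Membrane potential.
#' @param tau PSP duration in seconds.
#' @return Event rate (on plus off transitions) per second.
#' @export
event_rate_spiking <- function(u, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  (2 / tau) * stats::plogis(u)
}

#' Mean event rate of a continuous-time Gibbs (Boltzmann machine) unit
#'
#' On-transitions occur at rate \eqn{\rho_0\sigma(u)} and off-transitions at
#' \eqn{\rho_0\sigma(-u)}, giving the symmetric event rate
#' \eqn{R^{sym}(u) = 2\rho_0/(2 + e^u + e^{-u})}, sharply peaked at
#' \eqn{u = 0}.
#'
#' @param u Membrane potential.
#' @param rho0 Positive speed constant of the sampler.
#' @return Event rate per time unit.
#' @export
event_rate_gibbs <- function(u, rho0 = 1) {
  if (any(rho0 <= 0)) stop("rho0 must be positive")
  2 * rho0 / (2 + exp(u) + exp(-u))
}

#' Ratio of spiking to Gibbs event rates
#'
#' \eqn{F(u) = R(u)/R^{sym}(u) = (1 + e^u)/(\tau\rho_0)}: strictly
#' increasing in `u`, so the spiking dynamics specifically accelerates state
#' changes of strongly driven units, which is what lets it cross high energy
#' barriers more often than Gibbs sampling.
#'
#' @inheritParams event_rate_spiking
#' @inheritParams event_rate_gibbs
#' @return Numeric ratio.
#' @export
rate_ratio <- function(u, tau, rho0 = 1) {
  if (any(tau <= 0) || any(rho0 <= 0)) stop("tau and rho0 must be positive")
  (1 + exp(u)) / (tau * rho0)
}

#' Marginal energy over principal units
#'
#' For a joint model over principal and auxiliary units, the energy of the
#' principal marginal is \eqn{-\log \sum_\xi \exp(-E(x, \xi))} up to an
#' additive constant; the table is shifted so its minimum is 0.
#'
#' @param model An `energy_model` over all units (<= 20).
#' @param principal Integer indices of the principal units.
#' @return Named numeric vector of marginal energies over all principal
#'   states (bitstring names).
#' @export
marginal_energy <- function(model, principal) {
  n <- length(model$biases)
  if (n > 20) stop("too many units to enumerate")
  p <- boltzmann_exact(model)
  S <- all_states(n)
  key <- apply(S[, principal, drop = FALSE], 1, paste, collapse = "")
  marg <- tapply(p, key, sum)
  Em <- -log(as.numeric(marg))
  Em <- Em - min(Em)
  # order as binary counting over principal units
  ord <- apply(all_states(length(principal)), 1, paste, collapse = "")
  setNames(Em[match(ord, names(marg))], ord)
}

#' Total-variation distance between two distributions over state bitstrings
#'
#' @param p,q Named numeric vectors (names are state bitstrings); missing
#'   states count as probability 0.
#' @return TV distance in `[0, 1]`.
#' @export
tv_distance <- function(p, q) {
  states <- union(names(p), names(q))
  pv <- ifelse(states %in% names(p), p[states], 0)
  qv <- ifelse(states %in% names(q), q[states], 0)
  0.5 * sum(abs(pv - qv))
}

#' Histogram of energy jumps along a trajectory
#'
#' Each state change of a unit in the model contributes the jump
#' \eqn{\Delta E = E(after) - E(before)} of the (principal) energy
#' function; state changes of neurons outside the model leave the energy
#' unchanged and are ignored.
#'
#' @param changes Data frame of state changes (`time`, `neuron`,
#'   `direction`), as returned by [state_change_times()] or
#'   [gibbs_state_changes()].
#' @param model An `energy_model`.
#' @param model_ids Neuron ids corresponding to model units 1..n (default
#'   `1:n`).
#' @param breaks Histogram bin edges (energy units); jumps outside the range
#'   are clamped into the outermost bins.
#' @return A `jump_histogram`: list with `breaks`, `counts`,
#'   `total_transitions` and the raw `jumps`.
#' @export
energy_jump_histogram <- function(changes, model,
                                  model_ids = seq_along(model$biases),
                                  breaks = seq(-40, 40, by = 1)) {
  idx <- match(changes$neuron, model_ids)
  de <- energy_jumps_cpp(ifelse(is.na(idx), -1L, idx - 1L),
                         as.integer(changes$direction),
                         model$biases, model$weights,
                         integer(length(model$biases)))
  de <- de[!is.na(de)]
  clamped <- pmin(pmax(de, breaks[1]), breaks[length(breaks)])
  counts <- if (length(clamped)) {
    tabulate(findInterval(clamped, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  } else integer(length(breaks) - 1)
  structure(list(breaks = breaks, counts = counts,
                 total_transitions = length(de), jumps = de),
            class = "jump_histogram")
}

#' @export
print.jump_histogram <- function(x, ...) {
  cat(sprintf("<jump_histogram> %d transitions, |dE| range [%.2f, %.2f]\n",
              x$total_transitions,
              if (x$total_transitions) min(x$jumps) else NA,
              if (x$total_transitions) max(x$jumps) else NA))
  invisible(x)
}

#' Export a jump histogram as CSV
#' @param hist A `jump_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  df <- data.frame(bin_left = hist$breaks[-length(hist$breaks)],
                   bin_right = hist$breaks[-1],
                   count = hist$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Transitions into states with undefined problem variables
#'
#' A WTA-encoded variable is undefined while its group has a number of
#' active members different from one.  For every state change this tallies
#' the number of undefined groups of the state entered.
#'
#' @param traj A `spike_trajectory` (or `gibbs_trajectory` with a network).
#' @param wta_groups Named list of neuron-id groups; defaults to the
#'   network's registered groups.
#' @return An `undefined_stats` object: `frequency[k]` is the fraction of
#'   transitions into states with exactly `k - 1` undefined groups (named
#'   "0", "1", ...), plus raw `counts` and `total_transitions`.
#' @export
undefined_variable_stats <- function(traj, wta_groups = NULL) {
  net <- traj$network
  if (is.null(wta_groups)) wta_groups <- net$wta_groups
  if (!length(wta_groups)) stop("no WTA groups defined")
  ch <- if (inherits(traj, "gibbs_trajectory")) gibbs_state_changes(traj)
        else state_change_times(traj)
  group_of <- rep(-1L, n_neurons(net))
  for (g in seq_along(wta_groups)) group_of[wta_groups[[g]]] <- g - 1L
  # initial actives appear as explicit time-0 on-changes, so the trace
  # starts from the all-off state
  k_undef <- undefined_groups_trace_cpp(
    as.integer(ch$neuron) - 1L, as.integer(ch$direction),
    group_of, length(wta_groups), integer(0))
  counts <- tabulate(k_undef + 1L, nbins = length(wta_groups) + 1L)
  structure(list(
    counts = counts,
    frequency = setNames(counts / max(1, length(k_undef)),
                         as.character(0:length(wta_groups))),
    total_transitions = length(k_undef)),
    class = "undefined_stats")
}
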