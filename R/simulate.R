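#' Instantaneous firing rate of a stochastic spiking neuron
#'
#' The neuron model fires with intensity \eqn{\exp(u)/\tau} at membrane
#' potential \eqn{u}, so that over its on/off cycle it realizes the
#' log-odds dynamics required for neural sampling.
#'
#' @param u Membrane potential (dimensionless log-intensity units).
#' @param tau PSP duration \eqn{\tau} in seconds (> 0).
#' @return Firing rate in events per second.
#' @export
firing_rate <- function(u, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  exp(u) / tau
}

#' Simulate a spiking network
#'
#' Exact event-driven simulation of the stochastic dynamics: between events
#' every membrane potential is constant, so the next spike is drawn from the
#' total exponential intensity and attributed to a neuron proportionally to
#' its rate (equivalent, by memorylessness, to redrawing every neuron's
#' candidate waiting time \eqn{\tau_k e^{-u_k} E} after each event).
#' Scheduled deterministic events are delayed PSP onsets, PSP offsets
#' (spike time + delay + PSP duration) and refractory expirations;
#' simultaneous events are committed in the order (time, offsets before
#' onsets, id).  A refractory neuron integrates its inputs but cannot spike.
#'
#' @param net A `neural_network`.
#' @param t_end Simulated duration in seconds (> 0).
#' @param seed Integer seed; the trajectory is reproducible from
#'   (network, t_end, seed, initial).
#' @param initial Optional integer vector of neurons active at time 0
#'   (realized as virtual spikes at \eqn{t = 0^-}, recorded at time 0).
#' @param max_state_changes Optional budget: simulation stops once the
#'   number of state changes (2 per spike) reaches this value.
#' @return A `spike_trajectory`: list with `events` (data frame of `time`,
#'   `neuron`), `t_end`, `seed`, `initial` and the originating `network`.
#' @export
simulate_network <- function(net, t_end, seed, initial = integer(0),
                             max_state_changes = Inf) {
  validate_network(net)
  if (t_end <= 0) stop("t_end must be positive")
  if (!all(initial %in% net$neurons$id)) stop("unknown neuron in initial set")
  max_spikes <- if (is.finite(max_state_changes)) {
    floor(max_state_changes / 2)
  } else Inf
  set.seed(as.integer(seed))
  res <- sim_spiking_cpp(
    bias = net$neurons$bias,
    tau = net$neurons$psp_duration,
    refractory = net$neurons$refractory,
    syn_pre = net$synapses$pre - 1L,
    syn_post = net$synapses$post - 1L,
    syn_w = net$synapses$weight,
    syn_delay = net$synapses$delay,
    syn_psp = net$synapses$psp_duration,
    t_end = t_end, max_spikes = max_spikes,
    initial_active = as.integer(initial) - 1L)
  truncated <- is.finite(max_spikes) && length(res$time) >= max_spikes
  structure(list(
    events = data.frame(time = res$time, neuron = res$neuron + 1L),
    t_end = if (truncated) res$t_last else t_end,
    seed = as.integer(seed),
    initial = as.integer(initial),
    network = net
  ), class = "spike_trajectory")
}

#' @export
print.spike_trajectory <- function(x, ...) {
  cat(sprintf("<spike_trajectory> %d spikes over %.3f s (%d neurons, seed %d)\n",
              nrow(x$events), x$t_end, n_neurons(x$network), x$seed))
  invisible(x)
}

#' Membrane potential of a neuron at a time point
#'
#' Bias plus the weighted sum of currently active presynaptic PSPs: a spike
#' of neuron l at time s contributes `w` to its target during
#' `(s + delay, s + delay + psp_duration]`.
#'
#' @param k Neuron id.
#' @param t Time in seconds (<= `traj$t_end`).
#' @param traj A `spike_trajectory`.
#' @return Membrane potential (numeric scalar).
#' @export
membrane_potential <- function(k, t, traj) {
  net <- traj$network
  if (!k %in% net$neurons$id) stop("unknown neuron id")
  if (t > traj$t_end) stop("t beyond trajectory end")
  u <- net$neurons$bias[k]
  syn <- net$synapses[net$synapses$post == k, , drop = FALSE]
  if (!nrow(syn)) return(u)
  ev <- traj$events
  for (i in seq_len(nrow(syn))) {
    s <- ev$time[ev$neuron == syn$pre[i]]
    active <- any(s + syn$delay[i] < t & t <= s + syn$delay[i] + syn$psp_duration[i])
    if (active) u <- u + syn$weight[i]
  }
  u
}

#' Binary network state at a time point
#'
#' `x[k] = 1` iff neuron k spiked within its own on-state window
#' `(t - psp_duration_k, t]`.
#'
#' @param traj A `spike_trajectory`.
#' @param t Time in `[0, t_end]`.
#' @param ids Neurons to read out (default all).
#' @return Named integer vector of 0/1 states.
#' @export
state_at <- function(traj, t, ids = traj$network$neurons$id) {
  if (t < 0 || t > traj$t_end) stop("t out of trajectory range")
  tau <- traj$network$neurons$psp_duration
  ev <- traj$events
  x <- integer(length(ids))
  for (j in seq_along(ids)) {
    k <- ids[j]
    s <- ev$time[ev$neuron == k]
    x[j] <- as.integer(any(t - tau[k] < s & s <= t))
  }
  names(x) <- ids
  x
}

#' State changes of a trajectory
#'
#' Every spike produces an on-entry at the spike time and an off-entry one
#' PSP duration (the neuron's own) later; this is the unit in which search
#' effort is compared across samplers.  Entries are ordered by
#' (time, off before on, neuron id).
#'
#' @param traj A `spike_trajectory`.
#' @return Data frame with columns `time`, `neuron`, `direction` (+1 on,
#'   -1 off).
#' @export
state_change_times <- function(traj) {
  ev <- traj$events
  if (!nrow(ev)) {
    return(data.frame(time = numeric(), neuron = integer(),
                      direction = integer()))
  }
  tau <- traj$network$neurons$psp_duration
  ch <- data.frame(
    time = c(ev$time, ev$time + tau[ev$neuron]),
    neuron = c(ev$neuron, ev$neuron),
    direction = rep(c(1L, -1L), each = nrow(ev)))
  ch[order(ch$time, ch$direction, ch$neuron), , drop = FALSE]
}

#' Time-weighted empirical distribution of network states
#'
#' Occupancy of each visited binary state between `burn_in` and `t_end`,
#' computed from the piecewise-constant state trajectory.
#'
#' @param traj A `spike_trajectory` (or `gibbs_trajectory`).
#' @param ids Neurons defining the state vector (default: principal neurons).
#' @param burn_in Initial simulated time to discard (seconds).
#' @return Named numeric vector of occupancies summing to 1; names are state
#'   bitstrings over `ids` (first id = first character).
#' @export
occupancy_distribution <- function(traj, ids = NULL, burn_in = 1) {
  ch <- if (inherits(traj, "gibbs_trajectory")) gibbs_state_changes(traj)
        else state_change_times(traj)
  if (is.null(ids)) {
    if (!is.null(traj$network)) {
      ids <- principal_ids(traj$network)
      if (!length(ids)) ids <- traj$network$neurons$id
    } else {
      ids <- seq_along(traj$model$biases)
    }
  }
  n <- length(ids)
  if (n > 30) stop("too many neurons for bitstring occupancy")
  t_end <- traj$t_end
  pos <- match(ch$neuron, ids)
  keep <- !is.na(pos) & ch$time < t_end
  ch <- ch[keep, , drop = FALSE]
  pos <- pos[keep]
  # initial actives enter through their virtual time-0 on-changes
  codes <- c(0, cumsum(ch$direction * 2^(pos - 1)))
  times <- c(0, ch$time, t_end)
  # clip burn-in
  starts <- times[-length(times)]
  ends <- times[-1]
  w <- pmax(0, pmin(ends, t_end) - pmax(starts, burn_in))
  occ <- tapply(w, codes, sum)
  occ <- occ[occ > 0]
  tot <- sum(occ)
  if (tot <= 0) stop("no occupancy mass after burn-in")
  states <- vapply(as.numeric(names(occ)), function(cd) {
    paste(as.integer(intToBits(cd))[seq_len(n)], collapse = "")
  }, character(1))
  setNames(as.numeric(occ) / tot, states)
}

#' Export / import spike trajectories
#'
#' Events are written as JSON lines `{"t": <time>, "neuron": <id>}` preceded
#' by a header line with seed, t_end and a hash of the network.
#'
#' @param traj A `spike_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(traj, path) {
  hash <- sum(as.integer(charToRaw(write_network_json(traj$network))))
  header <- jsonlite::toJSON(list(seed = traj$seed, t_end = traj$t_end,
                                  initial = traj$initial,
                                  network_hash = hash),
                             auto_unbox = TRUE, digits = NA)
  lines <- sprintf("{\"t\": %.17g, \"neuron\": %d}",
                   traj$events$time, traj$events$neuron)
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @param net The `neural_network` the events belong to.
#' @rdname write_trajectory_jsonl
#' @export
read_trajectory_jsonl <- function(path, net) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  ev <- if (length(lines) > 1) {
    do.call(rbind, lapply(lines[-1], function(l) {
      o <- jsonlite::fromJSON(l)
      data.frame(time = o$t, neuron = as.integer(o$neuron))
    }))
  } else data.frame(time = numeric(), neuron = integer())
  structure(list(events = ev, t_end = header$t_end,
                 seed = as.integer(header$seed),
                 initial = as.integer(unlist(header$initial)),
                 network = net),
            class = "spike_trajectory")
}
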