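#' Continuous-time Gibbs sampler (Boltzmann machine)
#'
#' Simulates the continuous-time Markov chain in which unit k switches on
#' at rate \eqn{\rho_0\sigma(u_k)} while off and off at rate
#' \eqn{\rho_0\sigma(-u_k)} while on, with
#' \eqn{u_k = b_k + \sum_l w_{kl} x_l}.  For a symmetric zero-diagonal
#' model the chain satisfies detailed balance with respect to the Boltzmann
#' distribution of the model's energy function, i.e. it samples from
#' exactly the same stationary distribution as the matched spiking network
#' but with symmetric transition dynamics.
#'
#' @param model An `energy_model`, or a `gibbs_system` from
#'   [spiking_model_to_gibbs()] (which may carry directed weights).
#' @param t_end Simulated duration (in sampler time units).
#' @param seed Integer seed.
#' @param rho0 Overall speed constant \eqn{\rho_0 > 0}.
#' @param initial Units active at time 0 (recorded as time-0 flips).
#' @param max_state_changes Optional budget on the number of flips.
#' @return A `gibbs_trajectory`: list with `events` (`time`, `neuron`,
#'   `direction`), `t_end`, `seed`, `initial`, the `model` and (when
#'   derived from a network) the `network`.
#' @export
simulate_gibbs <- function(model, t_end, seed, rho0 = 1,
                           initial = integer(0), max_state_changes = Inf) {
  if (rho0 <= 0) stop("rho0 must be positive")
  if (t_end <= 0) stop("t_end must be positive")
  if (inherits(model, "energy_model")) {
    w <- which(model$weights != 0, arr.ind = TRUE)
    from <- w[, 2]; to <- w[, 1]; val <- model$weights[w]
    biases <- model$biases
    net <- NULL
  } else if (inherits(model, "gibbs_system")) {
    from <- model$from; to <- model$to; val <- model$weight
    biases <- model$biases
    net <- model$network
  } else stop("model must be an energy_model or gibbs_system")
  set.seed(as.integer(seed))
  res <- sim_gibbs_cpp(biases, as.integer(from) - 1L, as.integer(to) - 1L,
                       val, rho0, t_end,
                       if (is.finite(max_state_changes)) max_state_changes
                       else Inf,
                       as.integer(initial) - 1L)
  ev <- data.frame(time = res$time, neuron = res$unit + 1L,
                   direction = as.integer(res$dir))
  if (length(initial))
    ev <- rbind(data.frame(time = 0, neuron = as.integer(initial),
                           direction = 1L), ev)
  truncated <- is.finite(max_state_changes) &&
    length(res$time) >= max_state_changes
  structure(list(events = ev,
                 t_end = if (truncated) res$t_last else t_end,
                 seed = as.integer(seed), rho0 = rho0,
                 initial = as.integer(initial),
                 model = model, network = net),
            class = "gibbs_trajectory")
}

#' @export
print.gibbs_trajectory <- function(x, ...) {
  cat(sprintf("<gibbs_trajectory> %d flips over %.3f time units (seed %d)\n",
              nrow(x$events), x$t_end, x$seed))
  invisible(x)
}

#' State changes of a Gibbs trajectory
#'
#' Every flip is one state change; the returned frame matches the format of
#' [state_change_times()] so the analysis tooling (energy jumps, undefined
#' variables, tour/assignment readout, state-change budgets) applies to both
#' samplers.
#'
#' @param gtraj A `gibbs_trajectory`.
#' @return Data frame with `time`, `neuron`, `direction`.
#' @export
gibbs_state_changes <- function(gtraj) {
  gtraj$events
}

#' Extract the principal energy model of a spiking network
#'
#' Biases and summed synaptic weights of the principal subnetwork, which
#' must be symmetric (the compilers only ever use asymmetric weights on
#' auxiliary connections).
#'
#' @param net A `neural_network`.
#' @return An `energy_model` over the principal neurons (in id order).
#' @export
principal_energy_model <- function(net) {
  ids <- principal_ids(net)
  W <- weight_matrix(net, ids)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-9)))
    stop("principal subnetwork weights are not symmetric")
  energy_model(net$neurons$bias[ids], (W + t(W)) / 2)
}

#' Map a spiking network to a matched Gibbs sampler
#'
#' Two mappings are provided.  `"architecture"` (the default) retains every
#' neuron, including auxiliary ones, as a Boltzmann unit and keeps all
#' directed weights, so the Gibbs sampler runs on exactly the same
#' architecture; with purely symmetric weights its stationary distribution
#' is the Boltzmann distribution of the shared energy function.
#' `"lateral"` returns a sampler over the principal neurons only, replacing
#' each WTA auxiliary by its effective contribution: direct pairwise
#' lateral inhibition (the auxiliary-to-principal weight) between the
#' group's members.
#'
#' @param net A `neural_network` whose principal weights are symmetric.
#' @param option `"architecture"` or `"lateral"`.
#' @return A `gibbs_system`: list with `biases`, directed weight triplets
#'   (`from`, `to`, `weight`), `unit_ids` (network neuron ids of the
#'   units) and the originating `network`.
#' @export
spiking_model_to_gibbs <- function(net, option = c("architecture", "lateral")) {
  option <- match.arg(option)
  pm <- principal_energy_model(net)  # validates principal symmetry
  if (option == "architecture") {
    syn <- net$synapses
    agg <- stats::aggregate(weight ~ pre + post, data = syn, FUN = sum)
    structure(list(biases = net$neurons$bias,
                   from = agg$pre, to = agg$post, weight = agg$weight,
                   unit_ids = net$neurons$id, network = net),
              class = "gibbs_system")
  } else {
    ids <- principal_ids(net)
    W <- pm$weights
    pos <- match(seq_len(n_neurons(net)), ids)
    for (gname in names(net$wta_groups)) {
      g <- pos[net$wta_groups[[gname]]]
      if (length(g) < 2) next
      aux <- net$synapses[net$synapses$type == "wta_inh" &
                            net$synapses$post %in% net$wta_groups[[gname]], ]
      w_lat <- if (nrow(aux)) aux$weight[1] else -100
      for (a in seq_along(g)) for (b in seq_along(g)) {
        if (a != b) W[g[a], g[b]] <- W[g[a], g[b]] + w_lat
      }
    }
    em <- energy_model(pm$biases, W)
    w <- which(em$weights != 0, arr.ind = TRUE)
    structure(list(biases = em$biases, from = w[, 2], to = w[, 1],
                   weight = em$weights[w], unit_ids = ids,
                   network = NULL, model = em),
              class = "gibbs_system")
  }
}

#' Compare spiking and Gibbs stochastic search on a TSP instance
#'
#' Runs matched seeded searches with both samplers, records for each run the
#' number of state changes until a valid tour with cost at most
#' `cost_threshold` is found (runs that never reach the threshold within the
#' state-change budget are excluded), and compares the two samples with a
#' two-sided two-sample Kolmogorov-Smirnov test.
#'
#' @param instance A `tsp_instance`.
#' @param params TSP construction parameters ([tsp_params()]).
#' @param cost_threshold Target tour cost.
#' @param n_runs Number of seeded runs per sampler.
#' @param budget State-change budget per run.
#' @param seed Base seed; run r uses `seed + r` for the spiking network and
#'   `seed + 1000 + r` for the Gibbs sampler.
#' @param rho0 Gibbs speed constant.
#' @param t_end Simulated-time cap per run (seconds for the spiking
#'   network, sampler time units for Gibbs); the state-change budget is
#'   normally the binding limit.
#' @param option Network-to-Gibbs mapping ([spiking_model_to_gibbs()]);
#'   `"architecture"` keeps the full architecture including auxiliary
#'   units, `"lateral"` samples the principal energy model with explicit
#'   lateral inhibition.
#' @return A list with per-run counts (`spiking`, `gibbs`, `NA` when not
#'   reached), their means/sds over successful runs and the KS test result
#'   (`NULL` when either sample is empty).
#' @export
compare_samplers <- function(instance, params = tsp_params(),
                             cost_threshold, n_runs = 20, budget = 1e5,
                             seed = 1, rho0 = 1, t_end = 1e6,
                             option = c("architecture", "lateral")) {
  option <- match.arg(option)
  net <- compile_tsp(instance, params)
  gsys <- spiking_model_to_gibbs(net, option)
  if (is.null(gsys$network)) gsys$network <- net
  spiking <- gibbs <- rep(NA_integer_, n_runs)
  for (r in seq_len(n_runs)) {
    tr <- simulate_network(net, t_end = t_end, seed = seed + r,
                           max_state_changes = budget)
    spiking[r] <- state_changes_to_cost(tr, instance, cost_threshold)
    gt <- simulate_gibbs(gsys, t_end = t_end, seed = seed + 1000 + r,
                         rho0 = rho0, max_state_changes = budget)
    gibbs[r] <- state_changes_to_cost(gt, instance, cost_threshold)
  }
  s <- spiking[!is.na(spiking)]
  g <- gibbs[!is.na(gibbs)]
  ks <- if (length(s) && length(g))
    suppressWarnings(stats::ks.test(s, g)) else NULL
  list(spiking = spiking, gibbs = gibbs,
       summary = data.frame(
         sampler = c("spiking", "gibbs"),
         n_solved = c(length(s), length(g)),
         mean_changes = c(mean(s), mean(g)),
         sd_changes = c(stats::sd(s), stats::sd(g))),
       ks = ks)
}
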