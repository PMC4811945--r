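# Shared helpers for the test suite.

# A small symmetric energy model used across tests.
toy_model <- function() {
  energy_model(c(0.3, -0.4, 0.2),
               matrix(c(0, 0.8, -0.5,
                        0.8, 0, 0.3,
                        -0.5, 0.3, 0), 3, 3))
}

# Build a spiking network whose principal weights realize an energy model
# (symmetric pairwise synapses, default PSPs/refractory).
net_from_model <- function(model) {
  net <- neural_network()
  net <- add_neurons(net, length(model$biases), bias = model$biases)
  w <- which(model$weights != 0 & upper.tri(model$weights), arr.ind = TRUE)
  if (nrow(w)) {
    net <- add_synapses(net,
                        pre = c(w[, 1], w[, 2]),
                        post = c(w[, 2], w[, 1]),
                        weight = rep(model$weights[w], 2))
  }
  net
}

# Time-weighted probability that all clauses of a compiled SAT trajectory
# are simultaneously satisfied on [from, t_end].
prob_all_satisfied <- function(traj, from = 0) {
  tr <- sat_trace(traj)
  M <- length(traj$network$metadata$sat$formula$clauses)
  idx <- tr$time >= from
  if (!any(idx)) return(0)
  dt <- diff(c(tr$time[idx], traj$t_end))
  sum(dt[tr$satisfied[idx] == M]) / (traj$t_end - from)
}
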