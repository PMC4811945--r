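test_that("firing rate follows exp(u)/tau", {
  expect_equal(firing_rate(0, 0.01), 100)
  expect_equal(firing_rate(1, 0.01), exp(1) / 0.01)
  expect_error(firing_rate(0, 0), "positive")
})

test_that("simulation is reproducible from the seed", {
  net <- net_from_model(toy_model())
  a <- simulate_network(net, t_end = 5, seed = 42)
  b <- simulate_network(net, t_end = 5, seed = 42)
  c <- simulate_network(net, t_end = 5, seed = 43)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, c$events))
})

test_that("an isolated neuron matches its analytic duty cycle", {
  net <- neural_network()
  net <- add_neurons(net, 1, bias = 0.7)
  traj <- simulate_network(net, t_end = 300, seed = 11)
  occ <- occupancy_distribution(traj, ids = 1, burn_in = 1)
  expect_lt(abs(occ[["1"]] - plogis(0.7)), 0.02)
})

test_that("a strongly inhibited neuron stays silent", {
  net <- neural_network()
  net <- add_neurons(net, 1, bias = -30)
  traj <- simulate_network(net, t_end = 10, seed = 1)
  expect_equal(nrow(traj$events), 0L)
})

test_that("refractory period enforces minimum inter-spike interval", {
  net <- neural_network()
  net <- add_neurons(net, 1, bias = 5, refractory = 0.02)
  traj <- simulate_network(net, t_end = 5, seed = 2)
  expect_true(all(diff(traj$events$time) >= 0.02 - 1e-12))
})

test_that("synaptic delays postpone the PSP", {
  # neuron 1 clamped on; strong excitation with 50 ms delay to neuron 2
  net <- neural_network()
  net <- add_neurons(net, 2, bias = c(5, -30))
  net <- add_synapses(net, pre = 1, post = 2, weight = 40, delay = 0.05)
  traj <- simulate_network(net, t_end = 5, seed = 3)
  t2 <- traj$events$time[traj$events$neuron == 2]
  t1 <- min(traj$events$time[traj$events$neuron == 1])
  expect_gt(length(t2), 0)
  expect_true(all(t2 >= t1 + 0.05))
})

test_that("membrane_potential reflects active PSPs", {
  net <- neural_network()
  net <- add_neurons(net, 2, bias = c(5, 0))
  net <- add_synapses(net, pre = 1, post = 2, weight = 1.5)
  traj <- simulate_network(net, t_end = 1, seed = 4)
  s <- traj$events$time[traj$events$neuron == 1][1]
  expect_equal(membrane_potential(2, s + 0.005, traj), 1.5,
               tolerance = 1e-12)
  expect_error(membrane_potential(2, 2, traj), "beyond")
})

test_that("overlapping PSPs on one synapse renew rather than stack", {
  # presynaptic neuron re-fires every 5 ms (refractory < PSP duration), so
  # its single synapse must contribute its weight once, not cumulatively
  net <- neural_network()
  net <- add_neurons(net, 2, bias = c(10, 0), refractory = c(0.005, 0.01))
  net <- add_synapses(net, pre = 1, post = 2, weight = 1.5)
  traj <- simulate_network(net, t_end = 2, seed = 5)
  ts <- seq(0.5, 1.9, by = 0.09)
  u2 <- vapply(ts, function(t) membrane_potential(2, t, traj), numeric(1))
  expect_true(all(u2 <= 1.5 + 1e-9))
  expect_gt(mean(u2), 1.4)  # pre is on almost always
})

test_that("state_at uses each neuron's own on-state window", {
  net <- neural_network()
  net <- add_neurons(net, 1, bias = 5, psp_duration = 0.02,
                     refractory = 0.05)
  traj <- simulate_network(net, t_end = 1, seed = 6)
  s <- traj$events$time[1]
  expect_equal(unname(state_at(traj, s + 0.01)), 1L)
  expect_equal(unname(state_at(traj, s + 0.03)), 0L)
})

test_that("state changes pair each spike with an off event", {
  net <- net_from_model(toy_model())
  traj <- simulate_network(net, t_end = 5, seed = 7)
  ch <- state_change_times(traj)
  expect_equal(nrow(ch), 2 * nrow(traj$events))
  expect_equal(sum(ch$direction), 0L)
  expect_true(!is.unsorted(ch$time))
})

test_that("initial active set starts on and is recorded", {
  net <- neural_network()
  net <- add_neurons(net, 2, bias = c(-30, -30))
  net <- add_synapses(net, pre = 1, post = 2, weight = 10)
  traj <- simulate_network(net, t_end = 0.5, seed = 8, initial = 1)
  expect_equal(traj$events$time[1], 0)
  expect_equal(traj$events$neuron[1], 1L)
  expect_equal(unname(state_at(traj, 0.005, 1)), 1L)
})

test_that("state-change budget truncates the run", {
  net <- net_from_model(toy_model())
  traj <- simulate_network(net, t_end = 100, seed = 9,
                           max_state_changes = 50)
  expect_lte(nrow(traj$events), 25)
  expect_lt(traj$t_end, 100)
})

test_that("trajectories round-trip through JSONL", {
  net <- net_from_model(toy_model())
  traj <- simulate_network(net, t_end = 2, seed = 10)
  path <- tempfile(fileext = ".jsonl")
  write_trajectory_jsonl(traj, path)
  back <- read_trajectory_jsonl(path, net)
  expect_equal(back$events$time, traj$events$time)
  expect_equal(back$events$neuron, traj$events$neuron)
  expect_equal(back$t_end, traj$t_end)
  expect_equal(back$seed, traj$seed)
})

test_that("occupancy distribution sums to one over visited states", {
  net <- net_from_model(toy_model())
  traj <- simulate_network(net, t_end = 20, seed = 12)
  occ <- occupancy_distribution(traj, ids = 1:3, burn_in = 1)
  expect_equal(sum(occ), 1)
  expect_true(all(nchar(names(occ)) == 3))
})
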