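test_that("energy of trivial states", {
  m <- toy_model()
  expect_equal(energy(c(0, 0, 0), m), 0)
  expect_equal(energy(c(1, 0, 0), m), -0.3)
  expect_equal(energy(c(1, 1, 0), m), -0.3 + 0.4 - 0.8)
})

test_that("energy_model validates its inputs", {
  expect_error(energy_model(c(0, 0), matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(energy_model(c(0, 0), matrix(c(1, 0, 0, 0), 2)), "diagonal")
  expect_error(energy_model(c(0, 0, 0), matrix(0, 2, 2)), "dimension")
})

test_that("boltzmann_exact is a normalized Boltzmann distribution", {
  m <- toy_model()
  p <- boltzmann_exact(m)
  expect_equal(sum(p), 1)
  expect_equal(length(p), 8)
  # pairwise ratio check against energies
  E000 <- energy(c(0, 0, 0), m)
  E101 <- energy(c(1, 0, 1), m)
  expect_equal(unname(p["101"] / p["000"]), exp(E000 - E101))
})

test_that("apply_temperature rescales energies by 1/T", {
  m <- toy_model()
  m2 <- apply_temperature(m, 2)
  x <- c(1, 1, 0)
  expect_equal(energy(x, m2), energy(x, m) / 2)
  expect_error(apply_temperature(m, 0), "positive")
})

test_that("temperature sharpens / flattens the distribution", {
  m <- toy_model()
  p1 <- boltzmann_exact(m)
  cold <- boltzmann_exact(apply_temperature(m, 0.2))
  hot <- boltzmann_exact(apply_temperature(m, 50))
  expect_gt(max(cold), max(p1))
  expect_lt(max(hot), max(p1))
  expect_lt(tv_distance(hot, setNames(rep(1 / 8, 8), names(p1))), 0.05)
})

test_that("NCC membrane potential equals the conditional log-odds", {
  m <- toy_model()
  p <- boltzmann_exact(m)
  x <- c(NA, 1, 0)
  p1 <- p[["110"]]; p0 <- p[["010"]]
  expect_equal(ncc_membrane(1, c(0, 1, 0), m), log(p1 / p0))
})

test_that("rate laws and their ratio are mutually consistent", {
  for (u in c(-2, 0, 2)) {
    expect_equal(event_rate_spiking(u, 0.01) / event_rate_gibbs(u, 1),
                 rate_ratio(u, 0.01, 1), tolerance = 1e-12)
  }
  expect_equal(event_rate_spiking(0, 0.01), 100)
  expect_equal(event_rate_gibbs(0, 1), 0.5)
  expect_equal(rate_ratio(0, 0.01, 1), 200)
})

test_that("marginal energy matches direct marginalization", {
  m <- toy_model()
  me <- marginal_energy(m, principal = c(1, 2))
  p <- boltzmann_exact(m)
  pm <- tapply(p, substr(names(p), 1, 2), sum)
  E <- -log(pm); E <- E - min(E)
  expect_equal(unname(me[names(pm)]), as.numeric(E), tolerance = 1e-12)
  expect_equal(min(me), 0)
})

test_that("marginal energy with no auxiliaries reduces to the energy table", {
  m <- toy_model()
  me <- marginal_energy(m, principal = 1:3)
  S <- all_states(3)
  E <- apply(S, 1, energy, model = m)
  expect_equal(unname(me), E - min(E), tolerance = 1e-12)
})

test_that("energy jumps: trivial cases", {
  m <- energy_model(c(0.7, 0), matrix(0, 2, 2))
  empty <- energy_jump_histogram(
    data.frame(time = numeric(), neuron = integer(), direction = integer()), m)
  expect_equal(empty$total_transitions, 0L)
  expect_equal(sum(empty$counts), 0L)
  one <- energy_jump_histogram(
    data.frame(time = 0.1, neuron = 1L, direction = 1L), m)
  expect_equal(one$jumps, -0.7)
  expect_equal(sum(one$counts), one$total_transitions)
})

test_that("energy jumps telescope to zero over a closed trajectory", {
  m <- toy_model()
  net <- net_from_model(m)
  traj <- simulate_network(net, t_end = 10, seed = 21)
  ch <- state_change_times(traj)
  # closed: starts all-off and every spike's off-change is included
  h <- energy_jump_histogram(ch, m, model_ids = 1:3)
  expect_equal(sum(h$jumps), 0, tolerance = 1e-9)
})

test_that("undefined variable stats count groups with != 1 active member", {
  net <- neural_network()
  net <- add_neurons(net, 4, bias = 0)
  net <- register_wta_group(net, "a", 1:2)
  net <- register_wta_group(net, "b", 3:4)
  traj <- structure(list(
    events = data.frame(time = c(0.1, 0.15), neuron = c(1L, 3L)),
    t_end = 1, seed = 1, initial = integer(0), network = net),
    class = "spike_trajectory")
  us <- undefined_variable_stats(traj)
  # PSPs last 10 ms, so changes are on(1)@0.10, off(1)@0.11, on(3)@0.15,
  # off(3)@0.16 entering states with 1, 2, 1, 2 undefined groups
  expect_equal(us$total_transitions, 4L)
  expect_equal(us$counts, c(0L, 2L, 2L))
  expect_equal(sum(us$frequency), 1)
})

test_that("tv_distance handles disjoint supports", {
  expect_equal(tv_distance(c("0" = 1), c("1" = 1)), 1)
  expect_equal(tv_distance(c("0" = 0.5, "1" = 0.5), c("0" = 0.5, "1" = 0.5)), 0)
})
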