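test_that("cnf_formula validates clauses", {
  f <- cnf_formula(3, list(c(1, -2, 3), c(-1, 2)))
  expect_equal(f$n_vars, 3L)
  expect_length(f$clauses, 2)
  expect_error(cnf_formula(3, list(c(1, 1, 2))), "twice")
  expect_error(cnf_formula(2, list(c(1, 3))), "out of range")
})

test_that("count_satisfied counts correctly", {
  f <- cnf_formula(3, list(c(1, 2, 3), c(-1, -2, -3), c(1, -2, 3), c(-1, 2, -3)))
  expect_equal(count_satisfied(f, c(TRUE, TRUE, TRUE)), 3L)
  expect_equal(count_satisfied(f, c(FALSE, FALSE, FALSE)), 3L)
  expect_equal(count_satisfied(f, c(TRUE, FALSE, TRUE)), 3L)
})

test_that("compile_sat reproduces printed size formulas", {
  # N=2, M=1 two-literal clause: 3N + 2M neurons, 4N + (4k + 1) synapses
  f1 <- cnf_formula(2, list(c(1, 2)))
  n1 <- compile_sat(f1)
  expect_equal(n_neurons(n1), 8L)
  expect_equal(n_synapses(n1), 17L)
  expect_error(compile_sat(cnf_formula(1, list())), "empty")
  # general: 3N + 2M neurons, 4N + 13M synapses (no temperature control)
  f <- generate_random_3sat(8, m = 20, seed = 1)
  net <- compile_sat(f)
  expect_equal(n_neurons(net), 3 * 8 + 2 * 20)
  expect_equal(n_synapses(net), 4 * 8 + 13 * 20)
  # temperature control adds 3M + 1 neurons
  net_tc <- compile_sat(f, sat_params(temp_control = TRUE))
  expect_equal(n_neurons(net_tc), 3 * 8 + 2 * 20 + 3 * 20 + 1)
})

test_that("read_assignment uses currently-active semantics", {
  f <- cnf_formula(2, list(c(1, 2)))
  net <- compile_sat(f)
  mk <- function(neurons, times) structure(list(
    events = data.frame(time = times, neuron = neurons),
    t_end = 1, seed = 1, initial = integer(0), network = net),
    class = "spike_trajectory")
  # all inactive -> all undefined, fraction 0
  ro <- read_assignment(mk(integer(0), numeric(0)), 0.5)
  expect_true(all(is.na(ro$values)))
  expect_equal(ro$fraction, 0)
  # var1 TRUE active at readout -> satisfied
  ro2 <- read_assignment(mk(2L, 0.495), 0.5)
  expect_true(ro2$values[1])
  expect_equal(ro2$satisfied_clauses, 1L)
  # both principals of var1 active -> undefined
  ro3 <- read_assignment(mk(c(1L, 2L), c(0.495, 0.496)), 0.5)
  expect_true(is.na(ro3$values[1]))
})

test_that("clamped satisfying state gives fraction 1, one violation 0.75", {
  f <- cnf_formula(2, list(c(1, 2), c(1, -2), c(-1, 2), c(-1, -2)))
  net <- compile_sat(f)
  # x1 = TRUE (neuron 2), x2 = FALSE (neuron 3): satisfies 3 of 4
  traj <- structure(list(
    events = data.frame(time = c(0.495, 0.496), neuron = c(2L, 3L)),
    t_end = 1, seed = 1, initial = integer(0), network = net),
    class = "spike_trajectory")
  ro <- read_assignment(traj, 0.5)
  expect_equal(ro$fraction, 0.75)
})

test_that("sat_trace matches read_assignment at probe times", {
  f <- generate_random_3sat(8, m = 20, seed = 2)
  net <- compile_sat(f)
  traj <- simulate_network(net, t_end = 5, seed = 41)
  tr <- sat_trace(traj)
  for (t in c(1, 2.5, 4)) {
    i <- findInterval(t, tr$time)
    direct <- read_assignment(traj, t)$satisfied_clauses
    expect_equal(tr$satisfied[i], direct)
  }
})

test_that("solve_time finds the first fully satisfied moment", {
  f <- generate_random_3sat(8, ratio = 3, seed = 3, require_satisfiable = TRUE)
  net <- compile_sat(f)
  traj <- simulate_network(net, t_end = 10, seed = 42)
  st <- solve_time(traj)
  expect_false(is.na(st))
  tr <- sat_trace(traj)
  before <- tr$satisfied[tr$time < st]
  expect_true(all(before < length(f$clauses)))
})

test_that("random 3-SAT generator respects its contract", {
  f <- generate_random_3sat(10, ratio = 4.3, seed = 5)
  expect_equal(length(f$clauses), floor(4.3 * 10 + 0.5))
  expect_true(all(vapply(f$clauses,
                         function(cl) length(unique(abs(cl))) == 3L,
                         logical(1))))
  f2 <- generate_random_3sat(10, ratio = 4.3, seed = 5)
  expect_identical(f$clauses, f2$clauses)
  fs <- generate_random_3sat(10, ratio = 4.3, seed = 6,
                             require_satisfiable = TRUE)
  expect_true(complete_solver(fs)$satisfiable)
})

test_that("complete solver agrees with exhaustive enumeration (N <= 15)", {
  for (s in 1:6) {
    f <- generate_random_3sat(9, ratio = 4.5, seed = 100 + s)
    d <- complete_solver(f)
    states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), f$n_vars)))
    enum <- any(apply(states, 1, function(v)
      count_satisfied(f, v) == length(f$clauses)))
    expect_equal(d$satisfiable, enum)
    if (d$satisfiable) {
      expect_equal(count_satisfied(f, d$assignment), length(f$clauses))
    }
  }
  # a larger satisfiable-by-construction one
  f <- generate_random_3sat(15, ratio = 4, seed = 7, require_satisfiable = TRUE)
  expect_true(complete_solver(f)$satisfiable)
})

test_that("DIMACS round-trip and malformed input", {
  f <- generate_random_3sat(6, m = 10, seed = 8)
  path <- tempfile(fileext = ".cnf")
  write_dimacs(f, path)
  back <- read_dimacs(path)
  expect_equal(back$n_vars, f$n_vars)
  expect_identical(lapply(back$clauses, as.integer), f$clauses)
  writeLines(c("p cnf 3 2", "1 2 0"), path)
  expect_error(read_dimacs(path), "clause")
})

test_that("energy ordering: occupancy decreases with violated clauses", {
  # tiny formula; compare marginal occupancy of defined assignments
  f <- cnf_formula(3, list(c(1, 2, 3), c(-1, 2, 3)))
  net <- compile_sat(f)
  traj <- simulate_network(net, t_end = 120, seed = 43)
  prin <- principal_ids(net)
  occ <- occupancy_distribution(traj, ids = prin, burn_in = 1)
  # defined states: exactly one active per variable pair
  mass_by_violations <- c(`0` = 0, `1` = 0)
  for (s in names(occ)) {
    bits <- as.integer(strsplit(s, "")[[1]])
    pairs <- matrix(bits, nrow = 2)
    if (!all(colSums(pairs) == 1)) next
    vals <- pairs[2, ] == 1
    v <- length(f$clauses) - count_satisfied(f, vals)
    key <- as.character(min(v, 1))
    mass_by_violations[key] <- mass_by_violations[key] + occ[[s]]
  }
  # per-state occupancy: normalize by the number of states in each class
  # class 0: 6 assignments satisfy both clauses, class 1: 2 violate one
  expect_gt(mass_by_violations[["0"]] / 6, mass_by_violations[["1"]] / 2)
})

test_that("delay robustness: small uniform delays do not break solving", {
  f <- generate_random_3sat(8, ratio = 3, seed = 9, require_satisfiable = TRUE)
  net <- compile_sat(f)
  net$synapses$delay <- 1e-7  # 0.1 microseconds
  traj <- simulate_network(net, t_end = 10, seed = 44)
  expect_false(is.na(solve_time(traj)))
})
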