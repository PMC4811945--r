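test_that("tsp_instance validates and normalizes", {
  costs <- matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3)
  inst <- tsp_instance(costs, symmetric = TRUE)
  expect_equal(inst$n_cities, 3L)
  ct <- normalize_costs(inst)
  expect_equal(max(ct), 1)
  expect_equal(diag(ct), rep(0, 3))
})

test_that("compile_tsp reproduces the printed size formulas (N=4, Nr=1)", {
  inst <- generate_planar_instance(4, seed = 1)
  net <- compile_tsp(inst, tsp_params(n_resting = 1))
  expect_equal(n_neurons(net), 25L)           # (N + 1) (N + Nr)
  expect_equal(net$metadata$tsp$connection_count, 140L)  # N N' (2N + Nr - 2)
})

test_that("cost couplings are symmetric and exclude same-city pairs", {
  inst <- generate_planar_instance(4, seed = 2)
  net <- compile_tsp(inst, tsp_params(n_resting = 1))
  syn <- net$synapses
  cost <- syn[syn$type == "cost", ]
  map <- net$metadata$tsp
  # symmetric pairs
  key <- paste(pmin(cost$pre, cost$post), pmax(cost$pre, cost$post))
  expect_true(all(table(key) == 2))
  # never between same-city neurons
  expect_true(all(map$city_of[cost$pre] != map$city_of[cost$post]))
  # uniqueness links connect same city in non-adjacent modules
  uni <- syn[syn$type == "unique", ]
  expect_true(all(map$city_of[uni$pre] == map$city_of[uni$post]))
  d <- abs(map$module_of[uni$pre] - map$module_of[uni$post])
  np <- map$n_steps
  expect_true(all(d != 1 & d != np - 1 & d != 0))
  expect_true(all(uni$weight < 0))
})

test_that("first-step clamp sets b_P and b_N", {
  inst <- generate_planar_instance(4, seed = 3)
  net <- compile_tsp(inst, tsp_params(n_resting = 1))
  expect_equal(net$neurons$bias[1], 100)
  expect_equal(net$neurons$bias[2:4], rep(-100, 3))
  net2 <- compile_tsp(inst, tsp_params(n_resting = 1, clamp_first = FALSE))
  expect_equal(net2$neurons$bias[1:4], rep(-0.45, 4))
})

test_that("tour readout collapses duplicates and checks validity", {
  # 4 modules, 3 cities: steps 1,2,2,3 -> valid collapsed (1,2,3)
  inst <- generate_planar_instance(3, seed = 4)
  net <- compile_tsp(inst, tsp_params(n_resting = 1))
  nid <- function(step, city) (step - 1L) * 3L + city
  mk_traj <- function(neurons) structure(list(
    events = data.frame(time = seq_along(neurons) * 1e-3, neuron = neurons),
    t_end = 1, seed = 1, initial = integer(0), network = net),
    class = "spike_trajectory")
  ro <- read_tour(mk_traj(c(nid(1, 1), nid(2, 2), nid(3, 2), nid(4, 3))), 0.5)
  expect_true(ro$valid)
  expect_equal(ro$collapsed_tour, c(1, 2, 3))
  # non-consecutive repeat -> invalid
  ro2 <- read_tour(mk_traj(c(nid(1, 2), nid(2, 1), nid(3, 2), nid(4, 3))), 0.5)
  expect_false(ro2$valid)
  # no spikes -> all undefined, invalid
  ro3 <- read_tour(mk_traj(integer(0)), 0.5)
  expect_true(all(is.na(ro3$steps)))
  expect_false(ro3$valid)
})

test_that("tour cost sums cyclic edges and is reversal-invariant", {
  costs <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  inst <- tsp_instance(costs, symmetric = TRUE)
  ro <- structure(list(steps = c(1, 2, 3), collapsed_tour = c(1, 2, 3),
                       valid = TRUE, cost = NA_real_),
                  class = "tour_readout")
  expect_equal(tour_cost(ro, inst), 1 + 3 + 2)
  rev <- ro; rev$collapsed_tour <- c(3, 2, 1)
  expect_equal(tour_cost(rev, inst), tour_cost(ro, inst))
})

test_that("performance trace is opt/current with gaps when invalid", {
  inst <- generate_planar_instance(4, seed = 5)
  net <- compile_tsp(inst, tsp_params(n_resting = 1))
  traj <- simulate_network(net, t_end = 5, seed = 51)
  perf <- performance_trace(traj, inst, times = c(1, 3, 5))
  expect_true(all(is.na(perf$performance) |
                    (perf$performance > 0 & perf$performance <= 1 + 1e-9)))
})

test_that("brute force and Held-Karp agree", {
  for (s in 1:3) {
    inst <- generate_planar_instance(7, seed = s)
    b <- brute_force_tsp(inst)
    h <- held_karp_tsp(inst)
    expect_equal(b$cost, h$cost, tolerance = 1e-9)
    expect_equal(tour_cost(b$tour, inst), b$cost, tolerance = 1e-9)
  }
  # asymmetric case
  inst <- generate_asymmetric_instance(6, seed = 9)
  expect_equal(brute_force_tsp(inst)$cost, held_karp_tsp(inst)$cost,
               tolerance = 1e-9)
})

test_that("generators are reproducible and valid", {
  a <- generate_planar_instance(6, seed = 7)
  b <- generate_planar_instance(6, seed = 7)
  expect_equal(a$costs, b$costs)
  expect_true(isSymmetric(a$costs))
  d <- generate_asymmetric_instance(5, seed = 7)
  expect_false(isSymmetric(d$costs))
  expect_true(all(diag(d$costs) == 0))
})

test_that("TSPLIB round-trip preserves instances", {
  inst <- generate_planar_instance(5, seed = 8)
  path <- tempfile(fileext = ".tsp")
  write_tsplib(inst, path)
  back <- read_tsplib(path)
  expect_equal(back$n_cities, 5L)
  # EUC_2D distances are rounded to nearest integer on write
  expect_equal(back$costs, round(inst$costs))
  suppressWarnings(
    expect_error(read_tsplib(tempfile()), "cannot open|No such|not found"))
})

test_that("TSPLIB explicit full matrix dialect round-trips exactly", {
  costs <- matrix(c(0, 5, 9, 5, 0, 3, 9, 3, 0), 3)
  inst <- tsp_instance(costs, symmetric = TRUE, name = "toy")
  path <- tempfile(fileext = ".tsp")
  write_tsplib(inst, path)  # no coords -> explicit full matrix
  back <- read_tsplib(path)
  expect_equal(back$costs, costs)
})

test_that("unsupported TSPLIB dialects give a named error", {
  path <- tempfile(fileext = ".tsp")
  writeLines(c("NAME: x", "TYPE: TSP", "DIMENSION: 3",
               "EDGE_WEIGHT_TYPE: GEO", "NODE_COORD_SECTION",
               "1 0 0", "2 1 1", "3 2 2", "EOF"), path)
  expect_error(read_tsplib(path), "GEO|unsupported")
})
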