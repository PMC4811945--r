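# spikesolve

Networks of stochastically firing spiking neurons that solve constraint
satisfaction problems by sampling.  The package provides

- an **exact event-driven simulator** for neurons with instantaneous
  stochastic firing intensity `exp(u)/tau`, rectangular post-synaptic
  potentials (PSPs), absolute refractoriness, and per-synapse delays and
  PSP durations;
- **energy tooling**: the Boltzmann energy function a symmetric network
  samples from, exact enumeration, temperature scaling, neural computability
  conditions, rate laws, energy-jump histograms, and undefined-variable
  statistics;
- **circuit motifs**: winner-take-all (WTA) modules, OR gates, and an
  internal temperature-control circuit that freezes the network once it has
  found a solution;
- **problem compilers** that translate traveling-salesman (TSP) instances
  and k-SAT formulas into spiking networks, with readouts, performance
  traces, and exact reference solvers (brute force, Held–Karp, a complete
  DPLL-style SAT solver);
- a **matched continuous-time Gibbs sampler** (stochastic Boltzmann
  machine) baseline for comparing search dynamics;
- **file formats**: TSPLIB and DIMACS CNF readers/writers, JSON network
  snapshots, JSONL event logs, and a CLI (`run_command()` /
  `inst/cli/spikesolve`) whose runs are fully replayable from their saved
  configuration.

## Sampling from a Boltzmann distribution

A network with symmetric weights samples from the Boltzmann distribution of
the energy `E(x) = -sum_k b_k x_k - 1/2 sum_kl w_kl x_k x_l`, where `x_k = 1`
iff neuron `k` spiked within its last PSP window:

```r
library(spikesolve)

m <- energy_model(c(0.5, -0.2), matrix(c(0, 1.2, 1.2, 0), 2))
net <- neural_network()
net <- add_neurons(net, 2, bias = m$biases)
net <- add_synapses(net, pre = c(1, 2), post = c(2, 1), weight = 1.2)
net
#> <neural_network> 2 neurons (2 principal), 2 synapses, 0 WTA groups

traj <- simulate_network(net, t_end = 300, seed = 42)
traj
#> <spike_trajectory> 43152 spikes over 300.000 s (2 neurons, seed 42)

round(occupancy_distribution(traj, ids = 1:2, burn_in = 1), 4)
#>     00     10     01     11
#> 0.1262 0.2067 0.1026 0.5644
round(boltzmann_exact(m), 4)
#>     00     10     01     11
#> 0.1258 0.2074 0.1030 0.5638
```

The total-variation distance between the empirical occupancy and the exact
distribution is about `0.001` here (`tv_distance()`).

## Solving a TSP instance

`compile_tsp()` builds a ring of WTA modules (one per tour step, plus
resting steps), wires normalized travel costs as inhibitory couplings
between adjacent steps, and adds uniqueness constraints:

```r
inst <- generate_planar_instance(6, seed = 101)
net <- compile_tsp(inst, tsp_params(n_resting = 2))
net
#> <neural_network> 56 neurons (48 principal), 816 synapses, 8 WTA groups

traj <- simulate_network(net, t_end = 5, seed = 7)
best_tour(traj, inst)
#> $tour: 1 2 6 5 3 4    $cost: 1.954025    $time: 4.64
brute_force_tsp(inst)$cost
#> [1] 1.954025
```

The network's best read-out tour equals the brute-force optimum.
`performance_trace()` tracks optimal/current cost over time, and
`read_tour()` applies the validity rules (one city per step, consecutive
duplicates collapsed, every city visited once).

## Solving 3-SAT with internal temperature control

Each variable becomes a two-principal WTA module, each clause an OR motif
that rewards satisfying assignments.  With `temp_control = TRUE` an extra
circuit detects that all clauses are satisfied and silences a global
"heater" neuron, locking the network into the solution:

```r
f <- generate_random_3sat(20, ratio = 4.3, seed = 55, require_satisfiable = TRUE)
net <- compile_sat(f, sat_params(temp_control = TRUE))
traj <- simulate_network(net, t_end = 5, seed = 3)
solve_time(traj)
#> [1] 0.5559746
mean_satisfied_fraction(traj, from = 2)
#> [1] 1
```

Without temperature control the network keeps hopping out of solutions; with
it the post-solve mean satisfied fraction stays at 1.

## Comparing with Gibbs sampling

`spiking_model_to_gibbs()` maps a compiled network to a continuous-time
Gibbs sampler over the same energy landscape (either over the full
architecture or over principal neurons with WTA auxiliaries folded into
lateral inhibition).  `compare_samplers()` runs matched time-to-solution
experiments, and `energy_jump_histogram()` shows the characteristic
difference in dynamics: large energy jumps `|dE| > 15` are frequent under
spiking dynamics and virtually absent under Gibbs sampling.

## Command line

```sh
Rscript -e 'spikesolve::run_command()' solve-sat --cnf f.cnf --t-end 10 --seed 1 --out run/
```

Sub-commands: `generate-tsp`, `generate-sat`, `solve-tsp`, `solve-sat`,
`compare`, `analyze`.  Every run writes `config.yaml` (including the seed),
`network.json`, `events.jsonl`, `performance.csv` and `summary.json`, so any
run can be replayed to an identical event log.

## Further reading

See the vignette in `vignettes/` for the energy-based design methodology,
the exactness argument for the event-driven simulator, and the motif
parameterizations.
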