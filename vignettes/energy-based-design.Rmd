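---
title: "Energy-based design of spiking constraint solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based design of spiking constraint solvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesolve)
```

This vignette describes the methodology behind **spikesolve**: how a network
of stochastically firing spiking neurons defines a Boltzmann distribution,
why the event-driven simulator is exact, and how the circuit motifs and
problem compilers are derived from a target energy function.

## 1. The neuron model and its stationary distribution

Each neuron $k$ fires stochastically with instantaneous intensity

$$\rho_k(t) = \frac{1}{\tau} \exp\big(u_k(t)\big),$$

where the membrane potential is $u_k(t) = b_k + \sum_l w_{kl}\, x_l(t)$.
The binary state variable $x_l(t)$ is 1 iff neuron $l$ spiked within the
last $\tau$ seconds; a spike switches the neuron on for exactly $\tau$
(a rectangular PSP of height $w_{kl}$ at every efferent synapse) and
makes it refractory for the same duration.  An on-neuron therefore cannot
renew its own window before it ends, and overlapping PSPs on a single
synapse *renew* the window rather than stack — the synaptic drive is a
function of the binary state $x_l$, never a multiple of it.  The simulator
enforces this renewal semantics per synapse, which matters as soon as PSP
durations exceed presynaptic inter-spike intervals (the temperature-control
circuit below relies on it).

For symmetric weights ($w_{kl} = w_{lk}$, $w_{kk} = 0$) the network state
$x \in \{0,1\}^K$ has stationary distribution

$$p(x) \propto \exp\big(-E(x)\big), \qquad
  E(x) = -\sum_k b_k x_k - \tfrac12 \sum_{k,l} w_{kl}\, x_k x_l .$$

`energy_model()`, `energy()`, `boltzmann_exact()` and
`occupancy_distribution()` let you verify this directly:

```{r boltzmann}
m <- energy_model(c(0.5, -0.2), matrix(c(0, 1.2, 1.2, 0), 2))
net <- neural_network()
net <- add_neurons(net, 2, bias = m$biases)
net <- add_synapses(net, pre = c(1, 2), post = c(2, 1), weight = 1.2)
traj <- simulate_network(net, t_end = 200, seed = 1)
rbind(empirical = occupancy_distribution(traj, 1:2, burn_in = 1),
      exact = boltzmann_exact(m))
```

The *neural computability condition* states that at every moment the
membrane potential equals the log-odds the stationary distribution assigns
to the neuron being on given the rest of the state; `ncc_membrane()`
computes that conditional log-odds from an energy model for comparison
with `membrane_potential()`.

## 2. Exact event-driven simulation

Between events (spike onsets, PSP offsets, delayed-onset arrivals,
refractory ends) every membrane potential — and hence every intensity —
is constant.  The simulator therefore samples the next spike time exactly:
the total intensity $R = \sum_k \rho_k$ over the currently non-refractory
neurons yields an exponential waiting time, a categorical draw picks the
spiking neuron with probability $\rho_k / R$, and the state is advanced to
the earliest of the sampled spike and the next scheduled discontinuity.
No time discretization is involved, so the only approximation in any
result of `simulate_network()` is Monte-Carlo error.

Two numerical safeguards keep the categorical draw exact in floating
point: per-neuron rates are capped at $e^{25}/\tau$ before entering the
prefix-sum tree (far above any rate that matters dynamically, but low
enough that moderate rates are not absorbed when summed with it), and the
prefix-sum tree is rebuilt from scratch periodically so cancellation error
cannot accumulate.

Simultaneous events are ordered deterministically (by time, then event
type, then neuron index), so a trajectory is a pure function of the
network, the initial state and the seed — event logs replay bit-for-bit.

## 3. Rate laws: spiking vs Gibbs dynamics

A single unit with total input $u$ changes state (on- or off-transitions
counted together) at rate

$$R(u) = \frac{2}{\tau}\,\sigma(u)$$

under spiking dynamics (`event_rate_spiking()`), while a continuous-time
Gibbs sampler with update rate $\rho_0$ per unit changes state at

$$R^{\mathrm{sym}}(u) = \frac{2\rho_0}{2 + e^{u} + e^{-u}}$$

(`event_rate_gibbs()`).  Both dynamics share the stationary distribution,
but their speed profiles differ by the factor

$$F(u) = \frac{R(u)}{R^{\mathrm{sym}}(u)} = \frac{1 + e^{u}}{\tau \rho_0},$$

(`rate_ratio()`) which grows exponentially for strongly driven units.
This is the mechanistic reason the spiking network traverses steep energy
barriers that leave a Gibbs sampler stuck: `energy_jump_histogram()`
tallies the energy differences of observed state changes, and on compiled
TSP networks large jumps ($|\Delta E| > 15$) occur orders of magnitude
more often under spiking dynamics than under the matched Gibbs baseline
(`spiking_model_to_gibbs()`, `simulate_gibbs()`).

## 4. Motifs

Constraint problems need hard structural constraints, which are imposed by
small recurrent circuits rather than by pairwise couplings alone.

**Winner-take-all** (`add_wta()`): $K$ principal neurons plus one
inhibitory auxiliary.  Each principal excites the auxiliary strongly
(weight $+100$) and the auxiliary inhibits all principals ($-100$).  The
net keeps at most one principal active at a time while still allowing
rapid switching; with a common bias the stationary distribution
concentrates on the $K$ one-hot states.  A WTA module encodes one problem
variable, and a state in which a module has zero or two active principals
leaves that variable *undefined* (`undefined_variable_stats()`).

**OR** (`add_or()`): two auxiliary neurons per clause.  Auxiliary I
(bias $+0.5B$) tonically injects a small reward $w_{\mathrm{OR}}$ into its
target neurons, and each active target suppresses I ($-B$) while exciting
auxiliary II ($+B$, bias $-3.5B$), which relays the reward back.  The
effect is an energy reduction for states satisfying the clause that is,
to a controlled approximation, independent of *how many* literals are
satisfied — exactly the clause semantics of SAT.

**Internal temperature control** (`add_temperature_control()`): a global
"heater" neuron with a short PSP and matching refractory period fires
tonically and injects a small excitation into all principals, keeping the
effective temperature high while the network searches.  Per clause, two
further auxiliaries (III/IV) detect satisfaction in the presence of the
heater signal and drive a *status* neuron, wired so that the status
population is silent exactly when all clauses are satisfied; status
neurons inhibit the heater.  When a solution is found the heater shuts
off, the temperature drops, and the network locks in — without any
external annealing schedule.

## 5. Compiling problems

**TSP** (`compile_tsp()`): one WTA module per tour step (plus
`n_resting` resting steps for slack), one principal per city.  Normalized
costs $\tilde c \in [0, 1]$ enter as couplings
$w = w_{\mathrm{offset}} + (1 - \tilde c)\, w_{\mathrm{scale}}$ between
ring-adjacent modules (same-city pairs excluded), uniqueness constraints
inhibit the same city in non-adjacent modules, and the first step is
clamped to city 1 by biases $\pm 100$.  Read-out (`read_tour()`) takes the
most recently fired principal per module, collapses consecutive
duplicates, and applies validity rules.  Exact baselines:
`brute_force_tsp()`, `held_karp_tsp()`.

**3-SAT** (`compile_sat()`): a two-principal WTA per variable (neuron
$2n$ active $\Leftrightarrow x_n$ true), an OR motif per clause targeting
the literal-satisfying principals, optionally the temperature-control
circuit.  Read-out (`read_assignment()`) uses currently-active semantics;
`sat_trace()`, `solve_time()` and `mean_satisfied_fraction()` summarize
performance.  Exact baseline: `complete_solver()`.

```{r sat}
f <- generate_random_3sat(10, ratio = 4.3, seed = 5, require_satisfiable = TRUE)
net <- compile_sat(f, sat_params(temp_control = TRUE))
traj <- simulate_network(net, t_end = 3, seed = 2)
solve_time(traj)
mean_satisfied_fraction(traj, from = 1.5)
```

## 6. Reproducibility

Every stochastic entry point takes an explicit integer seed and uses R's
RNG stream; trajectories, generated instances and formulas are pure
functions of their arguments.  The CLI (`run_command()`) snapshots its
full configuration next to its outputs so that any run can be replayed to
an identical event log.
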