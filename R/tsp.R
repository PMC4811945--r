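#' Traveling salesman problem instance
#'
#' @param costs Square matrix of non-negative movement costs `c[i, j]` from
#'   city i to city j (diagonal ignored).
#' @param symmetric Logical; defaults to whether `costs` is symmetric.
#' @param optimal_cost Optional known optimal tour cost, used for
#'   performance scoring.
#' @param coords Optional `n x 2` matrix of planar coordinates (kept for
#'   TSPLIB round-trips).
#' @param name Optional instance name.
#' @return A `tsp_instance`.
#' @export
tsp_instance <- function(costs, symmetric = NULL, optimal_cost = NULL,
                         coords = NULL, name = "tsp") {
  costs <- as.matrix(costs)
  if (nrow(costs) != ncol(costs)) stop("cost matrix must be square")
  if (any(costs < 0)) stop("costs must be non-negative")
  diag(costs) <- 0
  if (is.null(symmetric)) symmetric <- isTRUE(all.equal(costs, t(costs)))
  if (symmetric && !isTRUE(all.equal(costs, t(costs))))
    stop("symmetric flag set but cost matrix is asymmetric")
  structure(list(n_cities = nrow(costs), costs = costs,
                 symmetric = symmetric, optimal_cost = optimal_cost,
                 coords = coords, name = name),
            class = "tsp_instance")
}

#' @export
print.tsp_instance <- function(x, ...) {
  cat(sprintf("<tsp_instance> '%s': %d cities, %s costs%s\n", x$name,
              x$n_cities, if (x$symmetric) "symmetric" else "asymmetric",
              if (is.null(x$optimal_cost)) ""
              else sprintf(", optimum %.6g", x$optimal_cost)))
  invisible(x)
}

#' Normalize a cost matrix to the unit interval
#'
#' Divides all costs by the maximum off-diagonal cost, the scale on which
#' the synaptic cost encoding operates.
#'
#' @param instance A `tsp_instance` (or bare cost matrix).
#' @return Matrix of normalized costs.
#' @export
normalize_costs <- function(instance) {
  costs <- if (inherits(instance, "tsp_instance")) instance$costs else instance
  off <- costs[row(costs) != col(costs)]
  m <- max(off)
  if (m <= 0) stop("all off-diagonal costs are zero")
  costs / m
}

#' Default parameters of the TSP network construction
#'
#' The defaults are tuned for planar instances; `asymmetric = TRUE` switches
#' to the variant tuned for general (asymmetric) cost matrices.
#'
#' @param n_resting Number of extra "resting" tour steps (>= 0); resting in
#'   a city (consecutive repetition) carries no cost and opens additional
#'   low-energy paths through the landscape.
#' @param asymmetric Use the asymmetric-instance parameter set.
#' @param ... Overrides for individual parameters (`b_wta`, `b_p`, `b_n`,
#'   `b_inh`, `w_wta`, `w_exc`, `w_unique`, `w_scale`, `w_offset`,
#'   `clamp_first`).
#' @return Named list of parameters.
#' @export
tsp_params <- function(n_resting = 7, asymmetric = FALSE, ...) {
  p <- list(n_resting = n_resting,
            b_wta = if (asymmetric) 1.3 else -0.45,
            b_p = 100, b_n = -100, b_inh = -10,
            w_wta = -100, w_exc = 100,
            w_unique = if (asymmetric) -14.1 else -14.7,
            w_scale = if (asymmetric) 20.8 else 19.4,
            w_offset = if (asymmetric) -7.9 else -5,
            clamp_first = TRUE)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Compile a TSP instance into a spiking network
#'
#' Builds a ring of `N' = N + n_resting` WTA modules of N principal neurons
#' each (one per city and tour step) plus one inhibitory auxiliary per
#' module.  Adjacent modules are coupled by symmetric weight pairs
#' \deqn{w = w_{offset} + (1 - \tilde c_{ij}) \, w_{scale}}
#' over the normalized costs, excluding same-city pairs (so that resting is
#' free); same-city neurons in non-adjacent modules repel each other with
#' `w_unique`.  Optionally the first step is clamped to city 1 through
#' biases `b_p` / `b_n`.  The principal subnetwork has purely symmetric
#' weights and therefore a second-order Boltzmann energy function whose low
#' energy states are low-cost tours.
#'
#' @param instance A `tsp_instance` with at least 3 cities.
#' @param params Parameter list from [tsp_params()].
#' @return A `neural_network` with readout metadata in
#'   `net$metadata$tsp` (`n_cities`, `n_steps`, `module_of`, `city_of`,
#'   `connection_count`).
#' @export
compile_tsp <- function(instance, params = tsp_params()) {
  N <- instance$n_cities
  if (N < 3) stop("need at least 3 cities")
  nr <- params$n_resting
  if (nr < 0) stop("n_resting must be >= 0")
  np <- N + nr  # number of tour steps / WTA modules
  ct <- normalize_costs(instance)

  net <- neural_network()
  net <- add_neurons(net, np * N, bias = params$b_wta, principal = TRUE)
  nid <- function(step, city) (step - 1L) * N + city

  # clamp the first problem variable to city 1
  if (isTRUE(params$clamp_first)) {
    net <- set_bias(net, nid(1L, 1L), params$b_p)
    if (N > 1) net <- set_bias(net, nid(1L, 2:N), params$b_n)
  }

  # one WTA auxiliary per module (biases already set, so b_wta = NULL)
  for (s in seq_len(np))
    net <- add_wta(net, nid(s, seq_len(N)), b_wta = NULL,
                   b_inh = params$b_inh, w_wta = params$w_wta,
                   w_exc = params$w_exc, name = paste0("step", s))

  # cost couplings between ring-adjacent modules: both synapse directions of
  # the pair (step s city i) <-> (step s+1 city j) carry the travel cost c_ij
  ij <- which(row(ct) != col(ct), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  w_cost <- params$w_offset + (1 - ct[ij]) * params$w_scale
  pre <- integer(0); post <- integer(0); w <- numeric(0)
  for (s in seq_len(np)) {
    s2 <- if (s == np) 1L else s + 1L
    a <- nid(s, i); b <- nid(s2, j)
    pre <- c(pre, a, b); post <- c(post, b, a); w <- c(w, w_cost, w_cost)
  }
  cost_syn <- data.frame(pre = pre, post = post, weight = w, delay = 0,
                         psp_duration = 0.010, type = "cost",
                         stringsAsFactors = FALSE)

  # uniqueness constraint: same city in non-adjacent modules
  pre <- integer(0); post <- integer(0)
  if (np > 3) {
    pairs <- which(outer(seq_len(np), seq_len(np), function(a, b) {
      d <- abs(a - b)
      a < b & d != 1 & d != np - 1
    }), arr.ind = TRUE)
    for (city in seq_len(N)) {
      a <- nid(pairs[, 1], city); b <- nid(pairs[, 2], city)
      pre <- c(pre, a, b); post <- c(post, b, a)
    }
  }
  uniq_syn <- data.frame(pre = pre, post = post, weight = params$w_unique,
                         delay = 0, psp_duration = 0.010, type = "unique",
                         stringsAsFactors = FALSE)
  net$synapses <- rbind(net$synapses, cost_syn, uniq_syn)

  net$metadata$tsp <- list(
    n_cities = N, n_steps = np,
    module_of = rep(seq_len(np), each = N),
    city_of = rep(seq_len(N), np),
    # connection count in the convention of the closed form
    # N * (N + n_resting) * (2N + n_resting - 2): each symmetric cost pair
    # counts once, WTA and uniqueness links count per direction
    connection_count = nrow(cost_syn) / 2 + nrow(uniq_syn) + 2L * N * np,
    params = params)
  validate_network(net)
  net
}

#' Read out the proposed tour at a time point
#'
#' Each module's current city is the city of its most recently fired
#' principal neuron at or before `t` (`NA` if none yet).  Consecutive
#' duplicate cities (cyclically) are collapsed into single visits; the
#' readout is a valid tour iff every module is defined and the collapsed
#' sequence visits every city exactly once.
#'
#' @param traj A `spike_trajectory` of a TSP-compiled network.
#' @param t Readout time.
#' @param semantics `"most_recent"` (default) or `"active"` (only spikes
#'   within the neuron's on-state window count).
#' @return A `tour_readout`: list with `steps` (per-module city or `NA`),
#'   `collapsed_tour`, `valid` and `cost` (`NA` when invalid).
#' @export
read_tour <- function(traj, t, semantics = c("most_recent", "active")) {
  semantics <- match.arg(semantics)
  map <- traj$network$metadata$tsp
  if (is.null(map)) stop("network has no TSP readout metadata")
  ev <- traj$events
  ev <- ev[ev$time <= t, , drop = FALSE]
  if (semantics == "active") {
    tau <- traj$network$neurons$psp_duration
    ev <- ev[ev$time > t - tau[ev$neuron], , drop = FALSE]
  }
  steps <- rep(NA_integer_, map$n_steps)
  mod <- map$module_of[ev$neuron]
  keep <- !is.na(mod)
  ev <- ev[keep, , drop = FALSE]; mod <- mod[keep]
  if (nrow(ev)) {
    ord <- order(ev$time)  # last occurrence wins
    steps[mod[ord]] <- map$city_of[ev$neuron[ord]]
  }
  collapse_tour(steps, map$n_cities)
}

# Collapse a cyclic step sequence and assess validity of the relaxed tour:
# every city at least once, repeats only in consecutive steps.
collapse_tour <- function(steps, n_cities, costs = NULL) {
  if (anyNA(steps)) {
    return(structure(list(steps = steps, collapsed_tour = integer(0),
                          valid = FALSE, cost = NA_real_),
                     class = "tour_readout"))
  }
  r <- rle(steps)$values
  if (length(r) > 1 && r[1] == r[length(r)]) r <- r[-length(r)]  # cyclic merge
  valid <- length(r) == n_cities && !anyDuplicated(r) &&
    length(unique(r)) == n_cities
  structure(list(steps = steps, collapsed_tour = r,
                 valid = valid, cost = NA_real_),
            class = "tour_readout")
}

#' @export
print.tour_readout <- function(x, ...) {
  cat(sprintf("<tour_readout> %s; tour: %s\n",
              if (x$valid) "valid" else "invalid",
              paste(x$collapsed_tour, collapse = " -> ")))
  invisible(x)
}

#' Cost of a valid tour readout
#'
#' @param readout A valid `tour_readout` (or a plain city permutation).
#' @param instance The `tsp_instance`.
#' @return Total cost over consecutive pairs of the cyclic tour.
#' @export
tour_cost <- function(readout, instance) {
  tour <- if (inherits(readout, "tour_readout")) {
    if (!readout$valid) stop("cannot cost an invalid tour")
    readout$collapsed_tour
  } else as.integer(readout)
  nxt <- c(tour[-1], tour[1])
  sum(instance$costs[cbind(tour, nxt)])
}

# Shared scan over a trajectory's state changes under most-recent readout:
# calls fn(change_index, time, tour_vector) whenever the proposed tour
# changes; tours only change at principal on-transitions.
scan_tours <- function(changes, net, fn,
                       semantics = c("most_recent", "active")) {
  semantics <- match.arg(semantics)
  map <- net$metadata$tsp
  n_prin <- length(map$module_of)
  dir <- changes$direction
  neuron <- changes$neuron
  tm <- changes$time
  if (semantics == "most_recent") {
    last <- rep(NA_integer_, map$n_steps)
    for (r in seq_along(dir)) {
      if (dir[r] != 1L) next
      k <- neuron[r]
      if (k > n_prin) next
      m <- map$module_of[k]
      city <- map$city_of[k]
      if (!is.na(last[m]) && last[m] == city) next
      last[m] <- city
      if (isTRUE(fn(r, tm[r], last))) return(invisible(NULL))
    }
  } else {
    # currently-on readout: a step is defined iff exactly one of its
    # principal neurons is active
    cnt <- integer(map$n_steps)
    citysum <- integer(map$n_steps)
    steps <- rep(NA_integer_, map$n_steps)
    for (r in seq_along(dir)) {
      k <- neuron[r]
      if (k > n_prin) next
      m <- map$module_of[k]
      cnt[m] <- cnt[m] + dir[r]
      citysum[m] <- citysum[m] + dir[r] * map$city_of[k]
      new_step <- if (cnt[m] == 1L) citysum[m] else NA_integer_
      if (identical(new_step, steps[m])) next
      steps[m] <- new_step
      if (isTRUE(fn(r, tm[r], steps))) return(invisible(NULL))
    }
  }
  invisible(NULL)
}

#' Performance trace of a TSP run
#'
#' Ratio of the known optimal tour cost to the currently read-out tour cost
#' at each requested time; `NA` while the readout is not a valid tour.
#'
#' @param traj A `spike_trajectory` of a TSP-compiled network.
#' @param instance The `tsp_instance`; its `optimal_cost` must be set (for
#'   <= 10 cities it is brute-forced on the fly).
#' @param times Numeric vector of readout times.
#' @return Data frame with columns `time` and `performance` in `[0, 1]`.
#' @export
performance_trace <- function(traj, instance, times) {
  opt <- instance$optimal_cost
  if (is.null(opt)) {
    if (instance$n_cities > 10) stop("optimal cost unknown")
    opt <- brute_force_tsp(instance)$cost
  }
  perf <- vapply(times, function(t) {
    ro <- read_tour(traj, t)
    if (!ro$valid) return(NA_real_)
    opt / tour_cost(ro, instance)
  }, numeric(1))
  data.frame(time = times, performance = perf)
}

#' Best tour found along a trajectory
#'
#' Scans every change of the most-recent readout and returns the lowest-cost
#' valid tour encountered.
#'
#' @param traj A `spike_trajectory` of a TSP-compiled network.
#' @param instance The `tsp_instance`.
#' @return List with `tour`, `cost` and `time` of first attainment, or
#'   `NULL` if no valid tour ever appeared.
#' @export
best_tour <- function(traj, instance) {
  best <- NULL
  changes <- state_change_times(traj)
  n_cities <- instance$n_cities
  scan_tours(changes, traj$network, function(r, t, steps) {
    if (anyNA(steps)) return(FALSE)
    ro <- collapse_tour(steps, n_cities)
    if (ro$valid) {
      cst <- tour_cost(ro, instance)
      if (is.null(best) || cst < best$cost)
        best <<- list(tour = ro$collapsed_tour, cost = cst, time = t)
    }
    FALSE
  })
  best
}

#' State changes until a tour of a given cost is found
#'
#' Counts the network state changes (spikes plus PSP offsets) before the
#' first time the read-out tour is valid with cost at most `cost_threshold`.
#'
#' @param traj A `spike_trajectory` (or `gibbs_trajectory`) of a
#'   TSP-compiled network.
#' @param instance The `tsp_instance`.
#' @param cost_threshold Positive cost threshold.
#' @return Integer count, or `NA` if the threshold is never reached.
#' @export
state_changes_to_cost <- function(traj, instance, cost_threshold) {
  if (cost_threshold <= 0) stop("threshold must be positive")
  gibbs <- inherits(traj, "gibbs_trajectory")
  changes <- if (gibbs) gibbs_state_changes(traj)
             else state_change_times(traj)
  n_cities <- instance$n_cities
  hit <- NA_integer_
  scan_tours(changes, traj$network,
             semantics = if (gibbs) "active" else "most_recent",
             fn = function(r, t, steps) {
    if (anyNA(steps)) return(FALSE)
    ro <- collapse_tour(steps, n_cities)
    if (ro$valid && tour_cost(ro, instance) <= cost_threshold) {
      hit <<- r
      return(TRUE)
    }
    FALSE
  })
  hit
}

#' Generate random TSP instances
#'
#' `generate_planar_instance()` draws `n` uniform points in the unit square
#' with Euclidean costs (symmetric, metric); this emulates the
#' country-style planar benchmark class.  `generate_asymmetric_instance()`
#' draws independent uniform costs in (0, 1] for every ordered city pair.
#'
#' @param n Number of cities (>= 3).
#' @param seed Integer seed (instances are reproducible).
#' @return A `tsp_instance`.
#' @export
generate_planar_instance <- function(n, seed) {
  if (n < 3) stop("need at least 3 cities")
  set.seed(as.integer(seed))
  xy <- matrix(runif(2 * n), ncol = 2)
  costs <- as.matrix(stats::dist(xy))
  tsp_instance(costs, symmetric = TRUE, coords = xy,
               name = sprintf("planar%d_seed%d", n, seed))
}

#' @rdname generate_planar_instance
#' @export
generate_asymmetric_instance <- function(n, seed) {
  if (n < 3) stop("need at least 3 cities")
  set.seed(as.integer(seed))
  costs <- matrix(runif(n * n), n, n)
  diag(costs) <- 0
  tsp_instance(costs, symmetric = FALSE,
               name = sprintf("asym%d_seed%d", n, seed))
}

#' Exact TSP solvers (oracles)
#'
#' `brute_force_tsp()` enumerates all cyclic permutations with city 1 fixed
#' (halved for symmetric instances); `held_karp_tsp()` is an independent
#' dynamic-programming check.  Both are exact and limited to small
#' instances.
#'
#' @param instance A `tsp_instance` with at most 10 cities (12 for
#'   Held-Karp).
#' @return List with `tour` (city order starting at 1) and `cost`.
#' @export
brute_force_tsp <- function(instance) {
  n <- instance$n_cities
  if (n > 10) stop("instance too large for exhaustive search")
  costs <- instance$costs
  perms <- permutations_of(2:n)
  if (instance$symmetric && n > 2) {
    # keep one orientation: second city smaller than last
    perms <- perms[perms[, 1] < perms[, n - 1], , drop = FALSE]
  }
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    tour <- c(1L, perms[r, ])
    cst <- sum(costs[cbind(tour, c(tour[-1], 1L))])
    if (is.null(best) || cst < best$cost) best <- list(tour = tour, cost = cst)
  }
  best
}

# All permutations of a vector (rows), lexicographic by recursion.
permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n))
    out[[i]] <- cbind(v[i], permutations_of(v[-i]))
  do.call(rbind, out)
}

#' @rdname brute_force_tsp
#' @export
held_karp_tsp <- function(instance) {
  n <- instance$n_cities
  if (n > 12) stop("instance too large for Held-Karp table")
  costs <- instance$costs
  m <- n - 1  # cities 2..n, bitmask over them
  nS <- bitwShiftL(1L, m)
  dp <- matrix(Inf, nS, m)       # dp[S+1, j]: best path 1 -> ... -> city j+1 visiting S
  parent <- matrix(NA_integer_, nS, m)
  for (j in seq_len(m)) dp[bitwShiftL(1L, j - 1L) + 1L, j] <- costs[1, j + 1]
  for (S in seq_len(nS - 1L)) {
    for (j in seq_len(m)) {
      if (!bitwAnd(S, bitwShiftL(1L, j - 1L))) next
      d <- dp[S + 1L, j]
      if (!is.finite(d)) next
      for (k in seq_len(m)) {
        if (bitwAnd(S, bitwShiftL(1L, k - 1L))) next
        S2 <- bitwOr(S, bitwShiftL(1L, k - 1L))
        cand <- d + costs[j + 1, k + 1]
        if (cand < dp[S2 + 1L, k]) {
          dp[S2 + 1L, k] <- cand
          parent[S2 + 1L, k] <- j
        }
      }
    }
  }
  full <- nS - 1L
  tot <- dp[full + 1L, ] + costs[1 + seq_len(m), 1]
  j <- which.min(tot)
  cost <- tot[j]
  tour <- integer(m)
  S <- full
  while (!is.na(j)) {
    tour[sum(bitwAnd(S, bitwShiftL(1L, seq_len(m) - 1L)) != 0)] <- j + 1L
    pj <- parent[S + 1L, j]
    S <- bitwAnd(S, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  list(tour = c(1L, tour), cost = unname(cost))
}

#' Read a TSPLIB problem file
#'
#' Supports `EDGE_WEIGHT_TYPE: EUC_2D` (planar coordinates with the TSPLIB
#' nearest-integer distance convention) and `EXPLICIT` with
#' `EDGE_WEIGHT_FORMAT: FULL_MATRIX`.
#'
#' @param path Path to a `.tsp` / `.atsp` file.
#' @return A `tsp_instance`.
#' @export
read_tsplib <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  header <- list()
  i <- 1
  while (i <= length(lines) && grepl(":", lines[i])) {
    kv <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    header[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
    i <- i + 1
  }
  dim <- suppressWarnings(as.integer(header[["DIMENSION"]]))
  ewt <- header[["EDGE_WEIGHT_TYPE"]]
  if (is.null(ewt) || is.na(dim)) stop("malformed TSPLIB header")
  name <- if (is.null(header[["NAME"]])) "tsplib" else header[["NAME"]]
  body <- lines[i:length(lines)]
  if (ewt == "EUC_2D") {
    j <- which(body == "NODE_COORD_SECTION")
    if (!length(j)) stop("missing NODE_COORD_SECTION")
    nums <- scan(text = paste(body[(j + 1):(j + dim)], collapse = "\n"),
                 quiet = TRUE)
    coords <- matrix(nums, ncol = 3, byrow = TRUE)[, 2:3, drop = FALSE]
    d <- as.matrix(stats::dist(coords))
    costs <- floor(d + 0.5)  # TSPLIB nint
    tsp_instance(costs, symmetric = TRUE, coords = coords, name = name)
  } else if (ewt == "EXPLICIT") {
    fmt <- header[["EDGE_WEIGHT_FORMAT"]]
    if (is.null(fmt) || fmt != "FULL_MATRIX")
      stop(sprintf("unsupported TSPLIB EDGE_WEIGHT_FORMAT '%s'",
                   if (is.null(fmt)) "(missing)" else fmt))
    j <- which(body == "EDGE_WEIGHT_SECTION")
    if (!length(j)) stop("missing EDGE_WEIGHT_SECTION")
    rest <- body[(j + 1):length(body)]
    rest <- rest[rest != "EOF"]
    nums <- scan(text = paste(rest, collapse = "\n"), quiet = TRUE)
    if (length(nums) < dim * dim) stop("EDGE_WEIGHT_SECTION too short")
    costs <- matrix(nums[seq_len(dim * dim)], dim, dim, byrow = TRUE)
    tsp_instance(costs, name = name)
  } else {
    stop(sprintf("unsupported TSPLIB EDGE_WEIGHT_TYPE '%s'", ewt))
  }
}

#' Write a TSPLIB problem file
#'
#' Planar instances with coordinates are written as `EUC_2D`; otherwise the
#' cost matrix is written as `EXPLICIT` / `FULL_MATRIX`.
#'
#' @param instance A `tsp_instance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsplib <- function(instance, path) {
  n <- instance$n_cities
  if (!is.null(instance$coords)) {
    lines <- c(sprintf("NAME: %s", instance$name), "TYPE: TSP",
               sprintf("DIMENSION: %d", n), "EDGE_WEIGHT_TYPE: EUC_2D",
               "NODE_COORD_SECTION",
               sprintf("%d %.12g %.12g", seq_len(n),
                       instance$coords[, 1], instance$coords[, 2]),
               "EOF")
  } else {
    lines <- c(sprintf("NAME: %s", instance$name),
               sprintf("TYPE: %s", if (instance$symmetric) "TSP" else "ATSP"),
               sprintf("DIMENSION: %d", n), "EDGE_WEIGHT_TYPE: EXPLICIT",
               "EDGE_WEIGHT_FORMAT: FULL_MATRIX", "EDGE_WEIGHT_SECTION",
               apply(instance$costs, 1, paste, collapse = " "),
               "EOF")
  }
  writeLines(lines, path)
  invisible(path)
}
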