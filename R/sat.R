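#' Boolean formula in conjunctive normal form
#'
#' @param n_vars Number of Boolean variables.
#' @param clauses List of integer vectors of signed literals (`v` for
#'   variable v, `-v` for its negation); no clause may reference a variable
#'   twice.
#' @return A `cnf_formula`.
#' @export
cnf_formula <- function(n_vars, clauses) {
  clauses <- lapply(clauses, as.integer)
  for (cl in clauses) {
    if (!length(cl) || any(cl == 0) || any(abs(cl) > n_vars))
      stop("literal out of range")
    if (anyDuplicated(abs(cl))) stop("clause references a variable twice")
  }
  structure(list(n_vars = as.integer(n_vars), clauses = clauses),
            class = "cnf_formula")
}

#' @export
print.cnf_formula <- function(x, ...) {
  cat(sprintf("<cnf_formula> %d variables, %d clauses\n",
              x$n_vars, length(x$clauses)))
  invisible(x)
}

#' Number of clauses satisfied by a complete assignment
#' @param formula A `cnf_formula`.
#' @param values Logical vector of variable values.
#' @return Integer count of satisfied clauses.
#' @export
count_satisfied <- function(formula, values) {
  sum(vapply(formula$clauses, function(cl) {
    any(values[abs(cl)] == (cl > 0))
  }, logical(1)))
}

#' Default parameters of the SAT network construction
#'
#' @param temp_control Attach the internal temperature-control circuitry.
#' @param ... Overrides for `b_wta`, `b_inh`, `w_wta`, `w_exc`, `B`,
#'   `w_or1`, `w_or2`, `b_glob`, `w_glob`.
#' @return Named parameter list.
#' @export
sat_params <- function(temp_control = FALSE, ...) {
  p <- list(b_wta = 2, b_inh = -10, w_wta = -100, w_exc = 100,
            B = 40, w_or1 = 2.5, w_or2 = 10, b_glob = 10, w_glob = 0.5,
            temp_control = temp_control)
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Compile a k-SAT formula into a spiking network
#'
#' Each Boolean variable becomes a 2-principal WTA circuit (neurons for the
#' FALSE and TRUE value); each clause becomes an OR motif over the principal
#' neurons whose activity makes its literals true, raising the energy of
#' states that violate the clause, so that the network energy of a fully
#' defined state is proportional to the number of violated clauses.  With
#' `temp_control` the internal temperature-control circuitry
#' ([add_temperature_control()]) is added on top.
#'
#' @param formula A `cnf_formula` with clauses of length >= 2.
#' @param params Parameter list from [sat_params()].
#' @return A `neural_network` with readout metadata in `net$metadata$sat`.
#' @export
compile_sat <- function(formula, params = sat_params()) {
  N <- formula$n_vars
  M <- length(formula$clauses)
  if (!M) stop("empty formula")
  if (any(vapply(formula$clauses, length, integer(1)) < 2))
    stop("clauses must have at least 2 literals")
  net <- neural_network()
  # principal layout: variable n -> neuron 2n-1 (value FALSE), 2n (value TRUE)
  net <- add_neurons(net, 2L * N, bias = params$b_wta, principal = TRUE,
                     label = paste0("v", rep(seq_len(N), each = 2),
                                    c("_0", "_1")))
  lit_neuron <- function(lit) {
    # principal neuron whose activity makes the literal true
    if (lit > 0) 2L * lit else -2L * lit - 1L
  }
  for (n in seq_len(N))
    net <- add_wta(net, c(2L * n - 1L, 2L * n), b_wta = NULL,
                   b_inh = params$b_inh, w_wta = params$w_wta,
                   w_exc = params$w_exc, name = paste0("x", n))
  clause_ids <- lapply(formula$clauses,
                       function(cl) vapply(cl, lit_neuron, integer(1)))
  for (ids in clause_ids)
    net <- add_or(net, ids, B = params$B, w_or = params$w_or1)
  if (isTRUE(params$temp_control))
    net <- add_temperature_control(net, clause_ids,
                                   B = params$B, w_or2 = params$w_or2,
                                   b_glob = params$b_glob,
                                   w_glob = params$w_glob)
  var_of <- rep(NA_integer_, n_neurons(net))
  val_of <- rep(NA_integer_, n_neurons(net))
  var_of[seq_len(2 * N)] <- rep(seq_len(N), each = 2)
  val_of[seq_len(2 * N)] <- rep(c(0L, 1L), N)
  net$metadata$sat <- list(formula = formula, var_of = var_of,
                           val_of = val_of, clause_ids = clause_ids,
                           params = params)
  validate_network(net)
  net
}

#' Read out the variable assignment at a time point
#'
#' A variable is TRUE (FALSE) iff exactly its TRUE (FALSE) principal neuron
#' is currently active; it is undefined (`NA`) when neither or both are.  A
#' clause counts as satisfied iff at least one principal neuron matching
#' one of its literals is active, so the satisfied fraction is well defined
#' even while variables are undefined.
#'
#' @param traj A `spike_trajectory` of a SAT-compiled network.
#' @param t Readout time.
#' @return An `assignment_readout`: list with `values` (TRUE/FALSE/`NA` per
#'   variable), `satisfied_clauses` and `fraction`.
#' @export
read_assignment <- function(traj, t) {
  map <- traj$network$metadata$sat
  if (is.null(map)) stop("network has no SAT readout metadata")
  N <- map$formula$n_vars
  x <- state_at(traj, t, ids = seq_len(2L * N))
  on0 <- x[seq(1, 2 * N, by = 2)] == 1
  on1 <- x[seq(2, 2 * N, by = 2)] == 1
  values <- rep(NA, N)
  values[on1 & !on0] <- TRUE
  values[on0 & !on1] <- FALSE
  sat <- vapply(map$clause_ids, function(ids) any(x[ids] == 1), logical(1))
  structure(list(values = values, satisfied_clauses = sum(sat),
                 fraction = mean(sat)),
            class = "assignment_readout")
}

#' @export
print.assignment_readout <- function(x, ...) {
  cat(sprintf("<assignment_readout> %d clauses satisfied (%.1f%%), %d undefined vars\n",
              x$satisfied_clauses, 100 * x$fraction, sum(is.na(x$values))))
  invisible(x)
}

#' Satisfied-clause trace over a trajectory
#'
#' Number of satisfied clauses after every state change, under
#' currently-active readout semantics.
#'
#' @param traj A `spike_trajectory` or `gibbs_trajectory` of a SAT-compiled
#'   network.
#' @return Data frame with `time`, `satisfied` and `fraction` columns (one
#'   row per state change).
#' @export
sat_trace <- function(traj) {
  net <- traj$network
  map <- net$metadata$sat
  if (is.null(map)) stop("network has no SAT readout metadata")
  ch <- if (inherits(traj, "gibbs_trajectory")) gibbs_state_changes(traj)
        else state_change_times(traj)
  M <- length(map$formula$clauses)
  K <- max(vapply(map$formula$clauses, length, integer(1)))
  cl_var <- matrix(-1L, M, K)
  cl_val <- matrix(0L, M, K)
  for (m in seq_len(M)) {
    cl <- map$formula$clauses[[m]]
    cl_var[m, seq_along(cl)] <- abs(cl) - 1L
    cl_val[m, seq_along(cl)] <- as.integer(cl > 0)
  }
  var_of <- ifelse(is.na(map$var_of), -1L, map$var_of - 1L)
  val_of <- ifelse(is.na(map$val_of), 0L, map$val_of)
  cnt <- sat_count_trace_cpp(as.integer(ch$neuron) - 1L,
                             as.integer(ch$direction),
                             as.integer(var_of), as.integer(val_of),
                             map$formula$n_vars, cl_var, cl_val)
  data.frame(time = ch$time, satisfied = cnt, fraction = cnt / M)
}

#' Satisfied fraction at requested times
#'
#' @param traj Trajectory of a SAT-compiled network.
#' @param times Numeric vector of readout times.
#' @return Data frame with `time` and `fraction` (0 before any activity).
#' @export
performance_trace_sat <- function(traj, times) {
  tr <- sat_trace(traj)
  idx <- findInterval(times, tr$time)
  frac <- ifelse(idx == 0, 0, tr$fraction[pmax(idx, 1)])
  data.frame(time = times, fraction = frac)
}

#' First time all clauses are satisfied
#'
#' @param traj Trajectory of a SAT-compiled network.
#' @return Solve time in seconds, or `NA` if the formula is never fully
#'   satisfied within the trajectory.
#' @export
solve_time <- function(traj) {
  tr <- sat_trace(traj)
  M <- length(traj$network$metadata$sat$formula$clauses)
  hit <- which(tr$satisfied == M)
  if (!length(hit)) return(NA_real_)
  tr$time[hit[1]]
}

#' Time-weighted mean satisfied fraction over a window
#'
#' @param traj Trajectory of a SAT-compiled network.
#' @param from,to Window bounds in seconds (clipped to the trajectory).
#' @return Mean fraction in `[0, 1]`.
#' @export
mean_satisfied_fraction <- function(traj, from = 0, to = traj$t_end) {
  tr <- sat_trace(traj)
  to <- min(to, traj$t_end)
  if (to <= from) stop("empty window")
  times <- c(0, tr$time, traj$t_end)
  frac <- c(0, tr$fraction, if (nrow(tr)) tr$fraction[nrow(tr)] else 0)
  starts <- times[-length(times)]
  ends <- times[-1]
  w <- pmax(0, pmin(ends, to) - pmax(starts, from))
  sum(w * frac[-length(frac)]) / sum(w)
}

#' Generate a uniform random k-SAT formula
#'
#' Each clause samples `k` distinct variables uniformly without replacement
#' with independent random polarities.  With `require_satisfiable` formulas
#' are rejection-sampled until the complete solver finds a witness.
#'
#' @param n_vars Number of variables (>= 3).
#' @param ratio Clause-to-variable ratio; `m = round(ratio * n_vars)`
#'   (half away from zero).  Ignored when `m` is given.
#' @param m Number of clauses (overrides `ratio`).
#' @param seed Integer seed.
#' @param require_satisfiable Rejection-sample satisfiable formulas
#'   (requires `n_vars` within the solver cap).
#' @param k Literals per clause.
#' @return A `cnf_formula`.
#' @export
generate_random_3sat <- function(n_vars, ratio = 4.3, m = NULL, seed = 1,
                                 require_satisfiable = FALSE, k = 3) {
  if (n_vars < 3) stop("need at least 3 variables")
  if (is.null(m)) m <- floor(ratio * n_vars + 0.5)  # round half away from zero
  m <- as.integer(m)
  if (require_satisfiable && n_vars > 40)
    stop("satisfiability filtering capped at 40 variables")
  set.seed(as.integer(seed))
  repeat {
    clauses <- lapply(seq_len(m), function(i) {
      vars <- sample.int(n_vars, k)
      sign <- sample(c(-1L, 1L), k, replace = TRUE)
      vars * sign
    })
    f <- cnf_formula(n_vars, clauses)
    if (!require_satisfiable || complete_solver(f)$satisfiable) return(f)
  }
}

#' Complete SAT solver (DPLL with unit propagation)
#'
#' Exact satisfiability decision used as the oracle for generated formulas;
#' any witness is verified against the formula before being returned.
#'
#' @param formula A `cnf_formula`.
#' @param cap Maximum number of variables accepted (tractability guard).
#' @return List with `satisfiable` (logical) and `assignment` (logical
#'   vector, or `NULL` for UNSAT).
#' @export
complete_solver <- function(formula, cap = 40) {
  if (formula$n_vars > cap) stop("formula exceeds solver cap")
  n <- formula$n_vars
  clauses <- formula$clauses

  dpll <- function(assign) {
    # unit propagation
    repeat {
      unit <- 0L
      for (cl in clauses) {
        vals <- assign[abs(cl)] * sign(cl)  # 1 satisfied, -1 falsified, 0 free
        if (any(vals == 1)) next
        free <- cl[vals == 0]
        if (!length(free)) return(NULL)      # conflict
        if (length(free) == 1 && unit == 0L) unit <- free[1]
      }
      if (unit == 0L) break
      assign[abs(unit)] <- sign(unit)
    }
    v <- which(assign == 0L)[1]
    if (is.na(v)) return(assign)
    for (s in c(1L, -1L)) {
      a2 <- assign
      a2[v] <- s
      res <- dpll(a2)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  res <- dpll(integer(n))
  if (is.null(res)) return(list(satisfiable = FALSE, assignment = NULL))
  values <- res == 1L
  stopifnot(count_satisfied(formula, values) == length(clauses))
  list(satisfiable = TRUE, assignment = values)
}

#' Read / write DIMACS CNF files
#'
#' @param path File path.
#' @return `read_dimacs()` returns a `cnf_formula`; `write_dimacs()` returns
#'   `path` invisibly.
#' @export
read_dimacs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^c", lines) & nzchar(trimws(lines))]
  hdr <- grep("^p cnf", lines)
  if (!length(hdr)) stop("missing 'p cnf' header")
  spec <- scan(text = sub("^p cnf", "", lines[hdr[1]]), quiet = TRUE)
  n <- as.integer(spec[1]); m <- as.integer(spec[2])
  nums <- scan(text = paste(lines[-seq_len(hdr[1])], collapse = "\n"),
               quiet = TRUE)
  ends <- which(nums == 0)
  if (length(ends) != m)
    stop(sprintf("clause count mismatch: header says %d, found %d",
                 m, length(ends)))
  starts <- c(1, head(ends, -1) + 1)
  clauses <- mapply(function(a, b) as.integer(nums[a:(b - 1)]),
                    starts, ends, SIMPLIFY = FALSE)
  cnf_formula(n, clauses)
}

#' @param formula A `cnf_formula`.
#' @rdname read_dimacs
#' @export
write_dimacs <- function(formula, path) {
  lines <- c(sprintf("p cnf %d %d", formula$n_vars, length(formula$clauses)),
             vapply(formula$clauses,
                    function(cl) paste(c(cl, 0L), collapse = " "),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}
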