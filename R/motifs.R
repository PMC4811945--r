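#' Attach a winner-take-all (WTA) motif
#'
#' Adds one inhibitory auxiliary neuron that is excited by every listed
#' principal neuron (weight `w_exc`) and inhibits all of them back (weight
#' `w_wta`).  Its bias `b_inh` is low, so inhibition is triggered only by a
#' principal spike; the motif lowers the energy of states in which exactly
#' one group member is active, making the group behave as a multinomial
#' problem variable.
#'
#' @param net A `neural_network`.
#' @param ids Principal neuron ids forming the group.
#' @param b_wta Bias assigned to the group's principal neurons, or `NULL`
#'   to leave individual biases untouched.
#' @param b_inh Bias of the inhibitory auxiliary neuron.
#' @param w_wta Inhibition strength (auxiliary to principal, < 0).
#' @param w_exc Excitation strength (principal to auxiliary, > 0).
#' @param name Group label; defaults to `"wta<g>"`.
#' @return The network with one auxiliary neuron, `2 * length(ids)` synapses
#'   and a registered WTA group added.
#' @export
add_wta <- function(net, ids, b_wta = NULL, b_inh = -10,
                    w_wta = -100, w_exc = 100, name = NULL) {
  if (!(w_wta < 0 && w_exc > 0)) stop("need w_wta < 0 < w_exc")
  ids <- as.integer(ids)
  if (!all(ids %in% principal_ids(net)))
    stop("WTA members must be existing principal neurons")
  if (is.null(name)) name <- paste0("wta", length(net$wta_groups) + 1L)
  net <- register_wta_group(net, name, ids)  # errors on overlap
  if (!is.null(b_wta)) net <- set_bias(net, ids, b_wta)
  net <- add_neurons(net, 1, bias = b_inh, principal = FALSE,
                     label = paste0("inh_", name))
  aux <- attr(net, "new_ids")
  net <- add_synapses(net, pre = ids, post = aux, weight = w_exc, type = "wta_exc")
  net <- add_synapses(net, pre = aux, post = ids, weight = w_wta, type = "wta_inh")
  attr(net, "aux_id") <- aux
  net
}

#' Attach an OR motif
#'
#' Adds two auxiliary neurons that raise the energy of states in which none
#' of the target principal neurons is active, so that most of the time at
#' least one target fires (a disjunctive clause constraint).  Auxiliary
#' neuron I (bias `0.5 * B`) excites the targets with weight `w_or` and is
#' suppressed (weight `-B`) as soon as any target is active; auxiliary
#' neuron II (bias `-3.5 * B`) curtails the excitation once a target fires:
#' it receives `3 * B` from I and `B` from each target and inhibits the
#' targets with `-w_or`.
#'
#' @param net A `neural_network`.
#' @param ids Two or more principal neuron ids (the clause's true-literal
#'   neurons).
#' @param B Scale constant of the motif (> 0).
#' @param w_or Excitation strength delivered to the targets.
#' @return The network with 2 auxiliary neurons and `4 * length(ids) + 1`
#'   synapses added.
#' @export
add_or <- function(net, ids, B = 40, w_or = 2.5) {
  if (B <= 0) stop("B must be positive")
  ids <- as.integer(ids)
  if (length(ids) < 2) stop("OR motif needs at least 2 targets")
  if (!all(ids %in% net$neurons$id)) stop("unknown target neuron")
  net <- add_neurons(net, 2, bias = c(0.5 * B, -3.5 * B), principal = FALSE,
                     label = c("or_I", "or_II"))
  aux <- attr(net, "new_ids")
  I <- aux[1]; II <- aux[2]
  net <- add_synapses(net, pre = I, post = ids, weight = w_or, type = "or")
  net <- add_synapses(net, pre = ids, post = I, weight = -B, type = "or")
  net <- add_synapses(net, pre = II, post = ids, weight = -w_or, type = "or")
  net <- add_synapses(net, pre = ids, post = II, weight = B, type = "or")
  net <- add_synapses(net, pre = I, post = II, weight = 3 * B, type = "or")
  attr(net, "aux_ids") <- aux
  net
}

#' Attach an internal temperature-control mechanism
#'
#' Implements spike-based rescaling of the energy landscape
#' (\eqn{E_T(x) = E(x)/T}): each clause's OR motif is duplicated with
#' stronger weights (`w_or2`, auxiliary neurons III and IV), gated by a
#' global temperature-control neuron.  One status neuron per clause fires
#' only when all of the clause's literals are set to the wrong values and
#' then silences the global neuron; while all clauses are satisfied the
#' global neuron stays active, the duplicated OR motifs become functional
#' and every principal neuron receives an extra drive `w_glob`, locking the
#' network into the found solution (low-temperature regime).
#'
#' The global neuron runs with a slightly shorter on-state window and
#' refractory period than its outgoing PSPs, so its gating input to III/IV
#' bridges its own refractory gaps.
#'
#' @param net A `neural_network` whose clauses were attached with [add_or()].
#' @param clause_ids List of integer vectors: per clause, the same principal
#'   ids that were passed to [add_or()].
#' @param negation_ids Per clause, the principal neurons encoding the
#'   negated literal values; if `NULL`, derived as each target's partners in
#'   its WTA group.
#' @param B Scale constant (matching the OR motifs).
#' @param w_or2 Excitation strength of the duplicated (low-temperature) OR
#'   motifs; the difference to the first-stage `w_or` sets the temperature
#'   contrast.
#' @param b_glob Bias of the global temperature-control neuron.
#' @param w_glob Weight from the global neuron to every principal neuron.
#' @param w_status Weight from each status neuron to the global neuron;
#'   must silence it on its own (default `-3 * B`).
#' @param global_refractory,global_tau Refractory period and on-state
#'   window of the global neuron (seconds).
#' @param global_psp PSP duration of the global neuron's synapses onto the
#'   duplicated OR neurons (seconds; longer than its refractory period).
#' @return The network with `3 * length(clause_ids) + 1` neurons added.
#' @export
add_temperature_control <- function(net, clause_ids, negation_ids = NULL,
                                    B = 40, w_or2 = 10, b_glob = 10,
                                    w_glob = 0.5, w_status = -3 * B,
                                    global_refractory = 0.009,
                                    global_tau = 0.009,
                                    global_psp = 0.011) {
  if (B <= 0) stop("B must be positive")
  if (is.null(negation_ids)) {
    negation_ids <- lapply(clause_ids, function(ids) {
      vapply(ids, function(id) {
        g <- Filter(function(grp) id %in% grp, net$wta_groups)
        if (!length(g)) stop("clause target not in any WTA group")
        other <- setdiff(g[[1]], id)
        if (length(other) != 1)
          stop("cannot derive negation neuron for groups of size != 2")
        other
      }, integer(1))
    })
  }
  stopifnot(length(negation_ids) == length(clause_ids))
  prins <- principal_ids(net)

  net <- add_neurons(net, 1, bias = b_glob, psp_duration = global_tau,
                     refractory = global_refractory, principal = FALSE,
                     label = "temp_global")
  glob <- attr(net, "new_ids")
  if (length(prins))
    net <- add_synapses(net, pre = glob, post = prins, weight = w_glob,
                        psp_duration = 0.010, type = "temp_glob_prin")

  for (m in seq_along(clause_ids)) {
    ids <- as.integer(clause_ids[[m]])
    negs <- as.integer(negation_ids[[m]])
    net <- add_neurons(net, 2, bias = c(-0.5 * B, -6.5 * B), principal = FALSE,
                       label = c("or_III", "or_IV"))
    aux <- attr(net, "new_ids")
    III <- aux[1]; IV <- aux[2]
    net <- add_synapses(net, pre = III, post = ids, weight = w_or2, type = "temp_or")
    net <- add_synapses(net, pre = ids, post = III, weight = -B, type = "temp_or")
    net <- add_synapses(net, pre = IV, post = ids, weight = -w_or2, type = "temp_or")
    net <- add_synapses(net, pre = ids, post = IV, weight = B, type = "temp_or")
    net <- add_synapses(net, pre = III, post = IV, weight = 3 * B, type = "temp_or")
    net <- add_synapses(net, pre = glob, post = c(III, IV), weight = c(B, 3 * B),
                        psp_duration = global_psp, type = "temp_gate")
    net <- add_neurons(net, 1, bias = -2.5 * B, principal = FALSE,
                       label = "status")
    status <- attr(net, "new_ids")
    net <- add_synapses(net, pre = negs, post = status, weight = B,
                        type = "status_in")
    net <- add_synapses(net, pre = status, post = glob, weight = w_status,
                        type = "status_glob")
  }
  attr(net, "global_id") <- glob
  net
}
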