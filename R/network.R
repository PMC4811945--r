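#' Create an empty spiking network specification
#'
#' A `neural_network` holds neurons (with bias, PSP duration and refractory
#' period), directed weighted synapses (with optional transmission delay and
#' per-synapse PSP duration), a principal/auxiliary role per neuron, and a
#' registry of winner-take-all (WTA) groups over principal neurons.  Neuron
#' ids are consecutive integers starting at 1.
#'
#' @return An object of class `neural_network`.
#' @seealso [add_neurons()], [add_synapses()], [add_wta()]
#' @export
neural_network <- function() {
  structure(list(
    neurons = data.frame(id = integer(), bias = numeric(),
                         psp_duration = numeric(), refractory = numeric(),
                         principal = logical(), label = character(),
                         stringsAsFactors = FALSE),
    synapses = data.frame(pre = integer(), post = integer(), weight = numeric(),
                          delay = numeric(), psp_duration = numeric(),
                          type = character(), stringsAsFactors = FALSE),
    wta_groups = list(),
    metadata = list()
  ), class = "neural_network")
}

#' Add neurons to a network
#'
#' @param net A `neural_network`.
#' @param n Number of neurons to add.
#' @param bias Intrinsic excitability \eqn{b_k} (log-intensity units); recycled.
#' @param psp_duration Duration \eqn{\tau} (seconds) of the rectangular PSP a
#'   spike of this neuron produces, and of its own on-state window.
#' @param refractory Absolute refractory period in seconds; defaults to
#'   `psp_duration`.
#' @param principal Logical; principal neurons form the computational
#'   interface of the network, auxiliary neurons shape its energy function.
#' @param label Optional character label, recycled.
#' @return The network with `n` new neurons; their ids are
#'   `n_neurons(net) + seq_len(n)` (also stored in `attr(, "new_ids")`).
#' @export
add_neurons <- function(net, n, bias = 0, psp_duration = 0.010,
                        refractory = psp_duration, principal = TRUE,
                        label = NA_character_) {
  stopifnot(inherits(net, "neural_network"), n >= 1)
  if (any(psp_duration <= 0)) stop("psp_duration must be positive")
  if (any(refractory <= 0)) stop("refractory period must be positive")
  ids <- nrow(net$neurons) + seq_len(n)
  net$neurons <- rbind(net$neurons, data.frame(
    id = ids, bias = rep_len(bias, n),
    psp_duration = rep_len(psp_duration, n),
    refractory = rep_len(refractory, n),
    principal = rep_len(principal, n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE))
  attr(net, "new_ids") <- ids
  net
}

#' Add directed synapses to a network
#'
#' Each synapse carries a weight \eqn{w_{kl}} (postsynaptic effect of a
#' presynaptic spike for the PSP duration), a transmission delay, and a PSP
#' duration that defaults to the presynaptic neuron's own.
#'
#' @param net A `neural_network`.
#' @param pre,post Integer vectors of pre- and postsynaptic neuron ids.
#' @param weight Synaptic weights, recycled.
#' @param delay Transmission delay in seconds (>= 0), recycled.
#' @param psp_duration PSP duration in seconds, or `NULL` for the presynaptic
#'   neuron's default.
#' @param type Free-form tag used by the compilers for bookkeeping.
#' @return The network with the synapses appended.
#' @export
add_synapses <- function(net, pre, post, weight, delay = 0,
                         psp_duration = NULL, type = "generic") {
  stopifnot(inherits(net, "neural_network"))
  n <- max(length(pre), length(post), length(weight))
  pre <- rep_len(as.integer(pre), n)
  post <- rep_len(as.integer(post), n)
  nn <- nrow(net$neurons)
  if (any(pre < 1 | pre > nn) || any(post < 1 | post > nn))
    stop("synapse endpoints must reference existing neurons")
  if (any(pre == post)) stop("self-connections are not allowed")
  delay <- rep_len(delay, n)
  if (any(delay < 0)) stop("delays must be non-negative")
  psp <- if (is.null(psp_duration)) net$neurons$psp_duration[pre]
         else rep_len(psp_duration, n)
  if (any(psp <= 0)) stop("psp_duration must be positive")
  net$synapses <- rbind(net$synapses, data.frame(
    pre = pre, post = post, weight = rep_len(weight, n),
    delay = delay, psp_duration = psp,
    type = rep_len(type, n), stringsAsFactors = FALSE))
  net
}

#' Number of neurons / synapses in a network
#' @param net A `neural_network`.
#' @return Integer count.
#' @export
n_neurons <- function(net) nrow(net$neurons)

#' @rdname n_neurons
#' @export
n_synapses <- function(net) nrow(net$synapses)

#' Ids of principal neurons
#' @param net A `neural_network`.
#' @return Integer vector of neuron ids.
#' @export
principal_ids <- function(net) net$neurons$id[net$neurons$principal]

#' Set neuron biases
#' @param net A `neural_network`.
#' @param ids Neuron ids.
#' @param bias New bias values, recycled.
#' @return The modified network.
#' @export
set_bias <- function(net, ids, bias) {
  stopifnot(all(ids %in% net$neurons$id))
  net$neurons$bias[ids] <- rep_len(bias, length(ids))
  net
}

#' Register a WTA group of principal neurons
#'
#' WTA groups label disjoint sets of principal neurons that together encode a
#' multinomial problem variable (defined when exactly one member is active).
#'
#' @param net A `neural_network`.
#' @param name Group label.
#' @param ids Member neuron ids (must be principal and unused by other groups).
#' @return The modified network.
#' @export
register_wta_group <- function(net, name, ids) {
  ids <- as.integer(ids)
  if (!all(ids %in% principal_ids(net)))
    stop("WTA group members must be principal neurons")
  if (any(ids %in% unlist(net$wta_groups)))
    stop("neuron already belongs to a WTA group")
  net$wta_groups[[name]] <- ids
  net
}

#' Synaptic weight lookup
#'
#' Returns the total weight of synapses from `pre` to `post` (0 if absent).
#'
#' @param net A `neural_network`.
#' @param pre,post Neuron ids (scalars).
#' @return Numeric weight.
#' @export
synaptic_weight <- function(net, pre, post) {
  sel <- net$synapses$pre == pre & net$synapses$post == post
  if (!any(sel)) 0 else sum(net$synapses$weight[sel])
}

#' Dense weight matrix over a set of neurons
#'
#' @param net A `neural_network`.
#' @param ids Neuron ids defining rows/columns; defaults to all neurons.
#' @return Matrix `W` with `W[k, l]` the weight of the synapse from `ids[l]`
#'   to `ids[k]` (0 where absent).
#' @export
weight_matrix <- function(net, ids = net$neurons$id) {
  n <- length(ids)
  W <- matrix(0, n, n)
  pos <- match(seq_len(nrow(net$neurons)), ids)
  syn <- net$synapses
  keep <- !is.na(pos[syn$pre]) & !is.na(pos[syn$post])
  syn <- syn[keep, , drop = FALSE]
  if (nrow(syn)) {
    idx <- cbind(pos[syn$post], pos[syn$pre])
    # accumulate (multiple synapses between a pair sum)
    for (i in seq_len(nrow(syn))) W[idx[i, 1], idx[i, 2]] <- W[idx[i, 1], idx[i, 2]] + syn$weight[i]
  }
  W
}

#' Validate network invariants
#'
#' Checks endpoint validity, positivity of time constants, absence of
#' self-connections and disjointness of WTA groups.
#'
#' @param net A `neural_network`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "neural_network"))
  nn <- nrow(net$neurons)
  if (nn && !identical(net$neurons$id, seq_len(nn)))
    stop("neuron ids must be 1..n")
  if (any(net$neurons$psp_duration <= 0) || any(net$neurons$refractory <= 0))
    stop("time constants must be positive")
  s <- net$synapses
  if (nrow(s)) {
    if (any(s$pre < 1 | s$pre > nn | s$post < 1 | s$post > nn))
      stop("dangling synapse endpoint")
    if (any(s$pre == s$post)) stop("self-connection present")
    if (any(s$delay < 0)) stop("negative delay")
  }
  g <- unlist(net$wta_groups)
  if (anyDuplicated(g)) stop("WTA groups overlap")
  if (length(g) && !all(g %in% principal_ids(net)))
    stop("WTA group member is not a principal neuron")
  invisible(TRUE)
}

#' @export
print.neural_network <- function(x, ...) {
  cat(sprintf("<neural_network> %d neurons (%d principal), %d synapses, %d WTA groups\n",
              n_neurons(x), sum(x$neurons$principal), n_synapses(x),
              length(x$wta_groups)))
  invisible(x)
}

#' Serialize a network to JSON
#'
#' @param net A `neural_network`.
#' @param path File path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
write_network_json <- function(net, path = NULL) {
  # metadata may hold classed helper objects (formulas, parameter sets);
  # serialize them as plain lists
  strip_classes <- function(x) {
    if (is.data.frame(x) || !is.list(x)) return(x)
    lapply(x, strip_classes)
  }
  obj <- list(neurons = net$neurons, synapses = net$synapses,
              wta_groups = net$wta_groups,
              metadata = strip_classes(net$metadata))
  js <- jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a network from JSON written by [write_network_json()]
#' @param path File path or JSON string.
#' @return A `neural_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  net <- neural_network()
  net$neurons <- as.data.frame(obj$neurons, stringsAsFactors = FALSE)
  net$synapses <- as.data.frame(obj$synapses, stringsAsFactors = FALSE)
  if (nrow(net$neurons)) net$neurons$id <- as.integer(net$neurons$id)
  if (nrow(net$synapses)) {
    net$synapses$pre <- as.integer(net$synapses$pre)
    net$synapses$post <- as.integer(net$synapses$post)
  }
  net$wta_groups <- lapply(obj$wta_groups, as.integer)
  net$metadata <- obj$metadata
  validate_network(net)
  net
}
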