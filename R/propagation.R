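# Recursive signal propagation along circuits.
#
# The signal reaching node n is
#   S_n = v_n * (1 - prod_{a in A}(1 - s_a)) * prod_{i in I}(1 - s_i)
# where v_n is the node's normalized expression proxy in [0,1], A the signals
# arriving through activation edges and I those arriving through inhibition
# edges. Receptors (circuit in-degree 0) receive the constant incoming signal
# 1, so S_receptor = v_receptor. Acyclic circuits are evaluated exactly in a
# single topological pass; circuits with feedback loops by Jacobi fixed-point
# iteration from zero.

#' Propagation configuration
#'
#' @param tol Convergence tolerance (max per-node signal change) for
#'   fixed-point iteration on cyclic circuits.
#' @param max_iter Iteration cap; hitting it raises a non-convergence warning
#'   and the result is returned flagged.
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(tol = 1e-6, max_iter = 1000L) {
  stopifnot(is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter), init = "zeros"),
            class = "propagation_config")
}

#' Signal emitted by a single node
#'
#' Evaluates `v * (1 - prod(1 - activations)) * prod(1 - inhibitions)`.
#' An empty inhibition set contributes a factor of 1. An empty activation set
#' yields 0 (no incoming signal), unless `source = TRUE`, which models a
#' receptor whose incoming signal is the constant 1, so the result is
#' `v * prod(1 - inhibitions)`.
#'
#' @param v Node value in `[0, 1]` (normalized expression proxy).
#' @param activations Numeric vector of incoming activation signals in `[0, 1]`.
#' @param inhibitions Numeric vector of incoming inhibition signals in `[0, 1]`.
#' @param source Is this node a signal source (receptor)?
#' @return Signal intensity in `[0, 1]`.
#' @export
node_signal <- function(v, activations = numeric(), inhibitions = numeric(),
                        source = length(activations) == 0L && length(inhibitions) == 0L) {
  vals <- c(v, activations, inhibitions)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    sig_abort("node_signal inputs must lie in [0, 1]", "domain_error")
  }
  act <- if (source) 1 else 1 - prod(1 - activations)
  v * act * prod(1 - inhibitions)
}

# Per-circuit precomputation: member index, incoming activation/inhibition
# lists, source flags and (when acyclic) a topological order.
.circuit_plan <- function(circuit) {
  nodes <- circuit$member_nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  e <- circuit$member_edges
  act_in <- lapply(nodes, function(n) unname(idx[e$source[e$target == n & e$sign == "activation"]]))
  inh_in <- lapply(nodes, function(n) unname(idx[e$source[e$target == n & e$sign == "inhibition"]]))
  indeg <- lengths(act_in) + lengths(inh_in)
  ig <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                      directed = TRUE, vertices = nodes)
  dag <- igraph::is_dag(ig)
  order <- if (dag) match(names(igraph::topo_sort(ig, mode = "out")), nodes) else NULL
  list(nodes = nodes, idx = idx, act_in = act_in, inh_in = inh_in,
       source = indeg == 0L, dag = dag, order = order,
       effector = unname(idx[circuit$effector]))
}

# Evaluate all samples of one circuit at once. v: member-nodes x samples.
.propagate_values <- function(plan, v, config) {
  n <- length(plan$nodes)
  ns <- ncol(v)
  prod_rows <- function(S, rows) {
    # prod over rows of (1 - S[rows, ]), per sample
    if (length(rows) == 0L) return(rep_len(1, ns))
    if (length(rows) == 1L) return(1 - S[rows, ])
    apply(1 - S[rows, , drop = FALSE], 2, prod)
  }
  step_node <- function(S, i) {
    act <- if (plan$source[i]) 1 else 1 - prod_rows(S, plan$act_in[[i]])
    v[i, ] * act * prod_rows(S, plan$inh_in[[i]])
  }
  if (plan$dag) {
    S <- matrix(0, n, ns)
    for (i in plan$order) S[i, ] <- step_node(S, i)
    return(list(S = S, converged = TRUE, iterations = 1L))
  }
  # Jacobi iteration from zeros (receptors fixed at v from the first sweep)
  S <- matrix(0, n, ns)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    S_new <- matrix(0, n, ns)
    for (i in seq_len(n)) S_new[i, ] <- step_node(S, i)
    delta <- max(abs(S_new - S))
    S <- S_new
    if (delta < config$tol) { converged <- TRUE; break }
  }
  list(S = S, converged = converged, iterations = it)
}

#' Propagate signal through one circuit
#'
#' @param circuit A circuit from [extract_circuits()].
#' @param node_values Nodes x samples matrix in `[0, 1]` (rownames must cover
#'   the circuit's member nodes), e.g. from [compute_node_values()].
#' @param config A [propagation_config()].
#' @return Named numeric vector of effector signal intensities, one per
#'   sample, with attributes `converged` (logical) and `iterations`.
#' @export
propagate_circuit <- function(circuit, node_values,
                              config = propagation_config()) {
  stopifnot(inherits(circuit, "circuit"), is.matrix(node_values))
  missing <- setdiff(circuit$member_nodes, rownames(node_values))
  if (length(missing) > 0L) {
    sig_abort(sprintf("node value(s) missing for circuit %s: %s",
                      circuit$circuit_id, paste(missing, collapse = ", ")),
              "domain_error")
  }
  v <- node_values[circuit$member_nodes, , drop = FALSE]
  if (any(v < 0 | v > 1)) {
    sig_abort("node values must lie in [0, 1]", "domain_error")
  }
  plan <- .circuit_plan(circuit)
  res <- .propagate_values(plan, v, config)
  if (!res$converged) {
    sig_warn(sprintf("circuit %s did not converge within %d iterations (tol %g)",
                     circuit$circuit_id, config$max_iter, config$tol),
             "non_convergence_warning")
  }
  out <- res$S[plan$effector, ]
  names(out) <- colnames(node_values)
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  out
}

#' Propagate signal through all circuits
#'
#' Each circuit is evaluated independently for every sample; results do not
#' depend on evaluation order.
#'
#' @param circuits List of circuits (one pathway's [extract_circuits()] output,
#'   or any list of circuits whose member nodes appear in `node_values`).
#' @param node_values Nodes x samples matrix in `[0, 1]`.
#' @param config A [propagation_config()].
#' @return Circuits x samples activity matrix with circuit IDs as rownames and
#'   attribute `non_converged` (circuit IDs that hit the iteration cap).
#' @export
propagate_all <- function(circuits, node_values,
                          config = propagation_config()) {
  if (length(circuits) == 0L) {
    sig_abort("empty circuit list", "domain_error")
  }
  non_conv <- character()
  rows <- lapply(circuits, function(circ) {
    s <- withCallingHandlers(
      propagate_circuit(circ, node_values, config),
      non_convergence_warning = function(w) {
        non_conv <<- c(non_conv, circ$circuit_id)
        invokeRestart("muffleWarning")
      }
    )
    as.numeric(s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(circuits, `[[`, character(1), "circuit_id")
  colnames(out) <- colnames(node_values)
  if (length(non_conv) > 0L) {
    sig_warn(sprintf("%d circuit(s) did not converge: %s", length(non_conv),
                     paste(non_conv, collapse = ", ")),
             "non_convergence_warning")
  }
  attr(out, "non_converged") <- non_conv
  out
}

#' Circuit activities for a set of pathways
#'
#' Convenience pipeline step: for each pathway, compute node values from the
#' rescaled expression matrix, extract circuits and propagate; stack all
#' pathways' activities into one matrix. Row order follows pathway order, then
#' each pathway's circuit order — deterministic for identical inputs.
#'
#' @param matrix Expression matrix rescaled to `[0, 1]`.
#' @param pathways List of [pathway_graph()] objects.
#' @param aggregator Node aggregation rule, see [compute_node_values()].
#' @param config A [propagation_config()].
#' @return Circuits x samples activity matrix with attributes `non_converged`
#'   and `circuits` (the flattened circuit list).
#' @export
circuit_activities <- function(matrix, pathways,
                               aggregator = "percentile90",
                               config = propagation_config()) {
  all_circuits <- list()
  blocks <- list()
  non_conv <- character()
  for (pw in pathways) {
    circuits <- extract_circuits(pw)
    if (length(circuits) == 0L) next
    nv <- compute_node_values(matrix, pw, aggregator = aggregator)
    act <- withCallingHandlers(
      propagate_all(circuits, nv, config),
      non_convergence_warning = function(w) invokeRestart("muffleWarning")
    )
    non_conv <- c(non_conv, attr(act, "non_converged"))
    blocks[[length(blocks) + 1L]] <- act
    all_circuits <- c(all_circuits, circuits)
  }
  if (length(blocks) == 0L) {
    sig_abort("no circuits could be extracted from the supplied pathways",
              "domain_error")
  }
  out <- do.call(rbind, blocks)
  if (length(non_conv) > 0L) {
    sig_warn(sprintf("%d circuit(s) did not converge", length(non_conv)),
             "non_convergence_warning")
  }
  attr(out, "non_converged") <- non_conv
  attr(out, "circuits") <- all_circuits
  out
}
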