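# Signed pathway topologies and receptor->effector circuit extraction.

#' Construct a pathway graph
#'
#' A pathway is a directed graph whose nodes house one or more genes (the
#' expression proxies of the corresponding proteins) and whose edges carry a
#' sign: `activation` or `inhibition`. The constructor validates the topology
#' (see [validate_pathway()]) and stores the cleaned graph.
#'
#' @param pathway_id Short identifier, used to prefix circuit IDs.
#' @param nodes Data frame with columns `node_id`, `label` (optional, defaults
#'   to `node_id`) and `genes` — either a list column of character vectors or a
#'   character column of comma-separated gene IDs. Gene lists must be
#'   non-empty; duplicate gene IDs within a node are collapsed.
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (`"activation"` or `"inhibition"`).
#'
#' @return An object of class `pathway_graph` with elements `pathway_id`,
#'   `nodes` (data frame with a `genes` list column), `edges` and
#'   `diagnostics` (the validation report).
#' @export
pathway_graph <- function(pathway_id, nodes, edges) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L, nzchar(pathway_id))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("node_id", "genes") %in% names(nodes))) {
    sig_abort("`nodes` must have columns node_id and genes", "malformed_pathway_error")
  }
  if (nrow(edges) > 0 && !all(c("source", "target", "sign") %in% names(edges))) {
    sig_abort("`edges` must have columns source, target, sign", "malformed_pathway_error")
  }
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) {
    sig_abort(
      sprintf("duplicate node IDs in pathway '%s'", pathway_id),
      "malformed_pathway_error"
    )
  }
  if (is.null(nodes$label)) nodes$label <- nodes$node_id
  nodes$label <- ifelse(is.na(nodes$label) | !nzchar(nodes$label),
                        nodes$node_id, as.character(nodes$label))
  if (!is.list(nodes$genes)) {
    nodes$genes <- strsplit(as.character(nodes$genes), ",", fixed = TRUE)
  }
  nodes$genes <- lapply(nodes$genes, function(g) unique(trimws(as.character(g))))
  empty <- vapply(nodes$genes, function(g) length(g) == 0L || all(!nzchar(g)), logical(1))
  if (any(empty)) {
    sig_abort(
      sprintf("node(s) %s carry no genes", paste(nodes$node_id[empty], collapse = ", ")),
      "malformed_pathway_error"
    )
  }
  if (nrow(edges) > 0) {
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.character(edges$sign)
    bad_sign <- !edges$sign %in% c("activation", "inhibition")
    if (any(bad_sign)) {
      sig_abort(
        sprintf("unknown edge sign(s): %s", paste(unique(edges$sign[bad_sign]), collapse = ", ")),
        "malformed_pathway_error"
      )
    }
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  g <- structure(
    list(pathway_id = pathway_id, nodes = nodes, edges = edges,
         diagnostics = NULL),
    class = "pathway_graph"
  )
  cleaned <- .clean_pathway(g)
  cleaned
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges (%d inhibition)\n",
              x$pathway_id, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "inhibition")))
  invisible(x)
}

# Apply the validation rules, mutating the graph: self-loops removed,
# duplicate edges collapsed (first sign kept), dangling edges fatal.
.clean_pathway <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  diags <- list()
  note <- function(level, code, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      level = level, code = code, message = message, stringsAsFactors = FALSE
    )
  }

  known <- nodes$node_id
  dangling <- !(edges$source %in% known) | !(edges$target %in% known)
  if (any(dangling)) {
    sig_abort(
      sprintf("pathway '%s': edge(s) reference undeclared node(s): %s",
              graph$pathway_id,
              paste(unique(c(edges$source, edges$target)[
                !(c(edges$source, edges$target) %in% known)]), collapse = ", ")),
      "malformed_pathway_error"
    )
  }

  loops <- edges$source == edges$target
  if (any(loops)) {
    note("info", "self_loop_removed",
         sprintf("removed %d self-loop edge(s): %s", sum(loops),
                 paste(edges$source[loops], collapse = ", ")))
    edges <- edges[!loops, , drop = FALSE]
  }

  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    for (k in unique(key[duplicated(key)])) {
      signs <- unique(edges$sign[key == k])
      pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
      if (length(signs) > 1) {
        note("warning", "edge_sign_conflict",
             sprintf("conflicting signs on duplicate edge %s->%s; kept first (%s)",
                     pair[1], pair[2], edges$sign[key == k][1]))
      } else {
        note("warning", "duplicate_edge",
             sprintf("duplicate edge %s->%s collapsed", pair[1], pair[2]))
      }
    }
    edges <- edges[first, , drop = FALSE]
  }

  deg_out <- table(factor(edges$source, levels = known))
  deg_in <- table(factor(edges$target, levels = known))
  isolated <- known[deg_out == 0 & deg_in == 0]
  if (length(isolated) > 0) {
    note("warning", "isolated_node",
         sprintf("isolated node(s) excluded from roles: %s",
                 paste(isolated, collapse = ", ")))
  }

  rownames(edges) <- NULL
  graph$edges <- edges
  graph$diagnostics <- if (length(diags)) do.call(rbind, diags) else
    data.frame(level = character(), code = character(), message = character(),
               stringsAsFactors = FALSE)
  graph
}

#' Validate a pathway graph
#'
#' Reports the cleaning diagnostics recorded at construction time: removed
#' self-loops, collapsed duplicate edges (with a warning on sign conflicts)
#' and isolated nodes. Dangling edge references are fatal at construction.
#'
#' @param graph A [pathway_graph()].
#' @return Data frame of diagnostics with columns `level`, `code`, `message`.
#' @export
validate_pathway <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  graph$diagnostics
}

.igraph_of <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target", "sign")],
    directed = TRUE,
    vertices = graph$nodes$node_id
  )
}

#' Identify receptor and effector nodes
#'
#' Receptors are the signal-entry nodes: nodes with no incoming edges.
#' Effectors are the terminal nodes that trigger cell functions: nodes with no
#' outgoing edges. Isolated nodes (no edges at all) take part in neither role.
#'
#' @param graph A [pathway_graph()].
#' @return List with character vectors `receptors` and `effectors`.
#' @export
identify_roles <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- graph$nodes$node_id
  deg_in <- table(factor(graph$edges$target, levels = ids))
  deg_out <- table(factor(graph$edges$source, levels = ids))
  connected <- deg_in > 0 | deg_out > 0
  receptors <- ids[deg_in == 0 & connected]
  effectors <- ids[deg_out == 0 & connected]
  if (length(receptors) == 0L || length(effectors) == 0L) {
    sig_abort(
      sprintf("pathway '%s' has no %s; cannot define circuits",
              graph$pathway_id,
              if (length(receptors) == 0L) "receptor (in-degree-0 node)"
              else "effector (out-degree-0 node)"),
      "empty_role_error"
    )
  }
  list(receptors = receptors, effectors = effectors)
}

#' Extract receptor-to-effector circuits
#'
#' One circuit is defined per effector: the subgraph of all nodes lying on a
#' directed route from any receptor to that effector, together with the edges
#' induced among them. Nodes inside feedback loops are retained whenever the
#' loop lies on a receptor-to-effector walk (reachability is evaluated on the
#' full graph, which is equivalent to reachability on the condensation of its
#' strongly connected components). Effectors not reachable from any receptor
#' are dropped with a warning.
#'
#' @param graph A [pathway_graph()].
#' @return List of `circuit` objects, one per retained effector, in the order
#'   effectors appear in the node table. Each circuit has elements
#'   `circuit_id` (`"<pathway_id>:<effector label>"`), `pathway_id`,
#'   `effector`, `effector_label`, `receptors`, `member_nodes`, `member_edges`
#'   and `node_genes` (named list of member gene vectors).
#' @export
extract_circuits <- function(graph) {
  roles <- identify_roles(graph)
  ig <- .igraph_of(graph)
  ids <- graph$nodes$node_id

  # nodes reachable from any receptor (walk semantics, so cycles included)
  from_receptors <- unique(unlist(lapply(
    roles$receptors,
    function(r) names(igraph::subcomponent(ig, r, mode = "out"))
  )))

  labels <- stats::setNames(graph$nodes$label, graph$nodes$node_id)
  genes <- stats::setNames(graph$nodes$genes, graph$nodes$node_id)
  eff_labels <- labels[roles$effectors]
  use_label <- !anyDuplicated(eff_labels)

  circuits <- list()
  for (eff in roles$effectors[order(match(roles$effectors, ids))]) {
    to_eff <- names(igraph::subcomponent(ig, eff, mode = "in"))
    members <- intersect(intersect(from_receptors, to_eff), ids)
    recs <- intersect(roles$receptors, members)
    if (length(recs) == 0L) {
      sig_warn(
        sprintf("pathway '%s': effector '%s' unreachable from any receptor; circuit dropped",
                graph$pathway_id, eff),
        "circuit_dropped_warning"
      )
      next
    }
    keep <- graph$edges$source %in% members & graph$edges$target %in% members
    medges <- graph$edges[keep, , drop = FALSE]
    rownames(medges) <- NULL
    cid <- sprintf("%s:%s", graph$pathway_id,
                   if (use_label) labels[[eff]] else eff)
    members <- ids[ids %in% members]  # deterministic node-table order
    circuits[[length(circuits) + 1L]] <- structure(
      list(
        circuit_id = cid,
        pathway_id = graph$pathway_id,
        effector = eff,
        effector_label = labels[[eff]],
        receptors = recs,
        member_nodes = members,
        member_edges = medges,
        node_genes = genes[members]
      ),
      class = "circuit"
    )
  }
  circuits
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit> %s: %d nodes, %d edges, receptors: %s\n",
              x$circuit_id, length(x$member_nodes), nrow(x$member_edges),
              paste(x$receptors, collapse = ", ")))
  invisible(x)
}

#' Tabulate circuits
#'
#' @param circuits List of circuits from [extract_circuits()].
#' @return Data frame with columns `circuit_id`, `pathway_id`, `effector`,
#'   `receptors` (comma-joined), `n_nodes`, `n_edges`.
#' @export
circuit_table <- function(circuits) {
  data.frame(
    circuit_id = vapply(circuits, `[[`, character(1), "circuit_id"),
    pathway_id = vapply(circuits, `[[`, character(1), "pathway_id"),
    effector = vapply(circuits, `[[`, character(1), "effector"),
    receptors = vapply(circuits, function(x) paste(x$receptors, collapse = ","), character(1)),
    n_nodes = vapply(circuits, function(x) length(x$member_nodes), integer(1)),
    n_edges = vapply(circuits, function(x) nrow(x$member_edges), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Nodes that cut every receptor-to-effector path of a circuit
#'
#' A node is a cut node if removing it disconnects the effector from every
#' receptor within the circuit subgraph. Zeroing the value of such a node
#' annihilates the circuit's signal; the effector and a sole receptor are
#' always cut nodes.
#'
#' @param circuit A circuit from [extract_circuits()].
#' @return Character vector of cut node IDs.
#' @export
circuit_cut_nodes <- function(circuit) {
  stopifnot(inherits(circuit, "circuit"))
  e <- circuit$member_edges
  Filter(function(node) {
    if (node == circuit$effector) return(TRUE)
    if (setequal(circuit$receptors, node)) return(TRUE)
    keep <- e$source != node & e$target != node
    ig <- igraph::graph_from_data_frame(
      e[keep, c("source", "target")], directed = TRUE,
      vertices = setdiff(circuit$member_nodes, node)
    )
    for (r in setdiff(circuit$receptors, node)) {
      if (circuit$effector %in% names(igraph::subcomponent(ig, r, mode = "out"))) {
        return(FALSE)
      }
    }
    TRUE
  }, circuit$member_nodes)
}

# All genes housed by any node of any pathway in a list of pathway graphs.
pathway_gene_universe <- function(pathways) {
  unique(unlist(lapply(pathways, function(p) unlist(p$nodes$genes))))
}
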