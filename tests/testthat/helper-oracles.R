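# Independent oracles and small fixture builders shared across test files.

# Build a pathway from a compact edge spec, one gene per node named g<node>.
toy_pathway <- function(edges, pathway_id = "TOY", genes = NULL) {
  ids <- unique(c(edges$source, edges$target))
  if (is.null(genes)) genes <- lapply(ids, function(n) paste0("g", n))
  pathway_graph(
    pathway_id,
    nodes = data.frame(node_id = ids, label = ids, genes = I(genes),
                       stringsAsFactors = FALSE),
    edges = edges
  )
}

edge_df <- function(source, target, sign = "activation") {
  data.frame(source = source, target = target, sign = sign,
             stringsAsFactors = FALSE)
}

# Brute-force circuit membership for DAGs: union of nodes/edges over all
# simple receptor -> effector paths, enumerated exhaustively.
oracle_circuit_members <- function(graph, effector) {
  roles <- identify_roles(graph)
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("source", "target")], directed = TRUE,
    vertices = graph$nodes$node_id
  )
  nodes <- character()
  ekeys <- character()
  for (r in roles$receptors) {
    paths <- igraph::all_simple_paths(ig, from = r, to = effector, mode = "out")
    for (p in paths) {
      nm <- names(p)
      nodes <- union(nodes, nm)
      if (length(nm) > 1) {
        ekeys <- union(ekeys, paste(nm[-length(nm)], nm[-1], sep = "->"))
      }
    }
  }
  list(nodes = sort(nodes), edges = sort(ekeys))
}

# Independent straight-line evaluation of the propagation recursion on an
# acyclic circuit: memoized depth-first recursion over the member edges.
oracle_propagate <- function(circuit, v) {
  e <- circuit$member_edges
  memo <- new.env(parent = emptyenv())
  eval_node <- function(n) {
    if (!is.null(memo[[n]])) return(memo[[n]])
    acts <- e$source[e$target == n & e$sign == "activation"]
    inhs <- e$source[e$target == n & e$sign == "inhibition"]
    s <- if (length(acts) + length(inhs) == 0L) {
      v[[n]]  # receptor: incoming signal is the constant 1
    } else {
      a <- if (length(acts)) 1 - prod(1 - vapply(acts, eval_node, numeric(1))) else 0
      i <- if (length(inhs)) prod(1 - vapply(inhs, eval_node, numeric(1))) else 1
      v[[n]] * a * i
    }
    memo[[n]] <- s
    s
  }
  eval_node(circuit$effector)
}

# Does removing `node` cut every receptor -> effector path of the circuit?
is_cut_node <- function(circuit, node) {
  if (node == circuit$effector) return(TRUE)
  if (setequal(circuit$receptors, node)) return(TRUE)
  e <- circuit$member_edges
  keep <- e$source != node & e$target != node
  ig <- igraph::graph_from_data_frame(
    e[keep, c("source", "target")], directed = TRUE,
    vertices = setdiff(circuit$member_nodes, node)
  )
  for (r in setdiff(circuit$receptors, node)) {
    reach <- names(igraph::subcomponent(ig, r, mode = "out"))
    if (circuit$effector %in% reach) return(FALSE)
  }
  TRUE
}

# Random node-value matrix for a circuit's members (values in [0,1]).
random_node_values <- function(circuit, n_samples = 1L) {
  m <- matrix(stats::runif(length(circuit$member_nodes) * n_samples),
              nrow = length(circuit$member_nodes),
              dimnames = list(circuit$member_nodes,
                              paste0("s", seq_len(n_samples))))
  m
}

# Null multi-pathway panel: many small pathways with disjoint gene universes
# sharing one expression matrix of 2 * n_per_group samples drawn from one
# generator (no group effect).
make_null_panel <- function(seed, n_pathways = 120L, n_per_group = 10L,
                            n_nodes = 6L) {
  pathways <- lapply(seq_len(n_pathways), function(i) {
    make_pathway(fixture_config(
      seed = seed + i, n_nodes = n_nodes, n_samples = 2L * n_per_group,
      edge_density = 0.4, inhibition_fraction = 0.2,
      pathway_id = sprintf("NP%03d", i)
    ))
  })
  mats <- lapply(seq_along(pathways), function(i) {
    make_expression(fixture_config(seed = seed + i,
                                   n_samples = 2L * n_per_group,
                                   pathway_id = pathways[[i]]$pathway_id),
                    pathways[[i]])
  })
  mat <- do.call(rbind, mats)
  design <- data.frame(
    sample_id = colnames(mat),
    group = rep(c("control", "case"), each = n_per_group),
    stringsAsFactors = FALSE
  )
  list(pathways = pathways, matrix = mat, design = design)
}
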