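# Deterministic synthetic generators: random signed pathway topologies,
# log-normal expression matrices (optionally with a two-group LoF effect
# injected) and multi-tissue control panels. Every generator is a pure
# function of its configuration, including the seed, so identical configs
# yield byte-identical files.

#' Fixture generator configuration
#'
#' @param seed Integer RNG seed; identical configurations produce identical
#'   outputs.
#' @param n_nodes Number of pathway nodes.
#' @param n_genes_per_node Genes housed by each node.
#' @param n_samples Samples per group / tissue.
#' @param edge_density Probability of each forward edge in the random DAG.
#' @param inhibition_fraction Probability that an edge is inhibitory.
#' @param cycle Add one feedback edge closing a loop?
#' @param effect Optional injected perturbation: list with `gene` (or `genes`)
#'   and `factor`; used by [make_expression()] to build a two-group matrix in
#'   which group B carries the loss of function.
#' @param pathway_id Pathway identifier; also prefixes generated gene IDs so
#'   multiple generated pathways have disjoint gene universes.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_nodes = 10L, n_genes_per_node = 1L,
                           n_samples = 10L, edge_density = 0.3,
                           inhibition_fraction = 0.2, cycle = FALSE,
                           effect = NULL, pathway_id = "PW1") {
  stopifnot(n_nodes >= 2, n_genes_per_node >= 1, n_samples >= 1,
            edge_density > 0, edge_density < 1,
            inhibition_fraction >= 0, inhibition_fraction <= 1)
  structure(
    list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
         n_genes_per_node = as.integer(n_genes_per_node),
         n_samples = as.integer(n_samples), edge_density = edge_density,
         inhibition_fraction = inhibition_fraction, cycle = isTRUE(cycle),
         effect = effect, pathway_id = pathway_id),
    class = "fixture_config"
  )
}

#' Generate a random signed pathway
#'
#' Draws a random DAG over `n_nodes` ordered nodes (forward edges sampled
#' independently with probability `edge_density`, so at least one source and
#' one sink always exist), assigns edge signs by `inhibition_fraction` and
#' houses `n_genes_per_node` uniquely named genes per node. With
#' `cycle = TRUE` one extra feedback (backward) edge is added across an
#' existing forward edge, creating a loop on a receptor-to-effector walk.
#'
#' @param config A [fixture_config()].
#' @param dir If given, the pathway is also written as `.sif`/`.att` files
#'   (with the seed recorded in a comment header) under this directory.
#' @param max_retries Attempts to satisfy the structural constraints before
#'   failing.
#' @return A [pathway_graph()].
#' @export
make_pathway <- function(config, dir = NULL, max_retries = 100L) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    graph <- NULL
    for (try in seq_len(max_retries)) {
      n <- config$n_nodes
      ids <- sprintf("%s_N%02d", config$pathway_id, seq_len(n))
      pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < config$edge_density
      if (!any(keep)) next
      edges <- data.frame(
        source = ids[pairs[keep, "row"]],
        target = ids[pairs[keep, "col"]],
        stringsAsFactors = FALSE
      )
      edges$sign <- ifelse(stats::runif(nrow(edges)) < config$inhibition_fraction,
                           "inhibition", "activation")
      if (config$cycle) {
        # close a loop over one forward edge; keep it activating so
        # activation-only configurations stay activation-only
        k <- sample.int(nrow(edges), 1L)
        back <- data.frame(source = edges$target[k], target = edges$source[k],
                           sign = "activation", stringsAsFactors = FALSE)
        edges <- rbind(edges, back)
      }
      deg_in <- table(factor(edges$target, levels = ids))
      deg_out <- table(factor(edges$source, levels = ids))
      connected <- deg_in > 0 | deg_out > 0
      if (!any(deg_in == 0 & connected) || !any(deg_out == 0 & connected)) next
      nodes <- data.frame(node_id = ids, label = ids, stringsAsFactors = FALSE)
      nodes$genes <- lapply(seq_len(n), function(i) {
        sprintf("%s_G%03d", config$pathway_id,
                (i - 1L) * config$n_genes_per_node + seq_len(config$n_genes_per_node))
      })
      graph <- suppressWarnings(pathway_graph(config$pathway_id, nodes, edges))
      # require at least one extractable circuit
      ok <- tryCatch(length(suppressWarnings(extract_circuits(graph))) > 0L,
                     error = function(e) FALSE)
      if (ok) break
      graph <- NULL
    }
    if (is.null(graph)) {
      sig_abort("could not generate a pathway satisfying the constraints",
                "generation_error")
    }
    if (!is.null(dir)) {
      write_pathway(graph, dir, comment = sprintf("seed=%d", config$seed))
    }
    graph
  })
}

# Log-normal expression draws: per-gene baseline meanlog ~ N(2, 1),
# per-sample noise sdlog 0.5 around the baseline.
.draw_expression <- function(genes, samples, meanlog, sdlog = 0.5) {
  m <- matrix(
    stats::rlnorm(length(genes) * length(samples),
                  meanlog = rep(meanlog, times = length(samples)),
                  sdlog = sdlog),
    nrow = length(genes), ncol = length(samples),
    dimnames = list(genes, samples)
  )
  m
}

#' Generate a synthetic expression matrix for a pathway
#'
#' Gene values are log-normal (per-gene baseline meanlog drawn from N(2, 1),
#' per-sample noise sdlog 0.5). Without an `effect`, a single group of
#' `n_samples` columns (`S01`, ...) is produced. With `config$effect`, a
#' two-group matrix is produced: group A (`A01`, ...) and group B (`B01`,
#' ...), where group B carries the configured loss of function on the target
#' gene(s). By default group B samples are independent draws from the same
#' generator before the perturbation is applied (a case/control design);
#' `duplicate_groups = TRUE` instead copies group A and perturbs the copy (the
#' exact in-silico simulation semantics).
#'
#' @param config A [fixture_config()] (its `effect` field: list with
#'   `gene`/`genes` and `factor`).
#' @param graph A [pathway_graph()] supplying the gene universe.
#' @param duplicate_groups Make group B a perturbed copy of group A instead of
#'   independent draws.
#' @param extra_genes Number of additional background genes (`<pathway>_BG...`)
#'   outside the pathway.
#' @param path If given, the matrix is also written as CSV (seed in a comment
#'   header).
#' @return Genes x samples matrix with attribute `design` (data frame
#'   `sample_id`, `group`) when an effect is configured.
#' @export
make_expression <- function(config, graph, duplicate_groups = FALSE,
                            extra_genes = 0L, path = NULL) {
  stopifnot(inherits(config, "fixture_config"), inherits(graph, "pathway_graph"))
  genes <- unique(unlist(graph$nodes$genes))
  if (extra_genes > 0L) {
    genes <- c(genes, sprintf("%s_BG%03d", config$pathway_id, seq_len(extra_genes)))
  }
  with_seed(config$seed + 1L, {
    meanlog <- stats::rnorm(length(genes), mean = 2, sd = 1)
    design <- NULL
    if (is.null(config$effect)) {
      samples <- sprintf("S%02d", seq_len(config$n_samples))
      mat <- .draw_expression(genes, samples, meanlog)
    } else {
      a <- sprintf("A%02d", seq_len(config$n_samples))
      b <- sprintf("B%02d", seq_len(config$n_samples))
      mat_a <- .draw_expression(genes, a, meanlog)
      mat_b <- if (duplicate_groups) {
        mb <- mat_a
        colnames(mb) <- b
        mb
      } else {
        .draw_expression(genes, b, meanlog)
      }
      targets <- config$effect$genes %||% config$effect$gene
      factor <- config$effect$factor %||% 0.01
      spec <- perturbation_spec(targets, mode = "lof_scale", factor = factor)
      mat_b <- apply_perturbation(mat_b, spec)
      attr(mat_b, "resolved_targets") <- NULL
      mat <- cbind(mat_a, mat_b)
      design <- data.frame(sample_id = c(a, b),
                           group = rep(c("control", "case"),
                                       each = config$n_samples),
                           stringsAsFactors = FALSE)
    }
    if (!is.null(path)) {
      df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                       stringsAsFactors = FALSE)
      con <- file(path, "w", encoding = "UTF-8")
      writeLines(sprintf("# seed=%d", config$seed), con)
      utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
      close(con)
    }
    attr(mat, "design") <- design
    mat
  })
}

#' Generate a multi-tissue control panel
#'
#' `k` tissues sharing one gene universe (from `graph`), each with
#' `config$n_samples` control samples and a tissue-specific baseline shift
#' added to the per-gene meanlog.
#'
#' @param config A [fixture_config()].
#' @param graph A [pathway_graph()] supplying the gene universe.
#' @param k Number of tissues.
#' @param offsets Numeric vector (length `k`) of per-tissue baseline meanlog
#'   shifts; 0 for all tissues makes tissues statistically exchangeable.
#' @param dir If given, one CSV per tissue plus a `manifest.tsv`
#'   (`tissue<TAB>file`) are written.
#' @return Named list of expression matrices (tissue label -> matrix).
#' @export
make_tissue_panel <- function(config, graph, k = 3L,
                              offsets = seq(0, by = 0.5, length.out = k),
                              dir = NULL) {
  stopifnot(inherits(config, "fixture_config"), length(offsets) == k)
  genes <- unique(unlist(graph$nodes$genes))
  tissues <- sprintf("tissue%02d", seq_len(k))
  panel <- with_seed(config$seed + 2L, {
    meanlog <- stats::rnorm(length(genes), mean = 2, sd = 1)
    stats::setNames(lapply(seq_len(k), function(i) {
      samples <- sprintf("%s_S%02d", tissues[i], seq_len(config$n_samples))
      .draw_expression(genes, samples, meanlog + offsets[i])
    }), tissues)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(tissues, function(t) {
      p <- file.path(dir, paste0(t, ".csv"))
      df <- data.frame(gene_id = rownames(panel[[t]]), panel[[t]],
                       check.names = FALSE, stringsAsFactors = FALSE)
      con <- file(p, "w", encoding = "UTF-8")
      writeLines(sprintf("# seed=%d", config$seed), con)
      utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
      close(con)
      p
    }, character(1))
    .write_tsv(data.frame(tissue = tissues, file = basename(files),
                          stringsAsFactors = FALSE),
               file.path(dir, "manifest.tsv"))
  }
  panel
}

#' Read a tissue panel from a directory or manifest
#'
#' With a `manifest.tsv` (`tissue<TAB>file`) present it is used; otherwise
#' every `.csv`/`.tsv` file becomes a tissue named after the file.
#'
#' @param dir Panel directory.
#' @return Named list of expression matrices.
#' @export
read_tissue_panel <- function(dir) {
  manifest <- file.path(dir, "manifest.tsv")
  if (file.exists(manifest)) {
    df <- utils::read.table(manifest, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    files <- file.path(dir, df$file)
    names(files) <- df$tissue
  } else {
    files <- list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    names(files) <- sub("\\.(csv|tsv)$", "", basename(files))
  }
  if (length(files) == 0L) {
    sig_abort(sprintf("no tissue matrices found in %s", dir), "io_error")
  }
  lapply(files, read_expression)
}
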