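# Expression preprocessing: probe summarization, log transform, quantile
# truncation, quantile normalization and [0,1] rescaling, producing the
# node-value matrix consumed by signal propagation.
#
# The normalization steps can be fitted on a reference matrix and applied
# frozen to another matrix of the same genes (fit_normalization /
# apply_normalization). This matters for perturbation simulations: refitting
# on the perturbed matrix would leak the perturbation into untouched genes.

#' Summarize probe intensities into gene expression values
#'
#' Per gene and sample, the 90th percentile of the intensities of the probes
#' mapping uniquely to that gene. Probes mapping to more than one gene are
#' discarded, unless they are the only probes mapping to a gene, in which case
#' the gene value is the median of those probes.
#'
#' @param probe_matrix Numeric matrix, probes x samples, probe IDs as rownames.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`; a probe may
#'   appear on several rows (multi-gene mapping).
#' @return Numeric matrix, genes x samples.
#' @export
aggregate_probes <- function(probe_matrix, probe_map) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    sig_abort("probe_map needs columns probe_id and gene_id", "io_error")
  }
  probe_map <- probe_map[probe_map$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(probe_map) == 0L) {
    sig_abort("no probe maps to any gene", "empty_mapping_error")
  }
  n_genes <- tapply(probe_map$gene_id, probe_map$probe_id,
                    function(g) length(unique(g)))
  multi <- names(n_genes)[n_genes > 1L]
  uni_map <- probe_map[!probe_map$probe_id %in% multi, , drop = FALSE]

  genes <- unique(probe_map$gene_id)
  rows <- lapply(genes, function(g) {
    probes <- unique(uni_map$probe_id[uni_map$gene_id == g])
    if (length(probes) > 0L) {
      apply(probe_matrix[probes, , drop = FALSE], 2, stats::quantile,
            probs = 0.9, type = 7, names = FALSE)
    } else {
      # only multi-gene probes cover this gene: take their median
      probes <- unique(probe_map$probe_id[probe_map$gene_id == g])
      apply(probe_matrix[probes, , drop = FALSE], 2, stats::median)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- genes
  colnames(out) <- colnames(probe_matrix)
  out
}

# Map each column of x onto a sorted reference distribution by rank; ties get
# the mean of the reference values at their rank positions.
.qn_to_target <- function(x, target) {
  n <- length(target)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    if (nrow(x) == n) {
      lo <- floor(r); hi <- ceiling(r)
      out[, j] <- (target[lo] + target[hi]) / 2
    } else {
      out[, j] <- stats::approx(seq_len(n), target,
                                xout = 1 + (r - 1) * (n - 1) / (nrow(x) - 1),
                                rule = 2)$y
    }
  }
  out
}

#' Fit the normalization chain on a reference matrix
#'
#' Records, from the reference matrix: the global truncation bounds of the
#' log-transformed values (quantiles `q_low` / `q_high`), the reference
#' distribution of quantile normalization (the across-column means of the
#' column order statistics), and the rescaling bounds. The fitted model can be
#' applied to other matrices over the same genes with [apply_normalization()],
#' keeping their normalization anchored to the reference — essential when a
#' perturbed copy of the matrix must stay comparable to the original.
#'
#' @param matrix Numeric nonnegative genes x samples matrix.
#' @param q_low,q_high Truncation quantiles of the log-transformed matrix.
#' @param rescale `"global"` (single min-max over the whole matrix, default),
#'   `"per_gene"`, or `"none"`.
#' @return An object of class `normalization_model`.
#' @export
fit_normalization <- function(matrix, q_low = 0.01, q_high = 0.99,
                              rescale = c("global", "per_gene", "none")) {
  rescale <- match.arg(rescale)
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (any(!is.finite(matrix))) sig_abort("non-finite values", "domain_error")
  if (any(matrix < 0)) sig_abort("negative expression values", "domain_error")
  if (q_low < 0 || q_high > 1 || q_low >= q_high) {
    sig_abort("need 0 <= q_low < q_high <= 1", "domain_error")
  }
  l <- log1p(matrix)
  bounds <- stats::quantile(l, probs = c(q_low, q_high), type = 7, names = FALSE)
  lc <- pmin(pmax(l, bounds[1]), bounds[2])
  degenerate <- all(apply(lc, 2, function(col) max(col) - min(col) == 0))
  target <- if (degenerate) NULL else rowMeans(apply(lc, 2, sort))
  qn <- if (degenerate) lc else .qn_to_target(lc, target)

  scale_bounds <- switch(rescale,
    global = matrix(range(qn), nrow = 1),
    per_gene = t(apply(qn, 1, range)),
    none = NULL
  )
  structure(
    list(q_low = q_low, q_high = q_high, trunc_bounds = bounds,
         qn_target = target, degenerate = degenerate,
         rescale = rescale, scale_bounds = scale_bounds,
         genes = rownames(matrix)),
    class = "normalization_model"
  )
}

#' Apply a fitted normalization chain
#'
#' Applies, frozen: `log(x + 1)`, truncation at the fitted bounds, quantile
#' normalization onto the fitted reference distribution, and (if fitted)
#' rescaling with the fitted bounds, clamped to `[0, 1]`.
#'
#' @param model A [fit_normalization()] model.
#' @param matrix Numeric nonnegative matrix over the same genes (row order may
#'   differ; rows are matched by name when rownames are present).
#' @return Normalized matrix of the same shape.
#' @export
apply_normalization <- function(model, matrix) {
  stopifnot(inherits(model, "normalization_model"), is.matrix(matrix))
  if (any(matrix < 0)) sig_abort("negative expression values", "domain_error")
  l <- log1p(matrix)
  lc <- pmin(pmax(l, model$trunc_bounds[1]), model$trunc_bounds[2])
  if (model$degenerate) {
    sig_warn("all reference columns constant; quantile normalization skipped",
             "degenerate_matrix_warning")
    qn <- lc
  } else {
    qn <- .qn_to_target(lc, model$qn_target)
  }
  out <- switch(model$rescale,
    none = qn,
    global = {
      b <- model$scale_bounds[1, ]
      if (b[2] - b[1] == 0) {
        sig_warn("constant reference matrix; rescaling to 0.5",
                 "degenerate_matrix_warning")
        array(0.5, dim = dim(qn), dimnames = dimnames(qn))
      } else {
        pmin(pmax((qn - b[1]) / (b[2] - b[1]), 0), 1)
      }
    },
    per_gene = {
      idx <- if (!is.null(rownames(matrix)) && !is.null(model$genes)) {
        match(rownames(matrix), model$genes)
      } else {
        seq_len(nrow(matrix))
      }
      if (any(is.na(idx))) {
        sig_abort("matrix contains genes absent from the fitted model",
                  "domain_error")
      }
      lo <- model$scale_bounds[idx, 1]
      hi <- model$scale_bounds[idx, 2]
      span <- hi - lo
      res <- (qn - lo) / ifelse(span == 0, 1, span)
      res[span == 0, ] <- 0.5
      pmin(pmax(res, 0), 1)
    }
  )
  dimnames(out) <- dimnames(matrix)
  out
}

#' Log-transform, truncate at global quantiles, quantile-normalize
#'
#' Applies `log(x + 1)` elementwise, clamps values outside the global
#' `[q_low, q_high]` quantiles of the transformed matrix to those bounds, then
#' quantile-normalizes columns: each column's sorted values are replaced by
#' the across-column means of the order statistics, ties receiving the mean of
#' their rank positions. If every column is constant, normalization is the
#' identity and a warning is raised.
#'
#' @inheritParams fit_normalization
#' @return Transformed matrix of the same shape.
#' @export
log_truncate_quantile_normalize <- function(matrix, q_high = 0.99, q_low = 0.01) {
  model <- fit_normalization(matrix, q_low = q_low, q_high = q_high,
                             rescale = "none")
  apply_normalization(model, matrix)
}

#' Rescale a matrix to the unit interval
#'
#' Global mode maps the matrix minimum to 0 and maximum to 1 with a single
#' affine map; per-gene mode rescales each row independently. Constant input
#' (or constant rows in per-gene mode) maps to 0.5 with a warning.
#'
#' @param matrix Numeric finite matrix.
#' @param mode `"global"` (default) or `"per_gene"`.
#' @return Matrix with values in `[0, 1]`.
#' @export
rescale_unit_interval <- function(matrix, mode = c("global", "per_gene")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(matrix), all(is.finite(matrix)))
  if (mode == "global") {
    r <- range(matrix)
    if (r[2] - r[1] == 0) {
      sig_warn("constant matrix; rescaling to 0.5", "degenerate_matrix_warning")
      out <- array(0.5, dim = dim(matrix), dimnames = dimnames(matrix))
      return(out)
    }
    (matrix - r[1]) / (r[2] - r[1])
  } else {
    lo <- apply(matrix, 1, min)
    hi <- apply(matrix, 1, max)
    span <- hi - lo
    if (any(span == 0)) {
      sig_warn(sprintf("%d constant gene row(s); rescaled to 0.5", sum(span == 0)),
               "degenerate_matrix_warning")
    }
    out <- (matrix - lo) / ifelse(span == 0, 1, span)
    out[span == 0, ] <- 0.5
    out
  }
}

#' Full normalization chain in one call
#'
#' Convenience wrapper: fit on `matrix` and apply to it
#' (log -> truncate -> quantile-normalize -> rescale).
#'
#' @inheritParams fit_normalization
#' @return List with `values` (normalized matrix in `[0, 1]` unless
#'   `rescale = "none"`) and `model` (the fitted [fit_normalization()] object,
#'   reusable on perturbed matrices).
#' @export
normalize_expression <- function(matrix, q_low = 0.01, q_high = 0.99,
                                 rescale = c("global", "per_gene", "none")) {
  rescale <- match.arg(rescale)
  model <- fit_normalization(matrix, q_low = q_low, q_high = q_high,
                             rescale = rescale)
  list(values = suppressWarnings(apply_normalization(model, matrix)),
       model = model)
}

#' Compute per-node values from a rescaled expression matrix
#'
#' Each pathway node's value is an aggregate of its member genes' rows
#' (default: 90th percentile, mirroring the probe-to-gene summarization).
#' Nodes with no measured gene receive `missing_default` in every sample and
#' are recorded in the `defaulted_nodes` attribute.
#'
#' @param matrix Expression matrix already rescaled to `[0, 1]`.
#' @param graph A [pathway_graph()].
#' @param aggregator `"percentile90"` (default), `"mean"`, `"min"` or `"max"`.
#' @param missing_default Value assigned to nodes with zero measured genes.
#' @return Nodes x samples matrix in `[0, 1]` with attribute
#'   `defaulted_nodes` (character vector).
#' @export
compute_node_values <- function(matrix, graph,
                                aggregator = c("percentile90", "mean", "min", "max"),
                                missing_default = 0.5) {
  aggregator <- match.arg(aggregator)
  stopifnot(inherits(graph, "pathway_graph"), is.matrix(matrix))
  if (any(matrix < -1e-9 | matrix > 1 + 1e-9)) {
    sig_abort("expression matrix must be rescaled to [0,1] before node values",
              "domain_error")
  }
  agg <- switch(aggregator,
    percentile90 = function(m) apply(m, 2, stats::quantile, probs = 0.9,
                                     type = 7, names = FALSE),
    mean = function(m) colMeans(m),
    min = function(m) apply(m, 2, min),
    max = function(m) apply(m, 2, max)
  )
  defaulted <- character()
  rows <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    genes <- intersect(graph$nodes$genes[[i]], rownames(matrix))
    if (length(genes) == 0L) {
      defaulted <<- c(defaulted, graph$nodes$node_id[i])
      rep_len(missing_default, ncol(matrix))
    } else if (length(genes) == 1L) {
      matrix[genes, ]
    } else {
      agg(matrix[genes, , drop = FALSE])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- graph$nodes$node_id
  colnames(out) <- colnames(matrix)
  out <- pmin(pmax(out, 0), 1)
  attr(out, "defaulted_nodes") <- defaulted
  out
}
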