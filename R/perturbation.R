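# In-silico perturbation of gene expression: loss-of-function (scale by a
# small factor, paper default 0.01), total knockout / forced value, and
# over-expression. The perturbed matrix re-enters the normalization ->
# propagation chain with the normalization reference FITTED ON THE ORIGINAL
# matrix, so untouched genes stay on the same scale and the comparison is
# all-else-equal.

#' Perturbation specification
#'
#' @param targets Non-empty character vector of gene IDs (Entrez or HUGO) to
#'   perturb.
#' @param mode `"lof_scale"` (multiply target expression by `factor`, default
#'   0.01 — simulates a loss-of-function mutation), `"set_value"` (force
#'   target expression to `value`; 0 simulates a total loss of function), or
#'   `"overexpress"` (multiply by `factor` > 1).
#' @param factor Scaling factor; in `(0, 1]` for `lof_scale`, `> 1` for
#'   `overexpress`.
#' @param value Forced value in `[0, 1]` for `set_value`.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(targets,
                              mode = c("lof_scale", "set_value", "overexpress"),
                              factor = 0.01, value = 0) {
  mode <- match.arg(mode)
  targets <- unique(as.character(targets))
  if (length(targets) == 0L || any(!nzchar(targets))) {
    sig_abort("perturbation targets must be a non-empty gene list", "domain_error")
  }
  if (mode == "lof_scale" && (factor <= 0 || factor > 1)) {
    sig_abort("lof_scale factor must lie in (0, 1]", "domain_error")
  }
  if (mode == "overexpress" && factor <= 1) {
    sig_abort("overexpress factor must be > 1", "domain_error")
  }
  if (mode == "set_value" && (value < 0 || value > 1)) {
    sig_abort("set_value must lie in [0, 1]", "domain_error")
  }
  structure(list(targets = targets, mode = mode, factor = factor, value = value),
            class = "perturbation_spec")
}

#' Apply a perturbation to an expression matrix
#'
#' Returns a copy of the matrix with the target gene rows transformed in every
#' sample; all other rows are untouched. Targets absent from the matrix are
#' reported with a warning; if none resolves, an error is raised.
#'
#' @param matrix Genes x samples expression matrix with gene rownames.
#' @param spec A [perturbation_spec()].
#' @return Perturbed matrix with attribute `resolved_targets`.
#' @export
apply_perturbation <- function(matrix, spec) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            inherits(spec, "perturbation_spec"))
  hit <- spec$targets[spec$targets %in% rownames(matrix)]
  miss <- setdiff(spec$targets, hit)
  if (length(hit) == 0L) {
    sig_abort(sprintf("no perturbation target found in the matrix: %s",
                      paste(spec$targets, collapse = ", ")),
              "no_target_resolved_error")
  }
  if (length(miss) > 0L) {
    sig_warn(sprintf("perturbation target(s) not in the matrix: %s",
                     paste(miss, collapse = ", ")),
             "unresolved_target_warning")
  }
  out <- matrix
  out[hit, ] <- switch(spec$mode,
    lof_scale = matrix[hit, , drop = FALSE] * spec$factor,
    overexpress = matrix[hit, , drop = FALSE] * spec$factor,
    set_value = spec$value
  )
  attr(out, "resolved_targets") <- hit
  out
}

# Which circuits house at least one target gene in a member node.
.circuits_with_targets <- function(circuits, targets) {
  vapply(circuits, function(circ) {
    any(targets %in% unlist(circ$node_genes))
  }, logical(1))
}

#' Effect of a perturbation on circuit activities
#'
#' Runs the full chain twice — once on the original matrix and once on the
#' perturbed copy — reusing the normalization reference (truncation bounds,
#' quantile-normalization target distribution and rescaling bounds) fitted on
#' the ORIGINAL matrix for both, so any activity change is attributable to the
#' perturbation. Fold change is computed on the mean activity across samples;
#' per-sample activity matrices are also returned.
#'
#' @param matrix Raw (normalized upstream, nonnegative) expression matrix.
#' @param spec A [perturbation_spec()].
#' @param pathways List of [pathway_graph()] objects.
#' @param aggregator Node aggregation rule, see [compute_node_values()].
#' @param config A [propagation_config()].
#' @param epsilon Pseudo-count added to both means in the log2 fold change.
#' @return List with `table` (data frame: `circuit_id`, `mean_original`,
#'   `mean_perturbed`, `log2_fc`, `contains_target`), `activity_original`,
#'   `activity_perturbed` (circuits x samples matrices) and `model` (the
#'   shared [fit_normalization()] reference).
#' @export
perturbation_effect <- function(matrix, spec, pathways,
                                aggregator = "percentile90",
                                config = propagation_config(),
                                epsilon = 1e-10) {
  model <- fit_normalization(matrix)
  norm_orig <- apply_normalization(model, matrix)
  pert <- apply_perturbation(matrix, spec)
  norm_pert <- apply_normalization(model, pert)

  act_orig <- circuit_activities(norm_orig, pathways, aggregator, config)
  act_pert <- circuit_activities(norm_pert, pathways, aggregator, config)
  circuits <- attr(act_orig, "circuits")

  mo <- rowMeans(act_orig)
  mp <- rowMeans(act_pert)
  tab <- data.frame(
    circuit_id = rownames(act_orig),
    mean_original = mo,
    mean_perturbed = mp,
    log2_fc = log2((mp + epsilon) / (mo + epsilon)),
    contains_target = .circuits_with_targets(circuits, attr(pert, "resolved_targets")),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(table = tab, activity_original = act_orig, activity_perturbed = act_pert,
       model = model)
}

#' Variant-interpreter scenario: simulated LoF across a tissue panel
#'
#' For each tissue's control matrix, a case matrix is generated by simulating
#' the loss of function of the listed genes (multiplying their expression by
#' `lof_factor`) in all samples, circuit activities are computed for both
#' (sharing the tissue's normalization reference), and a per-circuit Wilcoxon
#' case/control contrast with FDR adjustment is performed. Failures in one
#' tissue are isolated: the tissue is reported in `errors` and the others are
#' still produced.
#'
#' @param panel Named list of control expression matrices (one per tissue).
#' @param genes Character vector of gene IDs carrying the simulated mutations.
#' @param pathways List of [pathway_graph()] objects.
#' @param lof_factor Expression multiplier simulating the loss of function.
#' @param fdr Significance threshold on the adjusted p-value for the summary.
#' @param aggregator,config Passed to the activity pipeline.
#' @return List with `results` (named list of [wilcoxon_contrast()] tables),
#'   `summary` (tissues x circuits matrix: -1 significant down, +1 significant
#'   up, 0 otherwise) and `errors` (named list of per-tissue error messages).
#' @export
variant_interpreter <- function(panel, genes, pathways, lof_factor = 0.01,
                                fdr = 0.05, aggregator = "percentile90",
                                config = propagation_config()) {
  stopifnot(is.list(panel), length(panel) > 0L, !is.null(names(panel)))
  spec <- perturbation_spec(genes, mode = "lof_scale", factor = lof_factor)
  results <- list()
  errors <- list()
  for (tissue in names(panel)) {
    res <- tryCatch({
      control <- panel[[tissue]]
      if (ncol(control) < 2L) {
        sig_abort(sprintf("tissue '%s' has fewer than 2 samples", tissue),
                  "design_error")
      }
      eff <- perturbation_effect(control, spec, pathways,
                                 aggregator = aggregator, config = config)
      case <- eff$activity_perturbed
      colnames(case) <- paste0(colnames(case), "_sim")
      activity <- cbind(eff$activity_original, case)
      design <- data.frame(
        sample_id = colnames(activity),
        group = rep(c("control", "case"), each = ncol(control)),
        stringsAsFactors = FALSE
      )
      wilcoxon_contrast(activity, design)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[tissue]] <- conditionMessage(res)
    } else {
      results[[tissue]] <- res
    }
  }
  summary <- NULL
  if (length(results) > 0L) {
    cids <- results[[1]]$circuit_id
    summary <- do.call(rbind, lapply(results, function(tab) {
      tab <- tab[match(cids, tab$circuit_id), ]
      ifelse(tab$fdr_p < fdr,
             ifelse(tab$direction == "up", 1L, -1L), 0L)
    }))
    colnames(summary) <- cids
    rownames(summary) <- names(results)
  }
  list(results = results, summary = summary, errors = errors)
}

#' Systematic loss-of-function scan over the pathway gene universe
#'
#' Simulates a LoF (expression times `lof_factor`) of every gene housed in any
#' pathway node and measured in the matrix, one gene at a time, and records
#' the log2 fold change of every circuit. Breadth counts, per gene, the
#' circuits across all loaded pathways whose |log2 FC| exceeds
#' `breadth_threshold` — genes affecting many circuits in many pathways are
#' candidates for broadly deleterious (often lethal-like) effects.
#'
#' @param matrix Expression matrix.
#' @param pathways List of [pathway_graph()] objects.
#' @param lof_factor Expression multiplier.
#' @param breadth_threshold Absolute log2 FC above which a circuit counts as
#'   affected.
#' @param aggregator,config Passed to the activity pipeline.
#' @return List with `impact` (genes x circuits matrix of log2 fold changes),
#'   `breadth` (named integer vector) and `skipped` (pathway genes absent from
#'   the matrix).
#' @export
lof_scan <- function(matrix, pathways, lof_factor = 0.01,
                     breadth_threshold = 0.5, aggregator = "percentile90",
                     config = propagation_config()) {
  universe <- pathway_gene_universe(pathways)
  genes <- intersect(universe, rownames(matrix))
  skipped <- setdiff(universe, genes)
  if (length(genes) == 0L) {
    sig_abort("no pathway gene is measured in the matrix",
              "no_target_resolved_error")
  }
  model <- fit_normalization(matrix)
  norm_orig <- apply_normalization(model, matrix)
  act_orig <- circuit_activities(norm_orig, pathways, aggregator, config)
  mo <- rowMeans(act_orig)
  eps <- 1e-10

  impact <- matrix(0, nrow = length(genes), ncol = nrow(act_orig),
                   dimnames = list(genes, rownames(act_orig)))
  for (g in genes) {
    spec <- perturbation_spec(g, mode = "lof_scale", factor = lof_factor)
    pert <- apply_perturbation(matrix, spec)
    norm_pert <- apply_normalization(model, pert)
    act_pert <- circuit_activities(norm_pert, pathways, aggregator, config)
    impact[g, ] <- log2((rowMeans(act_pert) + eps) / (mo + eps))
  }
  breadth <- apply(abs(impact) > breadth_threshold, 1, sum)
  list(impact = impact, breadth = breadth, skipped = skipped)
}
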