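# Differential signaling: per-circuit Wilcoxon rank-sum contrast with
# Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, preserving input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    sig_abort("p-values must lie in [0, 1]", "domain_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

.check_design <- function(design, samples, case_label, control_label) {
  stopifnot(is.data.frame(design), all(c("sample_id", "group") %in% names(design)))
  labs <- unique(design$group)
  if (!setequal(labs, c(case_label, control_label))) {
    sig_abort(sprintf("design groups must be exactly {%s, %s}; got {%s}",
                      case_label, control_label, paste(labs, collapse = ", ")),
              "design_error")
  }
  missing <- setdiff(design$sample_id, samples)
  if (length(missing) > 0L) {
    sig_abort(sprintf("design sample(s) absent from activity matrix: %s",
                      paste(missing, collapse = ", ")), "design_error")
  }
  case <- design$sample_id[design$group == case_label]
  control <- design$sample_id[design$group == control_label]
  if (length(case) < 2L || length(control) < 2L) {
    sig_abort("each group needs at least 2 samples", "design_error")
  }
  list(case = case, control = control)
}

#' Per-circuit Wilcoxon rank-sum contrast
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of circuit activity between
#' two groups, with BH adjustment across circuits. The exact null distribution
#' is used when the smaller group has fewer than `exact_threshold` samples
#' (falling back to the normal approximation in the presence of ties);
#' otherwise the normal approximation with continuity and tie correction.
#' Circuits with identical values in every sample of both groups are reported
#' with `p = 1` and direction `"none"`.
#'
#' @param activity Circuits x samples activity matrix.
#' @param design Data frame with columns `sample_id`, `group`.
#' @param case_label,control_label The two group labels; direction and effect
#'   are reported as case minus control.
#' @param exact_threshold Minimum group size at which the normal approximation
#'   replaces the exact distribution.
#' @return Data frame with columns `circuit_id`, `statistic` (rank-sum U of
#'   the case group), `p_value`, `fdr_p`, `direction` (`up`/`down`/`none`),
#'   `effect` (case median minus control median), `median_case`,
#'   `median_control`.
#' @export
wilcoxon_contrast <- function(activity, design,
                              case_label = "case", control_label = "control",
                              exact_threshold = 8L) {
  stopifnot(is.matrix(activity))
  grp <- .check_design(design, colnames(activity), case_label, control_label)
  res <- lapply(rownames(activity), function(cid) {
    x <- activity[cid, grp$case]
    y <- activity[cid, grp$control]
    med_x <- stats::median(x)
    med_y <- stats::median(y)
    if (max(c(x, y)) - min(c(x, y)) == 0) {
      stat <- length(x) * length(y) / 2
      p <- 1
    } else {
      exact <- min(length(x), length(y)) < exact_threshold
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE)
      )
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    effect <- med_x - med_y
    data.frame(
      circuit_id = cid,
      statistic = stat,
      p_value = p,
      direction = if (effect > 0) "up" else if (effect < 0) "down" else "none",
      effect = effect,
      median_case = med_x,
      median_control = med_y,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$fdr_p <- bh_adjust(out$p_value)
  out[, c("circuit_id", "statistic", "p_value", "fdr_p", "direction",
          "effect", "median_case", "median_control")]
}

#' Per-circuit, per-group descriptive summary
#'
#' @param activity Circuits x samples activity matrix.
#' @param design Data frame with columns `sample_id`, `group`.
#' @return Data frame with columns `circuit_id`, `group`, `median`, `mean`,
#'   `iqr`, one row per circuit and group.
#' @export
summarize_activity <- function(activity, design) {
  stopifnot(is.matrix(activity))
  labs <- unique(design$group)
  rows <- lapply(labs, function(g) {
    cols <- design$sample_id[design$group == g]
    missing <- setdiff(cols, colnames(activity))
    if (length(missing) > 0L) {
      sig_abort(sprintf("design sample(s) absent from activity matrix: %s",
                        paste(missing, collapse = ", ")), "design_error")
    }
    sub <- activity[, cols, drop = FALSE]
    data.frame(
      circuit_id = rownames(activity),
      group = g,
      median = apply(sub, 1, stats::median),
      mean = rowMeans(sub),
      iqr = apply(sub, 1, stats::IQR),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
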