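# Readers and writers for the plain-text dialects the pipelines consume:
# .sif/.att pathway pairs, expression matrices (CSV/TSV), design tables,
# gene lists and the TSV result tables. Lines starting with '#' are comments.

.read_lines_nocomment <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Read a pathway from a .sif/.att file pair
#'
#' The `.sif` file is tab-separated with no header: `source`, `relation`
#' (`activation` or `inhibition`), `target`. The `.att` file has one header
#' line and columns `node_id`, `label`, `genes` (comma-separated gene IDs).
#' Comment lines starting with `#` are ignored in both files.
#'
#' @param sif Path to the `.sif` edge file.
#' @param att Path to the `.att` node-attribute file; defaults to `sif` with
#'   the extension swapped.
#' @param pathway_id Identifier; defaults to the file base name.
#' @return A [pathway_graph()].
#' @export
read_pathway <- function(sif, att = sub("\\.sif$", ".att", sif),
                         pathway_id = sub("\\.sif$", "", basename(sif))) {
  if (!file.exists(sif)) sig_abort(sprintf("no such file: %s", sif), "io_error")
  if (!file.exists(att)) sig_abort(sprintf("no such file: %s", att), "io_error")

  sif_lines <- .read_lines_nocomment(sif)
  edges <- if (length(sif_lines)) {
    parts <- strsplit(sif_lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 3L
    if (any(bad)) {
      sig_abort(sprintf("%s: line(s) without 3 tab-separated fields: %s",
                        sif, paste(which(bad), collapse = ", ")), "io_error")
    }
    m <- do.call(rbind, parts)
    data.frame(source = m[, 1], sign = m[, 2], target = m[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), sign = character(), target = character(),
               stringsAsFactors = FALSE)
  }

  att_lines <- .read_lines_nocomment(att)
  if (length(att_lines) < 2L) {
    sig_abort(sprintf("%s: expected a header line plus at least one node", att),
              "io_error")
  }
  parts <- strsplit(att_lines[-1], "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    sig_abort(sprintf("%s: line(s) without 3 tab-separated fields: %s",
                      att, paste(which(bad) + 1L, collapse = ", ")), "io_error")
  }
  m <- do.call(rbind, parts)
  nodes <- data.frame(node_id = m[, 1], label = m[, 2], genes = m[, 3],
                      stringsAsFactors = FALSE)
  pathway_graph(pathway_id, nodes, edges[, c("source", "target", "sign")])
}

#' Read every .sif/.att pathway pair in a directory
#'
#' @param dir Directory containing `<id>.sif` / `<id>.att` pairs.
#' @return Named list of [pathway_graph()] objects, sorted by pathway ID.
#' @export
read_pathway_dir <- function(dir) {
  sifs <- sort(list.files(dir, pattern = "\\.sif$", full.names = TRUE))
  if (length(sifs) == 0L) {
    sig_abort(sprintf("no .sif files found in %s", dir), "io_error")
  }
  pathways <- lapply(sifs, read_pathway)
  names(pathways) <- vapply(pathways, `[[`, character(1), "pathway_id")
  pathways
}

#' Write a pathway to .sif/.att files
#'
#' @param graph A [pathway_graph()].
#' @param dir Output directory.
#' @param comment Optional comment line(s) written `#`-prefixed at the top of
#'   both files (e.g. a generator seed).
#' @return Invisibly, the two file paths.
#' @export
write_pathway <- function(graph, dir, comment = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif <- file.path(dir, paste0(graph$pathway_id, ".sif"))
  att <- file.path(dir, paste0(graph$pathway_id, ".att"))
  hdr <- if (is.null(comment)) character() else paste0("# ", comment)
  writeLines(c(hdr, sprintf("%s\t%s\t%s", graph$edges$source,
                            graph$edges$sign, graph$edges$target)), sif)
  writeLines(c(hdr, "node_id\tlabel\tgenes",
               sprintf("%s\t%s\t%s", graph$nodes$node_id, graph$nodes$label,
                       vapply(graph$nodes$genes, paste, character(1), collapse = ","))),
             att)
  invisible(c(sif = sif, att = att))
}

#' Read an expression matrix (genes x samples)
#'
#' CSV or TSV with gene IDs in the first column and sample IDs in the header;
#' the delimiter is auto-detected from the header line. Values must be finite
#' and nonnegative. Duplicate gene rows are rejected unless
#' `aggregate_duplicates` selects a rule.
#'
#' @param path File path.
#' @param aggregate_duplicates `"none"` (reject), `"max"` or `"mean"`.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, aggregate_duplicates = c("none", "max", "mean")) {
  aggregate_duplicates <- match.arg(aggregate_duplicates)
  if (!file.exists(path)) sig_abort(sprintf("no such file: %s", path), "io_error")
  lines <- .read_lines_nocomment(path)
  if (length(lines) < 2L) sig_abort(sprintf("%s: no data rows", path), "io_error")
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (is.null(colnames(mat)) || any(!nzchar(colnames(mat)))) {
    sig_abort(sprintf("%s: missing sample IDs in header", path), "io_error")
  }
  if (any(!is.finite(mat))) {
    sig_abort(sprintf("%s: non-finite expression values", path), "io_error")
  }
  if (any(mat < 0)) {
    sig_abort(sprintf("%s: negative expression values rejected", path), "io_error")
  }
  if (anyDuplicated(genes)) {
    if (aggregate_duplicates == "none") {
      sig_abort(sprintf("%s: duplicate gene rows (%s); pass aggregate_duplicates",
                        path, paste(utils::head(unique(genes[duplicated(genes)]), 5),
                                    collapse = ", ")),
                "io_error")
    }
    fun <- if (aggregate_duplicates == "max") max else mean
    mat <- do.call(rbind, lapply(split(seq_along(genes), genes)[unique(genes)],
                                 function(i) apply(mat[i, , drop = FALSE], 2, fun)))
    genes <- unique(genes)
  }
  rownames(mat) <- genes
  mat
}

#' Write a numeric matrix as TSV
#'
#' First column holds the row IDs (named by `id_col`), remaining columns the
#' samples. Floating values are printed with 6 significant digits.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (row-ID) column.
#' @param comment Optional `#`-prefixed comment line(s).
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id", comment = NULL) {
  df <- data.frame(rownames(mat), signif(mat, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(mat))
  .write_tsv(df, path, comment)
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  lines <- .read_lines_nocomment(path)
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  mat
}

#' Read a sample design table
#'
#' TSV with header `sample_id<TAB>group` and exactly two group labels.
#'
#' @param path File path.
#' @return Data frame with columns `sample_id`, `group`.
#' @export
read_design <- function(path) {
  lines <- .read_lines_nocomment(path)
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    sig_abort(sprintf("%s: expected columns sample_id, group", path), "io_error")
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df
}

#' Write a sample design table
#' @param design Data frame with columns `sample_id`, `group`.
#' @param path Output path.
#' @param comment Optional comment line(s).
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path, comment = NULL) {
  .write_tsv(design[, c("sample_id", "group")], path, comment)
}

#' Read a gene list (one Entrez or HUGO ID per line)
#' @param path File path.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  trimws(.read_lines_nocomment(path))
}
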