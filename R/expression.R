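#' Expression matrix with sample metadata
#'
#' Lightweight container for a genes x samples expression matrix plus
#' per-sample metadata (biological group, technical batch). All pipeline
#' stages that consume expression take this object.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols, no
#'   duplicates), samples in columns (colnames = sample IDs).
#' @param group character vector of per-sample biological labels
#'   (histological subtype, intrinsic subtype, ...), recycled names allowed.
#' @param batch character vector of per-sample technical batch labels.
#' @return object of class `expr_matrix` with elements `values` and `meta`
#'   (data.frame with columns sample, group, batch).
#' @export
expression_matrix <- function(values, group = NULL, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix")
  n <- ncol(values)
  if (is.null(group)) group <- rep(NA_character_, n)
  if (is.null(batch)) batch <- rep("batch1", n)
  if (length(group) != n || length(batch) != n)
    stop("metadata length must match number of samples")
  structure(
    list(values = values,
         meta = data.frame(sample = colnames(values),
                           group = as.character(group),
                           batch = as.character(batch),
                           stringsAsFactors = FALSE)),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  groups: ", paste(utils::head(unique(x$meta$group), 8), collapse = ", "), "\n")
  cat("  batches:", paste(unique(x$meta$batch), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param em `expr_matrix`.
#' @param genes optional character vector of genes to keep (order preserved).
#' @param samples optional character vector of sample IDs to keep.
#' @return subsetted `expr_matrix`.
#' @export
em_subset <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  v <- em$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes absent from expression matrix: ",
           paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("samples absent from expression matrix: ",
           paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  meta <- em$meta[match(colnames(v), em$meta$sample), ]
  expression_matrix(v, group = meta$group, batch = meta$batch)
}

#' Per-sample group labels as a named vector
#' @param em `expr_matrix`.
#' @return named character vector (names = sample IDs).
#' @export
em_groups <- function(em) {
  stats::setNames(em$meta$group, em$meta$sample)
}
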