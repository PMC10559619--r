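# Single-sample gene set enrichment (ssGSEA) scoring and differential
# pathway statistics with volcano-rule flagging.

#' ssGSEA score of one gene set in one sample
#'
#' Genes are ranked by descending expression (ties broken by gene-symbol
#' order for determinism). Walking the ranked list, in-set genes advance
#' an in-set cumulative distribution weighted by `|rank statistic|^alpha`
#' (the rank statistic is the expression value itself), normalized over
#' in-set genes; out-of-set genes advance a uniform out-of-set
#' distribution with step `1/(N - m)`. The score is the integrated
#' enrichment statistic: the sum of the running difference over all list
#' positions. When the set spans the whole universe the out-of-set step is
#' undefined and the closed-form maximum (the in-set cumulative sum alone)
#' is returned.
#'
#' @param expr_column named numeric vector of expression over the gene
#'   universe.
#' @param gene_set character vector; its intersection with the universe
#'   must be non-empty.
#' @param alpha rank-weighting exponent (default 0.75; 0 = pure rank).
#' @return numeric enrichment score.
#' @export
ssgsea_score <- function(expr_column, gene_set, alpha = 0.75) {
  genes <- names(expr_column)
  if (is.null(genes)) stop("expr_column must be named by gene")
  in_set <- genes %in% gene_set
  m <- sum(in_set)
  if (m == 0) stop("gene set has empty intersection with the universe")
  ord <- order(-expr_column, genes)
  x <- expr_column[ord]
  inside <- in_set[ord]
  n <- length(x)
  w <- abs(x)^alpha
  w[!inside] <- 0
  p_in <- cumsum(w) / sum(w)
  if (m == n) return(sum(p_in)) # degenerate full-set case
  p_out <- cumsum(!inside) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA scores for a gene-set collection over all samples
#'
#' @param expr `expr_matrix`.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha rank-weighting exponent.
#' @param normalize when TRUE, divide the whole matrix by its global
#'   (max - min) score range.
#' @return list of class `enrichment_matrix`: `scores` (sets x samples),
#'   `normalized` flag. Sets with empty universe intersection yield NA
#'   rows with a warning.
#' @export
ssgsea_matrix <- function(expr, sets, alpha = 0.75, normalize = FALSE) {
  v <- expr$values
  scores <- matrix(NA_real_, length(sets), ncol(v),
                   dimnames = list(names(sets), colnames(v)))
  for (s in names(sets)) {
    if (!any(rownames(v) %in% sets[[s]])) {
      warning("gene set ", s, " has no genes in the universe; scores set NA")
      next
    }
    scores[s, ] <- apply(v, 2, ssgsea_score, gene_set = sets[[s]],
                         alpha = alpha)
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    scores <- scores / (rng[2] - rng[1])
  }
  structure(list(scores = scores, normalized = normalize),
            class = "enrichment_matrix")
}

#' Differential pathway table with volcano-rule flags
#'
#' Per gene set: mean enrichment difference (group a - group b) and a
#' pooled-variance two-sided Student's t p-value. A set is significant
#' when `|delta| >= lfc_cut` and `p <= p_cut` (both inclusive).
#'
#' @param em `enrichment_matrix`.
#' @param groups named character vector, sample -> group.
#' @param group_a,group_b group labels, each with >= 2 samples.
#' @param lfc_cut log-fold-change threshold (default 0.4).
#' @param p_cut p-value threshold (default 0.05).
#' @return data.frame (set, delta, p, significant).
#' @export
pathway_volcano <- function(em, groups, group_a, group_b,
                            lfc_cut = 0.4, p_cut = 0.05) {
  scores <- em$scores
  sa <- names(groups)[groups == group_a]
  sb <- names(groups)[groups == group_b]
  sa <- intersect(sa, colnames(scores)); sb <- intersect(sb, colnames(scores))
  if (length(sa) < 2 || length(sb) < 2) stop("both groups need >= 2 samples")
  tt <- pooled_t_rows(scores[, sa, drop = FALSE], scores[, sb, drop = FALSE])
  data.frame(set = rownames(scores), delta = tt$log_fc, p = tt$p_value,
             significant = abs(tt$log_fc) >= lfc_cut & tt$p_value <= p_cut,
             stringsAsFactors = FALSE, row.names = NULL)
}
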