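# Copy-number / expression integration: tie-corrected Kendall tau-b,
# per-gene CN-expression correlation with inclusive significance
# thresholds (tau >= 0.3, r >= 0.7), pooled-variance differential
# expression, the integrative DE-and-conserved-CNV gene set, and the
# clustering / PCA summaries used to stratify subtypes.

#' Kendall rank correlation tau-b
#'
#' Tie-corrected tau: `(C - D) / sqrt((n0 - n1)(n0 - n2))` with
#' `n0 = n(n-1)/2` and `n1`, `n2` the tie terms of x and y. Returns `NA`
#' (undefined) when either vector is fully tied.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in [-1, 1], or `NA_real_` when undefined.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (n < 2 || length(y) != n) stop("need equal-length vectors with n >= 2")
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  s <- sum(sx[upper.tri(sx)] * sy[upper.tri(sy)]) # C - D
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1)) / 2
  }
  n0 <- n * (n - 1) / 2
  n1 <- tie_term(x); n2 <- tie_term(y)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  s / den
}

#' Correlate gene-level copy number with expression
#'
#' For every gene with a discrete copy-number change (CN varying across the
#' shared samples and reaching at least one copy away from diploid),
#' computes Kendall tau-b and Pearson r between integer CN and expression
#' over the shared samples. Genes with constant CN emit undefined records
#' ("no discrete change"). Significance flags are inclusive:
#' tau >= `tau_cut`, r >= `r_cut`.
#'
#' @param cn long data.frame (gene, sample, integer_cn, delta).
#' @param expr `expr_matrix`.
#' @param tau_cut,r_cut significance thresholds (defaults 0.3 / 0.7).
#' @return data.frame (gene, tau, pearson_r, n, tau_significant,
#'   r_significant).
#' @export
correlate_cn_expression <- function(cn, expr, tau_cut = 0.3, r_cut = 0.7) {
  shared <- intersect(unique(cn$sample), colnames(expr$values))
  if (length(shared) == 0) stop("no shared samples between CN and expression")
  if (length(shared) < 3) stop("need >= 3 shared samples")
  cn <- cn[cn$sample %in% shared, , drop = FALSE]
  genes <- intersect(unique(cn$gene), rownames(expr$values))
  cn_wide <- matrix(NA_integer_, length(genes), length(shared),
                    dimnames = list(genes, shared))
  cn_wide[cbind(match(cn$gene, genes), match(cn$sample, shared))] <- cn$integer_cn
  res <- lapply(genes, function(g) {
    cnv <- cn_wide[g, ]
    ok <- !is.na(cnv)
    cnv <- cnv[ok]
    ev <- expr$values[g, shared[ok]]
    varying <- length(unique(cnv)) > 1 && any(abs(cnv - 2L) >= 1L)
    if (!varying) {
      return(data.frame(gene = g, tau = NA_real_, pearson_r = NA_real_,
                        n = length(cnv), tau_significant = FALSE,
                        r_significant = FALSE, stringsAsFactors = FALSE))
    }
    tau <- kendall_tau_b(cnv, ev)
    r <- if (stats::sd(ev) == 0) NA_real_ else stats::cor(cnv, ev)
    data.frame(gene = g, tau = tau, pearson_r = r, n = length(cnv),
               tau_significant = !is.na(tau) && tau >= tau_cut,
               r_significant = !is.na(r) && r >= r_cut,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Vectorized pooled-variance two-sided t-test across the rows of two
# matrices. Degenerate rows (zero pooled variance): p = 1 when the means
# agree, p = 0 otherwise.
pooled_t_rows <- function(ma, mb) {
  na <- ncol(ma); nb <- ncol(mb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  va <- apply(ma, 1, stats::var); vb <- apply(mb, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- mean_a - mean_b
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), na + nb - 2),
              ifelse(d == 0, 1, 0))
  data.frame(log_fc = d, t_stat = t, p_value = p)
}

#' Per-gene differential expression between two groups
#'
#' Pooled-variance two-sided Student's t-test per gene;
#' `log_fc = mean_a - mean_b` (expression assumed log scale).
#'
#' @param expr `expr_matrix` with group metadata.
#' @param group_a,group_b group labels present in the metadata, each with
#'   >= 2 samples.
#' @return data.frame (gene, log_fc, t_stat, p_value).
#' @export
differential_expression <- function(expr, group_a, group_b) {
  g <- em_groups(expr)
  sa <- names(g)[g == group_a]; sb <- names(g)[g == group_b]
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 samples")
  out <- pooled_t_rows(expr$values[, sa, drop = FALSE],
                       expr$values[, sb, drop = FALSE])
  cbind(data.frame(gene = rownames(expr$values), stringsAsFactors = FALSE),
        out)
}

#' Integrative gene set: differentially expressed and in a conserved
#' copy-number event
#'
#' A gene qualifies when (a) its p-value is below `p_cut` in at least one
#' of the supplied pairwise contrasts and (b) it resides in a conserved
#' copy-number event: for at least one group, at least `frac` of the
#' group's samples carry a same-sign delta with `|delta| >= 1`. Qualifying
#' genes are mapped through the homolog table; unmapped genes are dropped.
#'
#' @param de one DE result data.frame or a list of them (pairwise
#'   contrasts).
#' @param cn long data.frame (gene, sample, integer_cn, delta).
#' @param groups named character vector, sample -> group.
#' @param homologs named character vector, source symbol -> target symbol.
#' @param p_cut DE p-value cutoff (exclusive).
#' @param frac conservation fraction (inclusive).
#' @return character vector of mapped (e.g. human) gene symbols, sorted.
#' @export
integrative_gene_set <- function(de, cn, groups, homologs,
                                 p_cut = 0.05, frac = 0.66) {
  if (is.data.frame(de)) de <- list(de)
  de_all <- do.call(rbind, de)
  de_genes <- unique(de_all$gene[de_all$p_value < p_cut])
  cn$group <- groups[cn$sample]
  if (anyNA(cn$group)) stop("groups missing for some CN samples")
  conserved <- unlist(lapply(split(cn, cn$group), function(d) {
    n_samp <- length(unique(d$sample))
    gain <- tapply(d$delta >= 1, d$gene, sum) / n_samp
    loss <- tapply(d$delta <= -1, d$gene, sum) / n_samp
    names(gain)[gain >= frac | loss >= frac]
  }), use.names = FALSE)
  hits <- intersect(de_genes, unique(conserved))
  if (length(homologs) == 0) {
    warning("empty homolog map: all genes dropped")
    return(character())
  }
  mapped <- homologs[hits]
  sort(unique(unname(mapped[!is.na(mapped)])))
}

#' Ward-linkage hierarchical clustering
#'
#' Agglomerative clustering under Ward variance minimization on Euclidean
#' distance (`hclust` "ward.D2"); leaf order is deterministic (ties broken
#' by input index by construction).
#'
#' @param m numeric matrix; `axis` "rows" clusters rows, "cols" clusters
#'   columns. NAs are an error.
#' @param axis which margin to cluster.
#' @return list with `hclust` (dendrogram) and `order` (leaf labels in
#'   dendrogram order).
#' @export
ward_cluster <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  if (anyNA(m)) stop("ward_cluster: matrix contains NA/NaN")
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  list(hclust = hc, order = labels[hc$order])
}

#' Two-component PCA on standardized features
#'
#' Columns (features) are standardized to zero mean and unit variance;
#' zero-variance features are dropped with a warning. Returns the top-2
#' principal component scores and the explained-variance fractions of all
#' components.
#'
#' @param m numeric matrix, items in rows, features in columns (>= 3
#'   items, >= 2 features after dropping).
#' @return list with `scores` (items x 2), `explained` (length-2 fractions
#'   for PC1/PC2) and `all_explained`.
#' @export
pca_2d <- function(m) {
  if (nrow(m) < 3) stop("need >= 3 items for PCA")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance feature(s)")
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need >= 2 informative features for PCA")
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE],
       explained = frac[1:2], all_explained = frac)
}
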