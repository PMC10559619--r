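#!/usr/bin/env Rscript
# Stage 3: copy-number / expression integration on the matched cohort:
# per-gene Kendall tau-b and Pearson r with the inclusive 0.3 / 0.7
# significance flags, pairwise differential expression, the integrative
# (DE and conserved-CNV) gene set after homolog mapping, and Ward / PCA
# stratification summaries.

library(momic)

synth <- "results/synth"
out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cn <- read_cn_tsv(file.path(synth, "gene_copy_number.tsv"))
expr <- read_expression_tsv(file.path(synth, "matched_expression.tsv"))
meta <- read_meta_tsv(file.path(synth, "matched_meta.tsv"))
expr <- expression_matrix(expr$values, group = meta$group, batch = meta$batch)
hom_tab <- utils::read.delim(file.path(synth, "homologs.tsv"))
homologs <- stats::setNames(hom_tab$human, hom_tab$mouse)

rec <- correlate_cn_expression(cn, expr)
utils::write.table(rec, file.path(out, "cn_expression_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
defined <- rec[!is.na(rec$pearson_r), ]
cat("correlation: ", nrow(defined), " genes with discrete CN change; ",
    round(100 * mean(defined$r_significant)), "% at r >= 0.7, ",
    round(100 * mean(defined$tau_significant)), "% at tau >= 0.3\n", sep = "")

groups <- em_groups(expr)
contrasts <- utils::combn(unique(groups), 2, simplify = FALSE)
de_all <- do.call(rbind, lapply(contrasts, function(p) {
  d <- differential_expression(expr, p[1], p[2])
  d$contrast <- paste(p, collapse = "_vs_")
  d
}))
utils::write.table(de_all, file.path(out, "differential_expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

geneset <- integrative_gene_set(
  split(de_all, de_all$contrast), cn, groups, homologs)
writeLines(geneset, file.path(out, "integrative_gene_set.txt"))
cat("integrative gene set:", length(geneset),
    "homolog-mapped genes both DE and in a conserved CN event\n")

# stratification: the conserved blocks alone separate the histologies
wc <- ward_cluster(t(expr$values), axis = "rows")
writeLines(wc$order, file.path(out, "ward_leaf_order.txt"))
pca <- pca_2d(t(expr$values))
utils::write.table(
  data.frame(sample = rownames(pca$scores), pca$scores,
             group = groups[rownames(pca$scores)]),
  file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("PCA: first two components explain",
    paste(round(100 * pca$explained, 1), collapse = "% / "), "%\n")
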