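#!/usr/bin/env Rscript
# Stage 6: the cross-species subtype translator. A human-like 6-class
# training cohort is batch-adjusted jointly with a mouse-like cohort,
# features are narrowed by RFECV, the five-learner soft-voting ensemble is
# trained over 15 stratified 70/30 instantiations, and the mouse samples
# are assigned intrinsic subtypes by highest average probability.

library(momic)

seed <- as.integer(Sys.getenv("MOMIC_SEED", "42"))
out <- "results/subtype"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

classes <- canonical_subtypes()
panel <- synth_config(seed = seed, n_genes = 45, n_informative = 42,
                      effect_size = 3, noise_sd = 1,
                      n_samples_per_class = stats::setNames(rep(100L, 6),
                                                            classes))
human <- gen_expression(panel)
mouse <- gen_expression(synth_config(
  seed = seed + 17, n_genes = 45, n_informative = 42, effect_size = 3,
  noise_sd = 1,
  n_samples_per_class = stats::setNames(rep(7L, 6), classes),
  batch_offsets = c(mouse = 1.5), batch_scales = c(mouse = 1.2)))

# joint batch adjustment: platform differences between cohorts are the
# batch, biology is shared
joint_v <- cbind(human$values, mouse$values)
joint <- expression_matrix(
  joint_v,
  group = c(em_groups(human), em_groups(mouse)),
  batch = rep(c("human", "mouse"), c(ncol(human$values), ncol(mouse$values))))
adj <- eb_batch_adjust(joint)
human_adj <- em_subset(adj, samples = colnames(human$values))
mouse_adj <- em_subset(adj, samples = colnames(mouse$values))

labels <- em_groups(human_adj)
sel <- rfecv_select(human_adj, labels, folds = 10, seed = seed)
utils::write.table(sel$curve, file.path(out, "rfecv_curve.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sel$selected, file.path(out, "selected_genes.txt"))
cat("RFECV selected", length(sel$selected), "of", nrow(human$values),
    "genes (best CV accuracy",
    round(max(sel$curve$cv_accuracy), 3), ")\n")

train <- em_subset(human_adj, genes = sel$selected)
fit <- fit_voting_ensemble(train, labels, n_instantiations = 15,
                           seed = seed + 1)
m <- fit$metrics
cat(sprintf("ensemble: accuracy %.3f, weighted F1 %.3f, MCC %.3f (mean over 15 instantiations)\n",
            m$accuracy, m$f1_weighted, m$mcc))
cat(sprintf("pooled-confusion metrics: %.3f / %.3f / %.3f\n",
            m$pooled$accuracy, m$pooled$f1_weighted, m$pooled$mcc))
utils::write.table(m$confusion, file.path(out, "confusion.tsv"),
                   sep = "\t", quote = FALSE)
jsonlite::write_json(list(accuracy = m$accuracy,
                          f1_weighted = m$f1_weighted, mcc = m$mcc,
                          pooled = m$pooled),
                     file.path(out, "metrics.json"),
                     auto_unbox = TRUE, digits = NA)

asg <- assign_mouse_subtypes(fit$model,
                             em_subset(mouse_adj, genes = sel$selected))
utils::write.table(asg$assignments, file.path(out, "mouse_assignments.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(asg$proportions, file.path(out, "mouse_proportions.tsv"),
                   sep = "\t", quote = FALSE)
acc <- mean(asg$assignments$assigned == em_groups(mouse))
cat(sprintf("mouse assignment: %.1f%% of samples recover their generating class\n",
            100 * acc))
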