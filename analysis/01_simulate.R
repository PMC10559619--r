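#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input cohort the pipeline consumes and
# write them in their on-disk interchange formats under results/synth/.
# All later stages read these files, so the whole analysis is reproducible
# from one seed (default 42, override with MOMIC_SEED).

library(momic)

seed <- as.integer(Sys.getenv("MOMIC_SEED", "42"))
out <- "results/synth"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cat("simulating cohorts with seed", seed, "\n")

# 42-sample, 3-histology expression cohort in two technical batches
expr_cfg <- synth_config(seed = seed,
                         batch_offsets = c(chipA = 0, chipB = 2),
                         batch_scales = c(chipA = 1, chipB = 1.5))
em <- gen_expression(expr_cfg)
write_gct(em, file.path(out, "expression.gct"))
write_meta_tsv(em$meta, file.path(out, "expression_meta.tsv"))
cat("  expression:", nrow(em$values), "genes x", ncol(em$values), "samples\n")

# matched 9-sample WGS-like cohort: integer CN coupled to expression
dec <- gen_cn_and_expression(synth_config(seed = seed, cn_beta = 2,
                                          noise_sd = 0.1))
write_cn_tsv(dec$cn, file.path(out, "gene_copy_number.tsv"))
write_expression_tsv(dec$expr, file.path(out, "matched_expression.tsv"))
write_meta_tsv(dec$expr$meta, file.path(out, "matched_meta.tsv"))
utils::write.table(dec$truth$conserved, file.path(out, "truth_conserved_cn.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(mouse = names(dec$truth$homologs),
                              human = unname(dec$truth$homologs)),
                   file.path(out, "homologs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("  CN cohort:", length(unique(dec$cn$sample)), "samples,",
    nrow(dec$truth$conserved), "conserved-event genes\n")

# two-caller SV call sets with jitter, FPs and germline contamination
sv <- gen_sv_callsets(synth_config(seed = seed, n_sv_events = 60,
                                   sv_jitter_sd = 20, fp_rate = 0.2))
write_bedpe(sv$caller_a, file.path(out, "sv_callerA.bedpe"))
write_bedpe(sv$caller_b, file.path(out, "sv_callerB.bedpe"))
write_bedpe(sv$wildtype, file.path(out, "sv_wildtype.bedpe"))
write_bedpe(sv$truth, file.path(out, "sv_truth.bedpe"))
utils::write.table(sv$gene_breaks, file.path(out, "gene_breaks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(attr(sv$truth, "wt_ids"), file.path(out, "sv_truth_wt_ids.txt"))
cat("  SV call sets:", nrow(sv$caller_a), "+", nrow(sv$caller_b), "calls\n")

# signature-mixture mutation catalogs (one per WGS-like tumor)
sigs <- synthetic_signatures(seed = 42)
write_signatures_tsv(sigs, file.path(out, "signatures.tsv"))
catalog <- gen_mutation_catalog(synth_config(seed = seed), sigs, n_samples = 9)
rownames(catalog) <- unique(dec$cn$sample)
write_catalog_tsv(catalog, file.path(out, "mutation_catalog.tsv"))
cat("  catalogs:", nrow(catalog), "samples x 96 channels\n")

# two-arm survival cohort (altered vs unaltered, exponential times)
surv <- gen_survival(synth_config(seed = seed))
write_survival_tsv(surv, file.path(out, "survival.tsv"))
cat("  survival:", nrow(surv), "records,",
    round(100 * mean(surv$event == 0)), "% censored\n")
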