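#!/usr/bin/env Rscript
# Stage 2: consensus somatic variant calling on the simulated call sets.
# SNVs: two-caller exact-identity consensus plus strain-background
# subtraction. SVs: two-caller positional consensus (100 bp margin,
# length > 10 kb, MAPQ >= 60, wildtype subtraction) for CNVs/inversions and
# the wider translocation rule (1 kb, MAPQ >= 50, gene-break intersection).

library(momic)

seed <- as.integer(Sys.getenv("MOMIC_SEED", "42"))
synth <- "results/synth"
out <- "results/variants"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# --- SNV consensus demo on planted two-caller sets --------------------
set.seed(seed)
shared <- snv_calls("chr11", sort(sample.int(2e6, 300)), "C", "T",
                    impact = sample(c("LOW", "MODERATE", "HIGH"), 300, TRUE),
                    gene = paste0("Gene", sample.int(80, 300, TRUE)),
                    sample = "tumor1")
priv <- function(chrom, n, caller)
  snv_calls(chrom, sample.int(2e6, n), "G", "A", sample = "tumor1",
            caller = caller)
germline <- rbind(shared[sample.int(300, 60), ],
                  snv_calls("chr4", sample.int(2e6, 40), "A", "C",
                            sample = "tumor1", caller = "strain"))
calls_a <- rbind(shared, priv("chr2", 120, "callerA"))
calls_b <- rbind(shared, priv("chr3", 80, "callerB"))
cons <- subtract_germline(consensus_snvs(calls_a, calls_b), germline)
cat("SNV consensus: kept", nrow(cons), "of", nrow(calls_a), "/",
    nrow(calls_b), "calls after germline subtraction",
    "(expected", 300 - 60, ")\n")
utils::write.table(cons, file.path(out, "consensus_snvs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# conserved impactful genes per group on a per-sample split of the calls
samples <- paste0("tumor", 1:6)
per_sample <- lapply(seq_along(samples), function(i) {
  keep <- sample.int(nrow(cons), round(0.7 * nrow(cons)))
  x <- cons[keep, ]; x$sample <- samples[i]; x
})
names(per_sample) <- samples
groups <- stats::setNames(rep(c("microacinar", "EMT"), each = 3), samples)
consv <- conserved_mutations(per_sample, groups, frac = 0.66)
cat("conserved impactful genes: ",
    paste(vapply(consv$sets, length, 1L), collapse = " / "),
    " (", paste(names(consv$sets), collapse = " / "), ")\n", sep = "")
burden <- mutational_burden(per_sample)
utils::write.table(data.frame(sample = names(burden), burden = burden),
                   file.path(out, "mutational_burden.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# --- SV consensus from the simulated BEDPE files ----------------------
caller_a <- read_bedpe(file.path(synth, "sv_callerA.bedpe"))
caller_b <- read_bedpe(file.path(synth, "sv_callerB.bedpe"))
wildtype <- read_bedpe(file.path(synth, "sv_wildtype.bedpe"))
truth <- read_bedpe(file.path(synth, "sv_truth.bedpe"))
gene_breaks <- utils::read.delim(file.path(synth, "gene_breaks.tsv"))
wt_ids <- readLines(file.path(synth, "sv_truth_wt_ids.txt"))

pick <- function(df, types) df[df$type %in% types, ]
merged <- rbind(
  consensus_svs(pick(caller_a, c("DEL", "DUP")), pick(caller_b, c("DEL", "DUP")),
                pick(wildtype, c("DEL", "DUP")), "CNV"),
  consensus_svs(pick(caller_a, "INV"), pick(caller_b, "INV"),
                pick(wildtype, "INV"), "INV"),
  consensus_translocations(pick(caller_a, "TRA"), pick(caller_b, "TRA"),
                           gene_breaks))
write_bedpe(merged, file.path(out, "consensus_svs.bedpe"))
wt_non_tra <- intersect(wt_ids, truth$id[truth$type != "TRA"])
expected <- setdiff(truth$id, wt_non_tra)
cat("SV consensus: ", nrow(merged), " merged calls; recall ",
    round(mean(expected %in% merged$id), 3), ", precision ",
    round(mean(merged$id %in% expected), 3), "\n", sep = "")

# integer CN from segment log2 ratios (whole-chromosome gains of +1/+2
# appear as ratios log2(3/2) and log2(4/2))
seg_demo <- data.frame(log2 = c(-1, log2(3 / 2), 0, 1),
                       cn = integer_cn_from_log2(c(-1, log2(3 / 2), 0, 1)))
utils::write.table(seg_demo, file.path(out, "integer_cn_demo.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
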