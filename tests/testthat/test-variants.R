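test_that("SNV consensus keeps exact four-field matches only", {
  a <- snv_calls(c("chr1", "chr1", "chr2"), c(100L, 200L, 50L),
                 c("C", "G", "A"), c("A", "T", "G"),
                 impact = c("MODERATE", "LOW", "HIGH"),
                 gene = c("Kit", "Rara", "Kras"), caller = "callerA")
  b <- snv_calls(c("chr1", "chr1", "chr2"), c(100L, 200L, 50L),
                 c("C", "G", "A"), c("A", "C", "G"), caller = "callerB")
  out <- consensus_snvs(a, b)
  expect_identical(out$pos, c(100L, 50L)[order(c("chr1", "chr2"))])
  expect_identical(sort(out$gene), c("Kit", "Kras")) # alt mismatch drops Rara
  expect_identical(out$impact[out$gene == "Kit"], "MODERATE") # annotation from A
})

test_that("SNV consensus is a set intersection on planted call sets", {
  set.seed(71)
  shared <- snv_calls("chr1", sample.int(1e6, 50), "C", "T")
  a_priv <- snv_calls("chr2", sample.int(1e6, 30), "G", "A")
  b_priv <- snv_calls("chr3", sample.int(1e6, 20), "A", "G")
  a <- rbind(shared, a_priv); a$caller <- "callerA"
  b <- rbind(shared, b_priv); b$caller <- "callerB"
  out <- consensus_snvs(a, b)
  expect_identical(nrow(out), 50L)
  expect_error(consensus_snvs(a, snv_calls("chr1", 1, "C", "T", sample = "other")),
               "mix samples")
})

test_that("germline subtraction removes planted duplicates and is idempotent", {
  set.seed(72)
  somatic <- snv_calls("chr1", sample.int(1e6, 100), "C", "T")
  germline <- somatic[sample.int(100, 25), ]
  out <- subtract_germline(somatic, germline)
  expect_identical(nrow(out), 75L)
  expect_identical(subtract_germline(out, germline), out)
  expect_identical(subtract_germline(somatic, somatic[0, ]), somatic)
})

test_that("SV consensus applies margin, length, MAPQ and WT filters", {
  mk <- function(posA, posB, mapq = 60L, type = "DEL", caller = "x")
    sv_calls(type, "chr1", posA, "chr1", posB, mapq = mapq, caller = caller)
  wt0 <- mk(1, 2)[0, ]
  # |dStart| = 50, |dEnd| = 80, length 15000: retained
  out <- consensus_svs(mk(10000L, 25000L), mk(10050L, 25080L), wt0, "CNV")
  expect_identical(nrow(out), 1L)
  expect_identical(out$posA, 10000L) # caller-A coordinates
  # breakpoint off by 101: no match
  expect_identical(nrow(consensus_svs(mk(10000L, 25000L),
                                      mk(10101L, 25000L), wt0, "CNV")), 0L)
  # length 9000 is filtered even when matched
  expect_identical(nrow(consensus_svs(mk(10000L, 19000L),
                                      mk(10000L, 19000L), wt0, "CNV")), 0L)
  # min MAPQ of the pair must reach 60
  expect_identical(nrow(consensus_svs(mk(10000L, 25000L, mapq = 59L),
                                      mk(10000L, 25000L), wt0, "CNV")), 0L)
  # identical WT call suppresses the event
  expect_identical(nrow(consensus_svs(mk(10000L, 25000L), mk(10000L, 25000L),
                                      mk(10000L, 25000L, caller = "wt"),
                                      "CNV")), 0L)
  # kind / type consistency is enforced
  expect_error(consensus_svs(mk(1e4, 3e4, type = "INV"),
                             mk(1e4, 3e4, type = "INV"), wt0, "CNV"),
               "cannot take type")
})

test_that("greedy matching agrees with exhaustive matching and is symmetric", {
  for (seed in 1:12) {
    jit <- c(0, 20, 50)[(seed %% 3) + 1]
    sv <- random_sv_instance(seed, n_events = 40, jitter_sd = jit,
                             fp_rate = 0.2)
    a <- sv$caller_a; b <- sv$caller_b
    greedy <- momic:::sv_greedy_match(a, b, 100)
    oracle <- oracle_sv_match(a, b, 100)
    expect_identical(greedy[order(greedy$i), ]$i, oracle$i)
    expect_identical(greedy[order(greedy$i), ]$j, oracle$j)
    swapped <- momic:::sv_greedy_match(b, a, 100)
    expect_setequal(paste(greedy$i, greedy$j),
                    paste(swapped$j, swapped$i))
  }
})

test_that("consensus recall is perfect on jittered truth without FPs", {
  for (seed in c(3, 14)) {
    sv <- random_sv_instance(seed, n_events = 60, jitter_sd = 20)
    for (kind in c("CNV", "INV")) {
      types <- if (kind == "CNV") c("DEL", "DUP") else "INV"
      a <- sv$caller_a[sv$caller_a$type %in% types, ]
      b <- sv$caller_b[sv$caller_b$type %in% types, ]
      out <- consensus_svs(a, b, NULL, kind)
      truth <- sv$truth[sv$truth$type %in% types, ]
      expect_setequal(out$id, truth$id)
    }
  }
})

test_that("SV filters commute", {
  sv <- random_sv_instance(5, n_events = 50, jitter_sd = 20, fp_rate = 0.3)
  a <- sv$caller_a[sv$caller_a$type %in% c("DEL", "DUP"), ]
  b <- sv$caller_b[sv$caller_b$type %in% c("DEL", "DUP"), ]
  wt <- sv$truth[sv$truth$type %in% c("DEL", "DUP"), ][1:3, ]
  pairs <- momic:::sv_greedy_match(a, b, 100)
  merged <- momic:::merge_matched(a, b, pairs)
  f_len <- merged$length > 10000
  f_mapq <- merged$mapq >= 60
  f_wt <- !momic:::sv_in_wildtype(merged, wt, 100)
  ref <- merged[f_len & f_mapq & f_wt, ]$id
  expect_identical(merged[f_wt & f_len & f_mapq, ]$id, ref)
  expect_identical(merged[f_mapq & f_wt & f_len, ]$id, ref)
  out <- consensus_svs(a, b, wt, "CNV")
  expect_setequal(out$id, ref)
})

test_that("translocation consensus uses wider margin, MAPQ 50 and gene breaks", {
  mk <- function(posA, posB, mapq = 55L, genes = list("Fgfr2"), caller = "x")
    sv_calls("TRA", "chr1", posA, "chr7", posB, mapq = mapq,
             caller = caller, genes = genes)
  gb <- data.frame(gene = "Fgfr2", sample = "sample")
  # 800 bp apart at both ends, MAPQ 55, gene break present: retained
  expect_identical(nrow(consensus_translocations(
    mk(10000L, 50000L), mk(10800L, 50800L), gb)), 1L)
  # no gene-break intersection: dropped
  expect_identical(nrow(consensus_translocations(
    mk(10000L, 50000L), mk(10800L, 50800L),
    data.frame(gene = "Other", sample = "sample"))), 0L)
  # wrong sample in the gene-break table: dropped
  expect_identical(nrow(consensus_translocations(
    mk(10000L, 50000L), mk(10800L, 50800L),
    data.frame(gene = "Fgfr2", sample = "other"))), 0L)
  # MAPQ 49 fails the translocation floor
  expect_identical(nrow(consensus_translocations(
    mk(10000L, 50000L, mapq = 49L), mk(10000L, 50000L), gb)), 0L)
  # 1001 bp exceeds the margin
  expect_identical(nrow(consensus_translocations(
    mk(10000L, 50000L), mk(11001L, 50000L), gb)), 0L)
  expect_error(consensus_translocations(
    sv_calls("DEL", "chr1", 1e4, "chr1", 3e4), mk(1e4, 5e4), gb), "TRA")
})

test_that("integer CN derivation rounds half-up and floors at zero", {
  expect_identical(integer_cn_from_log2(0), 2L)
  expect_identical(integer_cn_from_log2(c(-1, 0.585, 1)), c(1L, 3L, 4L))
  expect_identical(integer_cn_from_log2(-10), 0L)
  expect_identical(integer_cn_from_log2(log2(2.5 / 2)), 3L) # exact half rounds up
  expect_identical(integer_cn_from_log2(0, baseline_ploidy = 4L), 4L)
  expect_error(integer_cn_from_log2(NaN), "non-finite")
})

test_that("conserved mutations respect fraction and impact rules", {
  mk <- function(gene, impact) snv_calls("chr1", 1L, "C", "T",
                                         impact = impact, gene = gene)
  calls <- list(
    s1 = rbind(mk("Kit", "MODERATE"), mk("Low1", "LOW")),
    s2 = rbind(mk("Kit", "HIGH"), mk("Low1", "LOW"), mk("Rare", "HIGH")),
    s3 = mk("Low1", "LOW"),
    t1 = mk("Scrib", "HIGH"), t2 = mk("Scrib", "MODERATE"))
  groups <- c(s1 = "micro", s2 = "micro", s3 = "micro", t1 = "emt", t2 = "emt")
  out <- conserved_mutations(calls, groups, frac = 0.66)
  expect_identical(out$sets$micro, "Kit") # 2/3 = 0.667 >= 0.66
  expect_identical(out$sets$emt, "Scrib") # 2/2
  expect_false("Low1" %in% out$sets$micro) # LOW impact never counts
  expect_false("Rare" %in% out$sets$micro) # 1/3 below threshold
  expect_identical(unname(out$venn[c("micro", "emt")]), c(1L, 1L))
  expect_error(conserved_mutations(calls, groups, frac = 0), "frac")
})

test_that("mutational burden counts calls and ignores order", {
  calls <- list(a = make_snvs(120, seed = 2), b = make_snvs(0, seed = 3))
  burden <- mutational_burden(calls)
  expect_identical(unname(burden), c(120L, 0L))
  shuffled <- list(a = calls$a[sample.int(120), ], b = calls$b)
  expect_identical(mutational_burden(shuffled), burden)
})
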