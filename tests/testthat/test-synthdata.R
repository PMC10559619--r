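test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(n_genes = 0), "n_genes")
  expect_error(synth_config(n_samples_per_class = c(a = 5)), "classes")
  expect_error(synth_config(batch_scales = c(batch1 = -1)), "scale")
  expect_error(synth_config(fp_rate = 1.5), "fp_rate")
  expect_error(synth_config(signature_mixture = c(SBS1 = 0.7)), "sum to 1")
  expect_error(synth_config(survival_medians = c(a = -3, b = 2)), "medians")
})

test_that("expression generator honors class means exactly at zero noise", {
  cfg <- synth_config(noise_sd = 0, n_genes = 10, n_informative = 4,
                      n_samples_per_class = c(lo = 3, hi = 3),
                      class_means = list(lo = rep(0, 4), hi = rep(3, 4)))
  em <- gen_expression(cfg)
  g <- em_groups(em)
  expect_true(all(em$values["Gene0001", g == "lo"] == 0))
  expect_true(all(em$values["Gene0001", g == "hi"] == 3))
  expect_true(all(em$values["Gene0010", ] == 0)) # non-informative
})

test_that("batch offsets appear as per-gene batch-mean differences", {
  cfg <- synth_config(seed = 11, n_genes = 200, noise_sd = 1,
                      batch_offsets = c(A = 0, B = 2),
                      batch_scales = c(A = 1, B = 1))
  em <- gen_expression(cfg)
  batch <- em$meta$batch
  diffs <- rowMeans(em$values[, batch == "B"]) -
    rowMeans(em$values[, batch == "A"])
  n_b <- sum(batch == "B"); n_a <- sum(batch == "A")
  sem <- sqrt(1 / n_a + 1 / n_b)
  # mean over genes is a much tighter estimate than any single gene
  expect_lt(abs(mean(diffs) - 2), 3 * sem / sqrt(200) * 20)
  expect_true(all(abs(diffs - 2) < 5 * sem))
})

test_that("generators are deterministic and leave the RNG state alone", {
  cfg <- synth_config(seed = 5)
  set.seed(123); before <- rnorm(1)
  em1 <- gen_expression(cfg)
  em2 <- gen_expression(cfg)
  expect_identical(em1$values, em2$values)
  sv1 <- gen_sv_callsets(cfg); sv2 <- gen_sv_callsets(cfg)
  expect_identical(sv1$caller_a, sv2$caller_a)
  cat1 <- gen_mutation_catalog(cfg); cat2 <- gen_mutation_catalog(cfg)
  expect_identical(cat1[, ], cat2[, ])
  s1 <- gen_survival(cfg); s2 <- gen_survival(cfg)
  expect_identical(s1$time, s2$time)
  set.seed(123); expect_identical(rnorm(1), before)
})

test_that("CN-expression coupling follows cn_beta", {
  dec <- gen_cn_and_expression(synth_config(seed = 3, cn_beta = 0, noise_sd = 1))
  cn_m <- dec$truth$cn_matrix
  varying <- rownames(cn_m)[apply(cn_m, 1, function(v) length(unique(v)) > 1)]
  rs <- vapply(varying, function(g)
    stats::cor(cn_m[g, ], dec$expr$values[g, ]), numeric(1))
  expect_lt(abs(mean(rs)), 0.15) # decoupled on average

  cpl <- gen_cn_and_expression(synth_config(seed = 3, cn_beta = 2, noise_sd = 0.1))
  cn_m <- cpl$truth$cn_matrix
  varying <- rownames(cn_m)[apply(cn_m, 1, function(v) length(unique(v)) > 1)]
  rs <- vapply(varying, function(g)
    stats::cor(cn_m[g, ], cpl$expr$values[g, ]), numeric(1))
  expect_gt(mean(rs > 0.9), 0.95)
})

test_that("conserved CN blocks are conserved and private variation is not", {
  dec <- gen_cn_and_expression(synth_config(seed = 8))
  cn <- dec$cn
  groups <- em_groups(dec$expr)
  cons <- dec$truth$conserved
  for (i in sample(nrow(cons), 5)) {
    g <- cons$gene[i]; cl <- cons$class[i]
    in_class <- cn[cn$gene == g & groups[cn$sample] == cl, ]
    expect_true(all(in_class$delta == cons$delta[i]))
  }
  # private genes never reach 2/3 of a class
  for (g in sample(dec$truth$variable, 5)) {
    d <- cn[cn$gene == g, ]
    frac <- tapply(abs(d$delta) >= 1, groups[d$sample], mean)
    expect_true(all(frac < 0.66))
  }
})

test_that("SV breakpoint jitter matches its normal model", {
  sv <- gen_sv_callsets(synth_config(seed = 21, n_sv_events = 400,
                                     sv_jitter_sd = 30, fp_rate = 0))
  offs <- c(sv$caller_a$posA - sv$truth$posA,
            sv$caller_a$posB - sv$truth$posB,
            sv$caller_b$posA - sv$truth$posA,
            sv$caller_b$posB - sv$truth$posB)
  p_within <- mean(abs(offs) <= 100)
  expected <- stats::pnorm(100 / 30) - stats::pnorm(-100 / 30) # ~0.9991
  expect_lt(abs(p_within - expected), 0.005)
  expect_true(all(offs == round(offs)))
})

test_that("zero jitter and no FPs reproduce the truth set exactly", {
  sv <- gen_sv_callsets(synth_config(seed = 2, sv_jitter_sd = 0, fp_rate = 0,
                                     wt_frac = 0))
  expect_identical(sv$caller_a$posA, sv$truth$posA)
  expect_identical(sv$caller_b$posB, sv$truth$posB)
  expect_identical(nrow(sv$wildtype), 0L)
})

test_that("false positives sit far from truth and never cross-match", {
  sv <- gen_sv_callsets(synth_config(seed = 4, fp_rate = 0.5))
  fps_a <- sv$caller_a[grepl("^fp_", sv$caller_a$id), ]
  fps_b <- sv$caller_b[grepl("^fp_", sv$caller_b$id), ]
  expect_gt(nrow(fps_a), 0)
  truth_bp <- c(sv$truth$posA, sv$truth$posB)
  fp_bp <- c(fps_a$posA, fps_a$posB, fps_b$posA, fps_b$posB)
  expect_gte(min(abs(outer(fp_bp, truth_bp, `-`))), 1e4)
  pairs <- momic:::sv_greedy_match(fps_a, fps_b, margin = 100)
  expect_identical(nrow(pairs), 0L)
})

test_that("mutation catalogs follow the signature mixture", {
  sigs <- synthetic_signatures(seed = 42)
  cfg <- synth_config(signature_mixture = c(SBS3 = 1), n_mutations = 10000)
  catalog <- gen_mutation_catalog(cfg, sigs)
  freq <- catalog[1, ] / sum(catalog[1, ])
  expect_lt(max(abs(freq - sigs["SBS3", ])), 0.02)

  cfg2 <- synth_config(signature_mixture = c(SBS1 = 0.7, SBS2 = 0.3),
                       n_mutations = 50000)
  cat2 <- gen_mutation_catalog(cfg2, sigs)
  expected <- 0.7 * sigs["SBS1", ] + 0.3 * sigs["SBS2", ]
  expect_lt(max(abs(cat2[1, ] / sum(cat2[1, ]) - expected)), 0.02)

  empty <- gen_mutation_catalog(synth_config(n_mutations = 0), sigs)
  expect_true(all(empty == 0L))
  expect_error(gen_mutation_catalog(synth_config(
    signature_mixture = c(NOPE = 1)), sigs), "unknown signature")
})

test_that("survival generator hits its medians and censor rate", {
  s <- gen_survival(synth_config(seed = 31, censor_rate = 0))
  expect_true(all(s$event == 1))
  med_alt <- km_fit(s[s$group == "altered", ])$median
  expect_lt(abs(med_alt - 77.7), 15)

  s2 <- gen_survival(synth_config(seed = 31, censor_rate = 1))
  expect_true(all(s2$event == 0))
  expect_true(is.na(km_fit(s2)$median))

  s3 <- gen_survival(synth_config(seed = 31, censor_rate = 0.35))
  expect_lt(abs(mean(s3$event == 0) - 0.35), 0.06)

  ratio_cfg <- synth_config(seed = 12, censor_rate = 0,
                            survival_medians = c(short = 50, long = 150))
  s4 <- gen_survival(ratio_cfg)
  m_s <- km_fit(s4[s4$group == "short", ])$median
  m_l <- km_fit(s4[s4$group == "long", ])$median
  expect_lt(abs(m_l / m_s - 3), 0.6)
})
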