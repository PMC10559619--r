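# shared small fixtures for the classifier tests
six_class_em <- function(seed, n_per_class = 30, effect = 3) {
  classes <- canonical_subtypes()
  gen_expression(synth_config(
    seed = seed, n_genes = 32, n_informative = 30, effect_size = effect,
    noise_sd = 1,
    n_samples_per_class = stats::setNames(rep(n_per_class, 6), classes)))
}

test_that("EB batch adjustment removes a planted location-scale batch effect", {
  cfg <- synth_config(seed = 81, n_genes = 250, noise_sd = 1,
                      n_samples_per_class = c(microacinar = 160, squamous = 160,
                                              EMT = 160),
                      batch_offsets = c(A = 0, B = 2),
                      batch_scales = c(A = 1, B = 1.5))
  em <- gen_expression(cfg)
  adj <- eb_batch_adjust(em)
  batch <- adj$meta$batch
  dm <- rowMeans(adj$values[, batch == "B"]) -
    rowMeans(adj$values[, batch == "A"])
  expect_lt(mean(abs(dm)), 0.1)
  vr <- apply(adj$values[, batch == "B"], 1, stats::var) /
    apply(adj$values[, batch == "A"], 1, stats::var)
  expect_true(median(vr) >= 0.8 && median(vr) <= 1.25)
  expect_gt(mean(vr >= 0.8 & vr <= 1.25), 0.9)
  # biological effect sizes survive: compare within-batch standardized mean
  # differences before and after (the raw batch offset itself masks the
  # pooled effect, so the comparison is per batch)
  g <- adj$meta$group
  smd <- function(v, in_batch) {
    a <- v[, g == "microacinar" & batch == in_batch]
    b <- v[, g == "EMT" & batch == in_batch]
    (rowMeans(a) - rowMeans(b)) /
      sqrt((apply(a, 1, stats::var) + apply(b, 1, stats::var)) / 2)
  }
  info <- attr(em, "truth")$informative
  for (bb in c("A", "B")) {
    pre <- smd(em$values[info, ], bb)
    post <- smd(adj$values[info, ], bb)
    big <- abs(pre) > 1
    expect_lt(median(abs(post[big] - pre[big]) / abs(pre[big])), 0.1)
  }
})

test_that("EB batch adjustment matches the reference implementation", {
  skip_if_not_installed("sva")
  em <- gen_expression(synth_config(seed = 82, n_genes = 120,
                                    batch_offsets = c(A = 0, B = 1.5),
                                    batch_scales = c(A = 1, B = 1.3)))
  adj <- eb_batch_adjust(em)
  ref <- suppressMessages(sva::ComBat(em$values, batch = em$meta$batch))
  expect_equal(adj$values, ref, tolerance = 1e-8)
})

test_that("single-batch adjustment is the identity, with a warning", {
  em <- gen_expression(synth_config(seed = 83, n_genes = 50))
  expect_warning(adj <- eb_batch_adjust(em), "single batch")
  expect_equal(adj$values, em$values, tolerance = 1e-8)
})

test_that("confusion-matrix metrics match their closed forms", {
  expect_identical(mcc_multiclass(diag(c(2, 2))), 1)
  # everything predicted into one class on balanced truth
  conf0 <- matrix(c(5, 0, 5, 0), 2, byrow = TRUE)
  expect_identical(mcc_multiclass(conf0), 0)
  # binary closed form
  conf <- matrix(c(3, 2, 1, 4), 2, byrow = TRUE,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  tp <- 3; fn <- 2; fp <- 1; tn <- 4
  expect_equal(mcc_multiclass(conf),
               (tp * tn - fp * fn) /
                 sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  expect_equal(accuracy_from_confusion(conf), 7 / 10)
  # weighted F1: perfect diagonal, fully missed class, equal supports
  expect_identical(weighted_f1(diag(c(4, 6))), 1)
  missed <- matrix(c(6, 0, 6, 0), 2, byrow = TRUE)
  f1_present <- 2 * 0.5 * 1 / (0.5 + 1)
  expect_equal(weighted_f1(missed), 0.5 * f1_present + 0.5 * 0)
  balanced <- matrix(c(4, 1, 2, 3), 2, byrow = TRUE)
  macro <- mean(c(2 * (4 / 6) * (4 / 5) / (4 / 6 + 4 / 5),
                  2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5)))
  expect_equal(weighted_f1(balanced), macro)
})

test_that("ensemble separates a strongly structured six-class cohort", {
  em <- six_class_em(seed = 84)
  labels <- em_groups(em)
  fit <- fit_voting_ensemble(em, labels, n_instantiations = 5, seed = 85)
  expect_gte(fit$metrics$accuracy, 0.9)
  m <- fit$metrics
  expect_equal(m$pooled$accuracy, accuracy_from_confusion(m$confusion))
  expect_equal(m$pooled$f1_weighted, weighted_f1(m$confusion))
  expect_equal(m$pooled$mcc, mcc_multiclass(m$confusion))
  expect_identical(colnames(m$confusion), canonical_subtypes())
  # stratification: per-instantiation train proportions within 1 sample
  inst <- fit$model$instantiations[[1]]
  for (cl in canonical_subtypes()) {
    n_tr <- sum(labels[inst$train] == cl)
    expect_lte(abs(n_tr - round(0.7 * sum(labels == cl))), 1)
  }
  expect_error(fit_voting_ensemble(em, replace(labels, labels == "BASAL",
                                               c("BASAL", rep("LONE", 29))),
                                   seed = 1),
               "single sample")
})

test_that("ensemble accuracy collapses to chance on shuffled labels", {
  em <- six_class_em(seed = 86, n_per_class = 20)
  set.seed(87)
  shuffled <- sample(em_groups(em))
  names(shuffled) <- colnames(em$values)
  fit <- fit_voting_ensemble(em, shuffled, n_instantiations = 5, seed = 88)
  expect_lt(abs(fit$metrics$accuracy - 1 / 6), 0.08)
})

test_that("fixed seed makes ensemble fits and assignments bit-identical", {
  em <- six_class_em(seed = 89, n_per_class = 12)
  labels <- em_groups(em)
  f1 <- fit_voting_ensemble(em, labels, n_instantiations = 2, seed = 90)
  f2 <- fit_voting_ensemble(em, labels, n_instantiations = 2, seed = 90)
  expect_identical(f1$metrics$per_instantiation, f2$metrics$per_instantiation)
  expect_identical(f1$metrics$confusion, f2$metrics$confusion)
  newdata <- six_class_em(seed = 91, n_per_class = 5)
  a1 <- assign_mouse_subtypes(f1$model, newdata)
  a2 <- assign_mouse_subtypes(f2$model, newdata)
  expect_identical(a1$assignments, a2$assignments)
})

test_that("cross-domain assignment recovers the generating class", {
  em <- six_class_em(seed = 92)
  fit <- fit_voting_ensemble(em, em_groups(em), n_instantiations = 5, seed = 93)
  mouse <- six_class_em(seed = 94, n_per_class = 8)
  asg <- assign_mouse_subtypes(fit$model, mouse)
  expect_gte(mean(asg$assignments$assigned == em_groups(mouse)), 0.9)
  expect_equal(unname(rowSums(asg$proportions)), rep(1, nrow(asg$proportions)))
  probs <- as.matrix(asg$assignments[, canonical_subtypes()])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  bad <- em_subset(mouse, genes = rownames(mouse$values)[-1])
  expect_error(assign_mouse_subtypes(fit$model, bad), "absent")
})

test_that("uniform probabilities resolve ties to the first canonical class", {
  prob <- matrix(1 / 6, 2, 6, dimnames = list(NULL, canonical_subtypes()))
  expect_identical(momic:::argmax_class(prob), c("BASAL", "BASAL"))
})

test_that("RFECV recovers planted class-defining genes", {
  classes <- paste0("C", 1:8)
  means <- lapply(1:8, function(k) { v <- numeric(8); v[k] <- 3; v })
  names(means) <- classes
  recovered <- vapply(1:4, function(s) {
    cfg <- synth_config(seed = s, n_genes = 32, n_informative = 8,
                        noise_sd = 1,
                        n_samples_per_class = stats::setNames(rep(10L, 8), classes),
                        class_means = means)
    em <- gen_expression(cfg)
    sel <- rfecv_select(em, em_groups(em), folds = 10, seed = s)
    sum(attr(em, "truth")$informative %in% sel$selected)
  }, numeric(1))
  expect_gte(mean(recovered >= 7), 0.8)
})

test_that("RFECV is chance-level on pure noise and keeps a perfect separator", {
  # all-noise features: the full-feature CV point (no adaptive selection)
  # sits at chance; adaptively selected subsets may drift above it because
  # elimination reuses the scoring folds, so the curve max gets a looser
  # bound
  cfg <- synth_config(seed = 95, n_genes = 12, n_informative = 2,
                      effect_size = 0, noise_sd = 1,
                      n_samples_per_class = c(a = 100, b = 100))
  em <- gen_expression(cfg)
  sel <- rfecv_select(em, em_groups(em), folds = 10, seed = 96)
  full <- sel$curve$cv_accuracy[sel$curve$n_features == 12]
  expect_lt(abs(full - 0.5), 0.075) # ~2 SEM of a 10-fold estimate at n = 200
  expect_lt(max(sel$curve$cv_accuracy), 0.5 + 0.15)
  # one perfectly separating feature is always retained
  cfg2 <- synth_config(seed = 97, n_genes = 10, n_informative = 1,
                       effect_size = 8, noise_sd = 0.2,
                       n_samples_per_class = c(a = 20, b = 20),
                       class_means = list(a = 0, b = 8))
  em2 <- gen_expression(cfg2)
  sel2 <- rfecv_select(em2, em_groups(em2), folds = 10, seed = 98)
  expect_true("Gene0001" %in% sel2$selected)
  expect_error(rfecv_select(em2, rep("a", 40), folds = 10), ">= 2 classes")
})
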