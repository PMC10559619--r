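# Cross-species subtype translation: parametric empirical-Bayes batch
# adjustment, recursive feature elimination with cross-validation, a
# five-learner soft-voting ensemble with stratified 70/30 instantiations,
# confusion-matrix metrics, and mouse-sample subtype assignment.

#' Canonical intrinsic-subtype order
#'
#' The fixed class order used everywhere as the tie-break authority:
#' BASAL, CLAUDIN_LOW, HER2, LUMA, LUMB, NORMAL.
#'
#' @return character vector of length 6.
#' @export
canonical_subtypes <- function() {
  c("BASAL", "CLAUDIN_LOW", "HER2", "LUMA", "LUMB", "NORMAL")
}

# Class order: canonical when the labels are intrinsic subtypes, otherwise
# sorted unique labels (deterministic).
resolve_class_order <- function(labels, class_order = NULL) {
  if (!is.null(class_order)) return(class_order)
  u <- unique(as.character(labels))
  if (all(u %in% canonical_subtypes()))
    return(canonical_subtypes()[canonical_subtypes() %in% u])
  sort(u)
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Location-scale batch-effect removal: per gene, data are standardized by
#' the grand mean (batch-size-weighted) and pooled variance; per-batch
#' additive (gamma) and multiplicative (delta^2) effects are estimated and
#' shrunk toward batch-level priors — normal for gamma, inverse-gamma for
#' delta^2, hyperparameters by method of moments — with the shrinkage
#' fixed point iterated to 1e-4; adjusted data are
#' `(Z - gamma*) / delta*`, restored to the original scale.
#'
#' @param expr `expr_matrix` with >= 2 batches of >= 2 samples each.
#'   Genes with zero pooled variance are dropped with a warning. A single
#'   batch returns the input unchanged with a warning.
#' @return adjusted `expr_matrix` (same shape minus dropped genes) with a
#'   `batch_model` attribute carrying the per-batch estimates and
#'   hyperparameters.
#' @export
eb_batch_adjust <- function(expr) {
  v <- expr$values
  batch <- expr$meta$batch
  batches <- unique(batch)
  if (length(batches) < 2) {
    warning("single batch: returning data unchanged")
    return(expr)
  }
  nb <- table(batch)[batches]
  if (any(nb < 2)) stop("every batch needs >= 2 samples")
  n <- ncol(v)
  idx <- lapply(batches, function(b) which(batch == b))
  names(idx) <- batches
  batch_mean <- vapply(idx, function(i) rowMeans(v[, i, drop = FALSE]),
                       numeric(nrow(v)))
  grand <- as.numeric(batch_mean %*% (as.numeric(nb) / n))
  resid <- v - batch_mean[, match(batch, batches)]
  var_pooled <- rowSums(resid^2) / n
  if (any(var_pooled == 0)) {
    warning("dropping ", sum(var_pooled == 0),
            " gene(s) with zero pooled variance")
    keep <- var_pooled > 0
    v <- v[keep, , drop = FALSE]
    batch_mean <- batch_mean[keep, , drop = FALSE]
    grand <- grand[keep]
    var_pooled <- var_pooled[keep]
  }
  sd_pooled <- sqrt(var_pooled)
  z <- (v - grand) / sd_pooled
  gamma_hat <- vapply(idx, function(i) rowMeans(z[, i, drop = FALSE]),
                      numeric(nrow(z)))
  delta_hat <- vapply(idx, function(i) apply(z[, i, drop = FALSE], 1, stats::var),
                      numeric(nrow(z)))
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, stats::var)
  # inverse-gamma hyperparameters by method of moments
  m_d <- colMeans(delta_hat)
  s2_d <- apply(delta_hat, 2, stats::var)
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  z_adj <- z
  for (k in seq_along(batches)) {
    zb <- z[, idx[[k]], drop = FALSE]
    nk <- ncol(zb)
    g_old <- gamma_hat[, k]
    d_old <- delta_hat[, k]
    repeat {
      # the location update always shrinks the unshrunk per-gene estimate
      g_new <- (nk * tau2[k] * gamma_hat[, k] + d_old * gamma_bar[k]) /
        (nk * tau2[k] + d_old)
      sum2 <- rowSums((zb - g_new)^2)
      d_new <- (b_prior[k] + 0.5 * sum2) / (nk / 2 + a_prior[k] - 1)
      # signed denominators, matching the standard parametric EB iteration
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
      if (change < 1e-4) break
    }
    gamma_star[, k] <- g_old
    delta_star[, k] <- d_old
    z_adj[, idx[[k]]] <- (zb - g_old) / sqrt(d_old)
  }
  out <- z_adj * sd_pooled + grand
  adjusted <- expression_matrix(out, group = expr$meta$group,
                                batch = expr$meta$batch)
  attr(adjusted, "batch_model") <- list(
    grand_mean = grand, pooled_sd = sd_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, tau2 = tau2,
    a_prior = a_prior, b_prior = b_prior)
  adjusted
}

#' Confusion matrix with a fixed class order
#'
#' @param true,pred vectors of class labels.
#' @param class_order row/column order (rows = true, columns = predicted).
#' @return K x K integer matrix.
#' @export
confusion_matrix <- function(true, pred, class_order = NULL) {
  class_order <- resolve_class_order(c(as.character(true), as.character(pred)),
                                     class_order)
  as.matrix(table(factor(true, levels = class_order),
                  factor(pred, levels = class_order)))
}

#' Accuracy from a confusion matrix
#' @param confusion K x K matrix, rows = true, columns = predicted.
#' @return trace / total.
#' @export
accuracy_from_confusion <- function(confusion) {
  sum(diag(confusion)) / sum(confusion)
}

#' Generalized multiclass Matthews correlation coefficient
#'
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, and `p_k` / `t_k` the predicted /
#' true marginals; returns 0 when either factor under the root is 0.
#'
#' @param confusion K x K matrix, rows = true, columns = predicted.
#' @return MCC in [-1, 1].
#' @export
mcc_multiclass <- function(confusion) {
  s <- sum(confusion)
  if (s <= 0) stop("empty confusion matrix")
  c_ <- sum(diag(confusion))
  t_k <- rowSums(confusion)
  p_k <- colSums(confusion)
  num <- c_ * s - sum(p_k * t_k)
  f1 <- s^2 - sum(p_k^2)
  f2 <- s^2 - sum(t_k^2)
  if (f1 == 0 || f2 == 0) return(0)
  num / sqrt(f1 * f2)
}

#' Support-weighted F1 from a confusion matrix
#'
#' Per-class F1 (harmonic mean of precision and recall, 0 when both are 0)
#' weighted by true-class support.
#'
#' @param confusion K x K matrix, rows = true, columns = predicted.
#' @return weighted F1 in [0, 1].
#' @export
weighted_f1 <- function(confusion) {
  s <- sum(confusion)
  if (s <= 0) stop("empty confusion matrix")
  support <- rowSums(confusion)
  f1 <- vapply(seq_len(nrow(confusion)), function(k) {
    tp <- confusion[k, k]
    prec_den <- sum(confusion[, k])
    rec_den <- support[k]
    prec <- if (prec_den > 0) tp / prec_den else 0
    rec <- if (rec_den > 0) tp / rec_den else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  sum(f1 * support) / s
}

# ---- base learners -------------------------------------------------------
# Each fitter returns a closure mapping a samples x features matrix to a
# probability matrix with columns in `class_order`. Hyperparameters are
# common defaults (unit-cost RBF SVM, ridge-regularized logistic
# regression, 100-tree forest, 100-round boosting, one hidden layer).

fit_base_learners <- function(x, y, class_order, seed) {
  y <- factor(as.character(y), levels = class_order)
  k <- length(class_order)
  reorder <- function(p) {
    p <- p[, class_order, drop = FALSE]
    p / rowSums(p)
  }
  learners <- list()

  set.seed(seed + 1)
  m_lr <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                         lambda = 1 / nrow(x))
  learners$logistic <- function(newx) {
    p <- stats::predict(m_lr, newx = newx, type = "response")[, , 1]
    if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
    reorder(p)
  }

  set.seed(seed + 2)
  m_svm <- e1071::svm(x, y, kernel = "radial", probability = TRUE)
  learners$svm_rbf <- function(newx) {
    pr <- stats::predict(m_svm, newx, probability = TRUE)
    reorder(attr(pr, "probabilities"))
  }

  set.seed(seed + 3)
  m_rf <- randomForest::randomForest(x, y, ntree = 100)
  learners$random_forest <- function(newx) {
    reorder(stats::predict(m_rf, newx, type = "prob"))
  }

  set.seed(seed + 4)
  m_xgb <- xgboost::xgboost(x, y, nrounds = 100, nthreads = 1,
                            learning_rate = 0.3, max_depth = 6,
                            verbosity = 0)
  learners$xgboost <- function(newx) {
    p <- stats::predict(m_xgb, newx, type = "response")
    if (k == 2 && is.null(dim(p)))
      p <- cbind(1 - p, p, deparse.level = 0,
                 dimnames = list(NULL, levels(y)))
    reorder(p)
  }

  set.seed(seed + 5)
  m_nn <- nnet::nnet(x, nnet::class.ind(y), size = 8, decay = 1e-3,
                     maxit = 200, softmax = TRUE, trace = FALSE,
                     MaxNWts = 10000)
  learners$mlp <- function(newx) {
    p <- stats::predict(m_nn, newx)
    colnames(p) <- class_order
    reorder(p)
  }

  learners
}

# Average the class-probability outputs of a learner list with equal
# weight (soft voting).
soft_vote <- function(learners, newx) {
  probs <- lapply(learners, function(f) f(newx))
  Reduce(`+`, probs) / length(probs)
}

# argmax with ties resolved to the earlier class in the column order
argmax_class <- function(prob) {
  colnames(prob)[apply(prob, 1, which.max)]
}

# Stratified train indices: per class, round(train_frac * n_c) samples.
stratified_split <- function(labels, train_frac) {
  train <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    n_tr <- round(train_frac * length(i))
    n_tr <- min(max(n_tr, 1L), length(i) - 1L) # keep both sides non-empty
    sample(i, n_tr)
  }), use.names = FALSE)
  sort(train)
}

#' Fit the five-learner soft-voting subtype ensemble
#'
#' Runs `n_instantiations` independent stratified shuffle splits
#' (train_frac / 1 - train_frac, class proportions preserved to within one
#' sample per class). In each instantiation the five base learners
#' (regularized logistic regression, RBF-kernel SVM with probability
#' outputs, random forest, gradient-boosted trees, multi-layer perceptron)
#' are fit on the training side and their class probabilities averaged
#' with equal weight on the test side; predictions are the argmax of the
#' averaged probabilities with ties resolved to the earlier class in the
#' canonical order. Metrics (accuracy, weighted F1, MCC) are computed per
#' instantiation and averaged; the confusion matrix is summed across
#' instantiations, and pooled-confusion metrics are reported alongside.
#'
#' @param expr `expr_matrix` (features = genes) or samples x features
#'   matrix.
#' @param labels class label per sample; every class needs >= 2 samples.
#' @param n_instantiations number of stratified shuffle splits (default 15).
#' @param train_frac training fraction (default 0.70).
#' @param seed root seed; fixes splits and learner fits end to end.
#' @param class_order optional explicit class order; defaults to the
#'   canonical intrinsic-subtype order when labels allow, else sorted.
#' @return list with `model` (class `voting_ensemble`: per-instantiation
#'   learner lists, feature names, class order) and `metrics` (mean and
#'   per-instantiation accuracy / weighted F1 / MCC, summed confusion,
#'   pooled metrics).
#' @export
fit_voting_ensemble <- function(expr, labels, n_instantiations = 15,
                                train_frac = 0.70, seed = 42,
                                class_order = NULL) {
  x <- if (inherits(expr, "expr_matrix")) t(expr$values) else as.matrix(expr)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop("cannot stratify: class(es) with a single sample: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  class_order <- resolve_class_order(labels, class_order)
  k <- length(class_order)
  conf_sum <- matrix(0L, k, k, dimnames = list(class_order, class_order))
  per_inst <- data.frame(instantiation = seq_len(n_instantiations),
                         accuracy = NA_real_, f1_weighted = NA_real_,
                         mcc = NA_real_)
  instantiations <- vector("list", n_instantiations)
  for (i in seq_len(n_instantiations)) {
    set.seed(seed + 1000 * i)
    tr <- stratified_split(labels, train_frac)
    te <- setdiff(seq_along(labels), tr)
    learners <- fit_base_learners(x[tr, , drop = FALSE], labels[tr],
                                  class_order, seed = seed + 1000 * i)
    prob <- soft_vote(learners, x[te, , drop = FALSE])
    pred <- argmax_class(prob)
    conf <- confusion_matrix(labels[te], pred, class_order)
    conf_sum <- conf_sum + conf
    per_inst$accuracy[i] <- accuracy_from_confusion(conf)
    per_inst$f1_weighted[i] <- weighted_f1(conf)
    per_inst$mcc[i] <- mcc_multiclass(conf)
    instantiations[[i]] <- list(learners = learners, train = tr, test = te)
  }
  model <- structure(list(features = colnames(x), class_order = class_order,
                          instantiations = instantiations, seed = seed),
                     class = "voting_ensemble")
  metrics <- list(
    accuracy = mean(per_inst$accuracy),
    f1_weighted = mean(per_inst$f1_weighted),
    mcc = mean(per_inst$mcc),
    per_instantiation = per_inst,
    confusion = conf_sum,
    pooled = list(accuracy = accuracy_from_confusion(conf_sum),
                  f1_weighted = weighted_f1(conf_sum),
                  mcc = mcc_multiclass(conf_sum)))
  list(model = model, metrics = metrics)
}

#' @export
print.voting_ensemble <- function(x, ...) {
  cat(sprintf("<voting_ensemble> %d instantiations x 5 learners, %d features\n",
              length(x$instantiations), length(x$features)))
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' Assign subtypes to new (e.g. mouse) samples
#'
#' Averages class probabilities over all learners and instantiations of a
#' fitted ensemble and assigns the argmax class (ties to the earlier class
#' in the canonical order). Input expression must already be batch-adjusted
#' jointly with the training data and restricted to the model features.
#'
#' @param model `voting_ensemble`.
#' @param expr `expr_matrix`; must contain every model feature.
#' @return list with `assignments` (data.frame: sample, one mean
#'   probability column per class, assigned) and `proportions` (per-cohort
#'   fraction of samples per assigned class, cohorts = metadata groups).
#' @export
assign_mouse_subtypes <- function(model, expr) {
  missing <- setdiff(model$features, rownames(expr$values))
  if (length(missing))
    stop("model features absent from expression data: ",
         paste(missing, collapse = ", "))
  x <- t(expr$values[model$features, , drop = FALSE])
  probs <- lapply(model$instantiations, function(inst)
    soft_vote(inst$learners, x))
  prob <- Reduce(`+`, probs) / length(probs)
  assigned <- argmax_class(prob)
  assignments <- data.frame(sample = colnames(expr$values), prob,
                            assigned = assigned, stringsAsFactors = FALSE,
                            row.names = NULL, check.names = FALSE)
  cohort <- expr$meta$group
  cohort[is.na(cohort)] <- "all"
  tab <- table(cohort, factor(assigned, levels = model$class_order))
  proportions <- sweep(as.matrix(tab), 1, rowSums(tab), `/`)
  list(assignments = assignments, proportions = proportions)
}

#' Recursive feature elimination with cross-validation
#'
#' Backward elimination driven by permutation importance of an RBF-kernel
#' SVM under stratified k-fold cross-validation: at each feature count the
#' mean CV accuracy is recorded, per-feature importance is the mean
#' accuracy drop over folds when that feature is permuted in the held-out
#' fold, and the `step` least important features are removed. Returns the
#' feature subset maximizing mean CV accuracy, with ties resolved toward
#' fewer features.
#'
#' @param expr `expr_matrix` or samples x features matrix.
#' @param labels class label per sample (>= `folds` samples per class).
#' @param folds stratified CV folds (default 10).
#' @param step features removed per round (default 1).
#' @param seed RNG seed for fold assignment and permutations.
#' @return list with `selected` (character vector) and `curve`
#'   (data.frame: n_features, cv_accuracy).
#' @export
rfecv_select <- function(expr, labels, folds = 10, step = 1, seed = 42) {
  x <- if (inherits(expr, "expr_matrix")) t(expr$values) else as.matrix(expr)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  counts <- table(labels)
  if (any(counts < folds))
    stop("every class needs >= `folds` samples for stratified CV")
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in names(counts)) {
    i <- which(labels == cl)
    fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  current <- colnames(x)
  history <- list()
  curve <- data.frame(n_features = integer(), cv_accuracy = numeric())
  round_i <- 0
  while (length(current) >= 1) {
    round_i <- round_i + 1
    acc <- numeric(folds)
    imp <- matrix(0, folds, length(current),
                  dimnames = list(NULL, current))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- e1071::svm(x[tr, current, drop = FALSE], factor(labels[tr]),
                      kernel = "radial")
      xv <- x[!tr, current, drop = FALSE]
      yv <- labels[!tr]
      base_acc <- mean(as.character(stats::predict(m, xv)) == yv)
      acc[f] <- base_acc
      if (length(current) > 1) {
        for (j in seq_along(current)) {
          xp <- xv
          set.seed(seed + 7919 * round_i + 97 * f + j)
          xp[, j] <- xp[sample(nrow(xp)), j]
          imp[f, j] <- base_acc -
            mean(as.character(stats::predict(m, xp)) == yv)
        }
      }
    }
    curve <- rbind(curve, data.frame(n_features = length(current),
                                     cv_accuracy = mean(acc)))
    history[[as.character(length(current))]] <- current
    if (length(current) == 1) break
    mean_imp <- colMeans(imp)
    drop_n <- min(step, length(current) - 1)
    drop_idx <- order(mean_imp, seq_along(mean_imp))[seq_len(drop_n)]
    current <- current[-drop_idx]
  }
  best_acc <- max(curve$cv_accuracy)
  candidates <- curve$n_features[curve$cv_accuracy == best_acc]
  best_n <- min(candidates) # ties -> fewer features
  list(selected = history[[as.character(best_n)]],
       curve = curve[order(curve$n_features), ])
}
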