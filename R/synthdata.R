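# Synthetic data generators. Every downstream stage of the pipeline can be
# exercised on these outputs without any download; each generator returns a
# ground-truth sidecar sufficient for parameter-recovery tests.
#
# All randomness flows from the single `seed` in the config: each generator
# derives its own fixed sub-stream offset so that generators are
# independently reproducible and identical (seed, config) pairs yield
# bit-identical output. The caller's RNG state is left untouched.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

#' Synthetic-data configuration
#'
#' Bundles every knob of the generators with validation. Defaults describe
#' the study conditions the pipeline targets: a 3-histology mouse cohort
#' (microacinar / squamous / EMT) of 14 expression samples per class
#' (42 total) with a 3-per-class genome-sequenced subset, conserved
#' copy-number blocks per histology, two jittered structural-variant
#' callers over one truth set, signature-mixture mutation catalogs, and
#' two-arm exponential survival with medians matching a printed
#' altered-vs-unaltered contrast (77.7 / 164.3 months).
#'
#' @param seed root seed for all generators (default 42).
#' @param n_genes number of genes in expression / CN outputs.
#' @param n_samples_per_class named integer vector, expression samples per
#'   biological class.
#' @param class_means named list, per-class mean vector over the
#'   informative genes; NULL builds a block design where each class is
#'   shifted by `effect_size` on its own third of the informative genes.
#' @param n_informative number of informative genes for `class_means`.
#' @param effect_size mean shift (expression units) of a class on its
#'   informative block.
#' @param noise_sd Gaussian noise sd (expression units, log-like scale).
#' @param batch_offsets,batch_scales named per-batch additive offset and
#'   multiplicative scale (> 0); samples are assigned round-robin within
#'   class so classes stay balanced across batches.
#' @param cn_beta expression units per copy deviation from diploid.
#' @param n_cn_samples_per_class samples per class in the matched CN +
#'   expression cohort.
#' @param cn_block_size genes per conserved copy-number block (one block
#'   per class).
#' @param n_var_cn_genes genes with sample-private (non-conserved) copy
#'   number variation.
#' @param sv_jitter_sd per-breakpoint Gaussian jitter sd in bp (rounded to
#'   integer, clamped to >= 1).
#' @param fp_rate caller-private false positive rate relative to the truth
#'   set size; false positives are placed >= 10 kb from any truth
#'   breakpoint so they cannot match by construction.
#' @param n_sv_events structural-variant truth events.
#' @param wt_frac fraction of truth events duplicated into the wildtype
#'   call set (germline contaminants).
#' @param signature_mixture named weights over signatures, summing to 1.
#' @param n_mutations mutations per sample in generated catalogs.
#' @param survival_medians named per-group median survival (months).
#' @param n_per_group survival records per group.
#' @param censor_rate expected fraction of censored records in [0, 1].
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 42,
                         n_genes = 500,
                         n_samples_per_class = c(microacinar = 14, squamous = 14, EMT = 14),
                         class_means = NULL,
                         n_informative = min(60, n_genes),
                         effect_size = 2,
                         noise_sd = 1,
                         batch_offsets = c(batch1 = 0),
                         batch_scales = c(batch1 = 1),
                         cn_beta = 1,
                         n_cn_samples_per_class = 3,
                         cn_block_size = 20,
                         n_var_cn_genes = 40,
                         sv_jitter_sd = 20,
                         fp_rate = 0.1,
                         n_sv_events = 24,
                         wt_frac = 0.25,
                         signature_mixture = c(SBS3 = 0.6, SBS1 = 0.25, SBS5 = 0.15),
                         n_mutations = 10000,
                         survival_medians = c(altered = 77.7, unaltered = 164.3),
                         n_per_group = 500,
                         censor_rate = 0.35) {
  cfg <- list(seed = seed, n_genes = as.integer(n_genes),
              n_samples_per_class = n_samples_per_class,
              class_means = class_means,
              n_informative = as.integer(n_informative),
              effect_size = effect_size, noise_sd = noise_sd,
              batch_offsets = batch_offsets, batch_scales = batch_scales,
              cn_beta = cn_beta,
              n_cn_samples_per_class = as.integer(n_cn_samples_per_class),
              cn_block_size = as.integer(cn_block_size),
              n_var_cn_genes = as.integer(n_var_cn_genes),
              sv_jitter_sd = sv_jitter_sd, fp_rate = fp_rate,
              n_sv_events = as.integer(n_sv_events), wt_frac = wt_frac,
              signature_mixture = signature_mixture,
              n_mutations = as.integer(n_mutations),
              survival_medians = survival_medians,
              n_per_group = as.integer(n_per_group),
              censor_rate = censor_rate)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes <= 0L) stop("configuration error: n_genes must be positive")
  if (length(cfg$n_samples_per_class) < 2 || is.null(names(cfg$n_samples_per_class)))
    stop("configuration error: need >= 2 named classes")
  if (any(cfg$n_samples_per_class < 2))
    stop("configuration error: need >= 2 samples per class")
  if (cfg$noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (any(cfg$batch_scales <= 0))
    stop("configuration error: batch scales must be > 0")
  if (!identical(names(cfg$batch_offsets), names(cfg$batch_scales)))
    stop("configuration error: batch offset / scale names must agree")
  if (cfg$sv_jitter_sd < 0) stop("configuration error: sv_jitter_sd must be >= 0")
  for (p in c("fp_rate", "wt_frac", "censor_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration error: ", p, " must lie in [0, 1]")
  if (abs(sum(cfg$signature_mixture) - 1) > 1e-9)
    stop("configuration error: signature mixture weights must sum to 1")
  if (any(cfg$survival_medians <= 0))
    stop("configuration error: survival medians must be > 0")
  if (cfg$n_informative > cfg$n_genes)
    stop("configuration error: n_informative exceeds n_genes")
  invisible(cfg)
}

synth_gene_names <- function(n) sprintf("Gene%04d", seq_len(n))

default_class_means <- function(cfg) {
  classes <- names(cfg$n_samples_per_class)
  k <- length(classes)
  per <- cfg$n_informative %/% k
  means <- lapply(seq_len(k), function(i) {
    v <- numeric(cfg$n_informative)
    lo <- (i - 1L) * per + 1L
    hi <- if (i == k) cfg$n_informative else i * per
    v[lo:hi] <- cfg$effect_size
    v
  })
  names(means) <- classes
  means
}

#' Generate a subtype-structured expression matrix with batch effects
#'
#' Sample j of class c in batch b gets, on gene g,
#' `offset_b + scale_b * (mean_c[g] + noise)`: the batch acts as a
#' location-scale distortion of the biological signal, the model the
#' empirical-Bayes batch adjustment assumes. Non-informative genes have
#' class mean 0.
#'
#' @param cfg `synth_config`.
#' @return `expr_matrix` with a `truth` attribute carrying the informative
#'   gene names and the class-mean map.
#' @export
gen_expression <- function(cfg) {
  validate_synth_config(cfg)
  classes <- names(cfg$n_samples_per_class)
  means <- if (is.null(cfg$class_means)) default_class_means(cfg) else cfg$class_means
  if (!all(classes %in% names(means)))
    stop("configuration error: class_means missing classes")
  genes <- synth_gene_names(cfg$n_genes)
  info <- genes[seq_len(cfg$n_informative)]
  sample_class <- rep(classes, times = cfg$n_samples_per_class)
  samples <- unlist(lapply(classes, function(cl)
    paste0(cl, "_", seq_len(cfg$n_samples_per_class[[cl]]))))
  batches <- names(cfg$batch_offsets)
  # round-robin within class keeps classes balanced across batches
  sample_batch <- unlist(lapply(cfg$n_samples_per_class, function(n)
    rep_len(batches, n)))
  v <- with_seed(cfg$seed + 101, {
    mu <- matrix(0, cfg$n_genes, length(samples),
                 dimnames = list(genes, samples))
    for (j in seq_along(samples))
      mu[seq_len(cfg$n_informative), j] <- means[[sample_class[j]]]
    eps <- matrix(stats::rnorm(length(mu), 0, cfg$noise_sd), nrow(mu))
    off <- cfg$batch_offsets[sample_batch]
    sc <- cfg$batch_scales[sample_batch]
    sweep(sweep(mu + eps, 2, sc, `*`), 2, off, `+`)
  })
  em <- expression_matrix(v, group = sample_class, batch = sample_batch)
  attr(em, "truth") <- list(informative = info, class_means = means)
  em
}

#' Generate a matched copy-number + expression cohort
#'
#' Emulates a genome-sequenced subset with copy-number events that drive
#' expression. Each class carries one conserved block of genes altered in
#' every sample of the class (deltas cycle over +2, -1, +1 across classes,
#' mirroring whole-chromosome gains/losses); a further block varies
#' per sample; all other genes are diploid throughout. Expression is
#' `cn_beta * (CN - 2) + noise`.
#'
#' @param cfg `synth_config`; `cn_beta` must be finite.
#' @return list with `cn` (long gene/sample/integer_cn/delta data.frame),
#'   `expr` (`expr_matrix`), and `truth` (conserved-event table, variable
#'   gene names, CN matrix, homolog map from mouse-style to human-style
#'   symbols).
#' @export
gen_cn_and_expression <- function(cfg) {
  validate_synth_config(cfg)
  if (!is.finite(cfg$cn_beta)) stop("configuration error: cn_beta must be finite")
  classes <- names(cfg$n_samples_per_class)
  k <- length(classes)
  genes <- synth_gene_names(cfg$n_genes)
  need <- k * cfg$cn_block_size + cfg$n_var_cn_genes
  if (need > cfg$n_genes)
    stop("configuration error: CN blocks exceed n_genes")
  sample_class <- rep(classes, each = cfg$n_cn_samples_per_class)
  samples <- paste0(sample_class, "_", rep(seq_len(cfg$n_cn_samples_per_class), k))
  deltas <- rep_len(c(2L, -1L, 1L), k)
  out <- with_seed(cfg$seed + 202, {
    delta <- matrix(0L, cfg$n_genes, length(samples),
                    dimnames = list(genes, samples))
    conserved <- data.frame(gene = character(), class = character(),
                            delta = integer(), stringsAsFactors = FALSE)
    for (i in seq_len(k)) {
      rows <- ((i - 1L) * cfg$cn_block_size + 1L):(i * cfg$cn_block_size)
      delta[rows, sample_class == classes[i]] <- deltas[i]
      conserved <- rbind(conserved, data.frame(
        gene = genes[rows], class = classes[i], delta = deltas[i],
        stringsAsFactors = FALSE))
    }
    # sample-private variation: one altered sample per class per gene, so
    # the altered fraction (1/n per class) can never reach a conservation
    # threshold of 2/3 or more
    var_rows <- (k * cfg$cn_block_size + 1L):need
    for (g in var_rows) {
      for (cl in classes) {
        j <- which(sample_class == cl)
        delta[g, sample(j, 1L)] <- sample(c(-1L, 1L, 2L), 1L)
      }
    }
    cn <- pmin(pmax(2L + delta, 0L), 4L)
    expr <- cfg$cn_beta * (cn - 2L) +
      matrix(stats::rnorm(length(cn), 0, cfg$noise_sd), nrow(cn))
    dimnames(expr) <- dimnames(cn)
    list(delta = delta, cn = cn, expr = expr,
         conserved = conserved, variable = genes[var_rows])
  })
  cn_long <- data.frame(
    gene = rep(genes, times = length(samples)),
    sample = rep(samples, each = cfg$n_genes),
    integer_cn = as.integer(out$cn),
    delta = as.integer(out$cn) - 2L,
    stringsAsFactors = FALSE)
  em <- expression_matrix(out$expr, group = sample_class)
  homologs <- stats::setNames(toupper(genes), genes)
  list(cn = cn_long, expr = em,
       truth = list(conserved = out$conserved, variable = out$variable,
                    cn_matrix = out$cn, homologs = homologs))
}

#' Generate two jittered SV call sets plus a wildtype set
#'
#' A single truth set of structural variants is emitted into two caller
#' call sets with independent Gaussian breakpoint jitter (rounded to
#' integer bp, clamped to >= 1). Caller-private false positives are added
#' at `fp_rate`, placed >= 10 kb from every truth breakpoint (and from each
#' other) so they can never match across callers under a 100 bp rule. A
#' leading fraction `wt_frac` of truth events is duplicated into the
#' wildtype set at identical coordinates.
#'
#' Non-TRA truth lengths are drawn in 20 kb..1 Mb and all truth MAPQ are
#' 60, so the expected post-filter consensus is exactly the truth minus its
#' wildtype-duplicated subset.
#'
#' @param cfg `synth_config`.
#' @return list with `caller_a`, `caller_b`, `wildtype` (SV call
#'   data.frames), `truth` (sidecar with `wt_ids` of contaminated events)
#'   and `gene_breaks` (gene/sample table covering every truth
#'   translocation).
#' @export
gen_sv_callsets <- function(cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_sv_events
  with_seed(cfg$seed + 303, {
    type <- rep_len(c("DEL", "DUP", "INV", "TRA"), n)
    chromA <- paste0("chr", sample(1:19, n, replace = TRUE))
    posA <- as.integer(round(stats::runif(n, 1e6, 1e8)))
    len <- as.integer(round(stats::runif(n, 2e4, 1e6)))
    tra <- type == "TRA"
    chromB <- chromA
    chromB[tra] <- paste0("chr", sample(1:19, sum(tra), replace = TRUE))
    posB <- posA + len
    posB[tra] <- as.integer(round(stats::runif(sum(tra), 1e6, 1e8)))
    genes <- rep(list(character()), n)
    genes[tra] <- lapply(which(tra), function(i) paste0("TraGene", i))
    truth <- sv_calls(type, chromA, posA, chromB, posB, mapq = 60L,
                      sample = "tumor1", caller = "truth",
                      id = paste0("ev", seq_len(n)), genes = genes)
    jitter <- function(calls, caller) {
      m <- nrow(calls)
      calls$posA <- pmax(1L, as.integer(calls$posA +
        round(stats::rnorm(m, 0, cfg$sv_jitter_sd))))
      calls$posB <- pmax(1L, as.integer(calls$posB +
        round(stats::rnorm(m, 0, cfg$sv_jitter_sd))))
      non_tra <- calls$type != "TRA"
      calls$length[non_tra] <- calls$posB[non_tra] - calls$posA[non_tra]
      calls$caller <- caller
      calls
    }
    fps <- function(caller, base) {
      m <- round(cfg$fp_rate * n)
      if (m == 0) return(NULL)
      ftype <- rep_len(c("DEL", "DUP", "INV", "TRA"), m)
      fposA <- as.integer(base + (seq_len(m) - 1L) * 1e6)
      ftra <- ftype == "TRA"
      fchromB <- ifelse(ftra, "chr2", "chr1")
      fposB <- as.integer(fposA + 2e4)
      sv_calls(ftype, "chr1", fposA, fchromB, fposB, mapq = 60L,
               sample = "tumor1", caller = caller,
               id = paste0("fp_", caller, "_", seq_len(m)))
    }
    caller_a <- rbind(jitter(truth, "callerA"), fps("callerA", 2e8))
    caller_b <- rbind(jitter(truth, "callerB"), fps("callerB", 3e8))
    n_wt <- round(cfg$wt_frac * n)
    wildtype <- truth[seq_len(n_wt), , drop = FALSE]
    if (n_wt > 0) wildtype$caller <- "wt"
    gene_breaks <- data.frame(
      gene = unlist(truth$genes[tra]),
      sample = "tumor1", stringsAsFactors = FALSE)
    truth_sidecar <- truth
    attr(truth_sidecar, "wt_ids") <- truth$id[seq_len(n_wt)]
    list(caller_a = caller_a, caller_b = caller_b, wildtype = wildtype,
         truth = truth_sidecar, gene_breaks = gene_breaks)
  })
}

#' Deterministic synthetic SBS signature profiles
#'
#' Builds a synthetic stand-in for a reference single-base-substitution
#' signature matrix: each row is a Dirichlet-like probability profile over
#' the 96 trinucleotide channels (gamma draws, normalized). Low
#' concentration yields the peaked, sparse shapes characteristic of real
#' signatures.
#'
#' @param n_signatures number of profiles.
#' @param seed RNG seed.
#' @param concentration gamma shape; smaller = sparser profiles.
#' @param names row names (default SBS1..SBSn).
#' @return numeric matrix signatures x 96, rows summing to 1.
#' @export
synthetic_signatures <- function(n_signatures = 5, seed = 42,
                                 concentration = 0.3,
                                 names = paste0("SBS", seq_len(n_signatures))) {
  with_seed(seed + 404000, {
    m <- matrix(stats::rgamma(n_signatures * 96, shape = concentration),
                n_signatures, 96,
                dimnames = list(names, sbs_channels()))
    m / rowSums(m)
  })
}

#' Generate signature-mixture mutation catalogs
#'
#' Draws `n_mutations` channel counts per sample from the multinomial
#' mixture `sum_k w_k S_k` over the 96 channels.
#'
#' @param cfg `synth_config`; `signature_mixture` names must exist in
#'   `sigs`.
#' @param sigs signature matrix (rows = probability profiles over 96
#'   channels); default [synthetic_signatures()] from the config seed.
#' @param n_samples catalog rows to generate.
#' @return integer matrix samples x 96 with a `truth` attribute holding
#'   the mixture.
#' @export
gen_mutation_catalog <- function(cfg, sigs = NULL, n_samples = 1) {
  validate_synth_config(cfg)
  if (is.null(sigs)) sigs <- synthetic_signatures(seed = cfg$seed)
  mix <- cfg$signature_mixture
  unknown <- setdiff(names(mix), rownames(sigs))
  if (length(unknown))
    stop("configuration error: mixture references unknown signature: ",
         paste(unknown, collapse = ", "))
  p <- as.numeric(mix %*% sigs[names(mix), , drop = FALSE])
  catalog <- with_seed(cfg$seed + 404, {
    if (cfg$n_mutations == 0) {
      matrix(0L, n_samples, 96)
    } else {
      t(stats::rmultinom(n_samples, cfg$n_mutations, p))
    }
  })
  dimnames(catalog) <- list(paste0("catalog_", seq_len(n_samples)),
                            sbs_channels())
  storage.mode(catalog) <- "integer"
  attr(catalog, "truth") <- list(mixture = mix)
  catalog
}

#' Generate group-structured survival records
#'
#' Event times are exponential with rate `log(2) / median` per group;
#' independent exponential censoring is tuned so the expected censored
#' fraction equals `censor_rate` (for competing exponentials the censoring
#' probability is `rate_c / (rate_c + rate_t)`).
#'
#' @param cfg `synth_config`.
#' @return data.frame (sample, time, event, group) with a `truth`
#'   attribute holding the group medians.
#' @export
gen_survival <- function(cfg) {
  validate_synth_config(cfg)
  groups <- names(cfg$survival_medians)
  records <- with_seed(cfg$seed + 505, {
    do.call(rbind, lapply(groups, function(g) {
      med <- cfg$survival_medians[[g]]
      rate <- log(2) / med
      tt <- stats::rexp(cfg$n_per_group, rate)
      if (cfg$censor_rate >= 1) {
        time <- tt * stats::runif(cfg$n_per_group) # censor strictly before event
        event <- rep(0L, cfg$n_per_group)
      } else if (cfg$censor_rate <= 0) {
        time <- tt
        event <- rep(1L, cfg$n_per_group)
      } else {
        crate <- rate * cfg$censor_rate / (1 - cfg$censor_rate)
        cc <- stats::rexp(cfg$n_per_group, crate)
        time <- pmin(tt, cc)
        event <- as.integer(tt <= cc)
      }
      data.frame(sample = paste0(g, "_", seq_len(cfg$n_per_group)),
                 time = time, event = event, group = g,
                 stringsAsFactors = FALSE)
    }))
  })
  attr(records, "truth") <- list(medians = cfg$survival_medians)
  records
}
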