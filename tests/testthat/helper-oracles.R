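# Independent oracle implementations used to check the package's
# algorithms. These deliberately use different algorithms (enumeration,
# brute force, closed forms) from the code paths they verify.

# Kendall tau-b by explicit pair enumeration with tie bookkeeping.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx * dy > 0) C <- C + 1
      if (dx * dy < 0) D <- D + 1
    }
  }
  ties <- function(v) { t <- table(v); sum(t * (t - 1)) / 2 }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - ties(x)) * (n0 - ties(y)))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# Exhaustive one-to-one SV matching: over the candidate-pair graph
# (same type/chromosomes, both breakpoints within `margin`), enumerate all
# matchings within each connected component and keep the one maximizing
# the number of matches, breaking ties by the smallest total breakpoint
# distance. Returns matched (i, j) pairs, unordered.
oracle_sv_match <- function(calls_a, calls_b, margin) {
  cand <- momic:::sv_candidate_pairs(calls_a, calls_b, margin)
  if (nrow(cand) == 0) return(cand[, c("i", "j")])
  # connected components over the bipartite candidate graph
  comp_a <- seq_len(nrow(calls_a)); comp_b <- rep(NA_integer_, nrow(calls_b))
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(cand))) {
      ca <- comp_a[cand$i[r]]; cb <- comp_b[cand$j[r]]
      m <- min(ca, cb, na.rm = TRUE)
      if (is.na(cb) || cb != m) { comp_b[cand$j[r]] <- m; changed <- TRUE }
      if (ca != m) { comp_a[comp_a == ca] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  best_pairs <- list()
  for (comp in unique(comp_a[cand$i])) {
    rows <- cand[comp_a[cand$i] == comp, , drop = FALSE]
    # enumerate subsets of candidate pairs that form a matching
    nr <- nrow(rows)
    best <- NULL; best_size <- -1; best_dist <- Inf
    for (mask in 0:(2^nr - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nr) - 1)) > 0)
      if (anyDuplicated(rows$i[sel]) || anyDuplicated(rows$j[sel])) next
      size <- length(sel); dist <- sum(rows$dist[sel])
      if (size > best_size || (size == best_size && dist < best_dist)) {
        best <- sel; best_size <- size; best_dist <- dist
      }
    }
    best_pairs[[length(best_pairs) + 1]] <- rows[best, c("i", "j")]
  }
  out <- do.call(rbind, best_pairs)
  out[order(out$i), , drop = FALSE]
}

# Hand-executable ssGSEA running sum on a ranked list.
oracle_ssgsea_walk <- function(expr_column, gene_set, alpha) {
  ord <- order(-expr_column, names(expr_column))
  x <- expr_column[ord]
  genes <- names(x)
  inside <- genes %in% gene_set
  n <- length(x); m <- sum(inside)
  p_in <- p_out <- numeric(n)
  acc_in <- acc_out <- 0
  w_total <- sum(abs(x[inside])^alpha)
  score <- 0
  for (i in seq_len(n)) {
    if (inside[i]) acc_in <- acc_in + abs(x[i])^alpha / w_total
    else acc_out <- acc_out + 1 / (n - m)
    score <- score + (acc_in - acc_out)
  }
  unname(score)
}

# small deterministic SNV call-set builder
make_snvs <- function(n, sample = "s1", caller = "caller", seed = 1) {
  if (n == 0)
    return(snv_calls("chr1", 1L, "C", "T", sample = sample,
                     caller = caller)[0, ])
  set.seed(seed)
  snv_calls(chrom = paste0("chr", sample.int(5, n, replace = TRUE)),
            pos = sample.int(1e6, n),
            ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
            alt = "N", # placeholder, fixed below
            impact = sample(c("LOW", "MODERATE", "HIGH"), n, replace = TRUE),
            gene = paste0("G", sample.int(50, n, replace = TRUE)),
            sample = sample, caller = caller) |>
    within({
      alt <- ifelse(ref == "A", "G", "A")
    })
}

# random SV call-set pair with known truth, for matcher property tests
random_sv_instance <- function(seed, n_events, jitter_sd, fp_rate = 0) {
  cfg <- synth_config(seed = seed, n_sv_events = n_events,
                      sv_jitter_sd = jitter_sd, fp_rate = fp_rate,
                      wt_frac = 0)
  gen_sv_callsets(cfg)
}
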