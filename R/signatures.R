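# Trinucleotide mutation catalogs and single-base-substitution signature
# exposure refitting by constrained forward selection.

#' The 96 trinucleotide substitution channels
#'
#' Pyrimidine-reference channels "X[R>A]Y" for the six substitution classes
#' C>A, C>G, C>T, T>A, T>C, T>G and all 4x4 flanking contexts, in
#' lexicographic order (A\[C>A\]A first, T\[T>G\]T last).
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b5 = bases, sub = subs, b3 = bases,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b5, "[", g$sub, "]", g$b3))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

#' Collapse SNV calls to a 96-channel mutation catalog
#'
#' Each SNV is mapped to one of the 96 channels using its trinucleotide
#' context; purine-reference calls are reverse-complemented to the
#' pyrimidine convention.
#'
#' @param snvs SNV call data.frame (single-base ref/alt only).
#' @param contexts named character vector mapping "chrom:pos" to the
#'   reference-strand trinucleotide centered on the variant.
#' @return integer matrix samples x 96.
#' @export
catalog_from_snvs <- function(snvs, contexts) {
  if (nrow(snvs) == 0)
    return(matrix(0L, 1, 96, dimnames = list("sample", sbs_channels())))
  key <- paste0(snvs$chrom, ":", snvs$pos)
  miss <- !(key %in% names(contexts))
  if (any(miss))
    stop("missing trinucleotide context for: ",
         paste(utils::head(key[miss], 10), collapse = ", "))
  tri <- contexts[key]
  ref <- snvs$ref; alt <- snvs$alt
  if (any(substr(tri, 2, 2) != ref))
    stop("context middle base disagrees with ref allele")
  purine <- ref %in% c("A", "G")
  tri[purine] <- revcomp(tri[purine])
  alt[purine] <- chartr("ACGT", "TGCA", alt[purine])
  channel <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt, "]",
                    substr(tri, 3, 3))
  channels <- sbs_channels()
  bad <- !(channel %in% channels)
  if (any(bad)) stop("invalid channel derived: ", channel[bad][1])
  samples <- unique(snvs$sample)
  out <- matrix(0L, max(1L, length(samples)), 96,
                dimnames = list(if (length(samples)) samples else "sample",
                                channels))
  if (nrow(snvs)) {
    tab <- table(snvs$sample, factor(channel, levels = channels))
    out[rownames(tab), ] <- as.integer(tab)
  }
  out
}

# Nonnegative least squares with the weights constrained to sum <= 1,
# by projected gradient with a fixed 1/L step. `basis` is channels x k.
nnls_simplex <- function(basis, y, max_iter = 2000, tol = 1e-12) {
  k <- ncol(basis)
  ata <- crossprod(basis)
  aty <- crossprod(basis, y)
  L <- 2 * max(eigen(ata, symmetric = TRUE, only.values = TRUE)$values)
  w <- rep(1 / (2 * k), k)
  project <- function(w) {
    w <- pmax(w, 0)
    if (sum(w) <= 1) return(w)
    # Euclidean projection onto the probability simplex
    u <- sort(w, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u > (css - 1) / seq_along(u)))
    pmax(w - (css[rho] - 1) / rho, 0)
  }
  for (it in seq_len(max_iter)) {
    grad <- 2 * (ata %*% w - aty)
    w_new <- project(w - as.numeric(grad) / L)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  sse <- sum((y - basis %*% w)^2)
  list(w = as.numeric(w), sse = sse)
}

#' Refit signature exposures for one mutation catalog
#'
#' Normalizes the 96-channel counts to frequencies, then runs forward
#' selection: at each step the signature whose inclusion (refitting
#' nonnegative weights constrained to sum at most 1 over the selected set)
#' most reduces the residual sum of squares is added, stopping once the
#' best improvement falls below `tol`. Weights below `cutoff` are
#' discarded, the survivors refit once, and the retained weights
#' renormalized to sum 1.
#'
#' @param catalog_row integer/numeric vector of 96 channel counts with a
#'   positive total.
#' @param sigs signature matrix (signatures x 96, rows summing to 1).
#' @param cutoff minimum retained weight (default 0.06).
#' @param tol minimum SSE improvement to continue selection (default 1e-3).
#' @return list of class `signature_exposure`: `weights` (named, sum 1),
#'   `residual_sse`, and `sse_path` (SSE after each accepted step,
#'   non-increasing).
#' @export
refit_exposures <- function(catalog_row, sigs, cutoff = 0.06, tol = 1e-3) {
  if (sum(catalog_row) <= 0) stop("catalog row has zero mutations")
  stopifnot(length(catalog_row) == 96, ncol(sigs) == 96)
  if (any(abs(rowSums(sigs) - 1) > 1e-6))
    stop("signature rows must sum to 1")
  y <- as.numeric(catalog_row) / sum(catalog_row)
  basis_all <- t(sigs) # channels x signatures
  selected <- integer()
  sse_prev <- sum(y^2) # empty-model residual
  sse_path <- numeric()
  fit_prev <- NULL
  repeat {
    remaining <- setdiff(seq_len(nrow(sigs)), selected)
    if (length(remaining) == 0) break
    fits <- lapply(remaining, function(j)
      nnls_simplex(basis_all[, c(selected, j), drop = FALSE], y))
    sses <- vapply(fits, `[[`, numeric(1), "sse")
    best <- which.min(sses)
    if (sse_prev - sses[best] < tol) break
    selected <- c(selected, remaining[best])
    fit_prev <- fits[[best]]
    sse_prev <- sses[best]
    sse_path <- c(sse_path, sse_prev)
  }
  if (length(selected) == 0)
    stop("no signature improves the fit above tol")
  w <- fit_prev$w
  keep <- w >= cutoff
  if (!any(keep)) keep <- w == max(w) # retain at least the dominant signature
  selected <- selected[keep]
  refit <- nnls_simplex(basis_all[, selected, drop = FALSE], y)
  w <- refit$w
  weights <- stats::setNames(w / sum(w), rownames(sigs)[selected])
  structure(list(weights = weights, residual_sse = refit$sse,
                 sse_path = sse_path),
            class = "signature_exposure")
}

#' Refit exposures for every catalog row
#'
#' @param catalog samples x 96 count matrix.
#' @param sigs signature matrix.
#' @param ... passed to [refit_exposures()].
#' @return named list of `signature_exposure` per sample.
#' @export
refit_exposures_all <- function(catalog, sigs, ...) {
  out <- lapply(seq_len(nrow(catalog)), function(i)
    refit_exposures(catalog[i, ], sigs, ...))
  names(out) <- rownames(catalog)
  out
}
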