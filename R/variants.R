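# Consensus somatic variant logic: two-caller SNV intersection, germline
# subtraction, structural-variant consensus with positional margins and
# quality filters, integer copy number, conserved-event and burden
# summaries.

#' Two-caller SNV consensus
#'
#' Retains calls present in both call sets under exact
#' (chrom, pos, ref, alt) identity. Annotation (impact, gene) is taken from
#' the first caller; output is sorted by (chrom, pos).
#'
#' @param calls_a,calls_b SNV call data.frames from the same sample.
#' @return SNV call data.frame.
#' @export
consensus_snvs <- function(calls_a, calls_b) {
  samp <- unique(c(calls_a$sample, calls_b$sample))
  if (length(samp) > 1)
    stop("consensus_snvs: call sets mix samples: ",
         paste(samp, collapse = ", "))
  keep <- snv_key(calls_a) %in% snv_key(calls_b)
  out <- calls_a[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract germline variants from somatic calls
#'
#' Removes somatic calls whose (chrom, pos, ref, alt) appears in the
#' germline set (strain-background subtraction); input order is preserved.
#' Idempotent.
#'
#' @param somatic,germline SNV call data.frames.
#' @return SNV call data.frame.
#' @export
subtract_germline <- function(somatic, germline) {
  if (nrow(germline) == 0) return(somatic)
  out <- somatic[!(snv_key(somatic) %in% snv_key(germline)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Candidate pairs (i from a, j from b): same type, same chromosome(s), both
# breakpoints within `margin` bp. Returns a data.frame ordered for greedy
# one-to-one resolution: smallest combined distance first, ties by
# leftmost caller-A call, then by index.
sv_candidate_pairs <- function(calls_a, calls_b, margin) {
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0)
    return(data.frame(i = integer(), j = integer(), dist = integer()))
  idx <- expand.grid(i = seq_len(nrow(calls_a)), j = seq_len(nrow(calls_b)))
  a <- calls_a[idx$i, ]; b <- calls_b[idx$j, ]
  ok <- a$type == b$type & a$chromA == b$chromA & a$chromB == b$chromB &
    abs(a$posA - b$posA) <= margin & abs(a$posB - b$posB) <= margin
  idx <- idx[ok, , drop = FALSE]
  idx$dist <- abs(calls_a$posA[idx$i] - calls_b$posA[idx$j]) +
    abs(calls_a$posB[idx$i] - calls_b$posB[idx$j])
  idx[order(idx$dist, calls_a$posA[idx$i], idx$i, idx$j), , drop = FALSE]
}

# Greedy one-to-one matching over candidate pairs; each call matches at
# most one partner. Returns matched (i, j) index pairs.
sv_greedy_match <- function(calls_a, calls_b, margin) {
  cand <- sv_candidate_pairs(calls_a, calls_b, margin)
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[r] <- TRUE
    }
  }
  cand[keep, c("i", "j"), drop = FALSE]
}

# TRUE for calls with a same-type wildtype call matching within the
# positional margin (both breakpoints).
sv_in_wildtype <- function(calls, wildtype, margin) {
  if (nrow(wildtype) == 0 || nrow(calls) == 0)
    return(logical(nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    any(wildtype$type == calls$type[i] &
          wildtype$chromA == calls$chromA[i] &
          wildtype$chromB == calls$chromB[i] &
          abs(wildtype$posA - calls$posA[i]) <= margin &
          abs(wildtype$posB - calls$posB[i]) <= margin)
  }, logical(1))
}

merge_matched <- function(calls_a, calls_b, pairs) {
  out <- calls_a[pairs$i, , drop = FALSE]
  out$mapq <- pmin(calls_a$mapq[pairs$i], calls_b$mapq[pairs$j])
  out$caller <- rep("consensus", nrow(out))
  out$genes <- mapply(function(ga, gb) union(ga, gb),
                      calls_a$genes[pairs$i], calls_b$genes[pairs$j],
                      SIMPLIFY = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-caller structural-variant consensus (CNVs and inversions)
#'
#' A pair matches when type and chromosome agree and both breakpoints lie
#' within `margin` bp; matches are resolved one-to-one greedily by smallest
#' combined breakpoint distance (ties by leftmost caller-A call). Merged
#' calls take caller-A coordinates and the pair's minimum MAPQ, then pass
#' through three order-independent filters: length strictly greater than
#' `min_length`, MAPQ at least `min_mapq`, and no same-type wildtype call
#' matching under the same positional rule.
#'
#' @param calls_a,calls_b SV call data.frames (caller A coordinates are
#'   reported).
#' @param wildtype wildtype / normal SV calls for background subtraction.
#' @param kind "CNV" (DEL + DUP) or "INV"; calls of other types are an
#'   error.
#' @param margin positional tolerance per breakpoint, bp.
#' @param min_length minimum event length, bp (exclusive bound).
#' @param min_mapq minimum merged MAPQ (inclusive).
#' @return merged, filtered SV call data.frame.
#' @export
consensus_svs <- function(calls_a, calls_b, wildtype = NULL,
                          kind = c("CNV", "INV"),
                          margin = 100, min_length = 10000, min_mapq = 60) {
  kind <- match.arg(kind)
  allowed <- if (kind == "CNV") c("DEL", "DUP") else "INV"
  for (cs in list(calls_a, calls_b)) {
    bad <- setdiff(unique(cs$type), allowed)
    if (length(bad))
      stop("consensus_svs: kind ", kind, " cannot take type ",
           paste(bad, collapse = ", "))
  }
  if (is.null(wildtype)) wildtype <- calls_a[0, , drop = FALSE]
  pairs <- sv_greedy_match(calls_a, calls_b, margin)
  merged <- merge_matched(calls_a, calls_b, pairs)
  keep <- merged$length > min_length & merged$mapq >= min_mapq &
    !sv_in_wildtype(merged, wildtype, margin)
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-caller translocation consensus with gene-break intersection
#'
#' Matching as in [consensus_svs()] but with a wider positional margin, no
#' length minimum and a lower MAPQ floor; a merged translocation is
#' retained only when at least one of its annotated genes appears in the
#' gene-break table for the same sample.
#'
#' @param calls_a,calls_b TRA call data.frames.
#' @param gene_breaks data.frame (gene, sample) of gene-break calls.
#' @param margin positional tolerance per breakpoint, bp.
#' @param min_mapq minimum merged MAPQ (inclusive).
#' @return merged, filtered TRA call data.frame.
#' @export
consensus_translocations <- function(calls_a, calls_b, gene_breaks,
                                     margin = 1000, min_mapq = 50) {
  for (cs in list(calls_a, calls_b))
    if (nrow(cs) && any(cs$type != "TRA"))
      stop("consensus_translocations expects only TRA calls")
  pairs <- sv_greedy_match(calls_a, calls_b, margin)
  merged <- merge_matched(calls_a, calls_b, pairs)
  has_break <- vapply(seq_len(nrow(merged)), function(i) {
    g <- merged$genes[[i]]
    length(g) > 0 && any(gene_breaks$gene %in% g &
                           gene_breaks$sample == merged$sample[i])
  }, logical(1))
  out <- merged[merged$mapq >= min_mapq & has_break, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integer copy number from a segment log2 ratio
#'
#' `round(baseline_ploidy * 2^log2_ratio)` with half-up rounding, floored
#' at zero.
#'
#' @param log2_ratio segment log2 ratio(s); must be finite.
#' @param baseline_ploidy assumed diploid baseline (>= 1).
#' @return integer copy number(s).
#' @export
integer_cn_from_log2 <- function(log2_ratio, baseline_ploidy = 2L) {
  if (baseline_ploidy < 1) stop("baseline_ploidy must be >= 1")
  if (any(!is.finite(log2_ratio)))
    stop("non-finite log2 ratio")
  raw <- baseline_ploidy * 2^log2_ratio
  pmax(0L, as.integer(floor(raw + 0.5))) # half-up, never negative
}

#' Conserved impactful mutations per group
#'
#' A gene is conserved in a group when at least `frac` of the group's
#' samples carry one or more MODERATE or HIGH impact calls in it. Also
#' reports the cross-group overlap structure (Venn region counts keyed by
#' group membership pattern, e.g. "EMT&squamous").
#'
#' @param calls_by_sample named list, sample -> SNV call data.frame.
#' @param groups named character vector, sample -> group.
#' @param frac conservation threshold in (0, 1] (inclusive).
#' @return list with `sets` (group -> character vector of genes) and
#'   `venn` (named integer vector of region counts).
#' @export
conserved_mutations <- function(calls_by_sample, groups, frac = 0.66) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  groups <- groups[names(calls_by_sample)]
  if (anyNA(groups)) stop("groups missing for some samples")
  sets <- lapply(split(names(calls_by_sample), groups), function(samps) {
    if (length(samps) == 0) stop("empty group")
    per_sample <- lapply(samps, function(s) {
      calls <- calls_by_sample[[s]]
      unique(calls$gene[calls$impact %in% c("MODERATE", "HIGH") &
                          nzchar(calls$gene)])
    })
    tab <- table(unlist(per_sample))
    sort(names(tab)[tab / length(samps) >= frac])
  })
  if (any(lengths(split(names(calls_by_sample), groups)) == 0))
    stop("empty group")
  all_genes <- unique(unlist(sets))
  pattern <- vapply(all_genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, "")
  venn <- table(pattern)
  list(sets = sets, venn = stats::setNames(as.integer(venn), names(venn)))
}

#' Per-sample somatic mutational burden
#'
#' @param calls_by_sample named list, sample -> consensus-filtered SNV call
#'   data.frame.
#' @return named integer vector of call counts.
#' @export
mutational_burden <- function(calls_by_sample) {
  vapply(calls_by_sample, nrow, integer(1))
}
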