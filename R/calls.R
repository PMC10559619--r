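# Call-record constructors. Both are plain data.frames with validated
# columns so they print, subset and rbind naturally.

#' Construct SNV call records
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (>= 1).
#' @param ref,alt reference / variant bases (must differ).
#' @param impact predicted impact, one of LOW, MODERATE, HIGH, MODIFIER or
#'   empty.
#' @param gene gene symbol or empty string.
#' @param sample,caller labels, recycled.
#' @return data.frame with one row per call.
#' @export
snv_calls <- function(chrom, pos, ref, alt, impact = "", gene = "",
                      sample = "sample", caller = "caller") {
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("SNV positions must be >= 1")
  if (any(ref == alt)) stop("ref must differ from alt")
  ok <- impact %in% c("", "LOW", "MODERATE", "HIGH", "MODIFIER")
  if (!all(ok)) stop("unknown impact: ", paste(unique(impact[!ok]), collapse = ", "))
  data.frame(chrom = as.character(chrom), pos = pos,
             ref = as.character(ref), alt = as.character(alt),
             impact = as.character(impact), gene = as.character(gene),
             sample = as.character(sample), caller = as.character(caller),
             stringsAsFactors = FALSE)
}

#' Construct SV call records
#'
#' Breakpoint-pair calls. For non-translocations (DEL, DUP, INV) both
#' breakpoints lie on one chromosome, posB > posA, and length is the
#' breakpoint span; translocations (TRA) have length 0.
#'
#' @param type DEL, DUP, INV or TRA.
#' @param chromA,posA first breakpoint (1-based).
#' @param chromB,posB second breakpoint (1-based).
#' @param mapq mapping quality in 0..60.
#' @param sample,caller labels, recycled.
#' @param id event identifiers (default running index).
#' @param genes list of per-call gene-symbol vectors (translocation
#'   annotation), or NULL.
#' @return data.frame with a list column `genes`.
#' @export
sv_calls <- function(type, chromA, posA, chromB, posB, mapq = 60L,
                     sample = "sample", caller = "caller",
                     id = NULL, genes = NULL) {
  n <- length(type)
  if (is.null(id)) id <- as.character(seq_len(n))
  if (is.null(genes)) genes <- rep(list(character()), n)
  if (!all(type %in% c("DEL", "DUP", "INV", "TRA")))
    stop("SV type must be DEL, DUP, INV or TRA")
  posA <- as.integer(posA); posB <- as.integer(posB)
  mapq <- as.integer(mapq)
  if (any(mapq < 0L | mapq > 60L)) stop("MAPQ must lie in [0, 60]")
  non_tra <- type != "TRA"
  if (any(non_tra & (chromA != chromB)))
    stop("non-TRA calls must have chromA == chromB")
  if (any(non_tra & (posB <= posA)))
    stop("non-TRA calls must have posB > posA")
  len <- ifelse(non_tra, posB - posA, 0L)
  out <- data.frame(type = as.character(type),
                    chromA = as.character(chromA), posA = posA,
                    chromB = as.character(chromB), posB = posB,
                    length = as.integer(len), mapq = mapq,
                    sample = as.character(sample),
                    caller = as.character(caller),
                    id = as.character(id), stringsAsFactors = FALSE)
  out$genes <- genes
  out
}

# shared key for exact SNV identity matching
snv_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
}
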