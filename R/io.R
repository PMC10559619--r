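# File formats used throughout the pipeline. Conventions:
#   * SNV/VCF positions are 1-based; BEDPE and segment intervals are
#     0-based half-open. All conversions happen here and nowhere else.
#   * Internal SV breakpoints (posA/posB) are 1-based.

#' Write an expression matrix as GCT 1.2
#'
#' @param em `expr_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gct <- function(em, path) {
  v <- em$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(v), ncol(v)), con)
  writeLines(paste(c("NAME", "Description", colnames(v)), collapse = "\t"), con)
  body <- cbind(rownames(v), "na", format(v, trim = TRUE, digits = 15))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GCT 1.2 expression file
#'
#' @param path GCT file; version line must be `#1.2`.
#' @return `expr_matrix` (metadata left NA; attach with [expression_matrix()]
#'   if known).
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2)
  if (!identical(header[1], "#1.2"))
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(header[2], "\t")[[1]])
  tab <- utils::read.delim(path, skip = 2, check.names = FALSE,
                           stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(v) <- tab[[1]]
  if (nrow(v) != dims[1] || ncol(v) != dims[2])
    stop("GCT dimension line disagrees with body")
  expression_matrix(v)
}

#' Write / read expression as plain TSV (genes x samples)
#' @param em `expr_matrix`.
#' @param path file path.
#' @return `path` / `expr_matrix`.
#' @export
write_expression_tsv <- function(em, path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  expression_matrix(v)
}

#' Write / read per-sample metadata TSV (sample, group, batch)
#' @param meta data.frame with columns sample, group, batch.
#' @param path file path.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read SV call sets as BEDPE
#'
#' Columns: chromA, startA, endA, chromB, startB, endB, name, mapq,
#' strandA, strandB, type, caller. Internal 1-based breakpoints map to
#' 0-based half-open single-base intervals; `name` carries
#' `<sample>|<event id>`; per-call gene annotations are a 13th
#' semicolon-joined column (empty when absent).
#'
#' @param calls SV call data.frame (see [sv_calls()]).
#' @param path file path.
#' @return `path` / SV call data.frame.
#' @export
write_bedpe <- function(calls, path) {
  genes <- vapply(calls$genes, function(g) paste(g, collapse = ";"), "")
  df <- data.frame(
    chromA = calls$chromA, startA = calls$posA - 1L, endA = calls$posA,
    chromB = calls$chromB, startB = calls$posB - 1L, endB = calls$posB,
    name = paste(calls$sample, calls$id, sep = "|"),
    mapq = calls$mapq, strandA = "+", strandB = "+",
    type = calls$type, caller = calls$caller, genes = genes,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  cols <- c("chromA", "startA", "endA", "chromB", "startB", "endB",
            "name", "mapq", "strandA", "strandB", "type", "caller", "genes")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 12) tab$V13 <- ""
  names(tab) <- cols
  name <- strsplit(tab$name, "|", fixed = TRUE)
  sv_calls(type = tab$type,
           chromA = tab$chromA, posA = tab$startA + 1L,
           chromB = tab$chromB, posB = tab$startB + 1L,
           mapq = tab$mapq,
           sample = vapply(name, `[`, "", 1L),
           caller = tab$caller,
           id = vapply(name, `[`, "", 2L),
           genes = strsplit(tab$genes, ";", fixed = TRUE))
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a mutation catalog TSV (samples x 96 channels)
#' @param catalog integer matrix, samples in rows, colnames = the 96
#'   trinucleotide channels in COSMIC lexicographic order.
#' @param path file path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- data.frame(sample = rownames(catalog), catalog,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a signature matrix TSV (signatures x 96 channels)
#' @param sigs numeric matrix, rows = signatures (profiles sum to 1).
#' @param path file path.
#' @export
write_signatures_tsv <- function(sigs, path) {
  df <- data.frame(signature = rownames(sigs), sigs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures_tsv
#' @export
read_signatures_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Write / read gene-level copy number TSV
#' (gene, sample, integer_cn, log2_ratio)
#' @param cn data.frame with columns gene, sample, integer_cn (and
#'   optionally log2_ratio).
#' @param path file path.
#' @export
write_cn_tsv <- function(cn, path) {
  if (is.null(cn$log2_ratio))
    cn$log2_ratio <- log2(pmax(cn$integer_cn, 0.5) / 2)
  utils::write.table(cn[, c("gene", "sample", "integer_cn", "log2_ratio")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_tsv
#' @export
read_cn_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$delta <- tab$integer_cn - 2L
  tab
}

#' Write / read survival records TSV (sample, time_months, event, group)
#' @param records data.frame with columns sample, time, event, group.
#' @param path file path.
#' @export
write_survival_tsv <- function(records, path) {
  df <- data.frame(sample = records$sample, time_months = records$time,
                   event = records$event, group = records$group,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(sample = tab$sample, time = tab$time_months,
             event = as.integer(tab$event), group = tab$group,
             stringsAsFactors = FALSE)
}

#' Read somatic SNV calls from a VCF
#'
#' Parses a VCF v4.2 via vcfR; when a SnpEff-style `ANN=` INFO field is
#' present, predicted impact and gene symbol are taken from its first
#' annotation, otherwise both are left empty.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param sample sample label to attach to every call.
#' @param caller caller label to attach to every call.
#' @return SNV call data.frame (see [snv_calls()]).
#' @export
read_snv_vcf <- function(path, sample = "sample", caller = "caller") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_snv_vcf() needs the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  info <- vcfR::extract.info(vcf, "ANN")
  impact <- rep("", nrow(fix))
  gene <- rep("", nrow(fix))
  has_ann <- !is.na(info)
  if (any(has_ann)) {
    first <- vapply(strsplit(info[has_ann], ",", fixed = TRUE), `[`, "", 1L)
    parts <- strsplit(first, "|", fixed = TRUE)
    impact[has_ann] <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
    gene[has_ann] <- vapply(parts, function(p) if (length(p) >= 4) p[4] else "", "")
  }
  snv_calls(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
            ref = fix[, "REF"], alt = fix[, "ALT"],
            impact = impact, gene = gene,
            sample = sample, caller = caller)
}
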