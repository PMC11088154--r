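#' Gene model collection
#'
#' Holds exon and coding intervals for a set of genes on a shared
#' coordinate system (0-based half-open, matching the panel). Exons of a
#' gene must be sorted and non-overlapping; coding intervals must lie
#' within the exon union.
#'
#' @param exons data.frame with columns gene, chrom, start, end and
#'   optionally exon_index (assigned in coordinate order if absent),
#'   strand (default "+") and transcript.
#' @param coding data.frame with columns gene, chrom, start, end; defaults
#'   to the exon table (fully coding genes).
#' @return an object of class `smmip_gene_models`.
#' @export
gene_models <- function(exons, coding = NULL) {
  req <- c("gene", "chrom", "start", "end")
  if (length(setdiff(req, names(exons))))
    stop("exon table needs columns gene, chrom, start, end")
  exons$gene <- as.character(exons$gene)
  exons$chrom <- as.character(exons$chrom)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (is.null(exons$strand)) exons$strand <- "+"
  if (is.null(exons$transcript)) exons$transcript <- exons$gene
  exons <- exons[order(exons$gene, exons$chrom, exons$start), , drop = FALSE]
  if (is.null(exons$exon_index))
    exons$exon_index <- stats::ave(seq_len(nrow(exons)), exons$gene,
                                   FUN = seq_along)
  exons$exon_index <- as.integer(exons$exon_index)
  rownames(exons) <- NULL
  for (g in unique(exons$gene)) {
    e <- exons[exons$gene == g, ]
    if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in gene ", g)
  }
  if (is.null(coding)) coding <- exons[, req]
  coding$gene <- as.character(coding$gene)
  coding$chrom <- as.character(coding$chrom)
  coding$start <- as.integer(coding$start)
  coding$end <- as.integer(coding$end)
  rownames(coding) <- NULL
  for (g in unique(coding$gene)) {
    cg <- coding[coding$gene == g, c("chrom", "start", "end")]
    eg <- exons[exons$gene == g, c("chrom", "start", "end")]
    if (nrow(eg) == 0L) stop("coding intervals for unknown gene ", g)
    leftover <- setdiff_intervals(cg, eg)
    if (nrow(leftover))
      stop("coding intervals of gene ", g, " extend outside its exons")
  }
  structure(list(exons = exons, coding = coding),
            class = "smmip_gene_models")
}

#' @export
print.smmip_gene_models <- function(x, ...) {
  cat(sprintf("gene models: %d genes, %d exons, %d bp coding\n",
              length(unique(x$exons$gene)), nrow(x$exons),
              intervals_total_bp(x$coding)))
  invisible(x)
}

#' Write gene models as exon and coding BED files
#'
#' Exon rows are BED4 with name `gene:exon_index`; coding rows BED4 with
#' the gene name. Deterministic coordinate-sorted order.
#'
#' @param models an `smmip_gene_models`.
#' @param exon_path,coding_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gene_beds <- function(models, exon_path, coding_path) {
  e <- models$exons[order(models$exons$chrom, models$exons$start), ]
  write.table(data.frame(e$chrom, e$start, e$end,
                         paste0(e$gene, ":", e$exon_index)),
              exon_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cd <- models$coding[order(models$coding$chrom, models$coding$start), ]
  write.table(data.frame(cd$chrom, cd$start, cd$end, cd$gene),
              coding_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(exon_path, coding_path))
}

#' Read gene models from exon (and optional coding) BED files
#'
#' @param exon_path BED4 file whose name column is `gene` or
#'   `gene:exon_index`.
#' @param coding_path optional BED4 file with gene names; when absent the
#'   exons are taken as fully coding.
#' @return an `smmip_gene_models`.
#' @export
read_gene_models <- function(exon_path, coding_path = NULL) {
  e <- read.delim(exon_path, header = FALSE, sep = "\t", quote = "",
                  col.names = c("chrom", "start", "end", "name"))
  parts <- strsplit(as.character(e$name), ":", fixed = TRUE)
  exons <- data.frame(gene = vapply(parts, `[`, "", 1L),
                      chrom = as.character(e$chrom),
                      start = as.integer(e$start), end = as.integer(e$end),
                      stringsAsFactors = FALSE)
  idx <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  if (!anyNA(idx)) exons$exon_index <- as.integer(idx)
  coding <- NULL
  if (!is.null(coding_path)) {
    cd <- read.delim(coding_path, header = FALSE, sep = "\t", quote = "",
                     col.names = c("chrom", "start", "end", "name"))
    coding <- data.frame(gene = as.character(cd$name),
                         chrom = as.character(cd$chrom),
                         start = as.integer(cd$start),
                         end = as.integer(cd$end), stringsAsFactors = FALSE)
  }
  gene_models(exons, coding)
}
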