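#' Minimal pileup SNV caller over deduplicated molecules
#'
#' Desk-scale stand-in caller for end-to-end tests: stacks each kept
#' molecule's insert at its probe's target coordinates (no indels, no
#' realignment), builds a per-position deduplicated pileup and emits a
#' site when depth >= `min_depth` and the top non-reference base reaches
#' `min_alt_fraction`. Genotype is het for alt fraction in
#' \[`min_alt_fraction`, `hom_threshold`) and hom at or above
#' `hom_threshold`.
#'
#' @param dedup an `smmip_dedup` (kept molecules).
#' @param panel an `smmip_panel` (provides each probe's target
#'   coordinates).
#' @param reference named character vector of contig sequences, or a
#'   FASTA path.
#' @param min_depth minimum deduplicated depth at the site.
#' @param min_alt_fraction minimum alternate-allele fraction.
#' @param hom_threshold alt fraction at or above which the call is hom.
#' @return data.frame of class `smmip_snvs`: chrom, pos (1-based), ref,
#'   alt, depth, alt_count, alt_fraction, genotype.
#' @export
call_pileup_snvs <- function(dedup, panel, reference, min_depth = 10L,
                             min_alt_fraction = 0.2, hom_threshold = 0.8) {
  stopifnot(inherits(dedup, "smmip_dedup"), inherits(panel, "smmip_panel"))
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    rs <- Biostrings::readDNAStringSet(reference)
    reference <- setNames(as.character(rs), sub("\\s.*$", "", names(rs)))
  }
  kept <- dedup$kept
  p <- panel$probes
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), alt_count = integer(),
                      alt_fraction = numeric(), genotype = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(kept)) return(structure(empty, class = c("smmip_snvs",
                                                     "data.frame")))
  pm <- match(kept$probe_id, p$probe_id)
  if (anyNA(pm)) stop("kept molecules reference unknown probes")
  miss <- setdiff(unique(p$chrom[pm]), names(reference))
  if (length(miss))
    stop("reference contig missing: ", paste(miss, collapse = ", "))
  # explode molecules into (contig position, base) pairs
  len <- nchar(kept$insert_seq)
  pos0 <- unlist(mapply(function(s, l) seq.int(s, length.out = l),
                        p$start[pm], len, SIMPLIFY = FALSE))
  base <- unlist(strsplit(kept$insert_seq, "", fixed = TRUE))
  chrom <- rep(p$chrom[pm], len)
  keep <- base %in% c("A", "C", "G", "T")
  tab <- table(paste(chrom[keep], pos0[keep], sep = "\r"), base[keep])
  key <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  site_chrom <- key[, 1]
  site_pos0 <- as.integer(key[, 2])
  depth <- as.integer(rowSums(tab))
  refb <- substring(reference[site_chrom], site_pos0 + 1L, site_pos0 + 1L)
  counts <- as.matrix(tab)
  alt_counts <- counts
  alt_counts[cbind(seq_len(nrow(counts)),
                   match(refb, colnames(counts)))] <- 0L
  alt_i <- max.col(alt_counts, ties.method = "first")
  alt <- colnames(counts)[alt_i]
  alt_n <- alt_counts[cbind(seq_len(nrow(counts)), alt_i)]
  alt_fraction <- ifelse(depth > 0, alt_n / depth, 0)
  sel <- depth >= min_depth & alt_fraction >= min_alt_fraction
  out <- data.frame(chrom = site_chrom[sel], pos = site_pos0[sel] + 1L,
                    ref = refb[sel], alt = alt[sel], depth = depth[sel],
                    alt_count = as.integer(alt_n[sel]),
                    alt_fraction = alt_fraction[sel],
                    genotype = ifelse(alt_fraction[sel] >= hom_threshold,
                                      "hom", "het"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("smmip_snvs", "data.frame"))
}

#' Write pileup SNV calls as VCF 4.2 site records
#'
#' @param snvs an `smmip_snvs` data.frame.
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, sample = "SAMPLE") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=smmipkit pileup caller",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Deduplicated depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")), con)
  if (nrow(snvs)) {
    gt <- ifelse(snvs$genotype == "hom", "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f\tGT\t%s",
                       snvs$chrom, snvs$pos, snvs$ref, snvs$alt,
                       snvs$depth, snvs$alt_fraction, gt), con)
  }
  invisible(path)
}
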