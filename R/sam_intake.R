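#' Recover molecule assignments from an aligned SAM/BAM file
#'
#' Post-alignment intake route: reads aligned by an external mapper are
#' resolved to probes by maximal overlap of their alignment span with
#' the probe targets, and the UMB is recovered from the read-name
#' suffix (`name<delim>UMB`, delimiter configurable). One record per
#' read name is used (primary alignments); unmapped records count as
#' unassigned.
#'
#' @param path SAM or BAM file path (SAM is converted on the fly).
#' @param panel an `smmip_panel`.
#' @param umb_delim delimiter separating the read name from the tag.
#' @return an `smmip_assignments` (see [assign_reads()]);
#'   `arm_mismatches` is 0 for aligned intake.
#' @export
assignments_from_sam <- function(path, panel, umb_delim = "#") {
  stopifnot(inherits(panel, "smmip_panel"))
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required for SAM/BAM intake")
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "seq", "qual"),
      flag = flag))[[1]]
  n_all <- length(rec$qname)
  keep <- !duplicated(rec$qname)
  qname <- rec$qname[keep]
  rname <- as.character(rec$rname[keep])
  pos <- rec$pos[keep]
  seqs <- as.character(rec$seq[keep])
  quals <- as.character(rec$qual[keep])
  mapped <- !is.na(pos)
  # probe by maximal overlap of the alignment span with probe targets
  p <- panel$probes
  probe_of <- rep(NA_integer_, sum(keep))
  if (any(mapped)) {
    rg <- GenomicRanges::GRanges(rname[mapped],
                                 IRanges::IRanges(start = pos[mapped],
                                                  width = nchar(seqs[mapped])))
    pg <- intervals_to_granges(p[, c("chrom", "start", "end")])
    g <- harmonize_seqlevels(rg, pg)
    hits <- GenomicRanges::findOverlaps(g[[1]], g[[2]])
    if (length(hits)) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        g[[1]][S4Vectors::queryHits(hits)],
        g[[2]][S4Vectors::subjectHits(hits)]))
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      midx <- which(mapped)
      for (q in unique(qh)) {
        sel <- which(qh == q)
        probe_of[midx[q]] <- sh[sel[which.max(ov[sel])]]
      }
    }
  }
  # tag from the read-name suffix
  parts <- strsplit(qname, umb_delim, fixed = TRUE)
  umb <- vapply(parts, function(x)
    if (length(x) > 1L) x[length(x)] else NA_character_, "")
  ok <- !is.na(probe_of) & !is.na(umb)
  assignments <- data.frame(
    read_id = qname[ok], probe_id = p$probe_id[probe_of[ok]],
    umb = umb[ok], insert_seq = seqs[ok], insert_qual = quals[ok],
    arm_mismatches = 0L, stringsAsFactors = FALSE)
  counters <- list(total = sum(keep), assigned = sum(ok),
                   unassigned = sum(keep) - sum(ok),
                   on_target_fraction =
                     if (sum(keep) > 0) sum(ok) / sum(keep) else NA_real_)
  structure(list(assignments = assignments, counters = counters),
            class = "smmip_assignments")
}
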