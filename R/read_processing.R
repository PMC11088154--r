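# Positional Hamming distance of `pattern` against each element of `seqs`
# starting at 1-based offset `at`. Reads too short to hold the pattern get
# distance nchar(pattern) (all-mismatch) via space padding.
hamming_at <- function(seqs, pattern, at) {
  L <- nchar(pattern)
  if (!length(seqs)) return(integer(0))
  sub <- substr(seqs, at, at + L - 1L)
  short <- nchar(sub) < L
  if (any(short))
    sub[short] <- paste0(sub[short],
                         strrep(" ", L - nchar(sub[short])))
  a <- matrix(charToRaw(paste(sub, collapse = "")), nrow = L)
  b <- charToRaw(pattern)
  as.integer(colSums(a != b))
}

read_fastq_pair <- function(fastq_r1, fastq_r2) {
  r1 <- Biostrings::readDNAStringSet(fastq_r1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq_r2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("FASTQ pair files differ in read count: ",
         length(r1), " vs ", length(r2))
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  if (!identical(id1, id2))
    stop("FASTQ pair files are not in matching read order")
  list(read_id = id1,
       r1_seq = as.character(r1), r1_qual = as.character(S4Vectors::mcols(r1)$qualities),
       r2_seq = as.character(r2), r2_qual = as.character(S4Vectors::mcols(r2)$qualities))
}

#' Assign read pairs to probes and extract UMBs
#'
#' Resolves each read pair to at most one probe by exact-position Hamming
#' matching of both arms under the package's read structure
#' (R1 = extension arm + insert; R2 = UMB + ligation arm + reverse
#' complement of the insert). A pair is assigned when both arms match
#' within `max_arm_mismatch` mismatches; among multiple candidates the
#' fewest-total-mismatch probe wins (first in panel order on ties). The
#' 5' random tag is extracted from R2 and the arms and tag are trimmed
#' from the reported insert.
#'
#' @param fastq_r1,fastq_r2 paths to the paired FASTQ files (gzip
#'   allowed).
#' @param panel an `smmip_panel`.
#' @param max_arm_mismatch per-arm mismatch tolerance (no indels).
#' @return list of class `smmip_assignments`: `assignments` (data.frame
#'   read_id, probe_id, umb, insert_seq, insert_qual, arm_mismatches) and
#'   `counters` (total, assigned, unassigned, on_target_fraction).
#' @export
assign_reads <- function(fastq_r1, fastq_r2, panel, max_arm_mismatch = 1L) {
  stopifnot(inherits(panel, "smmip_panel"))
  rp <- read_fastq_pair(fastq_r1, fastq_r2)
  assign_read_pairs(rp, panel, max_arm_mismatch)
}

# Core assignment on an in-memory read-pair list (see read_fastq_pair).
assign_read_pairs <- function(rp, panel, max_arm_mismatch = 1L) {
  p <- panel$probes
  n <- length(rp$read_id)
  umb_len <- p$umb_len[1]
  best_probe <- rep(NA_integer_, n)
  best_mm <- rep(NA_integer_, n)
  for (i in seq_len(nrow(p))) {
    mm1 <- hamming_at(rp$r1_seq, p$ext_arm[i], 1L)
    mm2 <- hamming_at(rp$r2_seq, p$lig_arm[i], umb_len + 1L)
    ok <- mm1 <= max_arm_mismatch & mm2 <= max_arm_mismatch
    tot <- mm1 + mm2
    better <- ok & (is.na(best_mm) | tot < best_mm)
    best_probe[better] <- i
    best_mm[better] <- tot[better]
  }
  hit <- !is.na(best_probe)
  idx <- which(hit)
  pi <- best_probe[idx]
  arm_len <- nchar(p$ext_arm[pi])
  ins_start <- arm_len + 1L
  ins_end <- arm_len + panel$capture_length
  assignments <- data.frame(
    read_id = rp$read_id[idx],
    probe_id = p$probe_id[pi],
    umb = substr(rp$r2_seq[idx], 1L, umb_len),
    insert_seq = substr(rp$r1_seq[idx], ins_start, ins_end),
    insert_qual = substr(rp$r1_qual[idx], ins_start, ins_end),
    arm_mismatches = best_mm[idx],
    stringsAsFactors = FALSE)
  counters <- list(total = n, assigned = length(idx),
                   unassigned = n - length(idx),
                   on_target_fraction =
                     if (n > 0) length(idx) / n else NA_real_)
  structure(list(assignments = assignments, counters = counters),
            class = "smmip_assignments")
}

#' Deduplicate assigned reads by (probe, UMB)
#'
#' Keeps exactly one read per (probe_id, UMB) group, chosen uniformly at
#' random under `seed`; UMBs containing N cannot define a molecule and
#' are excluded from grouping (counted separately). Per-probe raw and
#' deduplicated read counts form the dedup report.
#'
#' @param assignments an `smmip_assignments` (or its `assignments`
#'   data.frame).
#' @param seed integer RNG seed for the random-discard draw.
#' @param panel an `smmip_panel`, used to zero-fill probes without reads.
#' @return list of class `smmip_dedup`: `kept` (the retained
#'   molecule-level reads), `per_probe` (probe_id, raw_reads,
#'   dedup_reads, duplicate_fraction), `totals`, `umb_ambiguous`,
#'   `unassigned`.
#' @export
deduplicate <- function(assignments, seed, panel) {
  stopifnot(inherits(panel, "smmip_panel"))
  unassigned <- 0L
  if (inherits(assignments, "smmip_assignments")) {
    unassigned <- assignments$counters$unassigned
    assignments <- assignments$assignments
  }
  amb <- grepl("N", assignments$umb, fixed = TRUE)
  a <- assignments[!amb, , drop = FALSE]
  key <- paste(a$probe_id, a$umb, sep = "\r")
  keep_idx <- integer(0)
  if (nrow(a)) {
    groups <- split(seq_len(nrow(a)), key)
    groups <- groups[order(names(groups))]
    keep_idx <- with_seed(seed, vapply(groups, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1)))
  }
  kept <- a[sort(keep_idx), , drop = FALSE]
  rownames(kept) <- NULL
  probe_ids <- panel$probes$probe_id
  raw <- as.integer(table(factor(a$probe_id, levels = probe_ids)))
  ded <- as.integer(table(factor(kept$probe_id, levels = probe_ids)))
  per_probe <- data.frame(probe_id = probe_ids, raw_reads = raw,
                          dedup_reads = ded,
                          duplicate_fraction =
                            ifelse(raw > 0, 1 - ded / raw, 0),
                          stringsAsFactors = FALSE)
  totals <- list(raw_reads = sum(raw), dedup_reads = sum(ded),
                 duplicate_fraction =
                   if (sum(raw) > 0) 1 - sum(ded) / sum(raw) else 0)
  structure(list(kept = kept, per_probe = per_probe, totals = totals,
                 umb_ambiguous = sum(amb), unassigned = unassigned),
            class = "smmip_dedup")
}

#' Per-probe coverage report
#'
#' One row per panel probe (zero-filled where no reads were assigned)
#' with raw and deduplicated counts, plus summary statistics on the
#' deduplicated coverage and the count of probes below the read
#' threshold (strictly less than, default 30).
#'
#' @param dedup an `smmip_dedup`.
#' @param panel an `smmip_panel`.
#' @param path optional TSV output path.
#' @param threshold low-coverage threshold on dedup reads.
#' @param on_target_fraction optional assignment-stage on-target fraction
#'   carried into the report summary.
#' @return object of class `smmip_coverage`: `probes` data.frame
#'   (probe_id, gene, raw_reads, dedup_reads, duplicate_fraction) and
#'   `summary` (mean/median dedup coverage, n_below, threshold,
#'   on_target_pct, duplicate_pct).
#' @export
coverage_report <- function(dedup, panel, path = NULL, threshold = 30L,
                            on_target_fraction = NULL) {
  stopifnot(inherits(dedup, "smmip_dedup"), inherits(panel, "smmip_panel"))
  probes <- merge(data.frame(probe_id = panel$probes$probe_id,
                             gene = panel$probes$gene,
                             stringsAsFactors = FALSE),
                  dedup$per_probe, by = "probe_id", sort = FALSE)
  probes <- probes[match(panel$probes$probe_id, probes$probe_id), ]
  rownames(probes) <- NULL
  summary <- list(
    mean_coverage = mean(probes$dedup_reads),
    median_coverage = median(probes$dedup_reads),
    n_below = sum(probes$dedup_reads < threshold),
    threshold = as.integer(threshold),
    on_target_pct = if (!is.null(on_target_fraction))
      100 * on_target_fraction else NA_real_,
    duplicate_pct = 100 * dedup$totals$duplicate_fraction)
  out <- structure(list(probes = probes, summary = summary),
                   class = "smmip_coverage")
  if (!is.null(path)) write_coverage(out, path)
  out
}

#' @export
print.smmip_coverage <- function(x, ...) {
  s <- x$summary
  cat(sprintf("coverage over %d probes: mean %.1fx, median %.1fx, %d probe(s) < %d reads\n",
              nrow(x$probes), s$mean_coverage, s$median_coverage,
              s$n_below, s$threshold))
  if (!is.na(s$on_target_pct))
    cat(sprintf("on-target %.1f%%, duplicates %.1f%%\n",
                s$on_target_pct, s$duplicate_pct))
  invisible(x)
}

#' Write / read a coverage report TSV
#'
#' @param coverage an `smmip_coverage`.
#' @param path TSV path.
#' @return `path` (write) or an `smmip_coverage` (read; summary
#'   recomputed, assignment-stage percentages absent).
#' @export
write_coverage <- function(coverage, path) {
  write.table(coverage$probes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @param threshold low-coverage threshold used when recomputing the
#'   summary.
#' @export
read_coverage <- function(path, threshold = 30L) {
  probes <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("probe_id", "gene", "raw_reads", "dedup_reads")
  if (length(setdiff(req, names(probes))))
    stop("coverage report lacks columns: ",
         paste(setdiff(req, names(probes)), collapse = ", "))
  structure(list(
    probes = probes,
    summary = list(mean_coverage = mean(probes$dedup_reads),
                   median_coverage = median(probes$dedup_reads),
                   n_below = sum(probes$dedup_reads < threshold),
                   threshold = as.integer(threshold),
                   on_target_pct = NA_real_,
                   duplicate_pct = if (sum(probes$raw_reads) > 0)
                     100 * (1 - sum(probes$dedup_reads) /
                              sum(probes$raw_reads)) else 0)),
    class = "smmip_coverage")
}

#' Compare QC metrics of two runs
#'
#' Side-by-side on-target percentage, duplicate percentage and mean
#' deduplicated coverage for two coverage reports over the same panel,
#' with the coverage drop `100 * (A - B) / A`.
#'
#' @param reportA,reportB `smmip_coverage` objects over the same panel.
#' @return data.frame with columns metric, A, B, change; the mean
#'   coverage row's `change` is the percentage drop from A to B.
#' @export
qc_compare <- function(reportA, reportB) {
  stopifnot(inherits(reportA, "smmip_coverage"),
            inherits(reportB, "smmip_coverage"))
  if (!identical(reportA$probes$probe_id, reportB$probes$probe_id))
    stop("coverage reports are over different panels")
  sa <- reportA$summary; sb <- reportB$summary
  data.frame(
    metric = c("on_target_pct", "duplicate_pct", "mean_coverage"),
    A = c(sa$on_target_pct, sa$duplicate_pct, sa$mean_coverage),
    B = c(sb$on_target_pct, sb$duplicate_pct, sb$mean_coverage),
    change = c(sb$on_target_pct - sa$on_target_pct,
               sb$duplicate_pct - sa$duplicate_pct,
               100 * (sa$mean_coverage - sb$mean_coverage) /
                 sa$mean_coverage),
    stringsAsFactors = FALSE)
}

#' Process one sample end to end
#'
#' Convenience wrapper: assign, deduplicate, report.
#'
#' @inheritParams assign_reads
#' @param seed dedup RNG seed.
#' @param out_dir optional directory for `coverage.tsv` and `qc.json`.
#' @param threshold low-coverage threshold.
#' @return list with `assignments`, `dedup`, `coverage`.
#' @export
process_sample <- function(fastq_r1, fastq_r2, panel, seed,
                           out_dir = NULL, max_arm_mismatch = 1L,
                           threshold = 30L) {
  asn <- assign_reads(fastq_r1, fastq_r2, panel, max_arm_mismatch)
  ded <- deduplicate(asn, seed, panel)
  cov <- coverage_report(ded, panel, threshold = threshold,
                         on_target_fraction =
                           asn$counters$on_target_fraction)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_coverage(cov, file.path(out_dir, "coverage.tsv"))
    jsonlite::write_json(
      c(asn$counters, cov$summary,
        list(umb_ambiguous = ded$umb_ambiguous)),
      file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  }
  list(assignments = asn, dedup = ded, coverage = cov)
}
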