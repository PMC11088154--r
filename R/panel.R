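#' smMIP panel objects
#'
#' An smMIP panel is the ordered collection of probes together with the
#' panel-wide tiling geometry: each probe captures a `capture_length` bp
#' target (110 bp by default) and genomically adjacent probes on the same
#' tile are designed to overlap by 20--40 bp. Every probe carries an
#' extension arm, a ligation arm, a random-tag (UMB) length, a pool
#' concentration in uM and a phosphorylation flag.
#'
#' @param probes data.frame with columns probe_id, gene, chrom, start, end,
#'   ext_arm, lig_arm and optionally umb_len (default 5), conc_uM
#'   (default 0.1), phosphorylated (default TRUE). Coordinates are 0-based
#'   half-open.
#' @param capture_length target length in bp each probe is designed to
#'   capture.
#' @param min_overlap,max_overlap allowed overlap range (bp) between
#'   adjacent probes of one tile.
#' @return an object of class `smmip_panel`.
#' @export
smmip_panel <- function(probes, capture_length = 110L, min_overlap = 20L,
                        max_overlap = 40L) {
  required <- c("probe_id", "gene", "chrom", "start", "end",
                "ext_arm", "lig_arm")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols))
    stop("panel table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(probes) == 0L) stop("empty panel")
  probes$probe_id <- as.character(probes$probe_id)
  probes$gene <- as.character(probes$gene)
  probes$chrom <- as.character(probes$chrom)
  probes$start <- as.integer(probes$start)
  probes$end <- as.integer(probes$end)
  probes$ext_arm <- toupper(as.character(probes$ext_arm))
  probes$lig_arm <- toupper(as.character(probes$lig_arm))
  if (is.null(probes$umb_len)) probes$umb_len <- 5L
  if (is.null(probes$conc_uM)) probes$conc_uM <- 0.1
  if (is.null(probes$phosphorylated)) probes$phosphorylated <- TRUE
  probes$umb_len <- as.integer(probes$umb_len)
  probes$conc_uM <- as.numeric(probes$conc_uM)
  probes$phosphorylated <- as.logical(probes$phosphorylated)
  rownames(probes) <- NULL

  capture_length <- as.integer(capture_length)
  min_overlap <- as.integer(min_overlap)
  max_overlap <- as.integer(max_overlap)
  if (!(0L <= min_overlap && min_overlap <= max_overlap &&
        max_overlap < capture_length))
    stop("require 0 <= min_overlap <= max_overlap < capture_length")

  dup <- probes$probe_id[duplicated(probes$probe_id)]
  if (length(dup))
    stop("duplicate probe_id: ", paste(unique(dup), collapse = ", "))
  arm_key <- paste(probes$ext_arm, probes$lig_arm, sep = "|")
  if (anyDuplicated(arm_key))
    stop("duplicate (ext_arm, lig_arm) pair; read assignment keys on arms")
  if (any(is.na(probes$start)) || any(is.na(probes$end)))
    stop("non-integer probe coordinates")
  if (any(probes$start < 0L) || any(probes$end <= probes$start))
    stop("probe target must satisfy 0 <= start < end")
  bad_arm <- !grepl("^[ACGT]+$", probes$ext_arm) |
    !grepl("^[ACGT]+$", probes$lig_arm)
  if (any(bad_arm))
    stop("arms must be non-empty over {A,C,G,T}: ",
         paste(probes$probe_id[bad_arm], collapse = ", "))
  if (any(probes$umb_len < 1L)) stop("umb_len must be >= 1")
  if (any(!is.finite(probes$conc_uM)) || any(probes$conc_uM <= 0))
    stop("conc_uM must be > 0")

  structure(list(probes = probes, capture_length = capture_length,
                 min_overlap = min_overlap, max_overlap = max_overlap),
            class = "smmip_panel")
}

#' @export
print.smmip_panel <- function(x, ...) {
  cat(sprintf("smMIP panel: %d probes, %d genes, capture %d bp, overlap [%d, %d] bp\n",
              nrow(x$probes), length(unique(x$probes$gene)),
              x$capture_length, x$min_overlap, x$max_overlap))
  fp <- target_footprint(x)
  cat(sprintf("target footprint: %d merged intervals, %d bp\n",
              nrow(fp$intervals), fp$total_bp))
  invisible(x)
}

#' @export
length.smmip_panel <- function(x) nrow(x$probes)

#' Read a panel design table
#'
#' Parses the tab-separated panel design file (one probe per row) and
#' validates all panel invariants. The file must carry a header naming at
#' least probe_id, gene, chrom, start, end, ext_arm, lig_arm; conc_uM,
#' umb_len and phosphorylated are optional. Coordinates are 0-based
#' half-open by default; set `coords = "one_based"` for 1-based inclusive
#' input, converted at this boundary.
#'
#' @param path path to the panel TSV.
#' @param coords coordinate dialect of the file.
#' @inheritParams smmip_panel
#' @return an `smmip_panel`; the record count is reported via a message.
#' @export
read_panel <- function(path, coords = c("zero_based", "one_based"),
                       capture_length = 110L, min_overlap = 20L,
                       max_overlap = 40L) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
  required <- c("probe_id", "gene", "chrom", "start", "end",
                "ext_arm", "lig_arm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("panel header lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty panel: ", path)
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed panel row at line %d of %s", bad[1] + 1L, path))
  if (coords == "one_based") start <- start - 1L
  tab$start <- start
  tab$end <- end
  panel <- smmip_panel(tab, capture_length = capture_length,
                       min_overlap = min_overlap, max_overlap = max_overlap)
  message(sprintf("read %d probes from %s", nrow(panel$probes), path))
  panel
}

#' Write a panel design table
#'
#' Writes the panel to the same TSV dialect `read_panel()` accepts
#' (0-based half-open coordinates), in panel order, so that
#' `read_panel(write_panel(p))` round-trips bit-stably.
#'
#' @param panel an `smmip_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "smmip_panel"))
  cols <- c("probe_id", "gene", "chrom", "start", "end", "ext_arm",
            "lig_arm", "umb_len", "conc_uM", "phosphorylated")
  tab <- panel$probes[, cols]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export probe targets as BED6
#'
#' @param panel an `smmip_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
panel_to_bed <- function(panel, path) {
  p <- panel$probes
  ord <- order(p$chrom, p$start, p$end, p$probe_id)
  bed <- data.frame(p$chrom, p$start, p$end, p$probe_id, 0L, "+")[ord, ]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate panel tiling geometry
#'
#' Checks every probe target against the panel capture length and every
#' pair of genomically adjacent probes on a contiguous tile against the
#' allowed overlap range. A positive gap between consecutive targets starts
#' a new tile (exon tiles are separated by introns by design) and is
#' reported as an informational `tiling_gap` row only when
#' `include_info = TRUE`, never as a violation.
#'
#' @param panel an `smmip_panel`.
#' @param include_info also return informational `tiling_gap` rows.
#' @return data.frame with columns probe_id, rule, detail; zero rows iff
#'   the panel is compliant.
#' @export
validate_tiling <- function(panel, include_info = FALSE) {
  stopifnot(inherits(panel, "smmip_panel"))
  p <- panel$probes
  out <- list()
  add <- function(probe_id, rule, detail)
    out[[length(out) + 1L]] <<- data.frame(probe_id = probe_id, rule = rule,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  len <- p$end - p$start
  for (i in which(len != panel$capture_length))
    add(p$probe_id[i], "bad_target_length",
        sprintf("target length %d != capture_length %d",
                len[i], panel$capture_length))
  ord <- order(p$chrom, p$start, p$end)
  ps <- p[ord, ]
  if (nrow(ps) > 1L) {
    for (i in 2:nrow(ps)) {
      if (ps$chrom[i] != ps$chrom[i - 1L]) next
      ov <- ps$end[i - 1L] - ps$start[i]
      if (ov < 0L) {
        if (include_info)
          add(ps$probe_id[i], "tiling_gap",
              sprintf("%d bp gap after %s", -ov, ps$probe_id[i - 1L]))
        next
      }
      if (ov < panel$min_overlap)
        add(ps$probe_id[i], "overlap_below_min",
            sprintf("overlap %d < %d with %s", ov, panel$min_overlap,
                    ps$probe_id[i - 1L]))
      else if (ov > panel$max_overlap)
        add(ps$probe_id[i], "overlap_above_max",
            sprintf("overlap %d > %d with %s", ov, panel$max_overlap,
                    ps$probe_id[i - 1L]))
    }
  }
  if (!length(out))
    return(data.frame(probe_id = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Merged target footprint of a panel
#'
#' @param panel an `smmip_panel`.
#' @return list with `intervals` (merged, sorted interval table) and
#'   `total_bp`.
#' @export
target_footprint <- function(panel) {
  stopifnot(inherits(panel, "smmip_panel"))
  iv <- merge_intervals(panel$probes[, c("chrom", "start", "end")])
  list(intervals = iv, total_bp = intervals_total_bp(iv))
}

#' Coding-region coverage of a panel against gene models
#'
#' For each gene model, intersects its coding intervals with the panel's
#' merged target footprint and reports the covered fraction. Genes present
#' in the panel but lacking a model trigger a warning and are omitted.
#'
#' @param panel an `smmip_panel`.
#' @param models an `smmip_gene_models` object (see [gene_models()]).
#' @return data.frame with columns gene, coding_bp, covered_bp,
#'   pct_covered; the per-gene uncovered intervals are attached as the
#'   `uncovered` attribute (a named list of interval tables).
#' @export
coding_coverage <- function(panel, models) {
  stopifnot(inherits(panel, "smmip_panel"),
            inherits(models, "smmip_gene_models"))
  fp <- target_footprint(panel)$intervals
  panel_genes <- unique(panel$probes$gene)
  model_genes <- unique(models$coding$gene)
  orphan <- setdiff(panel_genes, model_genes)
  if (length(orphan))
    warning("no gene model for panel gene(s): ",
            paste(orphan, collapse = ", "), "; omitted from table")
  rows <- list(); uncovered <- list()
  for (g in model_genes) {
    coding <- merge_intervals(
      models$coding[models$coding$gene == g, c("chrom", "start", "end")])
    coding_bp <- intervals_total_bp(coding)
    covered <- intersect_intervals(coding, fp)
    covered_bp <- intervals_total_bp(covered)
    uncovered[[g]] <- setdiff_intervals(coding, fp)
    rows[[g]] <- data.frame(gene = g, coding_bp = coding_bp,
                            covered_bp = covered_bp,
                            pct_covered = 100 * covered_bp / coding_bp,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "uncovered") <- uncovered
  out
}
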