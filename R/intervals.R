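# Genomic intervals are plain data.frames with columns chrom, start, end,
# 0-based half-open throughout the package. GRanges (1-based closed) is used
# only transiently for the interval algebra; the +1/-0 shifts live here and
# nowhere else.

#' Build an interval table
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors; 0-based half-open, `end > start`.
#' @return data.frame with columns chrom, start, end.
#' @export
genomic_intervals <- function(chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Union of intervals, merged and sorted; abutting intervals are joined.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_granges(df))
  gr <- GenomicRanges::sort(gr)
  granges_to_intervals(gr)
}

# Total bases covered by the merged set of intervals.
intervals_total_bp <- function(df) {
  m <- merge_intervals(df)
  if (nrow(m) == 0L) return(0L)
  sum(m$end - m$start)
}

# Put two GRanges on the union of their seqlevels so set operations do
# not warn on disjoint contigs.
harmonize_seqlevels <- function(ga, gb) {
  sl <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- sl
  GenomeInfoDb::seqlevels(gb) <- sl
  list(ga, gb)
}

# Intersection a (intersect) b as a merged interval table.
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(genomic_intervals(character(), integer(), integer())[0, ])
  g <- harmonize_seqlevels(intervals_to_granges(a),
                           intervals_to_granges(b))
  gr <- GenomicRanges::intersect(g[[1]], g[[2]])
  granges_to_intervals(GenomicRanges::sort(gr))
}

# a minus b, merged.
setdiff_intervals <- function(a, b) {
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  ga <- intervals_to_granges(a)
  if (nrow(b) == 0L) return(granges_to_intervals(GenomicRanges::sort(GenomicRanges::reduce(ga))))
  g <- harmonize_seqlevels(ga, intervals_to_granges(b))
  gr <- GenomicRanges::setdiff(g[[1]], g[[2]])
  granges_to_intervals(GenomicRanges::sort(gr))
}
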