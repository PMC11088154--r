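#' Per-probe performance proportions
#'
#' Each probe's share of the run's reads; the assay aims for every probe
#' to sit near the uniform expectation `1 / panel size`. Deduplicated
#' counts are used by default (configurable).
#'
#' @param coverage an `smmip_coverage`.
#' @param use count column to base proportions on.
#' @return data.frame probe_id, raw_reads, dedup_reads, proportion
#'   (summing to 1 when any reads were seen).
#' @export
probe_performance <- function(coverage, use = c("dedup", "raw")) {
  stopifnot(inherits(coverage, "smmip_coverage"))
  use <- match.arg(use)
  p <- coverage$probes
  counts <- if (use == "dedup") p$dedup_reads else p$raw_reads
  total <- sum(counts)
  data.frame(probe_id = p$probe_id, raw_reads = p$raw_reads,
             dedup_reads = p$dedup_reads,
             proportion = if (total > 0) counts / total else
               rep(0, nrow(p)),
             stringsAsFactors = FALSE)
}

#' Uniform expected per-probe read proportion
#'
#' @param panel_size number of probes in the pool.
#' @return list with `value` (1/panel_size) and `rounded` (its
#'   one-significant-figure rounding, used in report text).
#' @export
expected_proportion <- function(panel_size) {
  panel_size <- as.integer(panel_size)
  if (is.na(panel_size) || panel_size < 1L)
    stop("panel_size must be a positive integer")
  v <- 1 / panel_size
  list(value = v, rounded = signif(v, 1))
}

#' Classify probe performance
#'
#' A probe is *under*-performing when its read proportion falls below
#' `low_cut` or its deduplicated reads fall below `min_reads` (strictly);
#' *over*-performing when its proportion exceeds `high_cut`; otherwise
#' *optimal*. Either under-performance signal alone triggers the class.
#'
#' @param perf output of [probe_performance()].
#' @param low_cut,high_cut proportion cut-offs.
#' @param min_reads minimum deduplicated reads.
#' @return `perf` with a `category` column in \{under, optimal, over\}.
#' @export
classify_probes <- function(perf, low_cut = 1e-4, high_cut = 1e-2,
                            min_reads = 30L) {
  stopifnot(all(c("probe_id", "dedup_reads", "proportion") %in%
                  names(perf)))
  category <- ifelse(perf$proportion < low_cut |
                       perf$dedup_reads < min_reads, "under",
                     ifelse(perf$proportion > high_cut, "over", "optimal"))
  perf$category <- category
  perf
}

#' Build a rebalanced pooling recipe
#'
#' Under-performing probes get a `boost`-fold phosphorylated
#' concentration; over-performing probes keep their phosphorylated
#' concentration and additionally receive an equimolar unphosphorylated
#' competitor; optimal probes are unchanged.
#'
#' @param classified output of [classify_probes()].
#' @param base_conc_uM pool base concentration (uM).
#' @param boost fold-increase applied to under-performers.
#' @return data.frame of class `smmip_plan`: probe_id, category,
#'   phos_uM, unphos_uM; base concentration kept as the `base_conc_uM`
#'   attribute.
#' @export
make_plan <- function(classified, base_conc_uM = 0.1, boost = 10) {
  stopifnot("category" %in% names(classified))
  phos <- ifelse(classified$category == "under",
                 boost * base_conc_uM, base_conc_uM)
  unphos <- ifelse(classified$category == "over", base_conc_uM, 0)
  plan <- data.frame(probe_id = classified$probe_id,
                     category = classified$category,
                     phos_uM = phos, unphos_uM = unphos,
                     stringsAsFactors = FALSE)
  attr(plan, "base_conc_uM") <- base_conc_uM
  class(plan) <- c("smmip_plan", "data.frame")
  plan
}

#' Derive a rebalancing plan straight from a coverage report
#'
#' @param coverage an `smmip_coverage`.
#' @inheritParams classify_probes
#' @inheritParams make_plan
#' @param use count column for proportions.
#' @return an `smmip_plan`.
#' @export
rebalance_plan <- function(coverage, low_cut = 1e-4, high_cut = 1e-2,
                           min_reads = 30L, base_conc_uM = 0.1,
                           boost = 10, use = "dedup") {
  perf <- probe_performance(coverage, use = use)
  make_plan(classify_probes(perf, low_cut, high_cut, min_reads),
            base_conc_uM, boost)
}

#' Write / read a pooling plan TSV
#'
#' @param plan an `smmip_plan`.
#' @param path TSV path.
#' @param summary_path optional JSON path for category tallies.
#' @return `path` (write) or an `smmip_plan` (read).
#' @export
write_plan <- function(plan, path, summary_path = NULL) {
  write.table(plan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(as.list(table(plan$category)), summary_path,
                         auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @param base_conc_uM base concentration attached to the read plan.
#' @export
read_plan <- function(path, base_conc_uM = 0.1) {
  plan <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  attr(plan, "base_conc_uM") <- base_conc_uM
  class(plan) <- c("smmip_plan", "data.frame")
  plan
}
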