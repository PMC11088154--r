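#' qPCR relative quantification (delta-delta-Ct)
#'
#' Computes the relative quantity of a target locus in a sample against
#' a two-copy calibrator from four cycle-threshold values:
#' `rq = E^-((ctT_s - ctR_s) - (ctT_c - ctR_c))` with amplification
#' efficiency `E` (2 under perfect doubling). The copy call uses
#' half-open nearest bands around the canonical values 0.5, 1 and 1.5:
#' rq in \[0.25, 0.75) is 1 copy, \[0.75, 1.25) is 2 copies,
#' \[1.25, 1.75) is 3 copies, anything else is unclassified.
#'
#' @param ct_target_sample,ct_ref_sample sample Ct for target and
#'   reference assays (cycles).
#' @param ct_target_cal,ct_ref_cal calibrator Ct values (cycles).
#' @param efficiency amplification efficiency per cycle (default 2 =
#'   perfect doubling).
#' @return data.frame with columns ddct, rq, copy_call (integer; NA when
#'   unclassified), band (character label).
#' @export
rq <- function(ct_target_sample, ct_ref_sample, ct_target_cal,
               ct_ref_cal, efficiency = 2) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("all Ct values must be finite and > 0")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_cal - ct_ref_cal)
  rqv <- efficiency^(-ddct)
  copy <- rq_copy_call(rqv)
  data.frame(ddct = ddct, rq = rqv, copy_call = copy,
             band = ifelse(is.na(copy), "unclassified",
                           paste0(copy, " copies")),
             stringsAsFactors = FALSE)
}

rq_copy_call <- function(rqv) {
  copy <- rep(NA_integer_, length(rqv))
  copy[rqv >= 0.25 & rqv < 0.75] <- 1L
  copy[rqv >= 0.75 & rqv < 1.25] <- 2L
  copy[rqv >= 1.25 & rqv < 1.75] <- 3L
  copy
}

#' Relative quantification over a qPCR run table
#'
#' @param runs data.frame/CSV path with columns sample, ct_target,
#'   ct_reference, ct_target_cal, ct_ref_cal.
#' @param efficiency amplification efficiency.
#' @return the run table with ddct, rq, copy_call, band appended.
#' @export
qpcr_rq <- function(runs, efficiency = 2) {
  if (is.character(runs)) runs <- utils::read.csv(runs)
  req <- c("sample", "ct_target", "ct_reference", "ct_target_cal",
           "ct_ref_cal")
  if (length(setdiff(req, names(runs))))
    stop("qPCR table lacks columns: ",
         paste(setdiff(req, names(runs)), collapse = ", "))
  cbind(runs, rq(runs$ct_target, runs$ct_reference, runs$ct_target_cal,
                 runs$ct_ref_cal, efficiency))
}

#' Diagnostic status of one case
#'
#' Applies the reporting rule: a case is *diagnosed* when its pathogenic
#' or likely pathogenic (P/LP) variants satisfy the gene's inheritance
#' model -- autosomal recessive: a homozygous P/LP variant, two or more
#' heterozygous P/LP variants (assumed trans when unphased, flagged), a
#' homozygous CNV, or a heterozygous SNV plus a heterozygous CNV in the
#' same gene; X-linked: a hemizygous (or homozygous) P/LP variant.
#' Exactly one heterozygous P/LP variant under AR is *partial*;
#' everything else (including VUS-only cases) is *negative*.
#'
#' @param record list with `case_id`, `gene` and `variants`, a
#'   data.frame with columns id, type ("snv"/"cnv"), zygosity
#'   ("het"/"hom"/"hemi"), classification ("P", "LP", "VUS", ...).
#' @param inheritance_map named character vector gene -> "AR" or "XL".
#' @return list with `status` ("diagnosed"/"partial"/"negative"),
#'   `phase_assumed` (TRUE when compound-het trans phase was assumed)
#'   and `reason`.
#' @export
case_status <- function(record, inheritance_map) {
  gene <- record$gene
  if (is.null(gene) || !gene %in% names(inheritance_map))
    stop("gene missing from inheritance map: ", gene %||% "<none>")
  v <- record$variants
  if (is.null(v) || nrow(v) == 0L)
    return(list(status = "negative", phase_assumed = FALSE,
                reason = "no variants"))
  if (is.null(v$type)) v$type <- "snv"
  plp <- v[v$classification %in% c("P", "LP"), , drop = FALSE]
  if (nrow(plp) == 0L)
    return(list(status = "negative", phase_assumed = FALSE,
                reason = "no P/LP variants"))
  mode <- inheritance_map[[gene]]
  hom <- plp$zygosity == "hom"
  hemi <- plp$zygosity == "hemi"
  het <- plp$zygosity == "het"
  if (mode == "XL") {
    if (any(hemi | hom))
      return(list(status = "diagnosed", phase_assumed = FALSE,
                  reason = "hemizygous/homozygous P/LP under XL"))
    if (sum(het) >= 2L)
      return(list(status = "diagnosed", phase_assumed = TRUE,
                  reason = "compound heterozygous P/LP (phase assumed)"))
    return(list(status = "partial", phase_assumed = FALSE,
                reason = "single heterozygous P/LP under XL"))
  }
  # autosomal recessive
  if (any(hom))
    return(list(status = "diagnosed", phase_assumed = FALSE,
                reason = "homozygous P/LP"))
  if (sum(het) >= 2L) {
    both_types <- length(unique(plp$type[het])) > 1L
    return(list(status = "diagnosed", phase_assumed = TRUE,
                reason = if (both_types)
                  "heterozygous SNV plus overlapping heterozygous CNV (phase assumed)"
                else "compound heterozygous P/LP (phase assumed)"))
  }
  if (sum(het) == 1L)
    return(list(status = "partial", phase_assumed = FALSE,
                reason = "single heterozygous P/LP under AR"))
  list(status = "negative", phase_assumed = FALSE,
       reason = "no qualifying genotype")
}

#' Cohort diagnostic yield by stratum
#'
#' Counts diagnosed cases per stratum and overall, with exact
#' Clopper-Pearson 95% confidence intervals.
#'
#' @param records data.frame with columns case_id, stratum, status
#'   (status as from [case_status()]; "diagnosed" counts as a
#'   diagnosis).
#' @param path optional TSV output path.
#' @return data.frame of class `smmip_yield`: stratum, n_total,
#'   n_diagnosed, yield_pct, ci_lo, ci_hi (percent).
#' @export
cohort_yield <- function(records, path = NULL) {
  req <- c("case_id", "stratum", "status")
  if (length(setdiff(req, names(records))))
    stop("records need columns case_id, stratum, status")
  strata <- c(sort(unique(as.character(records$stratum))), "overall")
  rows <- lapply(strata, function(st) {
    sel <- if (st == "overall") rep(TRUE, nrow(records)) else
      records$stratum == st
    n <- sum(sel)
    k <- sum(records$status[sel] == "diagnosed")
    if (n == 0L)
      return(data.frame(stratum = st, n_total = 0L, n_diagnosed = 0L,
                        yield_pct = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, stringsAsFactors = FALSE))
    ci <- binom.test(k, n)$conf.int
    data.frame(stratum = st, n_total = n, n_diagnosed = k,
               yield_pct = 100 * k / n, ci_lo = 100 * ci[1],
               ci_hi = 100 * ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("smmip_yield", "data.frame")
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Concordance of called variants against a truth set
#'
#' A case is concordant when every truth variant was recovered by the
#' assay; additional findings never break concordance. When a panel is
#' supplied, a missed truth variant lying outside the panel's target
#' footprint is annotated "uncovered_target" rather than
#' "not_detected".
#'
#' @param truth data.frame with columns case_id, variant_id and
#'   optionally chrom, pos (0-based) for footprint annotation.
#' @param called data.frame with columns case_id, variant_id; case ids
#'   must be a subset of the truth case ids (a truth case with no rows
#'   is simply all-missed).
#' @param panel optional `smmip_panel` for uncovered-target annotation.
#' @return list of class `smmip_concordance`: `n_cases`,
#'   `n_concordant`, `pct_concordant`, `discordant` (case_id,
#'   variant_id, reason).
#' @export
concordance <- function(truth, called, panel = NULL) {
  req <- c("case_id", "variant_id")
  if (length(setdiff(req, names(truth))) ||
      length(setdiff(req, names(called))))
    stop("truth and called tables need columns case_id, variant_id")
  unknown <- setdiff(unique(called$case_id), unique(truth$case_id))
  if (length(unknown))
    stop("called table contains unmatched case ids: ",
         paste(unknown, collapse = ", "))
  fp <- if (!is.null(panel)) target_footprint(panel)$intervals else NULL
  cases <- unique(as.character(truth$case_id))
  disc <- list()
  n_conc <- 0L
  for (cs in cases) {
    tv <- truth[truth$case_id == cs, , drop = FALSE]
    cv <- called$variant_id[called$case_id == cs]
    missing <- !(tv$variant_id %in% cv)
    if (!any(missing)) { n_conc <- n_conc + 1L; next }
    for (i in which(missing)) {
      reason <- "not_detected"
      if (!is.null(fp) && !is.null(tv$pos) && !is.na(tv$pos[i])) {
        covered <- any(fp$chrom == tv$chrom[i] & fp$start <= tv$pos[i] &
                         tv$pos[i] < fp$end)
        if (!covered) reason <- "uncovered_target"
      }
      disc[[length(disc) + 1L]] <- data.frame(
        case_id = cs, variant_id = tv$variant_id[i], reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  discordant <- if (length(disc)) do.call(rbind, disc) else
    data.frame(case_id = character(), variant_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(list(n_cases = length(cases), n_concordant = n_conc,
                 pct_concordant = 100 * n_conc / length(cases),
                 discordant = discordant),
            class = "smmip_concordance")
}

#' @export
print.smmip_concordance <- function(x, ...) {
  cat(sprintf("concordance: %d/%d cases (%.1f%%)\n", x$n_concordant,
              x$n_cases, x$pct_concordant))
  if (nrow(x$discordant)) {
    cat("discordant:\n")
    print(x$discordant)
  }
  invisible(x)
}
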