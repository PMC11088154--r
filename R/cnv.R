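# Read-depth CNV calling over exon-aggregated deduplicated counts, in the
# ExomeDepth/DECoN family: reference samples ranked by correlation and
# greedily aggregated, beta-binomial emissions with method-of-moments
# overdispersion, and a 3-state (deletion / diploid / duplication) Viterbi
# decode along each gene's exons.

#' Build a samples x exons count matrix
#'
#' Sums each sample's per-probe deduplicated counts into exons; each
#' probe maps to exactly one exon by maximal overlap. Exons with zero
#' counts in more than `mask_zero_frac` of samples are masked as
#' low-quality. Batch-level normalization against other samples in the
#' same sequencing run is central to the method, so at least `min_batch`
#' samples (default 17) are required unless explicitly overridden.
#'
#' @param coverages named list (sample id -> `smmip_coverage`), or a
#'   samples x probes count matrix with dimnames.
#' @param panel an `smmip_panel`.
#' @param models an `smmip_gene_models`.
#' @param min_batch minimum samples per batch.
#' @param enforce_min_batch set FALSE to override the batch-size error
#'   for toy runs.
#' @param mask_zero_frac masking rule: exon is masked when zero in more
#'   than this fraction of samples.
#' @return object of class `smmip_exon_matrix`: `samples`, `exons`
#'   (gene, exon_index, chrom, start, end, masked), `counts`
#'   (samples x exons), `probe_map`.
#' @export
build_exon_matrix <- function(coverages, panel, models, min_batch = 17L,
                              enforce_min_batch = TRUE,
                              mask_zero_frac = 0.5) {
  stopifnot(inherits(panel, "smmip_panel"),
            inherits(models, "smmip_gene_models"))
  if (is.matrix(coverages)) {
    counts_pp <- coverages
  } else {
    stopifnot(is.list(coverages), length(names(coverages)) ==
                length(coverages))
    counts_pp <- do.call(rbind, lapply(coverages, function(cv) {
      stopifnot(inherits(cv, "smmip_coverage"))
      if (!identical(cv$probes$probe_id, panel$probes$probe_id))
        stop("coverage report does not match the panel probe set")
      setNames(cv$probes$dedup_reads, cv$probes$probe_id)
    }))
    rownames(counts_pp) <- names(coverages)
  }
  n <- nrow(counts_pp)
  if (enforce_min_batch && n < min_batch)
    stop(sprintf(paste0("batch has %d samples but batch normalization ",
                        "requires a minimum of %d samples per batch; ",
                        "use enforce_min_batch = FALSE to override"),
                 n, min_batch))
  pm <- map_probes_to_exons(panel, models)
  if (anyNA(pm$exon)) {
    warning("probe(s) overlapping no exon dropped from the matrix: ",
            paste(pm$probe_id[is.na(pm$exon)], collapse = ", "))
  }
  keep <- !is.na(pm$exon)
  ex <- models$exons[order(models$exons$gene, models$exons$exon_index), ]
  exon_keys <- paste0(ex$gene, ":", ex$exon_index)
  f <- factor(pm$exon[keep], levels = exon_keys)
  counts <- t(apply(counts_pp[, pm$probe_id[keep], drop = FALSE], 1,
                    function(x) tapply(x, f, sum, default = 0)))
  counts[is.na(counts)] <- 0
  storage.mode(counts) <- "integer"
  colnames(counts) <- exon_keys
  masked <- colMeans(counts == 0) > mask_zero_frac
  exons <- data.frame(gene = ex$gene, exon_index = ex$exon_index,
                      chrom = ex$chrom, start = ex$start, end = ex$end,
                      masked = masked, stringsAsFactors = FALSE)
  structure(list(samples = rownames(counts_pp), exons = exons,
                 counts = counts, probe_map = pm),
            class = "smmip_exon_matrix")
}

#' @export
print.smmip_exon_matrix <- function(x, ...) {
  cat(sprintf("exon count matrix: %d samples x %d exons (%d masked)\n",
              length(x$samples), nrow(x$exons), sum(x$exons$masked)))
  invisible(x)
}

# Method-of-moments beta-binomial overdispersion of one sample's exon
# counts against expected fractions phi: Var = N phi (1-phi) (1+(N-1)rho).
# The per-exon chi-square statistics are summarized by their median
# (rescaled by the chi-square-1 median) rather than the mean, so a
# minority of CNV-affected exons in the test sample cannot inflate the
# estimate and flatten the emissions.
estimate_rho <- function(x, phi, floor = 1e-6, ceiling = 0.3,
                         clamp = TRUE) {
  N <- sum(x)
  if (N <= 1) return(floor)
  v <- N * phi * (1 - phi)
  chi <- (x - N * phi)^2 / v
  infl <- median(chi) / stats::qchisq(0.5, df = 1)
  rho <- (infl - 1) / (N - 1)
  if (!clamp) return(rho)
  min(max(rho, floor), ceiling)
}

#' Select reference samples for a test sample
#'
#' Ranks the other batch samples by Pearson correlation of their exon
#' count profiles with the test sample, then accumulates them greedily
#' while the method-of-moments beta-binomial overdispersion of the test
#' sample against the aggregated reference does not increase. At least
#' one sample is always selected.
#'
#' @param mat an `smmip_exon_matrix`.
#' @param test_sample sample id present in the matrix.
#' @param sex optional named character vector (sample -> "M"/"F"); when
#'   the panel contains X-chromosome exons, reference candidates are
#'   restricted to samples of the test sample's stated sex, since male
#'   and female X coverage differ two-fold. Without metadata a warning
#'   is raised and all samples are used.
#' @param x_chrom contig names treated as the X chromosome.
#' @return list: `reference_samples`, `expected_fraction` (per unmasked
#'   exon, aggregated reference exon sums over reference total), `rho`,
#'   `correlations`.
#' @export
select_reference <- function(mat, test_sample, sex = NULL,
                             x_chrom = c("chrX", "X")) {
  stopifnot(inherits(mat, "smmip_exon_matrix"))
  if (!test_sample %in% mat$samples)
    stop("unknown test sample: ", test_sample)
  un <- !mat$exons$masked
  x <- mat$counts[test_sample, un]
  if (sum(x) == 0) stop("all-zero count profile for ", test_sample)
  others <- setdiff(mat$samples, test_sample)
  if (any(mat$exons$chrom %in% x_chrom)) {
    if (is.null(sex)) {
      warning("panel contains X-chromosome exons but no sex metadata; ",
              "reference built from all samples")
    } else {
      if (!test_sample %in% names(sex))
        stop("no stated sex for test sample ", test_sample)
      same <- others[!is.na(sex[others]) &
                       sex[others] == sex[[test_sample]]]
      if (length(same)) others <- same
      else warning("no reference sample matches the sex of ",
                   test_sample, "; using all samples")
    }
  }
  if (!length(others)) stop("no other samples to form a reference")
  cors <- vapply(others,
                 function(s) suppressWarnings(
                   cor(x, mat$counts[s, un])), numeric(1))
  cors[is.na(cors)] <- -1
  ord <- others[order(cors, decreasing = TRUE)]
  # accumulate along the correlation ranking; keep the prefix whose
  # aggregated reference minimizes the robust test-vs-reference
  # overdispersion (equivalently: stop growing once adding samples only
  # increases it)
  agg <- rep(0L, sum(un))
  rhos <- numeric(length(ord))
  for (k in seq_along(ord)) {
    agg <- agg + mat$counts[ord[k], un]
    phi <- pmax(agg, 0.5) / sum(agg)  # guard zero expected fractions
    phi <- phi / sum(phi)
    rhos[k] <- estimate_rho(x, phi, clamp = FALSE)
  }
  # on ties (e.g. identical clone profiles) prefer the largest reference
  k_best <- max(which(rhos <= min(rhos) + 1e-12))
  chosen <- ord[seq_len(k_best)]
  agg <- colSums(mat$counts[chosen, un, drop = FALSE])
  phi <- pmax(agg, 0.5) / sum(agg)
  phi <- phi / sum(phi)
  list(reference_samples = chosen,
       expected_fraction = setNames(phi, colnames(mat$counts)[un]),
       rho = estimate_rho(x, phi),
       correlations = setNames(cors, others))
}

#' Observed/expected coverage ratios per exon
#'
#' Expected fraction per exon comes from the aggregated reference;
#' `ratio` is observed count over (expected fraction x test total).
#' `log_norm_cov` is the log2 size-factor-normalized count used in the
#' coverage panel of the plots. Masked exons are reported NA.
#'
#' @param mat an `smmip_exon_matrix`.
#' @param test_sample sample id.
#' @param ref output of [select_reference()] (computed when NULL).
#' @return data.frame: gene, exon_index, observed, expected, ratio,
#'   log_norm_cov, masked.
#' @export
compute_ratios <- function(mat, test_sample, ref = NULL) {
  stopifnot(inherits(mat, "smmip_exon_matrix"))
  if (is.null(ref)) ref <- select_reference(mat, test_sample)
  un <- !mat$exons$masked
  x <- mat$counts[test_sample, ]
  N <- sum(x[un])
  expected <- rep(NA_real_, ncol(mat$counts))
  expected[un] <- ref$expected_fraction * N
  ratio <- ifelse(expected > 0, x / expected, NA_real_)
  size_fac <- N / mean(rowSums(mat$counts[, un, drop = FALSE]))
  log_norm <- log2(x / size_fac + 1)
  out <- data.frame(gene = mat$exons$gene,
                    exon_index = mat$exons$exon_index,
                    observed = x, expected = expected, ratio = ratio,
                    log_norm_cov = log_norm, masked = mat$exons$masked,
                    stringsAsFactors = FALSE)
  out$ratio[out$masked] <- NA_real_
  rownames(out) <- NULL
  out
}

#' CNV caller parameters
#'
#' @param transition probability of entering a CNV state between
#'   adjacent exons.
#' @param stay_cnv probability of remaining in a CNV state.
#' @param state_fractions expected-fraction scale per state
#'   (deletion / diploid / duplication); a heterozygous deletion halves
#'   and a heterozygous duplication 1.5x-es the exon's expected share.
#' @param rho fixed beta-binomial overdispersion; NULL estimates it from
#'   the data (method of moments).
#' @param rho_floor,rho_ceiling clamp for the estimated overdispersion.
#' @return list of class `smmip_cnv_params`.
#' @export
cnv_params <- function(transition = 1e-4, stay_cnv = 0.5,
                       state_fractions = c(del = 0.5, dip = 1, dup = 1.5),
                       rho = NULL, rho_floor = 1e-6, rho_ceiling = 0.3) {
  stopifnot(transition > 0, transition < 0.5, stay_cnv > 0, stay_cnv < 1,
            length(state_fractions) == 3)
  structure(list(transition = transition, stay_cnv = stay_cnv,
                 state_fractions = state_fractions, rho = rho,
                 rho_floor = rho_floor, rho_ceiling = rho_ceiling),
            class = "smmip_cnv_params")
}

# log beta-binomial pmf with mean probability p and intra-class
# correlation rho.
dbetabinom_log <- function(x, size, p, rho) {
  if (rho <= 0) return(stats::dbinom(x, size, p, log = TRUE))
  s <- (1 - rho) / rho
  a <- p * s
  b <- (1 - p) * s
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

# Emission log-likelihood matrix (exons x 3 states) for one test sample.
# State scale s rescales the exon's expected odds: p_s = s*phi /
# (s*phi + 1 - phi), so a deletion halves the exon's expected share of
# the test total relative to everything else.
cnv_emissions <- function(x, N, phi, fractions, rho) {
  emis <- vapply(fractions, function(s) {
    ps <- s * phi / (s * phi + 1 - phi)
    ps <- pmin(pmax(ps, 1e-12), 1 - 1e-12)
    dbetabinom_log(x, N, ps, rho)
  }, numeric(length(x)))
  matrix(emis, nrow = length(x), ncol = length(fractions))
}

cnv_transition_matrix <- function(t, stay) {
  # states: del, dip, dup
  rbind(del = c(stay, 1 - stay - t, t),
        dip = c(t, 1 - 2 * t, t),
        dup = c(t, 1 - stay - t, stay))
}

# Viterbi decode; emissions and transitions in log space. Returns the
# maximum-likelihood state path (integer vector over rows of `emis`).
viterbi_path <- function(emis, log_trans, log_init) {
  n <- nrow(emis); k <- ncol(emis)
  if (n == 0L) return(integer(0))
  delta <- matrix(-Inf, n, k)
  back <- matrix(0L, n, k)
  delta[1, ] <- log_init + emis[1, ]
  if (n > 1) for (i in 2:n) {
    for (j in seq_len(k)) {
      cand <- delta[i - 1, ] + log_trans[, j]
      back[i, j] <- which.max(cand)
      delta[i, j] <- cand[back[i, j]] + emis[i, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) path[i] <- back[i + 1, path[i + 1]]
  path
}

#' Call copy number variants for one sample
#'
#' Runs reference selection, ratio computation and a three-state
#' (deletion / diploid / duplication) beta-binomial hidden Markov model
#' along each gene's exons; Viterbi segments in a CNV state are reported
#' as calls with a summed log-likelihood-ratio support score.
#' Single-exon calls are permitted.
#'
#' @param mat an `smmip_exon_matrix`.
#' @param test_sample sample id.
#' @param params a [cnv_params()].
#' @param sex optional sample sex metadata, see [select_reference()].
#' @return object of class `smmip_cnv`: `sample`, `calls` (gene,
#'   first_exon, last_exon, state, copy_estimate, ratio, score),
#'   `ratios`, `reference_samples`, `rho`.
#' @export
call_cnvs <- function(mat, test_sample, params = cnv_params(),
                      sex = NULL) {
  stopifnot(inherits(mat, "smmip_exon_matrix"),
            inherits(params, "smmip_cnv_params"))
  ref <- select_reference(mat, test_sample, sex = sex)
  ratios <- compute_ratios(mat, test_sample, ref)
  un <- !mat$exons$masked
  x <- mat$counts[test_sample, un]
  N <- sum(x)
  phi <- ref$expected_fraction
  rho <- params$rho %||%
    min(max(ref$rho, params$rho_floor), params$rho_ceiling)
  emis <- cnv_emissions(x, N, phi, params$state_fractions, rho)
  genes <- mat$exons$gene[un]
  exon_idx <- mat$exons$exon_index[un]
  lt <- log(cnv_transition_matrix(params$transition, params$stay_cnv))
  li <- log(c(params$transition, 1 - 2 * params$transition,
              params$transition))
  calls <- list()
  for (g in unique(genes)) {
    rows <- which(genes == g)
    path <- viterbi_path(emis[rows, , drop = FALSE], lt, li)
    r <- rle(path)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1L
    for (seg in which(r$values != 2L)) {
      sel <- rows[start_at[seg]:stop_at[seg]]
      state <- if (r$values[seg] == 1L) "deletion" else "duplication"
      mean_ratio <- mean(x[sel] / (phi[sel] * N))
      copy <- if (state == "duplication") "3+" else
        if (mean_ratio < 0.25) "0" else "1"
      score <- sum(emis[sel, r$values[seg]] - emis[sel, 2])
      calls[[length(calls) + 1L]] <- data.frame(
        sample = test_sample, gene = g,
        first_exon = exon_idx[sel[1]],
        last_exon = exon_idx[sel[length(sel)]],
        state = state, copy_estimate = copy, ratio = mean_ratio,
        score = score, stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample = character(), gene = character(),
               first_exon = integer(), last_exon = integer(),
               state = character(), copy_estimate = character(),
               ratio = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(sample = test_sample, calls = calls, ratios = ratios,
                 reference_samples = ref$reference_samples, rho = rho,
                 matrix = mat),
            class = "smmip_cnv")
}

#' @export
print.smmip_cnv <- function(x, ...) {
  cat(sprintf("CNV calls for %s (reference: %d samples, rho %.2g)\n",
              x$sample, length(x$reference_samples), x$rho))
  if (nrow(x$calls) == 0) cat("no calls\n") else print(x$calls)
  invisible(x)
}

#' Plot coverage and observed/expected ratio panels for a sample
#'
#' Two stacked panels in the style of read-depth CNV review plots: the
#' top panel shows the test sample's log2 normalized exon coverage
#' (blue) over the reference samples (grey); the bottom panel the
#' observed/expected ratio with called exons highlighted in red.
#'
#' @param x an `smmip_cnv`.
#' @param genes optional gene subset.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.smmip_cnv <- function(x, genes = NULL, ...) {
  mat <- x$matrix
  rt <- x$ratios
  keep <- if (is.null(genes)) rep(TRUE, nrow(rt)) else rt$gene %in% genes
  rt <- rt[keep, ]
  idx <- seq_len(nrow(rt))
  un <- !mat$exons$masked
  size_factors <- rowSums(mat$counts[, un, drop = FALSE])
  size_factors <- size_factors / mean(size_factors)
  norm <- sweep(mat$counts[, keep, drop = FALSE], 1, size_factors, "/")
  lognorm <- log2(norm + 1)
  old <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  matplot_y <- t(lognorm[setdiff(mat$samples, x$sample), , drop = FALSE])
  plot(idx, lognorm[x$sample, ], type = "n",
       ylim = range(c(matplot_y, lognorm[x$sample, ]), finite = TRUE),
       xlab = "", ylab = "log2 normalised coverage", xaxt = "n")
  for (j in seq_len(ncol(matplot_y)))
    points(idx, matplot_y[, j], type = "l", col = "grey70")
  points(idx, lognorm[x$sample, ], type = "b", col = "blue", pch = 16)
  gene_breaks <- which(diff(as.integer(factor(rt$gene))) != 0) + 0.5
  abline(v = gene_breaks, lty = 3, col = "grey50")
  mtext(unique(rt$gene), side = 3, cex = 0.8,
        at = tapply(idx, rt$gene, mean)[unique(rt$gene)], col = "red")
  in_call <- rep(FALSE, nrow(rt))
  for (i in seq_len(nrow(x$calls))) {
    cl <- x$calls[i, ]
    in_call <- in_call | (rt$gene == cl$gene &
                            rt$exon_index >= cl$first_exon &
                            rt$exon_index <= cl$last_exon)
  }
  plot(idx, rt$ratio, pch = 16, col = ifelse(in_call, "red", "black"),
       ylim = c(0, max(2, rt$ratio, na.rm = TRUE)),
       xlab = "exon", ylab = "observed / expected")
  abline(h = 1, col = "grey50")
  abline(h = c(0.5, 1.5), col = "grey80", lty = 2)
  abline(v = gene_breaks, lty = 3, col = "grey50")
  invisible(x)
}

#' Write CNV calls and per-exon ratios as TSV
#'
#' @param cnv an `smmip_cnv`.
#' @param calls_path,ratios_path output paths (NULL skips).
#' @return invisibly, the paths written.
#' @export
write_cnv <- function(cnv, calls_path = NULL, ratios_path = NULL) {
  if (!is.null(calls_path))
    write.table(cnv$calls, calls_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(ratios_path))
    write.table(cnv$ratios, ratios_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(calls_path, ratios_path))
}
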