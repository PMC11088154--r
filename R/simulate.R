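#' Simulation configuration
#'
#' Bundles every knob of the synthetic assay: toy-genome geometry, capture
#' depth and per-probe efficiency spread, PCR duplication, sequencing
#' error, cohort size, and the variants to inject. Defaults emulate the
#' assay's observed behaviour: ~200 distinct molecules per probe after
#' deduplication, log-normal capture-efficiency variation with a poorly
#' performing probe subset, and a 5-base random tag (UMB).
#'
#' @param seed integer seed governing every random draw.
#' @param n_genes,exons_per_gene,exon_len,intron_len,spacer toy-genome
#'   layout (bp); genes are laid out non-overlapping on one contig with
#'   `spacer` bp before, between and after genes.
#' @param flank intron-exon boundary coverage in bp: probe tiles span each
#'   exon extended by `flank` on both sides.
#' @param arm_len probe arm length in bp.
#' @param depth target distinct molecules per probe (dedup-scale depth).
#' @param pcr_dup_mean mean PCR duplicate count per molecule (>= 1).
#' @param seq_error_rate per-base sequencing error probability, in
#'   \[0, 0.05\].
#' @param capture_sigma log-normal sd of per-probe capture efficiency.
#' @param frac_poor_probes,poor_factor fraction of probes whose efficiency
#'   is additionally scaled by `poor_factor` (< 1), reproducing the
#'   underperforming-probe tail seen in real pools.
#' @param competitor_factor effective-capture multiplier applied to a probe
#'   when an unphosphorylated competitor is pooled alongside it.
#' @param n_samples samples in the cohort.
#' @param umb_len random-tag length (bases).
#' @param capture_length,min_overlap,max_overlap panel tiling geometry.
#' @param variants list of variant specs; see [snv_spec()] and
#'   [cnv_spec()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 2L, exons_per_gene = 3L,
                       exon_len = 150L, intron_len = 300L, spacer = 300L,
                       flank = 20L, arm_len = 20L, depth = 200,
                       pcr_dup_mean = 2, seq_error_rate = 0.001,
                       capture_sigma = 0.3, frac_poor_probes = 0,
                       poor_factor = 0.1, competitor_factor = 0.5,
                       n_samples = 1L, umb_len = 5L, capture_length = 110L,
                       min_overlap = 20L, max_overlap = 40L,
                       variants = list()) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              spacer = as.integer(spacer), flank = as.integer(flank),
              arm_len = as.integer(arm_len), depth = depth,
              pcr_dup_mean = pcr_dup_mean,
              seq_error_rate = seq_error_rate,
              capture_sigma = capture_sigma,
              frac_poor_probes = frac_poor_probes,
              poor_factor = poor_factor,
              competitor_factor = competitor_factor,
              n_samples = as.integer(n_samples),
              umb_len = as.integer(umb_len),
              capture_length = as.integer(capture_length),
              min_overlap = as.integer(min_overlap),
              max_overlap = as.integer(max_overlap), variants = variants)
  with(cfg, {
    if (n_genes < 1L) stop("need at least one gene")
    if (exons_per_gene < 1L || exon_len < 1L || intron_len < 1L ||
        spacer < 1L || depth <= 0 || n_samples < 1L || umb_len < 1L)
      stop("all counts and lengths must be positive")
    if (pcr_dup_mean < 1) stop("pcr_dup_mean must be >= 1")
    if (seq_error_rate < 0 || seq_error_rate > 0.05)
      stop("seq_error_rate must lie in [0, 0.05]")
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Injected-variant specs for the simulator
#'
#' @param sample sample id (e.g. "S03").
#' @param gene gene symbol in the toy genome (e.g. "G1").
#' @param pos 0-based contig position of the SNV (see [exon_midpoint()]).
#' @param zygosity "het" or "hom".
#' @param first_exon,last_exon inclusive exon range of the CNV.
#' @param copies total copy number over the event: 0 or 1 (deletion),
#'   3 (duplication).
#' @return a variant spec list.
#' @export
snv_spec <- function(sample, gene, pos, zygosity = c("het", "hom")) {
  list(sample = sample, type = "snv", gene = gene, pos = as.integer(pos),
       zygosity = match.arg(zygosity))
}

#' @rdname snv_spec
#' @export
cnv_spec <- function(sample, gene, first_exon, last_exon = first_exon,
                     copies = 1) {
  stopifnot(first_exon <= last_exon, copies %in% c(0, 1, 3))
  list(sample = sample, type = "cnv", gene = gene,
       first_exon = as.integer(first_exon),
       last_exon = as.integer(last_exon), copies = copies)
}

#' Midpoint of an exon (0-based contig coordinate)
#'
#' @param models an `smmip_gene_models`.
#' @param gene,exon gene symbol and exon index.
#' @return integer position.
#' @export
exon_midpoint <- function(models, gene, exon) {
  e <- models$exons[models$exons$gene == gene &
                      models$exons$exon_index == exon, ]
  if (nrow(e) != 1L) stop("no such exon: ", gene, " exon ", exon)
  as.integer((e$start + e$end) %/% 2L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a toy reference genome with gene models
#'
#' Lays `n_genes` non-overlapping genes on a single contig ("chrSim"),
#' each with `exons_per_gene` exons of `exon_len` bp separated by
#' `intron_len` bp introns, with `spacer` bp before, between and after
#' genes. Contig length is exactly
#' `n_genes * gene_len + (n_genes + 1) * spacer` with
#' `gene_len = exons_per_gene * exon_len + (exons_per_gene - 1) * intron_len`.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, writes `ref.fa`,
#'   `exons.bed` and `coding.bed` there.
#' @return list with `sequence` (named character, one contig), `models`
#'   (`smmip_gene_models`) and, if written, the file paths.
#' @export
make_reference <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_len <- cfg$exons_per_gene * cfg$exon_len +
    (cfg$exons_per_gene - 1L) * cfg$intron_len
  contig_len <- cfg$n_genes * gene_len + (cfg$n_genes + 1L) * cfg$spacer
  seq <- with_seed(cfg$seed, random_dna(contig_len))
  rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    gstart <- cfg$spacer + (g - 1L) * (gene_len + cfg$spacer)
    for (e in seq_len(cfg$exons_per_gene)) {
      es <- gstart + (e - 1L) * (cfg$exon_len + cfg$intron_len)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = paste0("G", g), chrom = "chrSim", start = es,
        end = es + cfg$exon_len, exon_index = e, stringsAsFactors = FALSE)
    }
  }
  exons <- do.call(rbind, rows)
  models <- gene_models(exons)
  out <- list(sequence = setNames(seq, "chrSim"), models = models)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "ref.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$sequence), fa)
    beds <- file.path(out_dir, c("exons.bed", "coding.bed"))
    write_gene_beds(models, beds[1], beds[2])
    out$paths <- c(fasta = fa, exons = beds[1], coding = beds[2])
  }
  out
}

# Tile one region [rstart, rend) with n targets of width `cap`, adjacent
# overlaps all within [min_ov, max_ov]; the tile may spill symmetrically
# beyond the region when the geometry requires it. Returns target starts.
tile_region <- function(rstart, rend, cap, min_ov, max_ov) {
  if (min_ov >= cap) stop("min_overlap must be smaller than capture length")
  L <- rend - rstart
  if (L <= cap) {
    return(rstart - (cap - L) %/% 2L)
  }
  step_min <- cap - max_ov
  step_max <- cap - min_ov
  # smallest n whose maximal span cap + (n-1)*step_max reaches L
  n <- max(2L, as.integer(ceiling((L - cap) / step_max)) + 1L)
  span_min <- cap + (n - 1L) * step_min
  span <- max(L, span_min)
  total_ov <- n * cap - span
  base <- total_ov %/% (n - 1L)
  extra <- total_ov %% (n - 1L)
  ovs <- rep(base, n - 1L)
  if (extra > 0L) ovs[seq_len(extra)] <- ovs[seq_len(extra)] + 1L
  start <- rstart - (span - L) %/% 2L
  as.integer(cumsum(c(start, cap - ovs))[seq_len(n)])
}

#' Design a tiling probe panel against a toy reference
#'
#' Greedily tiles every exon extended by `flank` bp on each side with
#' fixed-length targets whose adjacent overlaps fall inside
#' `[min_overlap, max_overlap]`; regions shorter than the capture length
#' get a single centred probe. Arms are lifted from the reference flanks
#' of each target (extension arm upstream, ligation arm the reverse
#' complement of the downstream flank); on the rare arm-pair collision the
#' colliding probe's arms are extended until unique.
#'
#' @param reference output of [make_reference()] (or a list with
#'   `sequence` and `models`).
#' @param models optional `smmip_gene_models`; defaults to
#'   `reference$models`.
#' @param capture_length,min_overlap,max_overlap,flank,arm_len geometry.
#' @param conc_uM,umb_len probe pool concentration and tag length.
#' @return an `smmip_panel` that passes [validate_tiling()] with zero
#'   violations.
#' @export
design_panel <- function(reference, models = NULL, capture_length = 110L,
                         min_overlap = 20L, max_overlap = 40L, flank = 20L,
                         arm_len = 20L, conc_uM = 0.1, umb_len = 5L) {
  if (min_overlap >= capture_length)
    stop("impossible constraints: min_overlap >= capture_length")
  models <- models %||% reference$models
  seqchr <- reference$sequence
  contig_len <- nchar(seqchr[[1]])
  chrom <- names(seqchr)[1]
  rows <- list()
  ex <- models$exons
  for (i in seq_len(nrow(ex))) {
    rstart <- max(ex$start[i] - flank, arm_len)
    rend <- min(ex$end[i] + flank, contig_len - arm_len)
    starts <- tile_region(rstart, rend, capture_length,
                          min_overlap, max_overlap)
    for (j in seq_along(starts)) {
      s <- starts[j]; e <- s + capture_length
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = sprintf("%s_E%02d_P%02d", ex$gene[i], ex$exon_index[i], j),
        gene = ex$gene[i], chrom = chrom, start = s, end = e,
        stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, rows)
  if (any(probes$start < arm_len) ||
      any(probes$end > contig_len - arm_len))
    stop("probe tile spills outside the reference arm margin")
  fl <- function(s, e) substring(seqchr[[1]], s + 1L, e)
  probes$ext_arm <- fl(probes$start - arm_len, probes$start)
  probes$lig_arm <- revcomp(fl(probes$end, probes$end + arm_len))
  key <- paste(probes$ext_arm, probes$lig_arm)
  grow <- 0L
  while (anyDuplicated(key) && grow < 8L) {
    grow <- grow + 1L
    idx <- which(duplicated(key))
    probes$ext_arm[idx] <- fl(probes$start[idx] - arm_len - grow,
                              probes$start[idx])
    key <- paste(probes$ext_arm, probes$lig_arm)
  }
  if (anyDuplicated(key)) stop("could not make probe arms unique")
  probes$umb_len <- as.integer(umb_len)
  probes$conc_uM <- conc_uM
  probes$phosphorylated <- TRUE
  smmip_panel(probes, capture_length = capture_length,
              min_overlap = min_overlap, max_overlap = max_overlap)
}

#' Map panel probes to exons by maximal overlap
#'
#' @param panel an `smmip_panel`.
#' @param models an `smmip_gene_models`.
#' @return data.frame probe_id, gene, exon_index, exon (key
#'   `gene:exon_index`); unmapped probes carry NA.
#' @export
map_probes_to_exons <- function(panel, models) {
  p <- panel$probes
  e <- models$exons
  pg <- intervals_to_granges(p[, c("chrom", "start", "end")])
  eg <- intervals_to_granges(e[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(pg, eg)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    pg[S4Vectors::queryHits(hits)], eg[S4Vectors::subjectHits(hits)]))
  best <- rep(NA_integer_, nrow(p))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (q in unique(qh)) {
      sel <- which(qh == q)
      best[q] <- sh[sel[which.max(ov[sel])]]
    }
  }
  data.frame(probe_id = p$probe_id,
             gene = ifelse(is.na(best), NA, e$gene[best]),
             exon_index = ifelse(is.na(best), NA, e$exon_index[best]),
             exon = ifelse(is.na(best), NA,
                           paste0(e$gene[best], ":", e$exon_index[best])),
             stringsAsFactors = FALSE)
}

#' Draw per-probe capture efficiencies
#'
#' Efficiencies are log-normal(0, `capture_sigma`); a random fraction
#' `frac_poor_probes` of probes is additionally scaled by `poor_factor`.
#'
#' @param panel an `smmip_panel`.
#' @param cfg a [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return named numeric vector of efficiencies, one per probe.
#' @export
draw_efficiencies <- function(panel, cfg, seed = cfg$seed) {
  n <- nrow(panel$probes)
  with_seed(seed, {
    eff <- rlnorm(n, meanlog = 0, sdlog = cfg$capture_sigma)
    n_poor <- round(cfg$frac_poor_probes * n)
    if (n_poor > 0) {
      poor <- sample.int(n, n_poor)
      eff[poor] <- eff[poor] * cfg$poor_factor
    }
    setNames(eff, panel$probes$probe_id)
  })
}

# Per-probe copy scale (0/0.5/1/1.5) for one sample's CNV genotype.
copy_scales <- function(panel, models, variants, sample) {
  pm <- map_probes_to_exons(panel, models)
  scale <- rep(1, nrow(panel$probes))
  for (v in variants) {
    if (!identical(v$type, "cnv") || !identical(v$sample, sample)) next
    hit <- !is.na(pm$gene) & pm$gene == v$gene &
      pm$exon_index >= v$first_exon & pm$exon_index <= v$last_exon
    scale[hit] <- v$copies / 2
  }
  scale
}

# Effective per-probe rate multiplier from a rebalancing plan: boosted
# phosphorylated concentration scales capture linearly; an unphosphorylated
# competitor multiplies effective capture by cfg$competitor_factor.
plan_multiplier <- function(panel, plan, cfg) {
  if (is.null(plan)) return(rep(1, nrow(panel$probes)))
  m <- match(panel$probes$probe_id, plan$probe_id)
  if (anyNA(m)) stop("plan does not cover all panel probes")
  base <- attr(plan, "base_conc_uM") %||% 0.1
  mult <- plan$phos_uM[m] / base
  mult[plan$unphos_uM[m] > 0] <-
    mult[plan$unphos_uM[m] > 0] * cfg$competitor_factor
  mult
}

#' Simulate deduplicated molecule counts for a cohort
#'
#' The capture model: per probe and sample, distinct molecules are
#' Poisson with mean `depth x efficiency x concentration multiplier x
#' copy scale`, where the copy scale is 0, 0.5, 1 or 1.5 from the
#' sample's CNV genotype. Each molecule draws a UMB uniformly from
#' `4^umb_len` tags, so the returned counts are the number of *distinct
#' tags* observed (tag collisions lose a few percent at typical depths),
#' exactly what deduplication of the corresponding reads would yield.
#'
#' @param panel an `smmip_panel`.
#' @param models an `smmip_gene_models`.
#' @param cfg a [sim_config()].
#' @param efficiencies optional fixed efficiency draw (see
#'   [draw_efficiencies()]); defaults to a fresh draw under `seed`.
#' @param plan optional rebalancing plan (see [make_plan()]) applied as a
#'   concentration multiplier.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param tag_collision model UMB-space saturation (default TRUE).
#' @return list with `counts` (samples x probes integer matrix),
#'   `molecules` (pre-collision molecule counts) and `efficiencies`.
#' @export
simulate_counts <- function(panel, models, cfg, efficiencies = NULL,
                            plan = NULL, seed = cfg$seed,
                            tag_collision = TRUE) {
  stopifnot(inherits(panel, "smmip_panel"), inherits(cfg, "sim_config"))
  if (is.null(efficiencies))
    efficiencies <- draw_efficiencies(panel, cfg, seed = seed + 1000L)
  np <- nrow(panel$probes)
  mult <- plan_multiplier(panel, plan, cfg)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  K <- 4^panel$probes$umb_len[1]
  with_seed(seed, {
    counts <- mols <- matrix(0L, cfg$n_samples, np,
                             dimnames = list(samples,
                                             panel$probes$probe_id))
    for (s in seq_along(samples)) {
      scale <- copy_scales(panel, models, cfg$variants, samples[s])
      lambda <- cfg$depth * efficiencies * mult * scale
      m <- rpois(np, lambda)
      mols[s, ] <- m
      if (tag_collision) {
        counts[s, ] <- vapply(m, function(mi) {
          if (mi == 0L) 0L
          else length(unique.default(sample.int(K, mi, replace = TRUE)))
        }, integer(1))
      } else counts[s, ] <- m
    }
    list(counts = counts, molecules = mols, efficiencies = efficiencies)
  })
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n <- nchar(seqs[1])
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    hits <- which(runif(nchar(s)) < rate)
    if (!length(hits)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[hits] <- vapply(ch[hits],
                       function(b) sample(setdiff(bases, b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate a UMB-tagged smMIP read cohort
#'
#' Generates paired FASTQ files per sample plus a truth manifest. Read
#' structure: R1 = extension arm + insert; R2 = UMB + ligation arm +
#' reverse-complemented insert. Each distinct molecule draws a UMB
#' uniformly over the tag space and a PCR duplicate count (geometric,
#' mean `pcr_dup_mean`); per-base errors are applied to every read copy
#' at `seq_error_rate`. Heterozygous SNVs are drawn per molecule
#' (Bernoulli 1/2 allele choice); CNV genotypes scale the molecule rate
#' by 0, 0.5, 1 or 1.5. Deterministic under `cfg$seed`.
#'
#' @inheritParams simulate_counts
#' @param reference output of [make_reference()].
#' @param out_dir output directory; per sample `<id>_R1.fastq[.gz]` and
#'   `<id>_R2.fastq[.gz]`, plus `manifest.json`.
#' @param gzip compress FASTQ output.
#' @return the truth manifest (list), invisibly also written as JSON.
#' @export
simulate_cohort <- function(panel, reference, cfg, out_dir,
                            efficiencies = NULL, plan = NULL,
                            gzip = FALSE) {
  stopifnot(inherits(panel, "smmip_panel"), inherits(cfg, "sim_config"))
  models <- reference$models
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(efficiencies))
    efficiencies <- draw_efficiencies(panel, cfg, seed = cfg$seed + 1000L)
  mult <- plan_multiplier(panel, plan, cfg)
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  p <- panel$probes
  refseq <- reference$sequence[[1]]
  umb_len <- p$umb_len[1]
  bases <- c("A", "C", "G", "T")
  # warn on variants outside the panel footprint
  fp <- target_footprint(panel)$intervals
  for (v in cfg$variants) {
    if (identical(v$type, "snv")) {
      inside <- any(fp$start <= v$pos & v$pos < fp$end)
      if (!inside)
        warning(sprintf("SNV at %d undetectable by design (outside footprint)",
                        v$pos))
    }
  }
  manifest <- list(seed = cfg$seed, samples = samples,
                   read_id_format = "sample:probe:m<molecule>:d<dup>",
                   efficiencies = as.list(efficiencies),
                   variants = cfg$variants, per_sample = list())
  with_seed(cfg$seed, {
    for (s in samples) {
      scale <- copy_scales(panel, models, cfg$variants, s)
      lambda <- cfg$depth * efficiencies * mult * scale
      snvs <- Filter(function(v) identical(v$type, "snv") &&
                       identical(v$sample, s), cfg$variants)
      r1 <- character(0); r2 <- character(0); ids <- character(0)
      mol_rows <- list()
      for (i in seq_len(nrow(p))) {
        m <- rpois(1L, lambda[i])
        if (m == 0L) next
        tstart <- p$start[i]; tend <- p$end[i]
        insert0 <- substr(refseq, tstart + 1L, tend)
        # SNVs overlapping this probe's target
        loc <- Filter(function(v) v$pos >= tstart && v$pos < tend, snvs)
        for (mol in seq_len(m)) {
          umb <- paste(sample(bases, umb_len, replace = TRUE),
                       collapse = "")
          ins <- insert0
          allele <- 0L
          for (v in loc) {
            carry <- if (v$zygosity == "hom") TRUE else runif(1) < 0.5
            if (carry) {
              allele <- 1L
              off <- v$pos - tstart + 1L
              refb <- substr(ins, off, off)
              altb <- bases[(match(refb, bases)) %% 4L + 1L]
              substr(ins, off, off) <- altb
            }
          }
          ndup <- 1L + if (cfg$pcr_dup_mean > 1)
            rgeom(1L, 1 / cfg$pcr_dup_mean) else 0L
          mol_rows[[length(mol_rows) + 1L]] <-
            data.frame(probe_id = p$probe_id[i], molecule = mol,
                       umb = umb, allele = allele, n_dups = ndup,
                       stringsAsFactors = FALSE)
          for (d in seq_len(ndup)) {
            ids <- c(ids, sprintf("%s:%s:m%04d:d%d", s, p$probe_id[i],
                                  mol, d))
            r1 <- c(r1, paste0(p$ext_arm[i], ins))
            r2 <- c(r2, paste0(umb, p$lig_arm[i], revcomp(ins)))
          }
        }
      }
      if (cfg$seq_error_rate > 0) {
        r1 <- apply_errors(r1, cfg$seq_error_rate)
        r2 <- apply_errors(r2, cfg$seq_error_rate)
      }
      ext <- if (gzip) ".fastq.gz" else ".fastq"
      f1 <- file.path(out_dir, paste0(s, "_R1", ext))
      f2 <- file.path(out_dir, paste0(s, "_R2", ext))
      write_fastq(ids, r1, f1, gzip)
      write_fastq(ids, r2, f2, gzip)
      manifest$per_sample[[s]] <-
        list(n_molecules = length(mol_rows), r1 = f1, r2 = f2,
             molecules = if (length(mol_rows)) do.call(rbind, mol_rows)
             else NULL)
    }
  })
  jsonlite::write_json(
    lapply(manifest$per_sample, function(x)
      list(n_molecules = x$n_molecules, r1 = x$r1, r2 = x$r2)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

write_fastq <- function(ids, seqs, path, gzip = FALSE) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, compress = gzip, format = "fastq",
                              qualities = qual)
  invisible(path)
}
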