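# Shared fixtures and independent brute-force oracles.

# A small explicit panel on chr1: two tiles of two probes (overlap 30),
# plus an isolated probe on a second gene.
tiny_panel <- function(capture_length = 110L) {
  probes <- data.frame(
    probe_id = c("P1", "P2", "P3"),
    gene = c("GA", "GA", "GB"),
    chrom = "chr1",
    start = c(100L, 180L, 1000L),
    end = c(100L, 180L, 1000L) + capture_length,
    ext_arm = c("ACGTACGTACGTACGTACGA", "ACGTACGTACGTACGTACGC",
                "ACGTACGTACGTACGTACGG"),
    lig_arm = c("TGCATGCATGCATGCATGCA", "TGCATGCATGCATGCATGCC",
                "TGCATGCATGCATGCATGCG"),
    stringsAsFactors = FALSE)
  smmip_panel(probes)
}

# Deterministic toy reference + designed panel used across tests.
sim_fixture <- function(seed = 11L, n_genes = 2L, exons_per_gene = 3L,
                        depth = 40, n_samples = 1L,
                        seq_error_rate = 0, pcr_dup_mean = 2,
                        variants = list(), ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    exons_per_gene = exons_per_gene, depth = depth,
                    n_samples = n_samples,
                    seq_error_rate = seq_error_rate,
                    pcr_dup_mean = pcr_dup_mean, variants = variants, ...)
  ref <- make_reference(cfg)
  panel <- design_panel(ref)
  list(cfg = cfg, ref = ref, panel = panel)
}

# Brute-force per-base union size of a set of intervals (oracle for
# target_footprint).
bf_union_bp <- function(df) {
  length(unique(unlist(mapply(function(c, s, e)
    paste0(c, ":", seq.int(s, e - 1L)), df$chrom, df$start, df$end,
    SIMPLIFY = FALSE))))
}

# Brute-force distinct-(probe, UMB) count (oracle for deduplicate).
bf_dedup_counts <- function(assignments) {
  a <- assignments[!grepl("N", assignments$umb, fixed = TRUE), ]
  tab <- table(a$probe_id[!duplicated(paste(a$probe_id, a$umb))])
  as.list(tab)
}

# Brute-force Viterbi: enumerate all k^n state paths and return the
# maximum joint-likelihood path (oracle for the HMM decode).
bf_viterbi <- function(emis, log_trans, log_init) {
  n <- nrow(emis); k <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  score <- apply(paths, 1, function(p) {
    s <- log_init[p[1]] + emis[1, p[1]]
    if (n > 1) for (i in 2:n)
      s <- s + log_trans[p[i - 1], p[i]] + emis[i, p[i]]
    s
  })
  as.integer(paths[which.max(score), ])
}

# Build an smmip_coverage with prescribed dedup counts via the public
# TSV reader.
coverage_from_counts <- function(counts, panel, raw = NULL) {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(probe_id = panel$probes$probe_id,
                   gene = panel$probes$gene,
                   raw_reads = if (is.null(raw)) counts else raw,
                   dedup_reads = counts,
                   duplicate_fraction = 0)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(tmp))
  read_coverage(tmp)
}

# Assignment table with n reads for one probe cycling through the given
# UMBs (for dedup-ceiling checks).
synthetic_assignments <- function(n, umbs, probe_id = "P1") {
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             probe_id = rep_len(probe_id, n),
             umb = rep_len(umbs, n),
             insert_seq = rep_len(strrep("A", 10), n),
             insert_qual = rep_len(strrep("I", 10), n),
             arm_mismatches = rep_len(0L, n), stringsAsFactors = FALSE)
}

all_umbs <- function(len = 5L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), len)))
}
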