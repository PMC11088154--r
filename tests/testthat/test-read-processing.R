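test_that("simulated reads are assigned back to their probes with their UMBs", {
  fx <- sim_fixture(seed = 17, depth = 25, n_samples = 1)
  man <- simulate_cohort(fx$panel, fx$ref, fx$cfg, dir <- tempfile())
  asn <- assign_reads(file.path(dir, "S01_R1.fastq"),
                      file.path(dir, "S01_R2.fastq"), fx$panel)
  # error rate 0, every pair on target
  expect_equal(asn$counters$on_target_fraction, 1.0)
  expect_equal(asn$counters$assigned + asn$counters$unassigned,
               asn$counters$total)
  # read ids encode sample:probe:molecule; the assignment must agree and
  # the extracted UMB must equal the tag the simulator drew
  truth_probe <- vapply(strsplit(asn$assignments$read_id, ":"), `[`, "", 2)
  expect_identical(asn$assignments$probe_id, truth_probe)
  mols <- man$per_sample$S01$molecules
  key <- paste(mols$probe_id, sprintf("m%04d", mols$molecule))
  akey <- paste(truth_probe,
                vapply(strsplit(asn$assignments$read_id, ":"), `[`, "", 3))
  expect_identical(asn$assignments$umb, mols$umb[match(akey, key)])
  unlink(dir, recursive = TRUE)
})

test_that("arm mismatches beyond tolerance leave reads unassigned", {
  panel <- tiny_panel()
  p <- panel$probes[1, ]
  insert <- strrep("A", 110)
  r1 <- paste0(p$ext_arm, insert)
  r2 <- paste0("ACGTA", p$lig_arm, strrep("T", 110))
  mutate_at <- function(s, i) {
    substr(s, i, i) <- ifelse(substr(s, i, i) == "A", "C", "A"); s
  }
  rp <- list(read_id = c("ok", "one_mm", "two_mm"),
             r1_seq = c(r1, mutate_at(r1, 3), mutate_at(mutate_at(r1, 3), 7)),
             r1_qual = rep(strrep("I", nchar(r1)), 3),
             r2_seq = rep(r2, 3), r2_qual = rep(strrep("I", nchar(r2)), 3))
  out <- smmipkit:::assign_read_pairs(rp, panel, max_arm_mismatch = 1L)
  expect_setequal(out$assignments$read_id, c("ok", "one_mm"))
  expect_equal(out$counters$unassigned, 1L)
  # a read shorter than arm + tag is unassigned, not an error
  rp_short <- list(read_id = "short", r1_seq = "ACGT", r1_qual = "IIII",
                   r2_seq = "ACG", r2_qual = "III")
  out2 <- smmipkit:::assign_read_pairs(rp_short, panel)
  expect_equal(out2$counters$assigned, 0L)
})

test_that("deduplication keeps one read per (probe, UMB) molecule", {
  panel <- tiny_panel()
  # 3 reads, same probe and UMB -> 1 kept
  a <- synthetic_assignments(3, "ACGTA")
  d <- deduplicate(a, seed = 1, panel = panel)
  expect_equal(nrow(d$kept), 1L)
  expect_true(d$kept$read_id %in% a$read_id)
  # UMBs containing N are excluded and counted
  a2 <- rbind(a, synthetic_assignments(2, "ACGTN"))
  d2 <- deduplicate(a2, seed = 1, panel = panel)
  expect_equal(nrow(d2$kept), 1L)
  expect_equal(d2$umb_ambiguous, 2L)
  # per-probe dedup can never exceed raw or the 4^5 tag space
  umbs <- all_umbs()
  a3 <- synthetic_assignments(2000, umbs)
  d3 <- deduplicate(a3, seed = 5, panel = panel)
  pp <- d3$per_probe[d3$per_probe$probe_id == "P1", ]
  expect_equal(pp$dedup_reads, 1024L)
  expect_equal(pp$raw_reads, 2000L)
  expect_equal(pp$duplicate_fraction, 1 - 1024 / 2000)
})

test_that("dedup counts match the closed-form tag-collision expectation", {
  # 500 molecules tagged uniformly over 4^5: expected distinct tags is
  # 1024 * (1 - (1 - 1/1024)^500); each molecule then PCR-amplified ~4x
  panel <- tiny_panel()
  m <- 500
  expected <- 1024 * (1 - (1 - 1 / 1024)^m)
  sd_bound <- 3 * sqrt(m)
  set.seed(88)
  umbs <- sample(all_umbs(), m, replace = TRUE)
  dups <- 1L + rgeom(m, 1 / 4)
  a <- synthetic_assignments(sum(dups), rep(umbs, dups))
  d <- deduplicate(a, seed = 2, panel = panel)
  got <- d$per_probe$dedup_reads[d$per_probe$probe_id == "P1"]
  expect_lt(abs(got - expected), sd_bound)
  expect_equal(got, length(unique(umbs)))
})

test_that("deduplicate agrees with the brute-force group-by oracle", {
  panel <- tiny_panel()
  set.seed(33)
  a <- data.frame(read_id = sprintf("r%03d", 1:100),
                  probe_id = sample(c("P1", "P2", "P3"), 100, TRUE),
                  umb = sample(c("AAAAA", "CCCCC", "GGGGG", "TTTTT",
                                 "ACGTA"), 100, TRUE),
                  insert_seq = "A", insert_qual = "I",
                  arm_mismatches = 0L, stringsAsFactors = FALSE)
  d <- deduplicate(a, seed = 4, panel = panel)
  oracle <- bf_dedup_counts(a)
  for (p in names(oracle))
    expect_equal(d$per_probe$dedup_reads[d$per_probe$probe_id == p],
                 as.integer(oracle[[p]]))
  # exactly one representative per group, drawn from that group
  key <- paste(d$kept$probe_id, d$kept$umb)
  expect_false(anyDuplicated(key) > 0)
  akey <- paste(a$probe_id, a$umb)
  for (i in seq_len(nrow(d$kept)))
    expect_true(d$kept$read_id[i] %in%
                  a$read_id[akey == key[i]])
  # byte-identical under the same seed, different under another
  d2 <- deduplicate(a, seed = 4, panel = panel)
  expect_identical(d$kept, d2$kept)
})

test_that("coverage report zero-fills, thresholds strictly, and round-trips", {
  panel <- tiny_panel()
  a <- rbind(synthetic_assignments(10, all_umbs()[1:10], "P1"),
             synthetic_assignments(30, all_umbs()[1:30], "P2"))
  d <- deduplicate(a, seed = 1, panel = panel)
  cov <- coverage_report(d, panel, threshold = 30)
  # probes with counts {10, 30, 0}: strictly-below-30 count is 2 (10 and 0)
  expect_equal(cov$probes$dedup_reads, c(10L, 30L, 0L))
  expect_equal(cov$summary$n_below, 2L)
  cov2 <- coverage_report(d, panel, threshold = 10)
  expect_equal(cov2$summary$n_below, 1L)
  # all-zero probes
  d0 <- deduplicate(synthetic_assignments(0, character(0)), 1, panel)
  cov0 <- coverage_report(d0, panel)
  expect_equal(cov0$summary$mean_coverage, 0)
  expect_equal(cov0$summary$median_coverage, 0)
  expect_equal(cov0$summary$n_below, 3L)
  # TSV round trip preserves counts
  tmp <- tempfile(fileext = ".tsv")
  write_coverage(cov, tmp)
  cov3 <- read_coverage(tmp)
  expect_equal(cov3$probes$dedup_reads, cov$probes$dedup_reads)
  expect_equal(cov3$summary$n_below, cov$summary$n_below)
})

test_that("uniform simulation recovers the target depth within 10%", {
  fx <- sim_fixture(seed = 29, depth = 200, capture_sigma = 0,
                    pcr_dup_mean = 2)
  man <- simulate_cohort(fx$panel, fx$ref, fx$cfg, dir <- tempfile())
  ps <- process_sample(file.path(dir, "S01_R1.fastq"),
                       file.path(dir, "S01_R2.fastq"), fx$panel, seed = 3)
  # molecule depth recovers the configured 200x within 10%
  mean_mols <- man$per_sample$S01$n_molecules / nrow(fx$panel$probes)
  expect_lt(abs(mean_mols - 200) / 200, 0.10)
  # dedup coverage additionally loses exactly the closed-form
  # tag-collision fraction: within 5% of 1024*(1-(1-1/1024)^200)
  exp_distinct <- 1024 * (1 - (1 - 1 / 1024)^200)
  expect_lt(abs(ps$coverage$summary$mean_coverage - exp_distinct) /
              exp_distinct, 0.05)
  # conservation: per-probe raw totals equal assigned reads
  expect_equal(sum(ps$dedup$per_probe$raw_reads),
               ps$assignments$counters$assigned)
  unlink(dir, recursive = TRUE)
})

test_that("full-loop identity recovers nearly all manifest molecules", {
  # depth well below the 4^5 tag space keeps collision loss under 1%
  fx <- sim_fixture(seed = 31, n_genes = 4L, depth = 5, pcr_dup_mean = 3,
                    n_samples = 1)
  man <- simulate_cohort(fx$panel, fx$ref, fx$cfg, dir <- tempfile())
  ps <- process_sample(file.path(dir, "S01_R1.fastq"),
                       file.path(dir, "S01_R2.fastq"), fx$panel, seed = 1)
  n_true <- man$per_sample$S01$n_molecules
  n_dedup <- sum(ps$dedup$per_probe$dedup_reads)
  expect_gte(n_dedup / n_true, 0.99)
  expect_lte(n_dedup, n_true)
  unlink(dir, recursive = TRUE)
})

test_that("qc_compare reports coverage drop and duplicate shift", {
  panel <- tiny_panel()
  a <- coverage_from_counts(rep(258L, 3), panel)
  b <- coverage_from_counts(rep(160L, 3), panel)
  cmp <- qc_compare(a, b)
  drop <- cmp$change[cmp$metric == "mean_coverage"]
  expect_equal(round(drop), 38)
  same <- qc_compare(a, a)
  expect_true(all(same$change[is.finite(same$change)] == 0))
  # lower input at a fixed read budget raises the duplicate fraction
  set.seed(51)
  budget <- 800
  high_in <- synthetic_assignments(budget,
                                   sample(all_umbs(), 400, TRUE))
  low_in <- synthetic_assignments(budget,
                                  sample(all_umbs(), 100, TRUE))
  dh <- deduplicate(high_in, 1, panel)
  dl <- deduplicate(low_in, 1, panel)
  ch <- coverage_report(dh, panel)
  cl <- coverage_report(dl, panel)
  expect_gt(cl$summary$duplicate_pct, ch$summary$duplicate_pct)
  # mismatched panels refuse to compare
  p2 <- smmip_panel(tiny_panel()$probes[1:2, ])
  expect_error(qc_compare(a, coverage_from_counts(c(1L, 2L), p2)),
               "different panels")
})

test_that("pileup caller finds injected SNVs and nothing else", {
  pos_for <- function(fx, gene, exon) exon_midpoint(fx$ref$models, gene, exon)
  # hom SNV at error rate 0: one call, alt fraction 1, hom
  fx <- sim_fixture(seed = 41, depth = 60)
  fx$cfg$variants <- list(snv_spec("S01", "G1", pos_for(fx, "G1", 2), "hom"))
  simulate_cohort(fx$panel, fx$ref, fx$cfg, dir <- tempfile())
  ps <- process_sample(file.path(dir, "S01_R1.fastq"),
                       file.path(dir, "S01_R2.fastq"), fx$panel, seed = 1)
  snv <- call_pileup_snvs(ps$dedup, fx$panel, fx$ref$sequence)
  expect_equal(nrow(snv), 1L)
  expect_equal(snv$pos, pos_for(fx, "G1", 2) + 1L)  # VCF is 1-based
  expect_equal(snv$alt_fraction, 1.0)
  expect_equal(snv$genotype, "hom")
  unlink(dir, recursive = TRUE)
  # het SNV at deeper coverage: alt fraction near 0.5, genotype het
  fx <- sim_fixture(seed = 43, depth = 200, pcr_dup_mean = 1)
  fx$cfg$variants <- list(snv_spec("S01", "G2", pos_for(fx, "G2", 1), "het"))
  simulate_cohort(fx$panel, fx$ref, fx$cfg, dir <- tempfile())
  ps <- process_sample(file.path(dir, "S01_R1.fastq"),
                       file.path(dir, "S01_R2.fastq"), fx$panel, seed = 1)
  snv <- call_pileup_snvs(ps$dedup, fx$panel, fx$ref$sequence)
  expect_equal(nrow(snv), 1L)
  expect_gt(snv$alt_fraction, 0.35); expect_lt(snv$alt_fraction, 0.65)
  expect_equal(snv$genotype, "het")
  # no injected variants, error 0 -> zero calls
  fx$cfg$variants <- list()
  simulate_cohort(fx$panel, fx$ref, fx$cfg, dir2 <- tempfile())
  ps0 <- process_sample(file.path(dir2, "S01_R1.fastq"),
                        file.path(dir2, "S01_R2.fastq"), fx$panel, seed = 1)
  expect_equal(nrow(call_pileup_snvs(ps0$dedup, fx$panel,
                                     fx$ref$sequence)), 0L)
  # VCF emission is well-formed
  vcf <- tempfile(fileext = ".vcf")
  write_snv_vcf(snv, vcf, sample = "S01")
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_equal(sum(!startsWith(lines, "#")), 1L)
  # missing contig errors
  expect_error(call_pileup_snvs(ps$dedup, fx$panel,
                                c(other = "ACGT")), "contig missing")
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("aligned SAM intake recovers probes by overlap and tags by name", {
  skip_if_not_installed("Rsamtools")
  panel <- tiny_panel()
  sam <- tempfile(fileext = ".sam")
  seq110 <- strrep("A", 110)
  q110 <- strrep("I", 110)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:2000",
    paste("r1#ACGTA", 0, "chr1", 101, 60, "110M", "*", 0, 0, seq110, q110,
          sep = "\t"),
    paste("r2#ACGTA", 0, "chr1", 101, 60, "110M", "*", 0, 0, seq110, q110,
          sep = "\t"),
    paste("r3#GGGGG", 0, "chr1", 1005, 60, "110M", "*", 0, 0, seq110, q110,
          sep = "\t"),
    paste("r4", 0, "chr1", 101, 60, "110M", "*", 0, 0, seq110, q110,
          sep = "\t"),
    paste("r5#TTTTT", 4, "*", 0, 0, "*", "*", 0, 0, seq110, q110,
          sep = "\t")), sam)
  asn <- assignments_from_sam(sam, panel)
  expect_equal(asn$counters$total, 5L)
  expect_equal(asn$counters$assigned, 3L)  # r4 lacks a tag, r5 unmapped
  a <- asn$assignments
  expect_equal(a$probe_id[a$read_id == "r1#ACGTA"], "P1")
  expect_equal(a$probe_id[a$read_id == "r3#GGGGG"], "P3")
  expect_equal(a$umb[a$read_id == "r1#ACGTA"], "ACGTA")
  d <- deduplicate(asn, seed = 1, panel = panel)
  expect_equal(d$per_probe$dedup_reads[d$per_probe$probe_id == "P1"], 1L)
})
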