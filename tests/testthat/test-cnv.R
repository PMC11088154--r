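# Shared 17-sample batch fixture for the CNV tests.
cnv_batch <- function(seed = 5, variants = list(), exons_per_gene = 14L,
                      n_samples = 17L, depth = 200, capture_sigma = 0.3) {
  cfg <- sim_config(seed = seed, n_genes = 2, exons_per_gene = exons_per_gene,
                    depth = depth, n_samples = n_samples,
                    capture_sigma = capture_sigma, variants = variants)
  ref <- make_reference(cfg)
  panel <- design_panel(ref)
  sim <- simulate_counts(panel, ref$models, cfg)
  list(cfg = cfg, ref = ref, panel = panel, sim = sim,
       mat = build_exon_matrix(sim$counts, panel, ref$models))
}

test_that("exon matrix enforces the batch minimum and maps probes once", {
  b <- cnv_batch()
  expect_equal(dim(b$mat$counts), c(17L, 28L))
  expect_false(any(b$mat$exons$masked))
  # 16 samples refuse to normalize
  expect_error(build_exon_matrix(b$sim$counts[1:16, ], b$panel,
                                 b$ref$models),
               "minimum of 17")
  m <- build_exon_matrix(b$sim$counts[1:16, ], b$panel, b$ref$models,
                         enforce_min_batch = FALSE)
  expect_equal(nrow(m$counts), 16L)
  # every panel probe maps to exactly one exon
  pm <- b$mat$probe_map
  expect_false(anyNA(pm$exon))
  expect_equal(nrow(pm), nrow(b$panel$probes))
  # counts are conserved: exon sums equal probe sums
  expect_equal(sum(b$mat$counts), sum(b$sim$counts))
})

test_that("a probe straddling two exons goes to the larger overlap", {
  models <- gene_models(data.frame(gene = "G", chrom = "chr1",
                                   start = c(100, 220), end = c(210, 320)))
  # probe [150, 260): 60 bp in exon 1, 40 bp in exon 2
  probes <- data.frame(probe_id = "P", gene = "G", chrom = "chr1",
                       start = 150L, end = 260L,
                       ext_arm = "ACGTA", lig_arm = "TGCAT",
                       stringsAsFactors = FALSE)
  pm <- map_probes_to_exons(smmip_panel(probes), models)
  expect_equal(pm$exon, "G:1")
})

test_that("low-quality exons are masked", {
  b <- cnv_batch()
  counts <- b$sim$counts
  # silence one exon's probes in 10 of 17 samples
  pm <- b$mat$probe_map
  kill <- pm$probe_id[pm$exon == "G2:3"]
  counts[1:10, kill] <- 0L
  m <- build_exon_matrix(counts, b$panel, b$ref$models)
  expect_true(m$exons$masked[m$exons$gene == "G2" & m$exons$exon_index == 3])
  r <- compute_ratios(m, "S15")
  expect_true(is.na(r$ratio[r$gene == "G2" & r$exon_index == 3]))
})

test_that("reference selection keeps correlated samples, drops outliers", {
  b <- cnv_batch()
  # test identical to 16 clones: every clone joins the reference
  clone <- b$sim$counts
  for (s in rownames(clone)) clone[s, ] <- clone["S01", ]
  mc <- build_exon_matrix(clone, b$panel, b$ref$models)
  expect_equal(length(select_reference(mc, "S01")$reference_samples), 16L)
  # noisy siblings from one efficiency draw: most still correlate in
  ref <- select_reference(b$mat, "S01")
  expect_gte(length(ref$reference_samples), 8L)
  # an uncorrelated-noise sample is excluded
  counts <- b$sim$counts
  set.seed(9)
  counts["S17", ] <- rpois(ncol(counts), sample(c(5, 800), ncol(counts),
                                                replace = TRUE))
  m2 <- build_exon_matrix(counts, b$panel, b$ref$models)
  ref2 <- select_reference(m2, "S01")
  expect_false("S17" %in% ref2$reference_samples)
  # two-sample batch: the reference is the other sample
  m3 <- build_exon_matrix(b$sim$counts[1:2, ], b$panel, b$ref$models,
                          enforce_min_batch = FALSE)
  ref3 <- select_reference(m3, "S01")
  expect_equal(ref3$reference_samples, "S02")
  # all-zero test profile errors
  counts0 <- b$sim$counts
  counts0["S01", ] <- 0L
  m0 <- build_exon_matrix(counts0, b$panel, b$ref$models)
  expect_error(select_reference(m0, "S01"), "all-zero")
})

test_that("observed/expected ratios sit at one for diploid samples", {
  b <- cnv_batch()
  for (s in c("S02", "S09")) {
    r <- compute_ratios(b$mat, s)
    expect_lt(abs(mean(r$ratio, na.rm = TRUE) - 1), 0.05)
  }
  # a test sample drawn exactly from reference proportions has ratio 1
  counts <- b$sim$counts
  counts["S01", ] <- as.integer(round(colMeans(counts[2:17, ])))
  m <- build_exon_matrix(counts, b$panel, b$ref$models)
  r <- compute_ratios(m, "S01")
  expect_true(all(abs(r$ratio - 1) < 0.1))
})

test_that("deletion ratios scale with copy number", {
  b <- cnv_batch(seed = 31,
                 variants = list(cnv_spec("S01", "G1", 5, 5, copies = 1),
                                 cnv_spec("S02", "G2", 9, 9, copies = 0)))
  r1 <- compute_ratios(b$mat, "S01")
  het <- r1$ratio[r1$gene == "G1" & r1$exon_index == 5]
  expect_lt(abs(het - 0.5), 0.15)
  r0 <- compute_ratios(b$mat, "S02")
  expect_lt(r0$ratio[r0$gene == "G2" & r0$exon_index == 9], 0.05)
})

test_that("Viterbi decode matches brute-force path enumeration", {
  params <- cnv_params()
  lt <- log(smmipkit:::cnv_transition_matrix(params$transition,
                                             params$stay_cnv))
  li <- log(c(params$transition, 1 - 2 * params$transition,
              params$transition))
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    phi <- rep(1 / n, n)
    truth <- sample(c(1L, 2L, 3L), n, replace = TRUE,
                    prob = c(0.2, 0.6, 0.2))
    scale <- c(0.5, 1, 1.5)[truth]
    x <- rpois(n, 200 * scale)
    emis <- smmipkit:::cnv_emissions(x, sum(x), phi,
                                     params$state_fractions, 0.01)
    expect_equal(smmipkit:::viterbi_path(emis, lt, li),
                 bf_viterbi(emis, lt, li))
  }
})

test_that("single- and multi-exon deletions are called with exact bounds", {
  b <- cnv_batch(seed = 13,
                 variants = list(cnv_spec("S01", "G1", 5, 5, copies = 0),
                                 cnv_spec("S02", "G2", 3, 14, copies = 0),
                                 cnv_spec("S03", "G1", 8, 8, copies = 1)))
  # homozygous exon-5 deletion in a 14-exon gene
  c1 <- call_cnvs(b$mat, "S01")
  expect_equal(nrow(c1$calls), 1L)
  expect_equal(c1$calls$state, "deletion")
  expect_equal(c(c1$calls$first_exon, c1$calls$last_exon), c(5L, 5L))
  expect_equal(c1$calls$copy_estimate, "0")
  expect_lt(c1$calls$ratio, 1)
  # multi-exon deletion spanning exons 3-14
  c2 <- call_cnvs(b$mat, "S02")
  expect_equal(nrow(c2$calls), 1L)
  expect_equal(c(c2$calls$first_exon, c2$calls$last_exon), c(3L, 14L))
  # heterozygous single-exon deletion
  c3 <- call_cnvs(b$mat, "S03")
  expect_equal(nrow(c3$calls), 1L)
  expect_equal(c(c3$calls$first_exon, c3$calls$last_exon), c(8L, 8L))
  expect_equal(c3$calls$copy_estimate, "1")
  expect_gt(c3$calls$score, 0)
  # a diploid sibling stays call-free
  expect_equal(nrow(call_cnvs(b$mat, "S10")$calls), 0L)
})

test_that("duplications are called with ratio above one", {
  # heterozygous duplications are the weakest detectable event (ratio
  # 1.5 against Poisson noise) and must also stay a small fraction of
  # the panel, or the event inflates the sample's own normalization
  # total; use a 4-gene panel with a 5-exon event and allow one exon of
  # boundary fuzz
  cfg <- sim_config(seed = 41, n_genes = 4, exons_per_gene = 14,
                    depth = 200, n_samples = 17, capture_sigma = 0.3,
                    variants = list(cnv_spec("S01", "G2", 2, 6,
                                             copies = 3)))
  ref <- make_reference(cfg)
  panel <- design_panel(ref)
  sim <- simulate_counts(panel, ref$models, cfg)
  mat <- build_exon_matrix(sim$counts, panel, ref$models)
  cl <- call_cnvs(mat, "S01")
  dup <- cl$calls[cl$calls$state == "duplication", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$gene, "G2")
  expect_lte(abs(dup$first_exon - 2L), 1L)
  expect_lte(abs(dup$last_exon - 6L), 1L)
  expect_gt(dup$ratio, 1)
  expect_equal(dup$copy_estimate, "3+")
})

test_that("cnv outputs serialize and plot", {
  b <- cnv_batch(seed = 13,
                 variants = list(cnv_spec("S01", "G1", 5, 5, copies = 0)))
  cl <- call_cnvs(b$mat, "S01")
  calls <- tempfile(fileext = ".tsv"); ratios <- tempfile(fileext = ".tsv")
  write_cnv(cl, calls, ratios)
  expect_equal(nrow(read.delim(calls)), nrow(cl$calls))
  expect_equal(nrow(read.delim(ratios)), nrow(cl$ratios))
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path, width = 700, height = 500)
  plot(cl)
  grDevices::dev.off()
  expect_gt(file.size(png_path), 0)
  unlink(c(calls, ratios, png_path))
})

test_that("X-chromosome exons demand sex-matched references", {
  b <- cnv_batch()
  # relabel gene G2 as X-linked
  exx <- b$ref$models$exons
  exx$chrom[exx$gene == "G2"] <- "chrX"
  px <- b$panel$probes
  px$chrom[px$gene == "G2"] <- "chrX"
  panel_x <- smmip_panel(px)
  models_x <- gene_models(exx)
  mx <- build_exon_matrix(b$sim$counts, panel_x, models_x)
  expect_warning(select_reference(mx, "S01"), "sex metadata")
  sex <- setNames(rep(c("M", "F"), length.out = 17), mx$samples)
  ref <- select_reference(mx, "S01", sex = sex)
  expect_true(all(sex[ref$reference_samples] == sex[["S01"]]))
  expect_error(select_reference(mx, "S01", sex = sex[-1]),
               "no stated sex")
})
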