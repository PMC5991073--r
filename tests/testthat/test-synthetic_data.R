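test_that("panel generation is deterministic and produces the requested records", {
  spec <- panel_spec(n_haplotypes = 100, n_snps_per_block = 3, n_blocks = 2, seed = 42)
  v1 <- tempfile(fileext = ".vcf")
  v2 <- tempfile(fileext = ".vcf")
  p1 <- gen_reference_panel(spec, vcf_path = v1)
  p2 <- gen_reference_panel(spec, vcf_path = v2)
  expect_identical(readLines(v1), readLines(v2))
  expect_identical(p1$genotypes, p2$genotypes)
  # 2 blocks x 3 SNPs = 6 records
  body <- grep("^#", readLines(v1), invert = TRUE, value = TRUE)
  expect_length(body, 6)
  expect_true(all(p1$genotypes %in% 0:2))
  # positions strictly increasing within each chromosome
  for (ch in unique(p1$snp_map$chrom)) {
    expect_true(all(diff(p1$snp_map$pos[p1$snp_map$chrom == ch]) > 0))
  }
})

test_that("panel spec validation rejects bad layouts and parameters", {
  expect_error(panel_spec(n_haplotypes = 101), "even")
  expect_error(panel_spec(block_rho = 1), "block_rho")
  expect_error(panel_spec(maf_range = c(0, 0.5)), "maf_range")
  lay <- data.frame(block = 1:2, chrom = "1", start = c(1000, 2000), spacing = 1000)
  expect_error(panel_spec(n_snps_per_block = 5, n_blocks = 2, chromosome_layout = lay),
               "overlapping")
})

test_that("empirical MAFs stay inside the requested range", {
  spec <- panel_spec(n_haplotypes = 300, n_snps_per_block = 10, n_blocks = 6,
                     maf_range = c(0.1, 0.4), seed = 9)
  pan <- gen_reference_panel(spec)
  f <- colMeans(pan$genotypes) / 2
  maf <- pmin(f, 1 - f)
  expect_true(all(maf >= 0.1 & maf <= 0.4))
})

test_that("block_rho = 0 gives near-zero within-block genotype correlation", {
  mad_offdiag <- vapply(1:20, function(s) {
    spec <- panel_spec(n_haplotypes = 2000, n_snps_per_block = 10, n_blocks = 1,
                       block_rho = 0, seed = s)
    R <- cor(gen_reference_panel(spec)$genotypes)
    mean(abs(R[upper.tri(R)]))
  }, numeric(1))
  expect_true(all(mad_offdiag < 0.1))
})

test_that("panel genotype LD reproduces the autoregressive target", {
  spec <- panel_spec(n_haplotypes = 2000, n_snps_per_block = 15, n_blocks = 1,
                     block_rho = 0.7, seed = 4)
  pan <- gen_reference_panel(spec)
  R <- cor(pan$genotypes)
  target <- 0.7^abs(outer(1:15, 1:15, "-"))
  expect_lt(mean(abs(R - target)[upper.tri(R)]), 0.05)
})

test_that("null summary statistics have uniform p-values", {
  spec <- panel_spec(n_haplotypes = 400, n_snps_per_block = 20, n_blocks = 500,
                     block_rho = 0.6, seed = 11)
  pan <- gen_reference_panel(spec)
  ss <- gen_summary_stats(pan, seed = 12)
  expect_true(all(ss$P > 0 & ss$P <= 1))
  D <- suppressWarnings(ks.test(ss$P, "punif")$statistic)
  expect_lt(D, 1.63 / sqrt(nrow(ss))) # 1% critical value of the KS distance
})

test_that("injected signal shifts the causal z-score by the noncentrality", {
  spec <- panel_spec(n_haplotypes = 200, n_snps_per_block = 5, n_blocks = 1,
                     block_rho = 0.5, seed = 2)
  pan <- gen_reference_panel(spec)
  sig <- signal_spec(pan$snp_map$snp[3], noncentrality = 5)
  z <- vapply(1:500, function(s) gen_summary_stats(pan, sig, seed = s)$Z[3],
              numeric(1))
  expect_lt(abs(mean(abs(z)) - 5), 3 * sd(abs(z)) / sqrt(500))
  expect_lt(abs(mean(z) - 5), 3 * sd(z) / sqrt(500))
})

test_that("empty causal set equals the explicit null and is deterministic", {
  spec <- panel_spec(n_haplotypes = 100, n_snps_per_block = 4, n_blocks = 2, seed = 3)
  pan <- gen_reference_panel(spec)
  a <- gen_summary_stats(pan, signal_spec(), seed = 7)
  b <- gen_summary_stats(pan, signal_spec(character(), 0), seed = 7)
  expect_identical(a, b)
  expect_error(gen_summary_stats(pan, signal_spec("rs9999999", 2), seed = 1),
               "not in panel")
})

test_that("synthetic annotations respect counts, bounds and determinism", {
  spec <- panel_spec(n_haplotypes = 100, n_snps_per_block = 10, n_blocks = 4, seed = 5)
  pan <- gen_reference_panel(spec)
  g1 <- tempfile(fileext = ".gff3")
  g2 <- tempfile(fileext = ".gff3")
  a1 <- gen_mirna_annotations(5, pan$snp_map, seed = 8, non_autosomal_fraction = 0.4,
                              gff_path = g1)
  gen_mirna_annotations(5, pan$snp_map, seed = 8, non_autosomal_fraction = 0.4,
                        gff_path = g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_equal(sum(a1$chrom == "X"), 2)
  len <- a1$tx_end - a1$tx_start + 1
  expect_true(all(len >= 60 & len <= 150))
})

test_that("synthetic Alda scores have valid ranges and are reproducible", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  d <- gen_alda_scores(100, seed = 21, csv_path = f1)
  gen_alda_scores(100, seed = 21, csv_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(d), 100)
  expect_true(all(d$A %in% 0:10))
  b_total <- d$B1 + d$B2 + d$B3 + d$B4 + d$B5
  expect_true(all(b_total >= 0 & b_total <= 10))
  expect_identical(names(d), c("subject_id", "A", "B1", "B2", "B3", "B4", "B5"))
})

test_that("eQTL list sampling honours fraction and id space", {
  spec <- panel_spec(n_haplotypes = 100, n_snps_per_block = 100, n_blocks = 10, seed = 6)
  map <- gen_reference_panel(spec)$snp_map
  expect_setequal(gen_eqtl_list(map, 1, seed = 1), map$snp)
  ids <- gen_eqtl_list(map, 0.1, seed = 2)
  expect_length(ids, 100)
  expect_true(all(ids %in% map$snp))
})
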