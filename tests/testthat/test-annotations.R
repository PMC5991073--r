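test_that("GFF3 and BED readers agree on miRBase-style coordinates", {
  gff <- write_gff3(data.frame(chrom = "chr20", start = 34990376L, end = 34990497L,
                               name = "miR-499a", type = "miRNA_primary_transcript"),
                    tempfile(fileext = ".gff3"))
  rec <- load_mirna_annotations(gff, "gff3")
  expect_equal(rec$name, "miR-499a")
  expect_equal(norm_chrom(rec$chrom), "20")
  expect_equal(rec$tx_start, 34990376)
  expect_equal(rec$tx_end, 34990497)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr20\t34990375\t34990497\tmiR-499a", bed)
  rec_bed <- load_mirna_annotations(bed, "bed")
  expect_equal(rec_bed$tx_start, 34990376) # 0-based half-open -> 1-based closed
  expect_equal(rec_bed$tx_end, 34990497)
  expect_equal(rec_bed$name, "miR-499a")
})

test_that("annotation reader handles empty files, feature filters and duplicates", {
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(load_mirna_annotations(empty, "gff3")), 0)

  mixed <- write_gff3(data.frame(chrom = c("1", "1"), start = c(100L, 120L),
                                 end = c(200L, 141L), name = c("mir-a", "mir-a-5p"),
                                 type = c("miRNA_primary_transcript", "exon")),
                      tempfile(fileext = ".gff3"))
  rec <- load_mirna_annotations(mixed, "gff3")
  expect_equal(rec$name, "mir-a") # non-miRNA feature types are ignored

  dup <- write_gff3(data.frame(chrom = "1", start = c(100L, 300L), end = c(200L, 400L),
                               name = "mir-a", type = "miRNA"),
                    tempfile(fileext = ".gff3"))
  expect_error(load_mirna_annotations(dup, "gff3"), "duplicate")
})

test_that("autosome filter keeps 1-22 only and counts removals", {
  rec <- data.frame(name = paste0("m", 1:5),
                    chrom = c("1", "X", "22", "Y", "MT"),
                    tx_start = 1:5 * 100, tx_end = 1:5 * 100 + 50,
                    stringsAsFactors = FALSE)
  out <- filter_autosomal(rec)
  expect_equal(out$records$chrom, c("1", "22"))
  expect_equal(out$n_removed, 3)

  all_auto <- data.frame(name = "m", chrom = "chr7", tx_start = 1, tx_end = 2)
  out2 <- filter_autosomal(all_auto)
  expect_equal(out2$n_removed, 0)
  expect_equal(out2$records$chrom, "7") # prefix stripped

  bad <- data.frame(name = "m", chrom = "contig_5", tx_start = 1, tx_end = 2)
  expect_error(filter_autosomal(bad), "unrecognized")
})

test_that("window expansion applies the flank symmetrically with clamping", {
  rec <- data.frame(name = "miR-499a", chrom = "20",
                    tx_start = 34990376, tx_end = 34990497)
  w <- expand_window(rec, 20000)
  expect_equal(w$win_start, 34970376)
  expect_equal(w$win_end, 35010497)

  near_start <- expand_window(data.frame(name = "m", chrom = "1",
                                         tx_start = 5000, tx_end = 5100), 20000)
  expect_equal(near_start$win_start, 1)

  no_flank <- expand_window(rec, 0)
  expect_equal(no_flank$win_start, rec$tx_start)
  expect_equal(no_flank$win_end, rec$tx_end)
})

test_that("SNP assignment uses closed intervals and flags uncovered windows", {
  win <- expand_window(data.frame(name = c("w1", "w2"),
                                  chrom = c("1", "2"),
                                  tx_start = c(100000, 100000),
                                  tx_end = c(100000, 100000)), 20000)
  ss <- make_sumstats(rep(0.5, 3), chrom = "1", start_bp = 80000, spacing = 0)
  ss$BP <- c(80000, 120000, 120001)
  asg <- assign_snps(win, ss)
  expect_equal(asg$sets[["w1"]]$snp_ids, c("s1", "s2")) # 120001 excluded (closed interval)
  expect_false(asg$sets[["w2"]]$covered) # no SNPs on chr2
  expect_equal(asg$n_covered, 1)
})

test_that("a SNP in overlapping windows is assigned to each of them", {
  win <- expand_window(data.frame(name = c("a", "b"), chrom = "1",
                                  tx_start = c(50000, 60000),
                                  tx_end = c(50100, 60100)), 20000)
  ss <- make_sumstats(0.5, chrom = "1", start_bp = 45000) # inside both windows
  asg <- assign_snps(win, ss)
  expect_equal(asg$sets[["a"]]$snp_ids, "s1")
  expect_equal(asg$sets[["b"]]$snp_ids, "s1")
})

test_that("assignment is independent of record order and idempotent", {
  set.seed(1)
  win <- expand_window(data.frame(name = paste0("w", 1:6),
                                  chrom = rep(c("1", "2"), 3),
                                  tx_start = rep(c(1e5, 2e5, 3e5), each = 2),
                                  tx_end = rep(c(1e5, 2e5, 3e5), each = 2) + 100),
                       20000)
  ss <- make_sumstats(runif(50), chrom = sample(c("1", "2"), 50, replace = TRUE),
                      start_bp = 9e4, spacing = 5000)
  a <- assign_snps(win, ss)
  perm_w <- sample(nrow(win))
  perm_s <- sample(nrow(ss))
  b <- assign_snps(win[perm_w, ], ss[perm_s, ])
  for (nm in win$name) {
    expect_identical(a$sets[[nm]]$snp_ids, b$sets[[nm]]$snp_ids)
  }
  expect_equal(a$n_covered, b$n_covered)
})
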