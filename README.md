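# mirwin — window-based miRNA association tests for GWAS summary statistics

`mirwin` asks whether microRNA loci are associated with a trait when all you
have is GWAS summary statistics. Its motivating use case is lithium treatment
response in bipolar disorder, phenotyped on the Alda scale, but the machinery
is trait-agnostic: any summary-statistics table with SNP id, chromosome,
position and p-value can be scanned against any miRBase-style annotation set.

miRNA genes are far too short to rely on single-SNP hits, so each miRNA is
tested as a *window* — the transcript ± 20 kb of flanking sequence — with a
set-based statistic in the VEGAS family:

1. transform each SNP p-value to its upper-tail χ²₁ quantile,
   `q_i = Q_{χ²₁}(1 − p_i)`;
2. sum the `k = max(1, ⌈0.1·m⌉)` largest values (the "top-0.1" statistic) of
   the window's `m` SNPs;
3. compare against statistics simulated from `z ~ MVN(0, R)` where `R` is the
   LD (dosage) correlation of the window's SNPs in a reference genotype
   panel, **re-selecting the top k within every simulated replicate** so that
   the data-driven selection of the observed statistic is mirrored in the
   null (without this correction the test is strongly anti-conservative under
   LD);
4. report the add-one empirical p-value `(1 + #{T_sim ≥ T_obs}) / (1 + n_sim)`
   with simulation counts escalating 10³ → 10⁶ for small p-values.

Around the core test the package provides: Alda-scale phenotype derivation
(total = max(0, A − ΣB); good responder at total ≥ 7; continuous = A score,
excluded when ΣB > 4), Benjamini–Hochberg correction across the tested
miRNAs, one-sided Fisher exact enrichment tests (nominally significant SNPs
in miRNA windows; cis-miR-eQTL SNP lists), and a fully seeded synthetic-data
module (LD-blocked diploid panels written as VCF, MVN summary statistics,
GFF3 miRNA annotations, Alda tables, eQTL lists) so every stage is testable
without access to consortium data.

## Worked example

A synthetic end-to-end scan: a 500-subject reference panel with 24 LD blocks
(AR(1) correlation 0.7), twelve miRNA windows, and an association signal
(noncentrality 5) injected at one SNP inside each of the first three windows.

```r
library(mirwin)

spec <- panel_spec(n_haplotypes = 1000, n_snps_per_block = 20, n_blocks = 24,
                   block_rho = 0.7, seed = 101)
panel <- gen_reference_panel(spec)

ann <- gen_mirna_annotations(12, panel$snp_map, seed = 102)
win <- expand_window(filter_autosomal(ann)$records, flank_bp = 20000)
causal <- vapply(1:3, function(i) {
  on_chr <- panel$snp_map$chrom == win$chrom[i]
  panel$snp_map$snp[on_chr][which.min(abs(panel$snp_map$pos[on_chr] - win$tx_start[i]))]
}, character(1))
ss <- gen_summary_stats(panel, signal_spec(causal, noncentrality = 5), seed = 103)

asg <- assign_snps(win, ss)
cfg <- set_test_config(top_fraction = 0.1, sim_stages = c(1e3, 1e4, 1e5), seed = 104)
rows <- lapply(asg$sets[sapply(asg$sets, `[[`, "covered")], function(set) {
  g  <- load_genotypes(panel, set$snp_ids, region = set$window, summary_stats = ss)
  ld <- ensure_psd(ld_correlation(g$dosage))
  r  <- test_window(set, ss, ld, cfg)
  data.frame(miRNA = r$mirna_name, n_SNPs = r$n_snps_tested,
             p_miRNA = r$empirical_p, top_SNP = r$top_snp_id,
             p_top_SNP = r$top_snp_p)
})
tab <- do.call(rbind, rows)
tab$p_corr_miRNA <- bh_adjust(tab$p_miRNA)
tab <- tab[order(tab$p_miRNA), ]
tab[c("p_miRNA", "p_corr_miRNA", "p_top_SNP")] <-
  lapply(tab[c("p_miRNA", "p_corr_miRNA", "p_top_SNP")], format_pval)
print(tab, row.names = FALSE)
```

```
       miRNA n_SNPs  p_miRNA   top_SNP p_top_SNP p_corr_miRNA
 syn-mir-001     20 3.00E-05 rs0000111  3.74E-09     3.60E-04
 syn-mir-002     19 2.30E-04 rs0000366  2.22E-08     1.38E-03
 syn-mir-003     16 3.50E-03 rs0000303  7.77E-06     1.40E-02
 syn-mir-004     14 1.73E-01 rs0000184  1.79E-02     4.65E-01
 syn-mir-005     18 1.94E-01 rs0000184  1.79E-02     4.65E-01
 syn-mir-009     20 4.41E-01 rs0000149  5.14E-02     8.81E-01
 syn-mir-012     19 6.55E-01 rs0000138  5.38E-02     9.78E-01
 syn-mir-008     20 6.94E-01 rs0000457  9.59E-02     9.78E-01
 syn-mir-006     20 8.32E-01 rs0000245  1.03E-01     9.78E-01
 syn-mir-011     16 8.68E-01 rs0000025  1.39E-01     9.78E-01
 syn-mir-010     20 9.30E-01 rs0000025  1.39E-01     9.78E-01
 syn-mir-007     14 9.78E-01 rs0000258  3.51E-01     9.78E-01
```

The three windows carrying injected signal (`syn-mir-001..003`, causal SNPs
`rs0000111`, `rs0000366`, `rs0000303`) head the table with BH-corrected
p-values below 0.05; the nine null windows scatter over (0.1, 1). `p_miRNA`
is the window's empirical set-test p-value, `p_top_SNP` the smallest per-SNP
p-value inside the window — a single strong SNP and a significant window
usually coincide here because each signal window has exactly one causal SNP.

The same scan runs in one call from files (`run_pipeline()` accepts TSV
summary statistics, a GFF3/BED annotation file, a VCF panel and an eQTL id
list, and writes per-phenotype result TSVs in the table layout above plus an
enrichment report), or fully synthetically via
`run_config(mode = "synthetic-demo", ...)`.

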