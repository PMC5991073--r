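#' Specification of a synthetic LD-blocked reference panel
#'
#' Describes a diploid reference panel made of independent LD blocks. Within a
#' block, haplotype alleles follow a first-order Markov copying process with
#' parameter `block_rho`, which yields a pairwise allele correlation of
#' `block_rho^|i - j|` between SNPs `i` and `j` (an autoregressive decay);
#' across blocks SNPs are independent. All SNPs of a block share one allele
#' frequency drawn from `maf_range`, so the autoregressive correlation target
#' is exact on the allele scale; frequencies vary across blocks.
#'
#' @param n_haplotypes even number of haplotypes; subjects are consecutive
#'   haplotype pairs, so the panel has `n_haplotypes / 2` diploid subjects.
#' @param n_snps_per_block SNPs per LD block.
#' @param n_blocks number of LD blocks.
#' @param block_rho within-block autoregressive correlation, in `[0, 1)`.
#' @param maf_range length-2 numeric, minor-allele-frequency bounds in
#'   `(0, 0.5]`; block frequencies are drawn uniformly from this interval and
#'   a block is regenerated until every empirical MAF falls inside it.
#' @param chromosome_layout data frame with columns `block`, `chrom`, `start`,
#'   `spacing` giving each block's chromosome label, first SNP position
#'   (1-based bp) and inter-SNP spacing (bp). Defaults to blocks laid out
#'   cyclically over autosomes 1-22 with 1500 bp spacing and 1 Mb gaps.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(n_haplotypes = 2000, n_snps_per_block = 20,
                       n_blocks = 10, block_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       chromosome_layout = NULL, seed = 1) {
  if (n_haplotypes < 4 || n_haplotypes %% 2 != 0) {
    stop("n_haplotypes must be an even number >= 4 (diploid pairing)")
  }
  if (n_snps_per_block < 1 || n_blocks < 1) stop("need >= 1 SNP per block and >= 1 block")
  if (block_rho < 0 || block_rho >= 1) stop("block_rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be increasing within (0, 0.5]")
  }
  if (is.null(chromosome_layout)) {
    chrom <- rep(as.character(1:22), length.out = n_blocks)
    idx_on_chrom <- stats::ave(seq_len(n_blocks), chrom, FUN = seq_along)
    spacing <- 1500
    span <- n_snps_per_block * spacing + 1e6
    chromosome_layout <- data.frame(
      block = seq_len(n_blocks), chrom = chrom,
      start = 1e6 + (idx_on_chrom - 1) * span,
      spacing = spacing, stringsAsFactors = FALSE
    )
  }
  req <- c("block", "chrom", "start", "spacing")
  if (!all(req %in% names(chromosome_layout))) {
    stop("chromosome_layout needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(chromosome_layout) != n_blocks) stop("chromosome_layout must have one row per block")
  lay <- chromosome_layout
  lay$end <- lay$start + (n_snps_per_block - 1) * lay$spacing
  for (ch in unique(lay$chrom)) {
    b <- lay[lay$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("invalid chromosome_layout: overlapping blocks on chromosome ", ch)
    }
  }
  structure(list(n_haplotypes = n_haplotypes, n_snps_per_block = n_snps_per_block,
                 n_blocks = n_blocks, block_rho = block_rho, maf_range = maf_range,
                 chromosome_layout = chromosome_layout, seed = seed),
            class = "panel_spec")
}

#' Specification of an injected association signal
#'
#' @param causal_snp_ids character vector of SNP ids that carry signal.
#' @param noncentrality non-negative mean shift of the association z-score at
#'   each causal SNP (unitless; a noncentrality of 5 corresponds to a strongly
#'   genome-wide-significant SNP).
#' @return an object of class `signal_spec`.
#' @export
signal_spec <- function(causal_snp_ids = character(), noncentrality = 0) {
  if (noncentrality < 0) stop("noncentrality must be >= 0")
  structure(list(causal_snp_ids = as.character(causal_snp_ids),
                 noncentrality = noncentrality),
            class = "signal_spec")
}

# One LD block of haplotypes: first-order Markov copying chain with shared
# allele frequency. Redrawn (with a fresh frequency) until all empirical MAFs
# fall inside maf_range.
.gen_block_haplotypes <- function(n_hap, m, rho, maf_range) {
  for (try in 1:200) {
    freq <- stats::runif(1, maf_range[1], maf_range[2])
    H <- matrix(0L, n_hap, m)
    H[, 1] <- stats::rbinom(n_hap, 1, freq)
    if (m > 1) {
      for (j in 2:m) {
        copy <- stats::runif(n_hap) < rho
        fresh <- stats::rbinom(n_hap, 1, freq)
        H[, j] <- ifelse(copy, H[, j - 1], fresh)
      }
    }
    f <- colMeans(H)
    maf <- pmin(f, 1 - f)
    if (all(maf >= maf_range[1] & maf <= maf_range[2])) {
      return(list(H = H, freq = freq))
    }
  }
  stop("could not generate a block with all MAFs inside maf_range after 200 tries")
}

#' Generate a synthetic diploid reference panel
#'
#' Simulates haplotypes block by block according to a [panel_spec()] and pairs
#' them into diploid genotype dosages in `{0, 1, 2}`. Optionally writes the
#' panel as an uncompressed VCF v4.2 file with unphased GT fields.
#'
#' @param spec a [panel_spec()].
#' @param vcf_path optional path; when given, the panel is written there with
#'   [write_panel_vcf()].
#' @return an object of class `ref_panel`: a list with `genotypes` (subjects x
#'   SNPs integer matrix, columns named by SNP id), `snp_map` (data frame with
#'   columns `snp`, `chrom`, `pos`, `block`, `freq`) and the `spec`.
#' @export
gen_reference_panel <- function(spec, vcf_path = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  lay <- spec$chromosome_layout
  lay <- lay[order(lay$block), , drop = FALSE]
  with_seed(spec$seed, {
    geno <- vector("list", spec$n_blocks)
    maps <- vector("list", spec$n_blocks)
    for (b in seq_len(spec$n_blocks)) {
      blk <- .gen_block_haplotypes(spec$n_haplotypes, spec$n_snps_per_block,
                                   spec$block_rho, spec$maf_range)
      H <- blk$H
      G <- H[seq(1, nrow(H), by = 2), , drop = FALSE] +
           H[seq(2, nrow(H), by = 2), , drop = FALSE]
      ids <- sprintf("rs%07d", (b - 1) * spec$n_snps_per_block + seq_len(spec$n_snps_per_block))
      colnames(G) <- ids
      geno[[b]] <- G
      maps[[b]] <- data.frame(
        snp = ids, chrom = as.character(lay$chrom[b]),
        pos = lay$start[b] + (seq_len(spec$n_snps_per_block) - 1) * lay$spacing[b],
        block = b, freq = blk$freq, stringsAsFactors = FALSE
      )
    }
    panel <- structure(list(genotypes = do.call(cbind, geno),
                            snp_map = do.call(rbind, maps), spec = spec),
                       class = "ref_panel")
    if (!is.null(vcf_path)) write_panel_vcf(panel, vcf_path)
    panel
  })
}

#' Write a reference panel as an uncompressed VCF v4.2 file
#'
#' Emits one diploid sample per panel subject with unphased GT fields
#' (`0/0`, `0/1`, `1/1`); alleles are coded REF=A, ALT=G. Output is
#' byte-identical for identical panels.
#'
#' @param panel a `ref_panel` from [gen_reference_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "ref_panel"))
  G <- panel$genotypes
  map <- panel$snp_map
  samples <- sprintf("S%04d", seq_len(nrow(G)))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mirwin-synthetic-panel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(map)), function(i) {
    paste(c(map$chrom[i], map$pos[i], map$snp[i], "A", "G", ".", "PASS", ".",
            "GT", gt_code[G[, i] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate GWAS summary statistics over a reference panel
#'
#' Draws, independently for each LD block, one z-score vector from a
#' multivariate normal distribution whose correlation equals the block's
#' genotype-dosage correlation and whose mean is `noncentrality` at causal
#' SNPs and 0 elsewhere. This is exactly the null (and local-alternative)
#' model the set-based test assumes, so type-I-error calibration of the test
#' against this generator is sharp. Two-sided p-values are computed from the
#' normal tail; values that underflow to 0 are clamped to `1e-300` so the
#' chi-squared transform stays finite.
#'
#' @param panel a `ref_panel`.
#' @param signal a [signal_spec()]; defaults to the global null.
#' @param seed integer seed.
#' @return a data frame with columns `SNP`, `CHR`, `BP`, `Z`, `P` (one row per
#'   panel SNP).
#' @export
gen_summary_stats <- function(panel, signal = signal_spec(), seed = 1) {
  stopifnot(inherits(panel, "ref_panel"), inherits(signal, "signal_spec"))
  map <- panel$snp_map
  unknown <- setdiff(signal$causal_snp_ids, map$snp)
  if (length(unknown) > 0) {
    stop("causal SNP ids not in panel: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  with_seed(seed, {
    z <- numeric(nrow(map))
    for (b in unique(map$block)) {
      idx <- which(map$block == b)
      dos <- panel$genotypes[, idx, drop = FALSE]
      R <- stats::cor(dos)
      R <- tryCatch(ensure_psd(R), error = function(e) {
        stop("correlation matrix of block ", b, " could not be repaired: ",
             conditionMessage(e))
      })
      mu <- ifelse(map$snp[idx] %in% signal$causal_snp_ids, signal$noncentrality, 0)
      z[idx] <- drop(rmvn(1, R, mean = mu))
    }
    p <- 2 * stats::pnorm(-abs(z))
    p <- pmax(p, 1e-300)
    data.frame(SNP = map$snp, CHR = map$chrom, BP = map$pos, Z = z, P = p,
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic miRNA annotations over a panel
#'
#' Places miRNA hairpin-length transcripts (60-150 bp) at the positions of
#' randomly chosen panel SNPs, so that flanked test windows are covered by
#' panel SNPs. A configurable fraction of records is placed on chromosome "X"
#' to exercise the autosome filter. Optionally written as GFF3 with feature
#' type `miRNA` and a `Name=` attribute.
#'
#' @param n_mirnas number of annotation records (>= 1).
#' @param snp_map data frame with columns `snp`, `chrom`, `pos` (autosomal
#'   panel SNPs are used as anchor positions).
#' @param seed integer seed.
#' @param non_autosomal_fraction fraction (rounded to a count) of records
#'   placed on chromosome "X".
#' @param gff_path optional GFF3 output path.
#' @return data frame with columns `name`, `chrom`, `tx_start`, `tx_end`.
#' @export
gen_mirna_annotations <- function(n_mirnas, snp_map, seed = 1,
                                  non_autosomal_fraction = 0, gff_path = NULL) {
  if (n_mirnas < 1) stop("n_mirnas must be >= 1")
  if (non_autosomal_fraction < 0 || non_autosomal_fraction > 1) {
    stop("non_autosomal_fraction must lie in [0, 1]")
  }
  auto <- snp_map[norm_chrom(snp_map$chrom) %in% .autosomes, , drop = FALSE]
  if (nrow(auto) == 0) stop("snp_map contains no autosomal SNPs")
  n_x <- round(non_autosomal_fraction * n_mirnas)
  n_auto <- n_mirnas - n_x
  with_seed(seed, {
    len <- sample(60:150, n_mirnas, replace = TRUE)
    anchor <- auto[sample.int(nrow(auto), n_auto, replace = TRUE), , drop = FALSE]
    rec <- data.frame(
      name = sprintf("syn-mir-%03d", seq_len(n_mirnas)),
      chrom = c(anchor$chrom, rep("X", n_x)),
      tx_start = c(anchor$pos, 1e6 + seq_len(n_x) * 1e5),
      stringsAsFactors = FALSE
    )
    rec$tx_end <- rec$tx_start + len - 1
    if (!is.null(gff_path)) {
      lines <- c("##gff-version 3",
                 sprintf("%s\tmirwin-synthetic\tmiRNA\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                         rec$chrom, rec$tx_start, rec$tx_end, rec$name, rec$name))
      writeLines(lines, gff_path)
    }
    rec
  })
}

#' Generate synthetic Alda-scale phenotype records
#'
#' Per-subject symptom-improvement score A in `{0..10}` and five confounder
#' criteria B1-B5, each scored 0, 1 or 2, drawn independently from
#' configurable marginal distributions.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @param a_probs length-11 probability vector for A = 0..10; the default is
#'   mildly peaked at intermediate improvement.
#' @param b_probs length-3 probability vector for each B criterion = 0, 1, 2.
#' @param csv_path optional CSV output path (header
#'   `subject_id,A,B1,B2,B3,B4,B5`).
#' @return data frame with columns `subject_id`, `A`, `B1`..`B5`.
#' @export
gen_alda_scores <- function(n_subjects, seed = 1, a_probs = NULL, b_probs = NULL,
                            csv_path = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(a_probs)) a_probs <- stats::dbinom(0:10, 10, 0.55)
  if (is.null(b_probs)) b_probs <- c(0.5, 0.3, 0.2)
  if (length(a_probs) != 11 || length(b_probs) != 3) {
    stop("a_probs must have length 11 and b_probs length 3")
  }
  with_seed(seed, {
    df <- data.frame(subject_id = sprintf("P%05d", seq_len(n_subjects)),
                     A = sample(0:10, n_subjects, replace = TRUE, prob = a_probs),
                     stringsAsFactors = FALSE)
    for (k in 1:5) {
      df[[paste0("B", k)]] <- sample(0:2, n_subjects, replace = TRUE, prob = b_probs)
    }
    if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
    df
  })
}

#' Generate a synthetic cis-miR-eQTL SNP id list
#'
#' Samples a subset of panel SNP ids of size `round(fraction * n_snps)`.
#' With `bias > 1` and a set of miRNA windows, SNPs inside windows are
#' `bias`-fold more likely to be sampled, creating true enrichment for power
#' tests; `bias = 1` gives a uniform (null) list.
#'
#' @param snp_map data frame with columns `snp`, `chrom`, `pos`.
#' @param fraction sampling fraction in `(0, 1]`.
#' @param seed integer seed.
#' @param windows optional data frame of expanded windows (see
#'   [expand_window()]) toward which sampling is biased.
#' @param bias sampling-weight multiplier (>= 1) for SNPs inside `windows`.
#' @param path optional output path (one SNP id per line).
#' @return character vector of SNP ids.
#' @export
gen_eqtl_list <- function(snp_map, fraction, seed = 1, windows = NULL, bias = 1,
                          path = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (bias < 1) stop("bias must be >= 1")
  n <- round(fraction * nrow(snp_map))
  w <- rep(1, nrow(snp_map))
  if (!is.null(windows) && bias > 1) {
    chrom <- norm_chrom(snp_map$chrom)
    inside <- rep(FALSE, nrow(snp_map))
    for (i in seq_len(nrow(windows))) {
      inside <- inside | (chrom == norm_chrom(windows$chrom[i]) &
                          snp_map$pos >= windows$win_start[i] &
                          snp_map$pos <= windows$win_end[i])
    }
    w[inside] <- bias
  }
  with_seed(seed, {
    ids <- if (n == nrow(snp_map)) snp_map$snp else {
      snp_map$snp[sample.int(nrow(snp_map), n, prob = w)]
    }
    ids <- sort(ids)
    if (!is.null(path)) writeLines(ids, path)
    ids
  })
}
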