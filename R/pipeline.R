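#' Build a pipeline run configuration
#'
#' Collects all inputs and tuning parameters of an end-to-end run. Inputs may
#' be file paths (TSV summary statistics with columns `SNP`, `CHR`, `BP`,
#' `P`; GFF3/BED annotations; VCF panel; one-id-per-line eQTL list) or
#' in-memory objects of the corresponding shapes. In `"synthetic-demo"` mode
#' every input is generated internally from the seed.
#'
#' @param sumstats_dichotomous,sumstats_continuous path or data frame; either
#'   may be `NULL`.
#' @param annotations path (GFF3/BED) or data frame with `name`, `chrom`,
#'   `tx_start`, `tx_end`.
#' @param panel path to a VCF or a `ref_panel` object.
#' @param eqtl path, character vector of SNP ids, or `NULL` to skip the eQTL
#'   enrichment test.
#' @param out_dir output directory for TSV/JSON reports, or `NULL` to return
#'   results only.
#' @param mode `"genomewide"`, `"candidate"` (restrict to `candidates`), or
#'   `"synthetic-demo"`.
#' @param candidates character vector of miRNA names (candidate mode).
#' @param annotation_format `"gff3"` or `"bed"` when `annotations` is a path.
#' @param flank_bp window flank in bp (default 20000).
#' @param alpha nominal significance threshold for enrichment (default 0.05).
#' @param maf_min panel MAF threshold for the LD matrix (default 0.01).
#' @param top_fraction,sim_stages,selection,k_rounding see [set_test_config()].
#' @param seed master seed.
#' @param demo list of synthetic-demo knobs: `n_mirnas`, `n_haplotypes`,
#'   `n_snps_per_block`, `n_blocks`, `block_rho`, `signal_fraction`,
#'   `noncentrality`, `eqtl_fraction`, `eqtl_bias`,
#'   `non_autosomal_fraction`. Defaults give a small but LD-realistic run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sumstats_dichotomous = NULL, sumstats_continuous = NULL,
                       annotations = NULL, panel = NULL, eqtl = NULL,
                       out_dir = NULL,
                       mode = c("genomewide", "candidate", "synthetic-demo"),
                       candidates = NULL, annotation_format = "gff3",
                       flank_bp = 20000, alpha = 0.05, maf_min = 0.01,
                       top_fraction = 0.1, sim_stages = c(1e3, 1e4, 1e5, 1e6),
                       selection = "per_replicate", k_rounding = "ceiling",
                       seed = 1, demo = list()) {
  mode <- match.arg(mode)
  if (mode == "candidate" && (is.null(candidates) || length(candidates) == 0)) {
    stop("candidate mode requires a non-empty candidates vector")
  }
  if (mode != "synthetic-demo") {
    if (is.null(annotations)) stop("annotations are required outside synthetic-demo mode")
    if (is.null(panel)) stop("a reference panel is required outside synthetic-demo mode")
    if (is.null(sumstats_dichotomous) && is.null(sumstats_continuous)) {
      stop("at least one summary-statistics input is required")
    }
    for (p in Filter(is.character, list(annotations, panel, eqtl,
                                        sumstats_dichotomous, sumstats_continuous))) {
      if (length(p) == 1 && !file.exists(p) && !is.null(p)) {
        # character eqtl input may be an id vector, not a path
        if (!identical(p, eqtl)) stop("input path does not exist: ", p)
      }
    }
  }
  demo_defaults <- list(n_mirnas = 40, n_haplotypes = 1000, n_snps_per_block = 25,
                        n_blocks = 30, block_rho = 0.7, signal_fraction = 0,
                        noncentrality = 0, eqtl_fraction = 0.1, eqtl_bias = 1,
                        non_autosomal_fraction = 0.1)
  demo <- utils::modifyList(demo_defaults, demo)
  structure(list(sumstats_dichotomous = sumstats_dichotomous,
                 sumstats_continuous = sumstats_continuous,
                 annotations = annotations, panel = panel, eqtl = eqtl,
                 out_dir = out_dir, mode = mode, candidates = candidates,
                 annotation_format = annotation_format, flank_bp = flank_bp,
                 alpha = alpha, maf_min = maf_min,
                 test_config = set_test_config(top_fraction, sim_stages, seed,
                                               selection, k_rounding),
                 seed = as.integer(seed), demo = demo),
            class = "run_config")
}

.read_sumstats <- function(x) {
  if (is.data.frame(x)) return(x)
  df <- utils::read.delim(x, stringsAsFactors = FALSE)
  req <- c("SNP", "CHR", "BP", "P")
  if (!all(req %in% names(df))) {
    stop("summary statistics file ", x, " needs columns: ", paste(req, collapse = ", "))
  }
  df
}

.demo_inputs <- function(config) {
  d <- config$demo
  spec <- panel_spec(n_haplotypes = d$n_haplotypes,
                     n_snps_per_block = d$n_snps_per_block,
                     n_blocks = d$n_blocks, block_rho = d$block_rho,
                     seed = hash_seed(config$seed, "panel"))
  panel <- gen_reference_panel(spec)
  ann <- gen_mirna_annotations(d$n_mirnas, panel$snp_map,
                               seed = hash_seed(config$seed, "annotations"),
                               non_autosomal_fraction = d$non_autosomal_fraction)
  signal <- signal_spec()
  signal_names <- character(0)
  if (d$signal_fraction > 0 && d$noncentrality > 0) {
    auto <- which(norm_chrom(ann$chrom) %in% .autosomes)
    n_sig <- max(1, round(d$signal_fraction * length(auto)))
    pick <- with_seed(hash_seed(config$seed, "signal"),
                      sample(auto, n_sig))
    signal_names <- ann$name[pick]
    causal <- vapply(pick, function(i) {
      on_chrom <- panel$snp_map$chrom == ann$chrom[i]
      j <- which.min(abs(panel$snp_map$pos - ann$tx_start[i]) + ifelse(on_chrom, 0, Inf))
      panel$snp_map$snp[j]
    }, character(1))
    signal <- signal_spec(unique(causal), d$noncentrality)
  }
  ss_dich <- gen_summary_stats(panel, signal, seed = hash_seed(config$seed, "sumstats-dich"))
  ss_cont <- gen_summary_stats(panel, signal, seed = hash_seed(config$seed, "sumstats-cont"))
  windows <- expand_window(ann[norm_chrom(ann$chrom) %in% .autosomes, , drop = FALSE],
                           config$flank_bp)
  eqtl <- gen_eqtl_list(panel$snp_map, d$eqtl_fraction,
                        seed = hash_seed(config$seed, "eqtl"),
                        windows = windows, bias = d$eqtl_bias)
  list(panel = panel, annotations = ann,
       sumstats = list(dichotomous = ss_dich, continuous = ss_cont),
       eqtl = eqtl, signal_names = signal_names)
}

#' Run the full window-based miRNA association pipeline
#'
#' Loads annotations, removes non-autosomal miRNAs, expands the remaining
#' transcripts by the configured flank, and, for each phenotype's summary
#' statistics: assigns SNPs to windows, estimates each covered window's LD
#' correlation from the reference panel (PSD-repaired), runs the
#' top-fraction set test with staged multivariate-normal simulation, and
#' applies Benjamini-Hochberg correction across the tested miRNAs. Both
#' enrichment tests (miRNA windows, cis-miR-eQTL list) are run per phenotype.
#' Fully deterministic for a fixed master seed, independently of window
#' processing order.
#'
#' @param config a [run_config()].
#' @return list with `results` (per-phenotype data frames, sorted by
#'   ascending miRNA p-value), `enrichment` (per phenotype: `window` and
#'   optionally `eqtl`), `counts` (per phenotype: `n_input`,
#'   `n_non_autosomal`, `n_not_covered`, `n_tested`), `log` (character
#'   vector), and in synthetic-demo mode `signal_names` (miRNAs with
#'   injected signal). Reports are written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  signal_names <- character(0)
  if (config$mode == "synthetic-demo") {
    demo <- .demo_inputs(config)
    ann <- demo$annotations
    panel <- demo$panel
    sumstats <- demo$sumstats
    eqtl <- demo$eqtl
    signal_names <- demo$signal_names
    say("synthetic-demo inputs: %d miRNAs, %d panel SNPs, %d subjects",
        nrow(ann), nrow(panel$snp_map), nrow(panel$genotypes))
  } else {
    ann <- if (is.data.frame(config$annotations)) config$annotations else {
      load_mirna_annotations(config$annotations, config$annotation_format)
    }
    panel <- if (inherits(config$panel, "ref_panel")) config$panel else {
      read_panel_vcf(config$panel)
    }
    sumstats <- list()
    if (!is.null(config$sumstats_dichotomous)) {
      sumstats$dichotomous <- .read_sumstats(config$sumstats_dichotomous)
    }
    if (!is.null(config$sumstats_continuous)) {
      sumstats$continuous <- .read_sumstats(config$sumstats_continuous)
    }
    eqtl <- config$eqtl
    if (is.character(eqtl) && length(eqtl) == 1 && file.exists(eqtl)) {
      eqtl <- readLines(eqtl, warn = FALSE)
    }
  }

  if (config$mode == "candidate") {
    missing <- setdiff(config$candidates, ann$name)
    if (length(missing) > 0) {
      say("candidate miRNAs absent from annotations: %s", paste(missing, collapse = ", "))
    }
    ann <- ann[ann$name %in% config$candidates, , drop = FALSE]
  }
  n_input <- nrow(ann)
  flt <- filter_autosomal(ann)
  say("annotations: %d input, %d non-autosomal removed", n_input, flt$n_removed)
  windows <- expand_window(flt$records, config$flank_bp)

  results <- list()
  enrichment <- list()
  counts <- list()
  for (phen in names(sumstats)) {
    ss <- sumstats[[phen]]
    asg <- assign_snps(windows, ss)
    rows <- list()
    n_untestable <- 0
    for (set in asg$sets) {
      if (!set$covered) next
      geno <- load_genotypes(panel, set$snp_ids, region = set$window,
                             summary_stats = ss)
      if (ncol(geno$dosage) == 0) {
        n_untestable <- n_untestable + 1
        say("window %s: no panel SNPs, excluded", set$window$name)
        next
      }
      ld <- withCallingHandlers(
        tryCatch(ld_correlation(geno$dosage, config$maf_min, geno$n_dropped),
                 error = function(e) NULL),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (is.null(ld)) {
        n_untestable <- n_untestable + 1
        say("window %s: all SNPs monomorphic/low-MAF, excluded", set$window$name)
        next
      }
      ld <- ensure_psd(ld)
      res <- test_window(set, ss, ld, config$test_config)
      if (res$untestable) {
        n_untestable <- n_untestable + 1
        next
      }
      w <- set$window
      rows[[length(rows) + 1]] <- data.frame(
        mirna = res$mirna_name,
        position = sprintf("chr%s:%d-%d", w$chrom, as.integer(w$tx_start),
                           as.integer(w$tx_end)),
        n_snps = res$n_snps_tested,
        n_dropped = ld$n_dropped,
        p_mirna = res$empirical_p,
        top_snp = res$top_snp_id,
        top_snp_position = sprintf("chr%s:%d", ss$CHR[match(res$top_snp_id, ss$SNP)],
                                   as.integer(ss$BP[match(res$top_snp_id, ss$SNP)])),
        p_top_snp = res$top_snp_p,
        n_sims = res$n_sims_used,
        stringsAsFactors = FALSE
      )
    }
    tab <- if (length(rows) > 0) do.call(rbind, rows) else {
      data.frame(mirna = character(), position = character(), n_snps = integer(),
                 n_dropped = integer(), p_mirna = numeric(), top_snp = character(),
                 top_snp_position = character(), p_top_snp = numeric(),
                 n_sims = numeric(), stringsAsFactors = FALSE)
    }
    if (nrow(tab) > 0) {
      tab$p_corr_mirna <- bh_adjust(tab$p_mirna)
      tab <- tab[order(tab$p_mirna, tab$mirna), , drop = FALSE]
      rownames(tab) <- NULL
    } else {
      tab$p_corr_mirna <- numeric(0)
    }
    results[[phen]] <- tab
    n_not_covered <- (length(asg$sets) - asg$n_covered) + n_untestable
    counts[[phen]] <- list(n_input = n_input, n_non_autosomal = flt$n_removed,
                           n_not_covered = n_not_covered, n_tested = nrow(tab))
    say("%s: %d tested, %d not covered, nominal hits (p<%g): %d",
        phen, nrow(tab), n_not_covered, config$alpha,
        sum(tab$p_mirna < config$alpha))

    enr <- list(window = window_enrichment(ss, asg$sets, config$alpha))
    if (!is.null(eqtl)) enr$eqtl <- eqtl_enrichment(ss, eqtl, config$alpha)
    enrichment[[phen]] <- enr
  }

  out <- list(results = results, enrichment = enrichment, counts = counts,
              log = log, seed = config$seed)
  if (config$mode == "synthetic-demo") out$signal_names <- signal_names
  if (!is.null(config$out_dir)) {
    report_tables(out, config$out_dir, alpha = config$alpha)
  }
  out
}

#' Write pipeline result tables and run metadata
#'
#' One TSV per phenotype (rows sorted by ascending miRNA p-value, p-values in
#' three-significant-digit scientific notation such as `1.71E-02`), an
#' enrichment report TSV, the run log, and a JSON metadata file with seeds
#' and counts.
#'
#' @param out pipeline output from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param alpha nominal threshold recorded in the enrichment report.
#' @return `out_dir`, invisibly.
#' @export
report_tables <- function(out, out_dir, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (phen in names(out$results)) {
    tab <- out$results[[phen]]
    disp <- data.frame(miRNA = tab$mirna, position = tab$position,
                       n_SNPs = tab$n_snps,
                       p_miRNA = format_pval(tab$p_mirna),
                       p_corr_miRNA = format_pval(tab$p_corr_mirna),
                       top_SNP = tab$top_snp,
                       top_SNP_position = tab$top_snp_position,
                       p_top_SNP = format_pval(tab$p_top_snp),
                       stringsAsFactors = FALSE)
    if (nrow(disp) == 0) warning("no tested miRNAs for phenotype ", phen)
    utils::write.table(disp, file.path(out_dir, paste0("results_", phen, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  enr_rows <- list()
  for (phen in names(out$enrichment)) {
    for (test in names(out$enrichment[[phen]])) {
      e <- out$enrichment[[phen]][[test]]
      enr_rows[[length(enr_rows) + 1]] <- data.frame(
        phenotype = phen, test = test,
        a = e$table[1, 1], b = e$table[1, 2], c = e$table[2, 1], d = e$table[2, 2],
        odds_ratio = sprintf("%.4f", e$odds_ratio),
        p_one_sided = format_pval(e$p), alpha = alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(enr_rows) > 0) {
    utils::write.table(do.call(rbind, enr_rows), file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(out$log, file.path(out_dir, "run_log.txt"))
  meta <- list(seed = out$seed, counts = out$counts,
               package_version = as.character(utils::packageVersion("mirwin")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
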