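#' Benjamini-Hochberg adjustment of the per-miRNA empirical p-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, `q_(i) = min over j >= i of (m * p_(j) / j)` capped at 1,
#' returned in the input order. Applied separately within each scan (each
#' phenotype's genome-wide table, and the candidate table), so each reported
#' `p_corr` column has its own correction context.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

.as_table2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2, 2))) stop("table must be 2x2")
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cnt <- c(a, b, c, d)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("table counts must be non-negative integers")
  }
  c(a = a, b = b, c = c, d = d)
}

#' One-sided (greater) Fisher exact p-value for a 2x2 table
#'
#' The probability, under fixed margins, of a count in cell `a` at least as
#' large as observed: the hypergeometric upper tail
#' `sum over x >= a of P(X = x)`. Rows index category membership (miRNA
#' window / eQTL list), columns nominal significance.
#'
#' @param a,b,c,d cell counts, or a 2x2 matrix as first argument.
#' @return one-sided p-value.
#' @export
fisher_exact_greater <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .as_table2x2(a, b, c, d)
  stats::phyper(t["a"] - 1, m = t["a"] + t["b"], n = t["c"] + t["d"],
                k = t["a"] + t["c"], lower.tail = FALSE)[[1]]
}

.enrichment <- function(in_category, significant, what) {
  a <- sum(in_category & significant)
  b <- sum(in_category & !significant)
  c <- sum(!in_category & significant)
  d <- sum(!in_category & !significant)
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(category = c("yes", "no"),
                                significant = c("yes", "no")))
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  if (degenerate) {
    warning("degenerate 2x2 table for ", what, " enrichment; p set to 1")
    p <- 1
  } else {
    p <- fisher_exact_greater(a, b, c, d)
  }
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) # continuity, display only
  }
  list(table = tab, p = p, odds_ratio = or,
       n_significant_in_category = a)
}

#' Enrichment of nominally significant SNPs in miRNA windows
#'
#' Tests whether SNPs with `p < alpha` are over-represented inside miRNA
#' windows, via a one-sided Fisher exact test on the 2x2 table of window
#' membership against nominal significance. Each SNP is counted once even
#' when it falls in several overlapping windows.
#'
#' @param summary_stats data frame with columns `SNP`, `P`.
#' @param window_snp_sets the `sets` element of [assign_snps()].
#' @param alpha nominal significance threshold (default 0.05).
#' @return list with `table` (2x2), `p`, `odds_ratio` and
#'   `n_significant_in_category` (significant SNPs inside windows).
#' @export
window_enrichment <- function(summary_stats, window_snp_sets, alpha = 0.05) {
  in_window_ids <- unique(unlist(lapply(window_snp_sets, `[[`, "snp_ids")))
  .enrichment(summary_stats$SNP %in% in_window_ids,
              summary_stats$P < alpha, "miRNA-window")
}

#' Enrichment of cis-miR-eQTL SNPs among nominally significant SNPs
#'
#' Tests whether SNPs from an externally supplied cis-miR-eQTL list are
#' over-represented among SNPs with `p < alpha`, via a one-sided Fisher
#' exact test. An eQTL list with no overlap with the summary statistics is an
#' error — it signals an id-space mismatch, not a null result.
#'
#' @param summary_stats data frame with columns `SNP`, `P`.
#' @param eqtl_snp_ids character vector of eQTL SNP ids.
#' @param alpha nominal significance threshold (default 0.05).
#' @return list as for [window_enrichment()].
#' @export
eqtl_enrichment <- function(summary_stats, eqtl_snp_ids, alpha = 0.05) {
  present <- intersect(eqtl_snp_ids, summary_stats$SNP)
  if (length(present) == 0) {
    stop("no eQTL SNP id overlaps the summary statistics (id-space mismatch?)")
  }
  .enrichment(summary_stats$SNP %in% present,
              summary_stats$P < alpha, "eQTL")
}
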