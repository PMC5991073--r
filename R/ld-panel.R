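#' Read a VCF genotype panel into dosage form
#'
#' Parses a VCF (v4.x, plain or bgzipped) and converts GT fields to dosage of
#' the alternate allele in `{0, 1, 2}`. Missing genotypes are mean-imputed per
#' SNP, matching standard LD-reference practice. Multi-allelic records are
#' rejected.
#'
#' @param vcf_path path to the VCF file.
#' @return an object of class `ref_panel` (see [gen_reference_panel()]) with
#'   `genotypes` (subjects x SNPs numeric matrix) and `snp_map`.
#' @export
read_panel_vcf <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("unreadable VCF: ", vcf_path)
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e) stop("unreadable VCF '", vcf_path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multi-allelic records are not supported: ", vcf_path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = SNPs, cols = samples; count ALT alleles, any separator
  alt_count <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x),
           NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, alt_count)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  dos <- t(dos) # subjects x SNPs
  for (j in seq_len(ncol(dos))) {
    miss <- is.na(dos[, j])
    if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
  }
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  colnames(dos) <- ids
  structure(list(genotypes = dos,
                 snp_map = data.frame(snp = ids,
                                      chrom = norm_chrom(fix[, "CHROM"]),
                                      pos = as.integer(fix[, "POS"]),
                                      stringsAsFactors = FALSE),
                 spec = NULL),
            class = "ref_panel")
}

#' Extract window dosages from a reference panel
#'
#' Looks up the requested SNPs in the panel, first by id and then by
#' chromosome:position for ids absent from the panel. SNPs found nowhere are
#' dropped and counted; the returned column order follows `snp_ids` with
#' dropped SNPs removed.
#'
#' @param panel a `ref_panel` (from [gen_reference_panel()] or
#'   [read_panel_vcf()]).
#' @param snp_ids SNP ids to extract.
#' @param region optional list/data frame row with `chrom`, `win_start`,
#'   `win_end`; when given, panel lookup is restricted to that interval
#'   (position fallback uses it too).
#' @param summary_stats optional data frame with `SNP`, `CHR`, `BP` used for
#'   the chromosome+position fallback when an id is missing from the panel.
#' @return list with `dosage` (subjects x SNPs matrix, possibly 0 columns),
#'   `n_dropped` and `dropped_ids`.
#' @export
load_genotypes <- function(panel, snp_ids, region = NULL, summary_stats = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  map <- panel$snp_map
  pool <- seq_len(nrow(map))
  if (!is.null(region)) {
    pool <- which(map$chrom == norm_chrom(region$chrom) &
                  map$pos >= region$win_start & map$pos <= region$win_end)
  }
  idx <- match(snp_ids, map$snp[pool])
  col <- ifelse(is.na(idx), NA_integer_, pool[idx])
  if (anyNA(col) && !is.null(summary_stats)) {
    ss <- summary_stats[match(snp_ids, summary_stats$SNP), , drop = FALSE]
    key_panel <- paste(map$chrom[pool], map$pos[pool])
    key_want <- paste(norm_chrom(ss$CHR), ss$BP)
    fb <- match(key_want, key_panel)
    miss <- is.na(col)
    col[miss] <- ifelse(is.na(fb[miss]), NA_integer_, pool[fb[miss]])
  }
  found <- !is.na(col)
  if (!any(found)) {
    warning("none of the requested SNPs were found in the panel")
  }
  list(dosage = panel$genotypes[, col[found], drop = FALSE],
       n_dropped = sum(!found),
       dropped_ids = snp_ids[!found])
}

#' Pairwise LD correlation of dosage columns
#'
#' Pearson correlation of genotype dosages across panel subjects, the LD
#' measure used as the covariance of the simulated null. Columns that are
#' monomorphic or below the minor-allele-frequency threshold are dropped with
#' a warning (their correlations are undefined or unstable) and counted in
#' `n_dropped`.
#'
#' @param dosage subjects x SNPs numeric matrix with column names.
#' @param maf_min minimum panel MAF (on the dosage scale) for a SNP to enter
#'   the LD matrix; default 0.01. Set to 0 to drop only monomorphic SNPs.
#' @param n_dropped_prior count of SNPs already dropped upstream (carried
#'   through so per-window accounting stays complete).
#' @return an object of class `ld_matrix`: list with `snp_ids`, `R`
#'   (correlation matrix with unit diagonal) and `n_dropped`.
#' @export
ld_correlation <- function(dosage, maf_min = 0.01, n_dropped_prior = 0L) {
  if (nrow(dosage) < 2) stop("need >= 2 subjects to estimate LD")
  if (ncol(dosage) == 0) stop("no SNP columns in dosage matrix")
  f <- colMeans(dosage) / 2
  maf <- pmin(f, 1 - f)
  v <- apply(dosage, 2, stats::var)
  keep <- v > 0 & maf >= maf_min
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic/low-MAF SNP(s) dropped from LD matrix: ",
            paste(utils::head(colnames(dosage)[!keep], 5), collapse = ", "))
  }
  if (!any(keep)) stop("all SNPs in the window are monomorphic or below maf_min")
  R <- stats::cor(dosage[, keep, drop = FALSE])
  diag(R) <- 1
  structure(list(snp_ids = colnames(dosage)[keep], R = R,
                 n_dropped = n_dropped_prior + sum(!keep)),
            class = "ld_matrix")
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Estimated LD matrices can have slightly negative eigenvalues (finite
#' panels, mean imputation, rounding); multivariate-normal sampling requires
#' a PSD covariance. Eigenvalues below `tol` are clipped to `tol`, the matrix
#' is reassembled and rescaled to unit diagonal. A matrix that is already PSD
#' is returned unchanged. A repair that moves any entry by more than 0.1 is
#' refused — that signals a panel too small or inconsistent for the window
#' rather than numerical noise.
#'
#' @param R a correlation matrix or an `ld_matrix`.
#' @param tol eigenvalue floor (default 1e-8).
#' @return the repaired object, same type as the input.
#' @export
ensure_psd <- function(R, tol = 1e-8) {
  obj <- NULL
  if (inherits(R, "ld_matrix")) {
    obj <- R
    R <- R$R
  }
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("R must be a square matrix")
  if (max(abs(R - t(R))) > 1e-10) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-6) stop("R must have unit diagonal")
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) {
    out <- R
  } else {
    vals <- pmax(e$values, tol)
    out <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
    out <- (out + t(out)) / 2
    diag(out) <- 1
    delta <- max(abs(out - R))
    if (delta > 0.1) {
      stop(sprintf("PSD repair would change an entry by %.3f (> 0.1); panel too small or inconsistent", delta))
    }
    dimnames(out) <- dimnames(R)
  }
  if (!is.null(obj)) {
    obj$R <- out
    return(obj)
  }
  out
}
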