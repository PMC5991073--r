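#' @useDynLib mirwin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Normalise chromosome labels
#'
#' Strips an optional "chr" prefix and upper-cases the remainder, so that
#' "chr20", "20" and "Chr20" all map to "20" and "chrM"/"MT" both map to a
#' mitochondrial label. Annotation files, summary statistics and reference
#' panels frequently disagree on the prefix; all internal comparisons use the
#' normalised form.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalised labels.
#' @export
norm_chrom <- function(x) {
  x <- toupper(sub("^chr", "", as.character(x), ignore.case = TRUE))
  x[x == "M"] <- "MT"
  x
}

.autosomes <- as.character(1:22)
.known_chroms <- c(.autosomes, "X", "Y", "MT")

#' Derive a reproducible integer seed from a master seed and a label
#'
#' Each analysis window gets its own random-number stream so that results do
#' not depend on the order in which windows are processed. The stream seed is
#' a deterministic hash of the master seed and the window label.
#'
#' @param master_seed integer master seed.
#' @param label character scalar (e.g. a miRNA name).
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
hash_seed <- function(master_seed, label) {
  mod <- 2147483629 # largest prime below 2^31; keeps arithmetic exact in doubles
  h <- 0
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% mod
  s <- ((master_seed %% mod) * 48271 + h) %% mod
  as.integer(s + 1)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

#' Format a p-value in the scientific style used in the result tables
#'
#' Three significant digits in upper-case scientific notation, e.g.
#' `0.0171` becomes `"1.71E-02"`.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pval <- function(p) {
  out <- sprintf("%.2E", p)
  out[is.na(p)] <- NA_character_
  out
}

# Lower-triangular-like factor L with L %*% t(L) == R, for MVN sampling.
# Cholesky when R is strictly positive definite, otherwise an eigen factor
# (valid for the positive semidefinite matrices produced by ensure_psd()).
mvn_factor <- function(R) {
  L <- tryCatch(t(chol(R)), error = function(e) NULL)
  if (is.null(L)) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-8) {
      stop("correlation matrix is not positive semidefinite; run ensure_psd() first")
    }
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
  }
  L
}

#' Draw correlated z-score vectors
#'
#' Samples `n` vectors from a multivariate normal with correlation `R` and
#' mean `mean` — the model behind both the synthetic summary-statistic
#' generator (z-scores of LD-correlated SNPs, shifted at causal SNPs) and
#' the set test's simulated null.
#'
#' @param n number of draws.
#' @param R correlation matrix (positive semidefinite).
#' @param mean scalar or length-`nrow(R)` mean vector (noncentrality).
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return an `n` x `nrow(R)` matrix of draws.
#' @export
rmvn <- function(n, R, mean = 0, seed = NULL) {
  m <- nrow(R)
  L <- mvn_factor(R)
  draw <- function() t(L %*% matrix(stats::rnorm(m * n), m, n) + mean)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
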