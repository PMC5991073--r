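# First-order autoregressive correlation matrix, the LD structure used by
# the synthetic panels.
ar1_cor <- function(m, rho) {
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  dimnames(R) <- list(paste0("s", seq_len(m)), paste0("s", seq_len(m)))
  R
}

# Minimal summary-statistics table on one chromosome.
make_sumstats <- function(p, chrom = "1", start_bp = 1000, spacing = 100,
                          ids = NULL) {
  m <- length(p)
  if (is.null(ids)) ids <- paste0("s", seq_len(m))
  data.frame(SNP = ids, CHR = chrom, BP = start_bp + (seq_len(m) - 1) * spacing,
             P = p, stringsAsFactors = FALSE)
}

# A random correlation matrix (positive definite) of dimension m.
random_corr <- function(m, df = m + 2) {
  A <- matrix(stats::rnorm(m * df), df, m)
  R <- stats::cov2cor(crossprod(A))
  dimnames(R) <- list(paste0("s", seq_len(m)), paste0("s", seq_len(m)))
  R
}

# Brute-force Benjamini-Hochberg step-up adjustment, straight from the
# definition; independent oracle for bh_adjust().
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# Write a tiny miRBase-style GFF3 file; records = data.frame(chrom, start,
# end, name, type).
write_gff3 <- function(records, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\t.\t%s\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                     records$chrom, records$type, records$start, records$end,
                     records$name, records$name))
  writeLines(lines, path)
  path
}
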