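#' Configuration of the top-fraction set test
#'
#' @param top_fraction fraction `f` of a window's SNPs entering the statistic
#'   (default 0.1, the "top-0.1" test).
#' @param sim_stages strictly increasing simulation counts; the test starts at
#'   the first stage and escalates while the empirical p-value is within
#'   `10 / nsim` of zero, so small p-values get the precision they need
#'   without paying the largest stage for every window.
#' @param seed master seed; each window derives its own stream from
#'   `(seed, window name)` so results do not depend on processing order.
#' @param selection `"per_replicate"` (the corrected test: the top `k` SNPs
#'   are re-selected within every simulated replicate, matching the
#'   data-driven selection of the observed statistic) or `"fixed_index"`
#'   (selection fixed at the observed top SNPs' indices in every replicate;
#'   anti-conservative under LD, retained only as a regression contrast).
#' @param k_rounding `"ceiling"` (default; `k = max(1, ceiling(f * m))`) or
#'   `"floor"` (`k = max(1, floor(f * m))`) for sensitivity analysis.
#' @return an object of class `set_test_config`.
#' @export
set_test_config <- function(top_fraction = 0.1,
                            sim_stages = c(1e3, 1e4, 1e5, 1e6),
                            seed = 1,
                            selection = c("per_replicate", "fixed_index"),
                            k_rounding = c("ceiling", "floor")) {
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must lie in (0, 1]")
  if (length(sim_stages) < 1 || any(diff(sim_stages) <= 0)) {
    stop("sim_stages must be a strictly increasing vector of simulation counts")
  }
  structure(list(top_fraction = top_fraction, sim_stages = as.numeric(sim_stages),
                 seed = as.integer(seed), selection = match.arg(selection),
                 k_rounding = match.arg(k_rounding)),
            class = "set_test_config")
}

#' Convert an association p-value to a 1-df chi-squared statistic
#'
#' Returns the value whose upper-tail probability under the chi-squared
#' distribution with one degree of freedom equals `p` — the quantile
#' transform that turns per-SNP p-values into summable evidence (small p,
#' large statistic). P-values of exactly 0 must be clamped upstream (the
#' summary-statistic generators use 1e-300).
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return numeric vector of chi-squared(1) statistics.
#' @export
p_to_chisq <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Top-fraction sum statistic
#'
#' Sums the `k` largest chi-squared values of a window, where
#' `k = max(1, ceiling(f * m))` for `m` values (at least one SNP always
#' enters, so small windows remain testable).
#'
#' @param chisq_values non-empty numeric vector of per-SNP chi-squared(1)
#'   statistics.
#' @param f top fraction in `(0, 1]`.
#' @param k_rounding `"ceiling"` or `"floor"` (see [set_test_config()]).
#' @return list with `k` (number of SNPs summed) and `stat`.
#' @export
top_fraction_stat <- function(chisq_values, f = 0.1, k_rounding = "ceiling") {
  m <- length(chisq_values)
  if (m == 0) stop("chisq_values must be non-empty")
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  k <- .top_k(m, f, k_rounding)
  list(k = k, stat = sum(sort(chisq_values, decreasing = TRUE)[seq_len(k)]))
}

.top_k <- function(m, f, k_rounding = "ceiling") {
  k <- if (identical(k_rounding, "floor")) floor(f * m) else ceiling(f * m)
  max(1L, as.integer(k))
}

#' Simulate null top-fraction statistics under LD
#'
#' Each replicate draws a z-vector from MVN(0, R), squares it componentwise
#' into chi-squared(1) values, and applies the top-fraction sum with the same
#' `f` as the observed statistic — re-selecting the top `k` values within
#' every replicate, so the null distribution reflects the data-driven
#' selection. With `fixed_indices` supplied, every replicate instead sums
#' those fixed components (the uncorrected variant kept for regression
#' contrast only).
#'
#' @param R correlation matrix (or `ld_matrix`), positive semidefinite; run
#'   [ensure_psd()] first on estimated LD.
#' @param f top fraction in `(0, 1]`.
#' @param nsim number of replicates.
#' @param seed integer seed; fixed seed gives identical output.
#' @param k_rounding `"ceiling"` or `"floor"`.
#' @param fixed_indices optional integer vector of component indices to sum
#'   in every replicate instead of per-replicate re-selection.
#' @return numeric vector of `nsim` simulated statistics.
#' @export
simulate_null_stats <- function(R, f = 0.1, nsim = 1000, seed = 1,
                                k_rounding = "ceiling", fixed_indices = NULL) {
  if (inherits(R, "ld_matrix")) R <- R$R
  m <- nrow(R)
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("R is not positive semidefinite (min eigenvalue ", format(min(ev)),
         "); run ensure_psd() before simulating")
  }
  L <- mvn_factor(R)
  with_seed(seed, {
    Z <- L %*% matrix(stats::rnorm(m * nsim), m, nsim)
    X <- Z * Z
    if (!is.null(fixed_indices)) {
      colSums(X[fixed_indices, , drop = FALSE])
    } else {
      k <- .top_k(m, f, k_rounding)
      if (k == m) colSums(X) else top_k_col_sums(X, k)
    }
  })
}

#' Monte-Carlo empirical p-value
#'
#' Add-one estimator `p = (1 + b) / (1 + nsim)` where `b` counts simulated
#' statistics at least as large as the observed one. Ties count against the
#' observed statistic (conservative) and the estimator never returns 0; with
#' `nsim` simulations the smallest attainable p-value is `1 / (1 + nsim)`.
#'
#' @param observed_stat observed statistic.
#' @param simulated_stats numeric vector of null statistics.
#' @return empirical p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed_stat, simulated_stats) {
  nsim <- length(simulated_stats)
  if (nsim < 1) stop("need at least one simulated statistic")
  (1 + sum(simulated_stats >= observed_stat)) / (1 + nsim)
}

#' Run the set-based test for one miRNA window
#'
#' Transforms the window's SNP p-values to chi-squared(1) statistics, forms
#' the top-fraction sum, and compares it with statistics simulated from
#' MVN(0, R). Simulation counts escalate through `config$sim_stages` while
#' the empirical p-value is within `10 / nsim` of zero. The reported top SNP
#' is the tested SNP with the smallest p-value (ties broken by position, then
#' id).
#'
#' @param snp_set one element of `assign_snps()$sets` (list with `window` and
#'   `snp_ids`), or a character vector of SNP ids.
#' @param summary_stats data frame with columns `SNP`, `CHR`, `BP`, `P`.
#' @param R an `ld_matrix` (or bare correlation matrix with SNP ids as
#'   dimnames) covering the window; SNPs absent from `R` are excluded from
#'   the test and from the reported SNP count, so the simulated null covers
#'   exactly the tested SNPs.
#' @param config a [set_test_config()].
#' @return an object of class `set_test_result`: list with `mirna_name`,
#'   `n_snps_tested`, `k`, `observed_stat`, `empirical_p`, `n_sims_used`,
#'   `top_snp_id`, `top_snp_p`, `untestable`.
#' @export
test_window <- function(snp_set, summary_stats, R, config = set_test_config()) {
  stopifnot(inherits(config, "set_test_config"))
  if (is.character(snp_set)) snp_set <- list(window = NULL, snp_ids = snp_set)
  name <- if (!is.null(snp_set$window)) snp_set$window$name else "window"
  ld_ids <- if (inherits(R, "ld_matrix")) R$snp_ids else colnames(R)
  Rm <- if (inherits(R, "ld_matrix")) R$R else R
  if (is.null(ld_ids)) stop("R must carry SNP ids (ld_matrix or named matrix)")

  tested <- snp_set$snp_ids[snp_set$snp_ids %in% ld_ids]
  base <- list(mirna_name = name, n_snps_tested = length(tested), k = NA_integer_,
               observed_stat = NA_real_, empirical_p = NA_real_,
               n_sims_used = 0, top_snp_id = NA_character_, top_snp_p = NA_real_,
               untestable = TRUE)
  if (length(tested) == 0) return(structure(base, class = "set_test_result"))

  ss <- summary_stats[match(tested, summary_stats$SNP), , drop = FALSE]
  if (anyNA(ss$P)) stop("summary statistics missing for tested SNPs of ", name)
  Rsub <- Rm[match(tested, ld_ids), match(tested, ld_ids), drop = FALSE]

  chisq <- p_to_chisq(ss$P)
  obs <- top_fraction_stat(chisq, config$top_fraction, config$k_rounding)
  ord <- order(ss$P, ss$BP, ss$SNP)[1]
  fixed_idx <- if (config$selection == "fixed_index") {
    order(chisq, decreasing = TRUE)[seq_len(obs$k)]
  } else NULL

  wseed <- hash_seed(config$seed, name)
  p <- NA_real_
  nsim_used <- 0
  for (s in seq_along(config$sim_stages)) {
    nsim <- config$sim_stages[s]
    stage_seed <- as.integer((wseed + 1000003 * (s - 1)) %% 2147483629) + 1L
    sims <- simulate_null_stats(Rsub, config$top_fraction, nsim, stage_seed,
                                config$k_rounding, fixed_idx)
    p <- empirical_p(obs$stat, sims)
    nsim_used <- nsim
    if (p >= 10 / nsim) break
  }

  structure(list(mirna_name = name, n_snps_tested = length(tested), k = obs$k,
                 observed_stat = obs$stat, empirical_p = p,
                 n_sims_used = nsim_used,
                 top_snp_id = ss$SNP[ord], top_snp_p = ss$P[ord],
                 untestable = FALSE),
            class = "set_test_result")
}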