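.check_alda <- function(A, B) {
  if (any(is.na(A)) || any(A != round(A)) || any(A < 0 | A > 10)) {
    stop("A score must be an integer in 0..10")
  }
  for (k in seq_len(ncol(B))) {
    b <- B[, k]
    if (any(is.na(b)) || any(b != round(b)) || any(b < 0 | b > 2)) {
      stop("B", k, " score must be an integer in 0..2")
    }
  }
}

#' Alda total score
#'
#' The Alda scale rates long-term lithium response: the A score (0-10)
#' measures symptom improvement and is weighted against five confounder
#' criteria B1-B5 (each 0, 1 or 2). The total score subtracts the summed B
#' score from A, with negative values set to 0, giving a 0-10 range.
#'
#' @param A integer vector, A scores in 0..10.
#' @param B1,B2,B3,B4,B5 integer vectors, criterion scores in 0..2.
#' @return integer vector of total scores in 0..10.
#' @export
alda_total <- function(A, B1, B2, B3, B4, B5) {
  B <- cbind(B1, B2, B3, B4, B5)
  .check_alda(A, B)
  as.integer(pmax(0, A - rowSums(B)))
}

#' Dichotomous lithium-response phenotype
#'
#' Subjects with an Alda total score of 7 or higher are classified as good
#' responders.
#'
#' @param total_score integer vector of Alda total scores (0..10).
#' @return character vector, `"good"` or `"poor"`.
#' @export
dichotomize <- function(total_score) {
  if (any(is.na(total_score)) || any(total_score < 0 | total_score > 10)) {
    stop("total_score must lie in 0..10")
  }
  ifelse(total_score >= 7, "good", "poor")
}

#' Continuous lithium-response phenotype
#'
#' The continuous measure is the raw A score; subjects whose summed B score
#' exceeds 4 are excluded (returned as `NA`) because heavy confounding makes
#' the A score unreliable as a graded response measure.
#'
#' @inheritParams alda_total
#' @return numeric vector: the A score, or `NA` for excluded subjects.
#' @export
continuous_phenotype <- function(A, B1, B2, B3, B4, B5) {
  B <- cbind(B1, B2, B3, B4, B5)
  .check_alda(A, B)
  ifelse(rowSums(B) > 4, NA_real_, as.numeric(A))
}

#' Derive both lithium-response phenotypes for a table of Alda records
#'
#' @param df data frame with columns `subject_id`, `A`, `B1`..`B5` (the
#'   layout written by [gen_alda_scores()]).
#' @return the input with added columns `total`, `responder`, `continuous`,
#'   `excluded_continuous`.
#' @export
derive_phenotypes <- function(df) {
  req <- c("A", paste0("B", 1:5))
  if (!all(req %in% names(df))) {
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  }
  df$total <- alda_total(df$A, df$B1, df$B2, df$B3, df$B4, df$B5)
  df$responder <- dichotomize(df$total)
  df$continuous <- continuous_phenotype(df$A, df$B1, df$B2, df$B3, df$B4, df$B5)
  df$excluded_continuous <- is.na(df$continuous)
  df
}
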