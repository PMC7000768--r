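# Library QC: coverage (fraction of designed guides seen at all) and
# evenness (90th / 10th percentile of detected-guide counts, nearest-rank).

#' Guide library coverage
#'
#' @param raw Raw count vector for one library.
#' @param n_designed Number of guides in the designed library.
#' @return Fraction of designed guides with count > 0.
#' @export
qc_coverage <- function(raw, n_designed = length(raw)) {
  stopifnot(n_designed > 0L, length(raw) <= n_designed)
  sum(raw > 0) / n_designed
}

# nearest-rank percentile on a sorted vector: value at ceiling(p * n)
nearest_rank <- function(sorted, p) {
  sorted[max(1L, ceiling(p * length(sorted)))]
}

#' Guide library evenness
#'
#' Ratio of the 90th to the 10th percentile of guide counts, computed with
#' the nearest-rank convention on the detected (count > 0) guides only.
#' Undetected guides are reported through [qc_coverage()], not here.
#'
#' @param raw Raw count vector for one library.
#' @param min_detected Minimum detected guides for the ratio to be defined.
#' @return Ratio >= 1, or `NA` (with a warning) when too few guides are
#'   detected.
#' @export
qc_evenness <- function(raw, min_detected = 10L) {
  x <- sort(raw[raw > 0])
  if (length(x) < min_detected) {
    warning(sprintf("only %d detected guides: evenness undefined", length(x)))
    return(NA_real_)
  }
  nearest_rank(x, 0.90) / nearest_rank(x, 0.10)
}

#' Per-library QC report
#'
#' @param raw_matrix Raw count matrix, guides x libraries.
#' @param n_designed Designed library size (default `nrow(raw_matrix)`).
#' @return data.frame with one row per library: `library_id`, `n_designed`,
#'   `n_detected`, `coverage`, `lost_fraction`, `evenness`.
#' @export
library_qc <- function(raw_matrix, n_designed = nrow(raw_matrix)) {
  stopifnot(is.matrix(raw_matrix), !is.null(colnames(raw_matrix)))
  cov <- apply(raw_matrix, 2L, qc_coverage, n_designed = n_designed)
  data.frame(
    library_id = colnames(raw_matrix),
    n_designed = n_designed,
    n_detected = as.integer(colSums(raw_matrix > 0)),
    coverage = cov,
    lost_fraction = 1 - cov,
    evenness = apply(raw_matrix, 2L, qc_evenness),
    row.names = NULL)
}
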