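# Screen inference: the three-level analysis of the survival challenge.
# Level 1: per-guide Dox contrast D - ND (log2 abundance in a +Dox library
# minus its matched -Dox library). Level 2: per-pair contrast T - MT
# (D - ND of the targeting guide minus that of its mismatch control),
# which cancels sequence-independent Dox effects. Level 3: per-transcript
# median T - MT, a one-sided paired t-test over all pair x replicate
# values, and Benjamini-Hochberg adjustment across the transcripts tested
# within each drug.

#' Match +Dox libraries to their -Dox controls
#'
#' Pairing is by identical (drug, batch, split): each biological batch is
#' carried through the challenge with and without Dox and each batch is
#' sequenced as two DNA splits, so the paper-scale design yields
#' 3 x 2 = 6 replicate pairs per drug.
#'
#' @param metadata data.frame with columns `library_id`, `drug`, `dox`
#'   (`"plus"`/`"minus"`), `batch`, `split` (and optionally `stage`; only
#'   `"post_challenge"` rows are paired when present).
#' @return data.frame with columns `drug`, `batch`, `split`, `plus_id`,
#'   `minus_id`, `rep_id`.
#' @export
pair_libraries <- function(metadata) {
  need <- c("library_id", "drug", "dox", "batch", "split")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  md <- data.table::as.data.table(metadata)
  if ("stage" %in% names(md)) md <- md[stage == "post_challenge"]
  if (anyDuplicated(md[, .(drug, dox, batch, split)])) {
    stop("duplicate (drug, dox, batch, split) combination in metadata",
         call. = FALSE)
  }
  plus <- md[dox == "plus"]
  minus <- md[dox == "minus"]
  pairs <- merge(plus[, .(drug, batch, split, plus_id = library_id)],
                 minus[, .(drug, batch, split, minus_id = library_id)],
                 by = c("drug", "batch", "split"), all = TRUE)
  orphan <- pairs[is.na(plus_id) | is.na(minus_id)]
  if (nrow(orphan) > 0L) {
    stop(sprintf("unmatched libraries: %s",
                 paste(ifelse(is.na(orphan$plus_id), orphan$minus_id,
                              orphan$plus_id), collapse = ", ")),
         call. = FALSE)
  }
  pairs[, rep_id := paste(drug, batch, split, sep = ".")]
  data.table::setorder(pairs, drug, batch, split)
  as.data.frame(pairs)
}

#' Per-guide Dox contrasts (D - ND)
#'
#' @param log2_matrix Guides x libraries matrix of log2 normalized
#'   abundances (column names = library ids).
#' @param pairs Output of [pair_libraries()].
#' @return Guides x replicate-pairs matrix; column names are `rep_id`s.
#' @export
dox_contrast <- function(log2_matrix, pairs) {
  miss <- setdiff(c(pairs$plus_id, pairs$minus_id), colnames(log2_matrix))
  if (length(miss) > 0L) {
    stop("libraries absent from log2 matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dnd <- log2_matrix[, pairs$plus_id, drop = FALSE] -
    log2_matrix[, pairs$minus_id, drop = FALSE]
  colnames(dnd) <- pairs$rep_id
  dnd
}

#' Per-pair targeting-vs-mismatch contrasts (T - MT)
#'
#' @param dnd Guides x replicate-pairs matrix from [dox_contrast()]
#'   (row names = guide ids).
#' @param manifest Design manifest.
#' @return Pairs x replicate-pairs matrix of T - MT values (row names =
#'   pair ids). Pairs with either member absent from `dnd` are dropped
#'   with a warning.
#' @export
pair_contrast <- function(dnd, manifest) {
  mf <- data.table::as.data.table(manifest)
  tg <- mf[role == "targeting", .(pair_id, guide_id)]
  mm <- mf[role == "mismatch", .(pair_id, guide_id)]
  both <- merge(tg, mm, by = "pair_id", suffixes = c("_t", "_mt"))
  ok <- both$guide_id_t %in% rownames(dnd) &
    both$guide_id_mt %in% rownames(dnd)
  if (!all(ok)) {
    warning(sprintf("%d pair(s) missing a member in the contrast matrix; dropped",
                    sum(!ok)))
    both <- both[ok]
  }
  if (nrow(both) == 0L) stop("no complete guide pairs", call. = FALSE)
  out <- dnd[both$guide_id_t, , drop = FALSE] -
    dnd[both$guide_id_mt, , drop = FALSE]
  rownames(out) <- both$pair_id
  out
}

#' Median T - MT for one transcript and drug
#'
#' @param values Numeric vector of T - MT values over all pairs and
#'   replicate pairs (60 for a 10-pair transcript with 6 replicates).
#' @return Median (even counts: mean of the two central values), or `NA`
#'   with a warning when no values exist.
#' @export
transcript_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    warning("no T - MT values: summary undefined")
    return(NA_real_)
  }
  stats::median(values)
}

#' One-sided paired t-test for a transcript
#'
#' Paired Student's t-test of targeting vs mismatch D - ND values (paired
#' by pair x replicate, i.e. a one-sample t-test of the T - MT differences
#' against zero), with the one-sided p-value taken in the direction of the
#' observed mean difference. The chosen side is reported; using the
#' observed direction makes the raw p equivalent to half the two-sided p,
#' so an either-direction significance call at level a has size 2a under
#' the null.
#'
#' @param differences Numeric vector of paired differences (T - MT).
#' @return List: `n`, `mean_diff`, `t`, `df`, `p`, `direction`
#'   (`"depleted"` if the mean difference is negative, else `"enriched"`),
#'   `tested` (FALSE when n < 2 or the differences have zero variance).
#' @export
transcript_test <- function(differences) {
  d <- differences[!is.na(differences)]
  n <- length(d)
  if (n < 2L) {
    return(list(n = n, mean_diff = if (n) mean(d) else NA_real_,
                t = NA_real_, df = NA_real_, p = NA_real_,
                direction = NA_character_, tested = FALSE))
  }
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(n = n, mean_diff = m, t = NA_real_, df = n - 1,
                p = NA_real_, direction = NA_character_, tested = FALSE))
  }
  tt <- m / (s / sqrt(n))
  list(n = n, mean_diff = m, t = tt, df = n - 1L,
       p = stats::pt(abs(tt), df = n - 1L, lower.tail = FALSE),
       direction = if (m < 0) "depleted" else "enriched",
       tested = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled BH (so tests can check it against an independent
#' implementation): p-values are ranked ascending, scaled by m/rank, and
#' monotonicity is enforced from the largest rank down. `NA` p-values are
#' passed through and do not count towards the family size.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0L) return(out)
  pv <- p[idx]
  o <- order(pv)
  scaled <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out[idx[o]] <- adj
  out
}

#' Significance calls from median and p-values
#'
#' @param median_t_mt Median T - MT per transcript.
#' @param p_raw,p_adj Raw and BH-adjusted p-values.
#' @param alpha Significance threshold (default 0.05).
#' @param marginal_upper Upper edge of the marginal band on `p_adj`
#'   (default 0.1); `alpha <= p_adj < marginal_upper` is annotated.
#' @return data.frame with `call_permissive`, `call_strict` (each
#'   `"depleted"`, `"enriched"` or `"ns"`) and logical `marginal`.
#' @export
call_transcripts <- function(median_t_mt, p_raw, p_adj, alpha = 0.05,
                             marginal_upper = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  dir <- ifelse(median_t_mt < 0, "depleted", "enriched")
  mk <- function(p) {
    ifelse(is.na(p) | p >= alpha, "ns", dir)
  }
  data.frame(call_permissive = mk(p_raw),
             call_strict = mk(p_adj),
             marginal = !is.na(p_adj) & p_adj >= alpha &
               p_adj < marginal_upper)
}

#' Full three-level screen analysis
#'
#' Runs [pair_libraries()], [dox_contrast()], [pair_contrast()], then per
#' transcript x drug the median summary, one-sided paired t-test and BH
#' adjustment (family: all transcripts tested within one drug), and the
#' permissive/strict calls.
#'
#' @param log2_matrix Guides x libraries log2 abundance matrix.
#' @param metadata Library metadata (see [pair_libraries()]).
#' @param manifest Design manifest.
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame with one row per transcript x drug: `transcript_id`,
#'   `drug`, `n_pairs`, `n_values`, `median_t_mt`, `t`, `p_raw`, `p_adj`,
#'   `direction`, `call_permissive`, `call_strict`, `marginal`, `tested`.
#' @export
screen_calls <- function(log2_matrix, metadata, manifest, alpha = 0.05) {
  pairs_meta <- pair_libraries(metadata)
  dnd <- dox_contrast(log2_matrix, pairs_meta)
  tmt <- pair_contrast(dnd, manifest)

  mf <- data.table::as.data.table(manifest)
  pair2tx <- unique(mf[, .(pair_id, transcript_id)])
  tx_of <- stats::setNames(pair2tx$transcript_id, pair2tx$pair_id)
  drugs <- unique(pairs_meta$drug)

  res <- list()
  for (dg in drugs) {
    cols <- pairs_meta$rep_id[pairs_meta$drug == dg]
    sub <- tmt[, cols, drop = FALSE]
    tx_ids <- unique(tx_of[rownames(sub)])
    rows <- lapply(tx_ids, function(tx) {
      prs <- rownames(sub)[tx_of[rownames(sub)] == tx]
      vals <- as.vector(sub[prs, , drop = FALSE])
      tst <- transcript_test(vals)
      data.frame(transcript_id = tx, drug = dg, n_pairs = length(prs),
                 n_values = sum(!is.na(vals)),
                 median_t_mt = transcript_summary(vals),
                 t = tst$t, p_raw = tst$p, direction = tst$direction,
                 tested = tst$tested)
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- adjust_bh(tab$p_raw)
    res[[dg]] <- tab
  }
  out <- do.call(rbind, res)
  calls <- call_transcripts(out$median_t_mt, out$p_raw, out$p_adj,
                            alpha = alpha)
  out <- cbind(out, calls)
  rownames(out) <- NULL
  out[, c("transcript_id", "drug", "n_pairs", "n_values", "median_t_mt",
          "t", "p_raw", "p_adj", "direction", "call_permissive",
          "call_strict", "marginal", "tested")]
}
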