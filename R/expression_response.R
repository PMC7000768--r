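# Expression response: drug-induced fold changes from an already
# normalized count table, the two-tier target-selection rule, and group
# comparisons of fold-change sets.

#' Pseudocounted log2 expression fold change
#'
#' `FC = log2((nrc_drug + 1) / (nrc_dmso + 1))` on normalized read counts.
#'
#' @param nrc_drug,nrc_dmso Non-negative normalized read counts
#'   (vectorized).
#' @return log2 fold change(s).
#' @export
fold_change <- function(nrc_drug, nrc_dmso) {
  if (any(nrc_drug < 0) || any(nrc_dmso < 0)) {
    stop("normalized read counts must be non-negative", call. = FALSE)
  }
  log2((nrc_drug + 1) / (nrc_dmso + 1))
}

#' Fold-change table from a long-format expression table
#'
#' @param expr data.frame with columns `gene_id`, `condition` (drug names
#'   plus `"DMSO"`), `timepoint`, `nrc`. Every (gene, drug, timepoint)
#'   must have a matched DMSO record at the same timepoint.
#' @return data.frame with columns `gene_id`, `drug`, `timepoint`, `fc`.
#' @export
fc_table <- function(expr) {
  need <- c("gene_id", "condition", "timepoint", "nrc")
  if (!all(need %in% names(expr))) {
    stop("expression table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ex <- data.table::as.data.table(expr)
  dmso <- ex[condition == "DMSO",
             .(gene_id, timepoint, nrc_dmso = nrc)]
  drug <- ex[condition != "DMSO",
             .(gene_id, drug = condition, timepoint, nrc)]
  mg <- merge(drug, dmso, by = c("gene_id", "timepoint"))
  if (nrow(mg) < nrow(drug)) {
    stop("missing DMSO baseline for some (gene, timepoint)", call. = FALSE)
  }
  mg[, fc := fold_change(nrc, nrc_dmso)]
  data.table::setorder(mg, gene_id, drug, timepoint)
  as.data.frame(mg[, .(gene_id, drug, timepoint, fc)])
}

#' Tiered target selection from fold changes
#'
#' Strong tier: FC > `strong_threshold` at both timepoints for at least
#' one drug. Weak tier: FC > `weak_threshold` at both timepoints for at
#' least one drug, excluding strong genes. The multi-drug subset (strong
#' in >= 2 drugs) is reported separately. Thresholds are strict (`>`).
#'
#' @param fc Output of [fc_table()] (two timepoints per gene x drug; genes
#'   missing a timepoint for a drug are skipped for that drug with a
#'   warning).
#' @param strong_threshold,weak_threshold log2 FC cutoffs (defaults 0.58
#'   and 0).
#' @return data.frame with one row per gene: `gene_id`, `tier`
#'   (`"strong"`, `"weak"` or `"none"`), `n_strong_drugs`, `multi_drug`.
#' @export
select_targets <- function(fc, strong_threshold = 0.58,
                           weak_threshold = 0) {
  ft <- data.table::as.data.table(fc)
  ntp <- length(unique(ft$timepoint))
  cnt <- ft[, .N, by = .(gene_id, drug)]
  incomplete <- cnt[N < ntp]
  if (nrow(incomplete) > 0L) {
    warning(sprintf("%d gene x drug combination(s) missing a timepoint; skipped",
                    nrow(incomplete)))
    ft <- ft[!incomplete, on = c("gene_id", "drug")]
  }
  per_drug <- ft[, .(strong = all(fc > strong_threshold),
                     weak = all(fc > weak_threshold)),
                 by = .(gene_id, drug)]
  per_gene <- per_drug[, .(n_strong_drugs = sum(strong),
                           any_weak = any(weak)), by = gene_id]
  per_gene[, tier := data.table::fifelse(
    n_strong_drugs >= 1L, "strong",
    data.table::fifelse(any_weak, "weak", "none"))]
  per_gene[, multi_drug := n_strong_drugs >= 2L]
  data.table::setorder(per_gene, gene_id)
  as.data.frame(per_gene[, .(gene_id, tier, n_strong_drugs, multi_drug)])
}

#' Compare two sets of fold changes
#'
#' Group medians and a two-sided pooled-variance (classical Student)
#' two-sample t-test.
#'
#' @param fc_a,fc_b Numeric vectors of log2 fold changes (each length
#'   >= 2).
#' @return List: `median_a`, `median_b`, `t`, `df`, `p`, `degenerate`
#'   (TRUE when the pooled variance is zero; `p` is then `NA`).
#' @export
compare_fc_groups <- function(fc_a, fc_b) {
  stopifnot(length(fc_a) >= 2L, length(fc_b) >= 2L)
  na <- length(fc_a)
  nb <- length(fc_b)
  sp2 <- ((na - 1) * stats::var(fc_a) + (nb - 1) * stats::var(fc_b)) /
    (na + nb - 2)
  med_a <- stats::median(fc_a)
  med_b <- stats::median(fc_b)
  if (sp2 == 0) {
    return(list(median_a = med_a, median_b = med_b, t = NA_real_,
                df = na + nb - 2L, p = NA_real_, degenerate = TRUE))
  }
  tt <- (mean(fc_a) - mean(fc_b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  list(median_a = med_a, median_b = med_b, t = tt, df = df,
       p = 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE),
       degenerate = FALSE)
}
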