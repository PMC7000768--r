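# Guide quantification: exact-match spacer counting in amplicon reads and
# the zero-handled normalization / log2 transform feeding the contrasts.

#' Count exact spacer matches in amplicon reads
#'
#' For each guide in the manifest, counts the reads that contain the
#' 28-mer spacer, or its reverse complement, as an exact substring.
#' No alignment, no fuzzy matching: a single mismatch means no count.
#' Each read contributes at most once per guide (a spacer occurring twice
#' in one read is still one read); a read may in principle match several
#' guides, in which case all are incremented and a warning is logged.
#'
#' @param reads A `Biostrings::DNAStringSet`, a character vector of read
#'   sequences, or a path to a FASTQ file (optionally gzipped).
#' @param manifest Design manifest (see [build_design_manifest()]); spacer
#'   sequences must be unique.
#' @param id_column Manifest column naming guides (default `"guide_id"`).
#' @return Named integer vector of per-guide read counts, in manifest order.
#' @export
count_exact <- function(reads, manifest, id_column = "guide_id") {
  stopifnot(is.data.frame(manifest), "spacer" %in% names(manifest))
  if (anyDuplicated(manifest$spacer)) {
    stop("manifest spacers are not unique", call. = FALSE)
  }
  if (is.character(reads) && length(reads) == 1L &&
      file.exists(reads) && !grepl("^[ACGTN]+$", reads)) {
    reads <- tryCatch(
      Biostrings::readDNAStringSet(reads, format = "fastq"),
      error = function(e) stop(sprintf("malformed FASTQ %s: %s", reads,
                                       conditionMessage(e)), call. = FALSE))
  } else if (is.character(reads)) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  ids <- manifest[[id_column]]
  n_guides <- nrow(manifest)
  counts <- integer(n_guides)
  names(counts) <- ids
  if (length(reads) == 0L) {
    warning("no reads supplied: returning all-zero counts")
    return(counts)
  }
  spac <- Biostrings::DNAStringSet(manifest$spacer)
  fwd <- Biostrings::vwhichPDict(Biostrings::PDict(spac), reads)
  rev <- Biostrings::vwhichPDict(
    Biostrings::PDict(Biostrings::reverseComplement(spac)), reads)
  hits_per_read <- mapply(function(f, r) unique(c(f, r)), fwd, rev,
                          SIMPLIFY = FALSE)
  multi <- sum(lengths(hits_per_read) > 1L)
  if (multi > 0L) {
    warning(sprintf("%d read(s) matched more than one guide", multi))
  }
  tab <- tabulate(unlist(hits_per_read), nbins = n_guides)
  counts[] <- tab
  counts
}

# naive per-read scan; used as the independent counting oracle in tests and
# kept exported for auditability
#' Reference substring-scan counter
#'
#' Slow per-read `grepl(fixed = TRUE)` scan over both orientations;
#' independent oracle for [count_exact()].
#'
#' @inheritParams count_exact
#' @return Named integer vector as in [count_exact()].
#' @export
count_exact_naive <- function(reads, manifest, id_column = "guide_id") {
  if (!is.character(reads)) reads <- as.character(reads)
  spac <- manifest$spacer
  rsp <- revcomp(spac)
  counts <- vapply(seq_along(spac), function(i) {
    sum(grepl(spac[i], reads, fixed = TRUE) |
          grepl(rsp[i], reads, fixed = TRUE))
  }, integer(1L))
  names(counts) <- manifest[[id_column]]
  counts
}

#' Normalize raw guide counts with the zero-to-one rule
#'
#' Zero counts are converted to 1 *before* totaling, then each count is
#' divided by the post-replacement library total. With `scale = 1` the
#' values are fractions summing to 1; the default counts-per-million scale
#' is purely cosmetic and cancels in every downstream contrast.
#'
#' @param raw Non-negative integer vector (one sequencing library).
#' @param scale Multiplier applied to the fractions (default `1e6`, CPM).
#' @return Numeric vector of normalized abundances.
#' @export
normalize_counts <- function(raw, scale = 1e6) {
  if (any(raw < 0) || anyNA(raw)) {
    stop("raw counts must be non-negative and non-missing", call. = FALSE)
  }
  if (all(raw == 0)) {
    stop("all-zero count column: library failed", call. = FALSE)
  }
  x <- ifelse(raw == 0, 1, raw)
  x / sum(x) * scale
}

#' Log2 of normalized abundances
#'
#' @param normalized Positive numeric vector from [normalize_counts()].
#' @return Elementwise `log2`.
#' @export
log2_abundance <- function(normalized) {
  if (any(normalized <= 0) || anyNA(normalized)) {
    stop("non-positive normalized abundance: zero handling was skipped",
         call. = FALSE)
  }
  log2(normalized)
}

#' Count, normalize and log-transform a set of libraries
#'
#' @param fastq_by_library Named list (names = library ids) of read inputs
#'   accepted by [count_exact()].
#' @param manifest Design manifest.
#' @param scale Passed to [normalize_counts()].
#' @return List with matrices `raw`, `normalized`, `log2` (guides x
#'   libraries).
#' @export
quantify_libraries <- function(fastq_by_library, manifest, scale = 1e6) {
  stopifnot(length(fastq_by_library) > 0L,
            !is.null(names(fastq_by_library)))
  raw <- vapply(fastq_by_library, count_exact, integer(nrow(manifest)),
                manifest = manifest)
  rownames(raw) <- manifest$guide_id
  nrm <- apply(raw, 2L, normalize_counts, scale = scale)
  list(raw = raw, normalized = nrm, log2 = log2(nrm))
}
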