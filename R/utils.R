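#' @keywords internal
"_PACKAGE"

#' @import data.table
NULL

# Internal sequence helpers shared across modules. Sequences are plain
# uppercase character vectors; Biostrings containers are used at the I/O
# boundary (FASTA/FASTQ) and for bulk matching.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) == 0L || anyNA(x)) {
    stop(sprintf("%s must be a non-missing character vector", what),
         call. = FALSE)
  }
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s: non-ACGT character in %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GATC")
#' @export
revcomp <- function(x) {
  assert_dna(x)
  vapply(x, function(s) {
    paste(rev(DNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

complement_bases <- function(x) {
  # positionwise complement without reversal
  vapply(x, function(s) {
    paste(DNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1L]]], collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# 1-based closed-interval overlap with a 0-based half-open interval set
overlaps_mask <- function(start1, end1, mask) {
  if (is.null(mask) || nrow(mask) == 0L) {
    return(rep(FALSE, length(start1)))
  }
  # convert window to 0-based half-open: [start1 - 1, end1)
  ws <- start1 - 1L
  we <- end1
  vapply(seq_along(ws), function(i) {
    any(ws[i] < mask$end & mask$start < we[i])
  }, logical(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
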