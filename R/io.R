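# Shared readers and writers. All tables are tab-separated with headers
# and stable column order; FASTA/FASTQ go through Biostrings. Transcript
# coordinates are 1-based inclusive in manifests; BED-style interval
# inputs are 0-based half-open.

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  x <- tryCatch(data.table::fread(path, sep = "\t", header = TRUE,
                                  data.table = FALSE),
                error = function(e) {
                  stop(sprintf("malformed %s file %s: %s", what, path,
                               conditionMessage(e)), call. = FALSE)
                })
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s file %s lacks column(s): %s", what, path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read a design manifest TSV
#' @param path Manifest path.
#' @return Manifest data.frame (see [build_design_manifest()]).
#' @export
read_manifest <- function(path) {
  mf <- read_tsv_checked(path, c("guide_id", "pair_id", "transcript_id",
                                 "role", "spacer"), "manifest")
  assert_dna(mf$spacer, "manifest spacer")
  if (anyDuplicated(mf$spacer)) {
    stop("manifest spacers are not unique", call. = FALSE)
  }
  mf
}

#' Read a library metadata TSV
#' @param path Metadata path.
#' @return Metadata data.frame (see [pair_libraries()]).
#' @export
read_metadata <- function(path) {
  read_tsv_checked(path, c("library_id", "drug", "dox", "batch", "split"),
                   "metadata")
}

#' Read a guide count (or log2-abundance) matrix TSV
#'
#' First column `guide_id`, remaining columns one per library.
#'
#' @param path Counts path.
#' @return Numeric matrix with guide row names.
#' @export
read_count_matrix <- function(path) {
  x <- read_tsv_checked(path, "guide_id", "count matrix")
  m <- as.matrix(x[, setdiff(names(x), "guide_id"), drop = FALSE])
  rownames(m) <- x$guide_id
  m
}

#' Write a guide matrix TSV
#' @param m Matrix with guide row names.
#' @param path Output path.
#' @export
write_count_matrix <- function(m, path) {
  write_tsv(data.frame(guide_id = rownames(m), m, check.names = FALSE),
            path)
}

#' Read transcript targets from FASTA
#'
#' Sequence names are transcript ids; a `class=coding` token in the FASTA
#' description marks coding targets (default class is `vlinc`).
#'
#' @param path FASTA path.
#' @param pairs_vlinc,pairs_coding Requested pairs per class.
#' @return List of [transcript_target()]s.
#' @export
read_targets_fasta <- function(path, pairs_vlinc = 10L, pairs_coding = 5L) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    nm <- names(ss)[i]
    id <- strsplit(nm, "\\s+")[[1L]][1L]
    cls <- if (grepl("class=coding", nm)) "coding" else "vlinc"
    transcript_target(id, as.character(ss[[i]]), class = cls,
                      requested_pairs = if (cls == "coding") pairs_coding
                                        else pairs_vlinc)
  })
}

#' Read a repeat mask BED as per-transcript interval tables
#'
#' @param path BED path (chrom column holds transcript ids; 0-based
#'   half-open intervals are kept as such).
#' @return Named list of data.frames with `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(transcript_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  split(df[, c("start", "end")], df$transcript_id)
}

#' Read a per-base uniqueness track
#'
#' Three-column TSV `transcript_id`, `position` (1-based), `score`.
#'
#' @param path Track path.
#' @return Named list of numeric vectors (`NA` at unlisted positions).
#' @export
read_uniqueness <- function(path) {
  x <- read_tsv_checked(path, c("transcript_id", "position", "score"),
                        "uniqueness track")
  lapply(split(x, x$transcript_id), function(d) {
    v <- rep(NA_real_, max(d$position))
    v[d$position] <- d$score
    v
  })
}

#' Write reads as FASTQ
#'
#' @param reads Character vector of read sequences.
#' @param path Output path; a `.gz` suffix triggers compression.
#' @param quality_char Constant per-base quality character (default "I").
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ss <- Biostrings::DNAStringSet(reads)
  names(ss) <- sprintf("read_%06d", seq_along(ss))
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a long-format expression table TSV
#' @param path Expression table path.
#' @return data.frame (see [fc_table()]).
#' @export
read_expression <- function(path) {
  read_tsv_checked(path, c("gene_id", "condition", "timepoint", "nrc"),
                   "expression")
}
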