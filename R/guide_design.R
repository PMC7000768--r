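# Guide design: enumerate, filter and select 28-mer Cas13 crRNA spacers per
# transcript, derive the central-mismatch control for each targeting guide,
# and emit the cloning-ready design manifest used by all downstream stages.
#
# The filters mirror the screening-library design rules: 40-60% GC, no
# homopolymer longer than 3, no dinucleotide run longer than 2 units, mean
# 20-bp-window uniqueness > 0.7 over the spacer footprint, no overlap with
# repeat-masked bases, and (for coding targets) exonic sequence only. The
# spacer is reported as the reverse complement of the sense-strand window:
# the crRNA base-pairs with the target RNA.

#' Default spacer design constraints
#'
#' @param gc_min,gc_max Inclusive GC-fraction bounds (defaults 0.40, 0.60).
#' @param max_homopolymer Longest tolerated single-base run (default 3).
#' @param max_dinucleotide_repeats Longest tolerated tandem run of an
#'   unequal-base 2-mer unit, in units (default 2; `ACACAC` is 3 units).
#' @param uniqueness_min Strict lower bound on mean per-base uniqueness
#'   (default 0.7; candidates at exactly 0.7 fail).
#' @param mismatch_window 1-based closed interval of spacer positions whose
#'   bases are flipped in the mismatch control (default `c(12L, 14L)`).
#' @param spacer_length Spacer length in nt (default 28).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(gc_min = 0.40, gc_max = 0.60,
                               max_homopolymer = 3L,
                               max_dinucleotide_repeats = 2L,
                               uniqueness_min = 0.7,
                               mismatch_window = c(12L, 14L),
                               spacer_length = 28L) {
  stopifnot(gc_min >= 0, gc_max <= 1, gc_min <= gc_max,
            max_homopolymer >= 1L, max_dinucleotide_repeats >= 1L,
            spacer_length >= 1L,
            length(mismatch_window) == 2L,
            mismatch_window[1L] >= 1L,
            mismatch_window[2L] <= spacer_length,
            mismatch_window[1L] <= mismatch_window[2L])
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_dinucleotide_repeats = as.integer(max_dinucleotide_repeats),
                 uniqueness_min = uniqueness_min,
                 mismatch_window = as.integer(mismatch_window),
                 spacer_length = as.integer(spacer_length)),
            class = "design_constraints")
}

#' A transcript target for guide design
#'
#' @param transcript_id Transcript identifier.
#' @param sequence Sense-strand transcript sequence (for coding genes, the
#'   concatenated exonic sequence).
#' @param class `"vlinc"` or `"coding"`.
#' @param requested_pairs Number of guide pairs to design (10 for vlincRNAs,
#'   3-5 for coding genes in the reference configuration).
#' @param exon_intervals Optional matrix/data.frame of 1-based closed
#'   intervals *on the transcript sequence* delimiting exonic sequence.
#'   When `NULL` the whole supplied sequence is treated as exonic (the
#'   usual case for coding targets supplied as concatenated exons).
#' @return A list of class `transcript_target`.
#' @export
transcript_target <- function(transcript_id, sequence,
                              class = c("vlinc", "coding"),
                              requested_pairs = 10L,
                              exon_intervals = NULL) {
  class <- match.arg(class)
  assert_dna(sequence, "transcript sequence")
  stopifnot(length(sequence) == 1L, requested_pairs >= 1L)
  if (nchar(sequence) < 28L) {
    warning(sprintf("transcript %s is shorter than 28 nt; no candidates",
                    transcript_id))
  }
  structure(list(transcript_id = as.character(transcript_id),
                 class = class, sequence = sequence,
                 requested_pairs = as.integer(requested_pairs),
                 exon_intervals = exon_intervals),
            class = "transcript_target")
}

#' GC fraction of a spacer
#'
#' @param spacer ACGT string (any length; the designer uses 28-mers).
#' @return Fraction of G/C bases.
#' @examples
#' gc_fraction(strrep("AT", 14))  # 0
#' @export
gc_fraction <- function(spacer) {
  assert_dna(spacer, "spacer")
  vapply(spacer, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    mean(b == "G" | b == "C")
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Longest homopolymer run in a spacer
#'
#' @inheritParams gc_fraction
#' @return Integer length of the longest single-base run.
#' @export
max_homopolymer_run <- function(spacer) {
  assert_dna(spacer, "spacer")
  vapply(spacer, function(s) {
    max(rle(strsplit(s, "", fixed = TRUE)[[1L]])$lengths)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Longest tandem dinucleotide run in a spacer
#'
#' Counts tandem repetitions of any 2-mer unit with unequal bases
#' (`ACACAC` = 3 units of `AC`). Homopolymer stretches are judged only by
#' [max_homopolymer_run()] and are ignored here.
#'
#' @inheritParams gc_fraction
#' @return Integer, the maximum tandem unit count over both frames.
#' @export
max_dinucleotide_repeats <- function(spacer) {
  assert_dna(spacer, "spacer")
  vapply(spacer, function(s) {
    n <- nchar(s)
    if (n < 2L) return(0L)
    best <- 0L
    for (phase in 0:1) {
      starts <- seq.int(1L + phase, n - 1L, by = 2L)
      if (length(starts) == 0L) next
      units <- substring(s, starts, starts + 1L)
      keep <- substr(units, 1L, 1L) != substr(units, 2L, 2L)
      r <- rle(units)
      ok <- substr(r$values, 1L, 1L) != substr(r$values, 2L, 2L)
      if (any(ok)) best <- max(best, max(r$lengths[ok]))
      if (any(keep) && best == 0L) best <- 1L
    }
    best
  }, integer(1L), USE.NAMES = FALSE)
}

#' Mean uniqueness over a spacer window
#'
#' @param track Numeric vector of per-base uniqueness scores in `[0, 1]`,
#'   indexed by 1-based transcript position (`NA` = missing).
#' @param window Length-2 integer vector, 1-based closed interval.
#' @return Mean score over the window.
#' @export
mean_uniqueness <- function(track, window) {
  stopifnot(is.numeric(track), length(window) == 2L,
            window[1L] >= 1L, window[1L] <= window[2L])
  if (window[2L] > length(track)) {
    stop("uniqueness window extends beyond track", call. = FALSE)
  }
  v <- track[window[1L]:window[2L]]
  if (anyNA(v)) stop("missing uniqueness scores in window", call. = FALSE)
  if (any(v < 0 | v > 1)) stop("uniqueness scores outside [0, 1]", call. = FALSE)
  mean(v)
}

# positions (1-based starts) fully inside exonic sequence
exonic_starts <- function(target, width) {
  L <- nchar(target$sequence)
  starts <- seq_len(max(L - width + 1L, 0L))
  if (target$class != "coding" || is.null(target$exon_intervals)) {
    return(starts)
  }
  ex <- as.data.frame(target$exon_intervals)
  names(ex)[1:2] <- c("start", "end")
  keep <- vapply(starts, function(s) {
    any(ex$start <= s & s + width - 1L <= ex$end)
  }, logical(1L))
  starts[keep]
}

#' Enumerate passing candidate guide windows on a transcript
#'
#' Slides a spacer-length window over the sense strand (step 1) and keeps
#' windows whose spacer (reverse complement of the window) passes the GC,
#' homopolymer and dinucleotide filters, whose footprint passes the
#' uniqueness threshold and overlaps no repeat-masked base, and which lies
#' in exonic sequence for coding targets.
#'
#' @param target A [transcript_target()].
#' @param mask `NULL` or a data.frame with 0-based half-open `start`/`end`
#'   columns of repeat-masked transcript intervals.
#' @param track `NULL` (treated as uniformly unique) or a per-base
#'   uniqueness vector as in [mean_uniqueness()].
#' @param constraints A [design_constraints()].
#' @return data.frame with columns `target_start`, `window_seq`, `spacer`,
#'   `gc` (one row per passing window, ordered by position).
#' @export
enumerate_candidates <- function(target, mask = NULL, track = NULL,
                                 constraints = design_constraints()) {
  k <- constraints$spacer_length
  L <- nchar(target$sequence)
  empty <- data.frame(target_start = integer(), window_seq = character(),
                      gc = numeric(), spacer = character())
  if (L < k) {
    warning(sprintf("transcript %s shorter than %d nt: no candidate windows",
                    target$transcript_id, k))
    return(empty)
  }
  starts <- exonic_starts(target, k)
  if (length(starts) == 0L) return(empty)
  wins <- substring(target$sequence, starts, starts + k - 1L)
  spacers <- revcomp(wins)

  gc <- gc_fraction(spacers)
  ok <- gc >= constraints$gc_min & gc <= constraints$gc_max
  ok <- ok & max_homopolymer_run(spacers) <= constraints$max_homopolymer
  ok <- ok & max_dinucleotide_repeats(spacers) <=
    constraints$max_dinucleotide_repeats
  ok <- ok & !overlaps_mask(starts, starts + k - 1L, mask)
  if (!is.null(track)) {
    uniq_ok <- vapply(seq_along(starts), function(i) {
      u <- tryCatch(mean_uniqueness(track, c(starts[i], starts[i] + k - 1L)),
                    error = function(e) NA_real_)
      !is.na(u) && u > constraints$uniqueness_min
    }, logical(1L))
    ok <- ok & uniq_ok
  }
  data.frame(target_start = starts[ok], window_seq = wins[ok],
             gc = gc[ok], spacer = spacers[ok])
}

# Greedy feasibility: can we place n picks from sorted positions with
# pairwise gap >= d?
.placeable <- function(pos, n, d) {
  cnt <- 0L
  last <- -Inf
  for (p in pos) {
    if (p - last >= d) {
      cnt <- cnt + 1L
      last <- p
      if (cnt >= n) return(TRUE)
    }
  }
  cnt >= n
}

#' Select guide windows maximizing spread along the transcript
#'
#' Deterministic selection among passing candidates: maximize the minimum
#' pairwise start distance of the selected set; within that optimum, picks
#' are made left to right preferring GC closest to 0.5 and then the
#' 5'-most position. Returns fewer than `n` windows (with a shortfall
#' attribute) when candidates are scarce.
#'
#' @param candidates data.frame from [enumerate_candidates()].
#' @param n Number of windows requested.
#' @return Subset of `candidates` (n or fewer rows, position-ordered) with
#'   attribute `shortfall` (integer, 0 when `n` were found).
#' @export
select_guides <- function(candidates, n) {
  stopifnot(is.data.frame(candidates), n >= 1L)
  if (nrow(candidates) == 0L) {
    out <- candidates
    attr(out, "shortfall") <- as.integer(n)
    return(out)
  }
  cand <- candidates[order(candidates$target_start), , drop = FALSE]
  if (nrow(cand) <= n) {
    out <- cand
    attr(out, "shortfall") <- as.integer(n - nrow(cand))
    return(out)
  }
  pos <- cand$target_start
  # max-min-gap via binary search over achievable integer gaps
  lo <- 1L
  hi <- as.integer(pos[length(pos)] - pos[1L])
  if (n == 1L) {
    dstar <- 0L
  } else {
    while (lo < hi) {
      mid <- as.integer((lo + hi + 1L) %/% 2L)
      if (.placeable(pos, n, mid)) lo <- mid else hi <- mid - 1L
    }
    dstar <- lo
  }
  # suffix feasibility: most picks placeable starting at or after index i
  m <- length(pos)
  key <- order(abs(cand$gc - 0.5), cand$target_start)
  rank <- integer(m)
  rank[key] <- seq_len(m)
  chosen <- integer(0)
  last <- -Inf
  need <- as.integer(n)
  i <- 1L
  while (need > 0L) {
    elig <- which(pos >= last + dstar)
    elig <- elig[elig >= i]
    # first candidate in preference order from which the remaining picks
    # can still be completed at gap dstar
    elig <- elig[order(rank[elig])]
    pick <- NA_integer_
    for (j in elig) {
      if (.placeable(pos[pos >= pos[j]], need, dstar)) {
        pick <- j
        break
      }
    }
    stopifnot(!is.na(pick))
    chosen <- c(chosen, pick)
    last <- pos[pick]
    i <- pick + 1L
    need <- need - 1L
  }
  out <- cand[sort(chosen), , drop = FALSE]
  attr(out, "shortfall") <- 0L
  out
}

#' Derive the central-mismatch control spacer
#'
#' Replaces each base in the mismatch window (default positions 12-14 of
#' the 28-mer, first base = 1) by its Watson-Crick complement, guaranteeing
#' a mismatch at all three positions; all other positions are untouched.
#' The operation is an involution.
#'
#' @inheritParams gc_fraction
#' @param constraints A [design_constraints()] supplying the window.
#' @return Mismatch spacer(s) of the same length.
#' @export
make_mismatch <- function(spacer, constraints = design_constraints()) {
  assert_dna(spacer, "spacer")
  w <- constraints$mismatch_window
  if (any(nchar(spacer) < w[2L])) {
    stop("spacer shorter than mismatch window", call. = FALSE)
  }
  vapply(spacer, function(s) {
    mid <- substr(s, w[1L], w[2L])
    paste0(substr(s, 1L, w[1L] - 1L), complement_bases(mid),
           substr(s, w[2L] + 1L, nchar(s)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Cloning oligos for a spacer
#'
#' Adds the annealing adapters to the 5' ends: sense oligo is
#' `AAAC` + spacer, antisense oligo is `AAAA` + reverse complement of the
#' spacer, so that the annealed duplex carries the correct overhangs.
#'
#' @inheritParams gc_fraction
#' @return data.frame with columns `sense_oligo`, `antisense_oligo`.
#' @export
cloning_oligos <- function(spacer) {
  assert_dna(spacer, "spacer")
  data.frame(sense_oligo = paste0("AAAC", spacer),
             antisense_oligo = paste0("AAAA", revcomp(spacer)))
}

#' Design guide pairs for one transcript
#'
#' @inheritParams enumerate_candidates
#' @return data.frame with one row per pair: `pair_id`, `transcript_id`,
#'   `transcript_class`, `target_start`, `targeting_spacer`,
#'   `mismatch_spacer` plus the four cloning oligos; attribute `shortfall`.
#' @export
design_guides <- function(target, mask = NULL, track = NULL,
                          constraints = design_constraints()) {
  cand <- enumerate_candidates(target, mask, track, constraints)
  sel <- select_guides(cand, target$requested_pairs)
  shortfall <- attr(sel, "shortfall")
  if (shortfall > 0L) {
    warning(sprintf("transcript %s: only %d of %d requested pairs designed",
                    target$transcript_id, nrow(sel), target$requested_pairs))
  }
  if (nrow(sel) == 0L) {
    out <- data.frame(pair_id = character(), transcript_id = character(),
                      transcript_class = character(), target_start = integer(),
                      targeting_spacer = character(),
                      mismatch_spacer = character())
    attr(out, "shortfall") <- shortfall
    return(out)
  }
  tsp <- sel$spacer
  msp <- make_mismatch(tsp, constraints)
  out <- data.frame(
    pair_id = sprintf("%s_p%02d", target$transcript_id, seq_len(nrow(sel))),
    transcript_id = target$transcript_id,
    transcript_class = target$class,
    target_start = sel$target_start,
    targeting_spacer = tsp,
    mismatch_spacer = msp)
  attr(out, "shortfall") <- shortfall
  out
}

#' Build the library design manifest
#'
#' Expands per-transcript guide pairs into the oligo-level manifest that is
#' the guide universe for counting, QC and inference: one row per spacer
#' sequence, two rows (roles `targeting` and `mismatch`) per pair.
#'
#' @param pair_tables list (or single data.frame) of [design_guides()]
#'   outputs.
#' @return data.frame with columns `guide_id`, `pair_id`, `transcript_id`,
#'   `transcript_class`, `role`, `target_start`, `spacer`, `sense_oligo`,
#'   `antisense_oligo`.
#' @export
build_design_manifest <- function(pair_tables) {
  if (is.data.frame(pair_tables)) pair_tables <- list(pair_tables)
  pairs <- data.table::rbindlist(pair_tables)
  if (nrow(pairs) == 0L) stop("no guide pairs to assemble", call. = FALSE)
  long <- data.table::rbindlist(list(
    pairs[, .(pair_id, transcript_id, transcript_class, role = "targeting",
              target_start, spacer = targeting_spacer)],
    pairs[, .(pair_id, transcript_id, transcript_class, role = "mismatch",
              target_start, spacer = mismatch_spacer)]))
  long[, guide_id := paste(pair_id, substr(role, 1L, 1L), sep = "_")]
  if (anyDuplicated(long$spacer)) {
    dup <- long$spacer[duplicated(long$spacer)][1L]
    stop(sprintf("duplicate spacer sequence in manifest (%s...): guides must be unique barcodes",
                 substr(dup, 1L, 12L)), call. = FALSE)
  }
  olig <- cloning_oligos(long$spacer)
  out <- cbind(as.data.frame(long), olig)
  out <- out[order(out$pair_id, out$role == "mismatch"),
             c("guide_id", "pair_id", "transcript_id", "transcript_class",
               "role", "target_start", "spacer", "sense_oligo",
               "antisense_oligo")]
  rownames(out) <- NULL
  out
}
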