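test_that("composition filters match direct counting", {
  expect_equal(gc_fraction(strrep("A", 28)), 0)
  expect_equal(gc_fraction(paste0(strrep("GC", 7), strrep("AT", 7))), 0.5)
  # 11 G/C of 28 sits below the 0.40 bound
  sp11 <- paste0(strrep("G", 11), strrep("A", 3), strrep("T", 14))
  expect_equal(gc_fraction(sp11), 11 / 28, tolerance = 1e-12)
  expect_lt(gc_fraction(sp11), 0.40)
  expect_error(gc_fraction("ACGTN"), "invalid")

  expect_equal(max_homopolymer_run(strrep("ACGT", 7)), 1L)
  expect_equal(max_homopolymer_run(paste0("ACG", "AAAA", strrep("CT", 10), "C")), 4L)
  expect_equal(max_homopolymer_run(paste0("GGGTTTACC", strrep("AG", 9), "T")), 3L)

  expect_equal(max_dinucleotide_repeats(paste0("TTACAC", strrep("GACT", 5), "GA")), 2L)
  expect_equal(max_dinucleotide_repeats(paste0("AGAGAG", strrep("GACT", 5), "TC")), 3L)
  expect_equal(max_dinucleotide_repeats(strrep("ACGT", 7)), 1L)
})

test_that("dinucleotide scan equals a brute-force oracle on random spacers", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_spacer(sample(10:40, 1))
    expect_identical(max_dinucleotide_repeats(s), oracle_dinuc(s), label = s)
  }
})

test_that("mean uniqueness is a strict-threshold window mean", {
  expect_equal(mean_uniqueness(rep(1, 50), c(10, 37)), 1)
  expect_equal(mean_uniqueness(rep(0.7, 28), c(1, 28)), 0.7)
  expect_equal(mean_uniqueness(c(rep(1, 14), rep(0.5, 14)), c(1, 28)), 0.75)
  expect_error(mean_uniqueness(c(rep(1, 10), NA, rep(1, 20)), c(1, 28)),
               "missing")
  expect_error(mean_uniqueness(rep(1, 20), c(1, 28)), "beyond")
})

test_that("candidate enumeration equals a naive brute-force filter", {
  set.seed(77)
  seq100 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                  collapse = "")
  track <- runif(100, 0.5, 1)
  mask <- data.frame(start = c(10L, 60L), end = c(18L, 66L))  # 0-based half-open
  cons <- design_constraints()
  tgt <- transcript_target("tx", seq100, "vlinc", requested_pairs = 5L)

  got <- enumerate_candidates(tgt, mask = mask, track = track,
                              constraints = cons)

  # oracle: re-apply each published rule window by window
  keep <- integer(0)
  for (s in 1:(100 - 28 + 1)) {
    win <- substr(seq100, s, s + 27)
    sp <- revcomp(win)
    ok <- gc_fraction(sp) >= 0.40 && gc_fraction(sp) <= 0.60 &&
      max_homopolymer_run(sp) <= 3 && max_dinucleotide_repeats(sp) <= 2 &&
      mean(track[s:(s + 27)]) > 0.7 &&
      !any(seq(s - 1, s + 26) >= mask$start[1] & seq(s - 1, s + 26) < mask$end[1]) &&
      !any(seq(s - 1, s + 26) >= mask$start[2] & seq(s - 1, s + 26) < mask$end[2])
    if (ok) keep <- c(keep, s)
  }
  expect_identical(got$target_start, keep)
  expect_identical(got$spacer, revcomp(substring(seq100, keep, keep + 27)))
})

test_that("enumeration handles degenerate transcripts", {
  short <- transcript_target("s", strrep("ACGT", 7), "vlinc")
  full_mask <- data.frame(start = 0L, end = 28L)
  expect_identical(nrow(enumerate_candidates(short, mask = full_mask)), 0L)
  # a 28-nt transcript passing all filters gives one candidate at position 1
  ok28 <- transcript_target("ok", revcomp(paste0(strrep("GACT", 3),
                                                 strrep("TCAG", 4))), "vlinc")
  cand <- enumerate_candidates(ok28)
  expect_identical(cand$target_start, 1L)
  expect_warning(tiny <- transcript_target("t", strrep("GACT", 5), "vlinc"),
                 "shorter")
  expect_warning(res <- enumerate_candidates(tiny), "shorter")
  expect_identical(nrow(res), 0L)
})

test_that("guide selection is spacing-optimal and deterministic", {
  # trivial cases
  one <- data.frame(target_start = 5L, window_seq = "w", gc = 0.5,
                    spacer = "s")
  expect_identical(select_guides(one, 1L)$target_start, 5L)
  ten <- data.frame(target_start = seq(1L, 901L, by = 100L),
                    window_seq = "w", gc = 0.5, spacer = letters[1:10])
  expect_identical(select_guides(ten, 10L)$target_start, ten$target_start)

  # 20 candidates, n = 5: compare against exhaustive max-min-gap search
  set.seed(31)
  pos <- sort(sample(1:500, 20))
  cand <- data.frame(target_start = pos, window_seq = "w",
                     gc = runif(20, 0.4, 0.6),
                     spacer = replicate(20, random_spacer()))
  sel <- select_guides(cand, 5L)
  min_gap <- function(p) min(diff(sort(p)))
  combos <- utils::combn(20, 5)
  best <- max(apply(combos, 2, function(ix) min_gap(pos[ix])))
  expect_equal(min_gap(sel$target_start), best)
  expect_identical(nrow(sel), 5L)
  # determinism
  expect_identical(select_guides(cand, 5L), sel)

  # shortfall is flagged, not an error
  few <- select_guides(cand[1:3, ], 5L)
  expect_identical(nrow(few), 3L)
  expect_identical(attr(few, "shortfall"), 2L)
})

test_that("mismatch controls flip exactly the central window", {
  expect_identical(make_mismatch(strrep("A", 28)),
                   paste0(strrep("A", 11), "TTT", strrep("A", 14)))
  set.seed(9)
  for (i in 1:50) {
    sp <- random_spacer()
    mm <- make_mismatch(sp)
    expect_identical(make_mismatch(mm), sp)  # involution
    diff_pos <- which(strsplit(sp, "")[[1]] != strsplit(mm, "")[[1]])
    expect_identical(diff_pos, 12:14)
  }
  expect_error(make_mismatch("ACGTZ..."), "invalid")
})

test_that("cloning oligos carry adapters and exact complementarity", {
  sp <- random_spacer(seed = 4)
  ol <- cloning_oligos(sp)
  expect_identical(ol$sense_oligo, paste0("AAAC", sp))
  expect_identical(ol$antisense_oligo, paste0("AAAA", revcomp(sp)))
  expect_identical(nchar(ol$sense_oligo), 32L)
  expect_identical(nchar(ol$antisense_oligo), 32L)
  expect_identical(revcomp(substr(ol$antisense_oligo, 5, 32)),
                   substr(ol$sense_oligo, 5, 32))
})

test_that("manifest assembly doubles pairs and enforces barcode uniqueness", {
  sm <- tiny_manifest()
  mf <- sm$manifest
  expect_identical(nrow(mf), 2L * length(unique(mf$pair_id)))
  expect_false(anyDuplicated(mf$spacer) > 0)
  # filter idempotence: every emitted targeting spacer passes the filters
  tg <- mf$spacer[mf$role == "targeting"]
  expect_true(all(gc_fraction(tg) >= 0.40 & gc_fraction(tg) <= 0.60))
  expect_true(all(max_homopolymer_run(tg) <= 3L))
  expect_true(all(max_dinucleotide_repeats(tg) <= 2L))
  # mismatch spacers differ from targeting at exactly 12-14
  pr <- split(mf, mf$pair_id)
  for (p in pr) {
    expect_identical(make_mismatch(p$spacer[p$role == "targeting"]),
                     p$spacer[p$role == "mismatch"])
  }
  # one target, one pair -> 2 rows
  tgt <- transcript_target("solo", strrep("GACT", 30), "vlinc",
                           requested_pairs = 1L)
  m1 <- build_design_manifest(design_guides(tgt))
  expect_identical(nrow(m1), 2L)
  # duplicate spacers across pairs are a hard error
  dup <- design_guides(tgt)
  dup2 <- dup
  dup2$pair_id <- "other_p01"
  expect_error(build_design_manifest(list(dup, dup2)), "unique barcodes")
})
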