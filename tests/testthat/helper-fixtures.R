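# Shared fixtures, all generated in code.

# deterministic random spacer over ACGT
random_spacer <- function(n = 28L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a tiny two-transcript manifest built through the real design pipeline
tiny_manifest <- function(seed = 11L, n_vlinc = 2L, pairs = 3L) {
  d <- sim_design(n_vlinc = n_vlinc, pairs_per_vlinc = pairs,
                  n_coding = 1L, pairs_per_coding = 2L,
                  transcript_length = 400L, seed = seed)
  simulate_manifest(d)
}

# small, fast screen design (scaled-down population/depth for unit tests;
# the acceptance suite runs the full-scale defaults)
small_screen_design <- function(seed = 5L, effects = NULL, rho = 0,
                                efficacy_shape = c(8, 2),
                                drugs = data.frame(drug = "mirin",
                                                   survival = 0.9,
                                                   rounds = 4L)) {
  sim_design(n_vlinc = 4L, pairs_per_vlinc = 4L, n_coding = 0L,
             pairs_per_coding = integer(0), drugs = drugs,
             effects = effects, rho = rho,
             efficacy_shape = efficacy_shape,
             population = 5e4, depth = 1e5,
             transcript_length = 400L, seed = seed)
}

# metadata for a hand-built paired library layout
paired_metadata <- function(drugs = "mirin", batches = 3L, splits = 2L) {
  g <- expand.grid(split = seq_len(splits), batch = seq_len(batches),
                   dox = c("plus", "minus"), drug = drugs,
                   stringsAsFactors = FALSE)
  g$library_id <- sprintf("%s_%s_b%d_s%d", g$drug, g$dox, g$batch, g$split)
  g$stage <- "post_challenge"
  g[, c("library_id", "drug", "dox", "batch", "split", "stage")]
}

# independent brute-force max tandem dinucleotide scan (unequal-base units)
oracle_dinuc <- function(s) {
  n <- nchar(s)
  best <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    unit <- substr(s, i, i + 1L)
    if (substr(unit, 1L, 1L) == substr(unit, 2L, 2L)) next
    k <- 1L
    while (i + 2L * k + 1L <= n &&
           substr(s, i + 2L * k, i + 2L * k + 1L) == unit) {
      k <- k + 1L
    }
    best <- max(best, k)
  }
  best
}
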