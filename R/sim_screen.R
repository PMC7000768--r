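# Screen simulator: fully seeded generators for guide manifests, survival
# challenge count tables, amplicon reads and drug-response expression
# tables, each emitting its ground truth so every analysis stage can be
# validated end to end without external data.
#
# Generative model for counts: a cell library with lognormal guide
# abundances is carried through repeated kill/recovery rounds. Each round,
# a cell carrying guide g survives with probability
#   min(1, s_drug * 2^(dox * effect_g / rounds))
# where s_drug is the drug's per-round bottleneck survival and effect_g is
# the total Dox-dependent log2 effect of that guide (targeting guides:
# transcript effect x guide efficacy; mismatch controls: transcript effect
# x rho, the residual mismatch activity, 0 by default). Survivors are
# regrown to the working population size (multinomial resampling = drift),
# and each batch's final population is sequenced as two independent DNA
# splits with multinomial sampling at the stated depth under a gamma
# (negative-binomial) overdispersion layer.

DEFAULT_DRUGS <- data.frame(
  drug = c("imatinib", "mirin", "etoposide"),
  survival = c(0.498, 0.900, 0.094),
  rounds = c(5L, 4L, 1L))

#' Simulation design for a survival-challenge screen
#'
#' Defaults reproduce the reference screen geometry: 25 vlincRNAs with 10
#' guide pairs each plus 10 coding genes with 3-5 pairs (294 pairs, 588
#' guides), three drugs with per-round bottleneck survivals 0.498
#' (imatinib, 5 rounds), 0.900 (mirin, 4 rounds) and 0.094 (etoposide,
#' 1 round), 3 biological batches x 2 DNA splits per drug/Dox arm, and a
#' lognormal initial guide abundance whose spread (sdlog 0.98) matches a
#' 90th/10th-percentile evenness of ~12.
#'
#' @param n_vlinc,pairs_per_vlinc vlincRNA targets and pairs per target.
#' @param n_coding Number of coding targets.
#' @param pairs_per_coding Integer vector recycled over coding targets
#'   (default `c(rep(5, 7), rep(3, 3))`).
#' @param drugs data.frame with columns `drug`, `survival`, `rounds`.
#' @param effects `NULL` (all zero) or data.frame `transcript_id`, `drug`,
#'   `effect` — total Dox-dependent log2 effect on targeting guides
#'   (negative = transcript needed for survival, so its targeting guides
#'   deplete under +Dox).
#' @param efficacy_shape Length-2 Beta shape for per-pair guide efficacy
#'   (default `c(8, 2)`, mean 0.8), or `NULL` for all-1 efficacies.
#' @param rho Residual mismatch-guide activity in `[0, 1]` (default 0;
#'   1 makes effects sequence-independent, hitting both pair members
#'   equally).
#' @param population Working cell population per batch (default 7e5).
#' @param depth Sequencing depth per library (default 1e6 reads).
#' @param abundance_sdlog Lognormal sdlog of initial guide abundance.
#' @param nb_dispersion Negative-binomial dispersion of the sequencing
#'   layer (default 0.05; 0 disables the gamma layer).
#' @param n_batches,n_splits Replication structure (defaults 3 and 2).
#' @param transcript_length Simulated transcript length in nt.
#' @param seed Integer seed recorded in the design and used by all
#'   generators.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(n_vlinc = 25L, pairs_per_vlinc = 10L,
                       n_coding = 10L,
                       pairs_per_coding = c(rep(5L, 7L), rep(3L, 3L)),
                       drugs = DEFAULT_DRUGS,
                       effects = NULL,
                       efficacy_shape = c(8, 2),
                       rho = 0,
                       population = 7e5,
                       depth = 1e6,
                       abundance_sdlog = 0.98,
                       nb_dispersion = 0.05,
                       n_batches = 3L, n_splits = 2L,
                       transcript_length = 600L,
                       seed = 1L) {
  stopifnot(all(drugs$survival > 0), all(drugs$survival <= 1),
            all(drugs$rounds >= 1L), rho >= 0, rho <= 1,
            population > 0, depth > 0, n_batches >= 1L, n_splits >= 1L,
            transcript_length >= 28L)
  pairs_per_coding <- rep_len(as.integer(pairs_per_coding),
                              max(n_coding, 0L))
  structure(list(n_vlinc = as.integer(n_vlinc),
                 pairs_per_vlinc = as.integer(pairs_per_vlinc),
                 n_coding = as.integer(n_coding),
                 pairs_per_coding = pairs_per_coding,
                 drugs = drugs, effects = effects,
                 efficacy_shape = efficacy_shape, rho = rho,
                 population = population, depth = depth,
                 abundance_sdlog = abundance_sdlog,
                 nb_dispersion = nb_dispersion,
                 n_batches = as.integer(n_batches),
                 n_splits = as.integer(n_splits),
                 transcript_length = as.integer(transcript_length),
                 seed = as.integer(seed)),
            class = "sim_design")
}

sim_transcript_ids <- function(design) {
  c(sprintf("vlinc_%02d", seq_len(design$n_vlinc)),
    sprintf("coding_%02d", seq_len(design$n_coding)))
}

#' Simulate a design manifest with ground truth
#'
#' Draws random transcript sequences, runs the real design pipeline
#' ([design_guides()]) on each with a uniform uniqueness track and no
#' repeat mask, and assembles the manifest. Deterministic under the design
#' seed.
#'
#' @param design A [sim_design()].
#' @return List: `manifest` (see [build_design_manifest()]), `targets`
#'   (list of [transcript_target()]s), `efficacy` (data.frame `pair_id`,
#'   `efficacy`).
#' @export
simulate_manifest <- function(design) {
  set.seed(design$seed)
  ids <- sim_transcript_ids(design)
  classes <- rep(c("vlinc", "coding"), c(design$n_vlinc, design$n_coding))
  npairs <- c(rep(design$pairs_per_vlinc, design$n_vlinc),
              design$pairs_per_coding)
  targets <- lapply(seq_along(ids), function(i) {
    sq <- paste(sample(DNA_BASES, design$transcript_length, replace = TRUE),
                collapse = "")
    transcript_target(ids[i], sq, class = classes[i],
                      requested_pairs = npairs[i])
  })
  pair_tables <- lapply(targets, design_guides)
  manifest <- build_design_manifest(pair_tables)
  pair_ids <- unique(manifest$pair_id)
  eff <- if (is.null(design$efficacy_shape)) {
    rep(1, length(pair_ids))
  } else {
    stats::rbeta(length(pair_ids), design$efficacy_shape[1L],
                 design$efficacy_shape[2L])
  }
  list(manifest = manifest, targets = targets,
       efficacy = data.frame(pair_id = pair_ids, efficacy = eff))
}

# per-guide total log2 effect for one drug; targeting guides get
# transcript effect x efficacy, mismatch controls transcript effect x rho
.guide_effects <- function(design, manifest, efficacy, drug) {
  eff_tx <- stats::setNames(rep(0, length(unique(manifest$transcript_id))),
                            unique(manifest$transcript_id))
  if (!is.null(design$effects)) {
    e <- design$effects[design$effects$drug == drug, , drop = FALSE]
    eff_tx[e$transcript_id] <- e$effect
  }
  pe <- stats::setNames(efficacy$efficacy, efficacy$pair_id)
  base <- eff_tx[manifest$transcript_id]
  ifelse(manifest$role == "targeting",
         base * pe[manifest$pair_id],
         base * design$rho)
}

#' Simulate survival-challenge count tables
#'
#' Runs the generative model described at the top of this file for every
#' drug, Dox arm, batch and split of the design, all from a single shared
#' initial guide-abundance profile (one cell library feeds every arm).
#'
#' @param design A [sim_design()].
#' @param sim_manifest Output of [simulate_manifest()] (regenerated from
#'   the design when `NULL`).
#' @return List: `counts` (integer matrix guides x libraries), `metadata`
#'   (library metadata data.frame), `truth` (per transcript x drug
#'   direction and magnitude), `efficacy`, `manifest`, `seed`.
#' @export
simulate_screen_counts <- function(design, sim_manifest = NULL) {
  if (is.null(sim_manifest)) sim_manifest <- simulate_manifest(design)
  manifest <- sim_manifest$manifest
  efficacy <- sim_manifest$efficacy
  set.seed(design$seed + 1L)
  ng <- nrow(manifest)
  weights <- stats::rlnorm(ng, meanlog = 0, sdlog = design$abundance_sdlog)

  libs <- list()
  meta <- list()
  for (di in seq_len(nrow(design$drugs))) {
    drug <- design$drugs$drug[di]
    surv <- design$drugs$survival[di]
    rounds <- design$drugs$rounds[di]
    geff <- .guide_effects(design, manifest, efficacy, drug)
    for (dox in c(1, 0)) {
      p_round <- pmin(1, surv * 2^(dox * geff / rounds))
      for (b in seq_len(design$n_batches)) {
        n <- as.vector(stats::rmultinom(1L, design$population, weights))
        for (r in seq_len(rounds)) {
          n <- stats::rbinom(ng, n, p_round)
          if (sum(n) == 0L) {
            stop("population extinct during challenge: increase `population`",
                 call. = FALSE)
          }
          n <- as.vector(stats::rmultinom(1L, design$population, n))
        }
        for (s in seq_len(design$n_splits)) {
          w <- as.numeric(n)
          if (design$nb_dispersion > 0) {
            shape <- 1 / design$nb_dispersion
            w <- w * stats::rgamma(ng, shape = shape, rate = shape)
          }
          if (sum(w) == 0) {
            stop("no template in sequencing split: increase `population`",
                 call. = FALSE)
          }
          lib_id <- sprintf("%s_%s_b%d_s%d", drug,
                            if (dox == 1) "plus" else "minus", b, s)
          libs[[lib_id]] <- as.vector(stats::rmultinom(1L, design$depth, w))
          meta[[lib_id]] <- data.frame(
            library_id = lib_id, drug = drug,
            dox = if (dox == 1) "plus" else "minus",
            batch = b, split = s, stage = "post_challenge")
        }
      }
    }
  }
  counts <- do.call(cbind, libs)
  rownames(counts) <- manifest$guide_id
  storage.mode(counts) <- "integer"

  tx <- unique(manifest$transcript_id)
  truth <- do.call(rbind, lapply(design$drugs$drug, function(dg) {
    eff <- rep(0, length(tx))
    names(eff) <- tx
    if (!is.null(design$effects)) {
      e <- design$effects[design$effects$drug == dg, , drop = FALSE]
      eff[e$transcript_id] <- e$effect
    }
    data.frame(transcript_id = tx, drug = dg, effect = unname(eff),
               direction = ifelse(eff < 0, "depleted",
                                  ifelse(eff > 0, "enriched", "null")))
  }))
  list(counts = counts, metadata = do.call(rbind, meta), truth = truth,
       efficacy = efficacy, manifest = manifest, seed = design$seed)
}

# synthetic amplicon cassette context flanking the spacer in simulated
# reads; arbitrary fixed sequences, not any real vector
SIM_FLANK5 <- "ACGAAACACCGGATTTAGACTACCTTGGA"
SIM_FLANK3 <- "GTTGGAACCATTCAAAACAGCATAGCAAGTTTAAATAAGGCTAGTCCGTT"
SIM_PAD <- paste(rep("TCGA", 64L), collapse = "")

#' Simulate amplicon reads from a count column
#'
#' Emits one read per counted molecule: 5' flank + spacer + 3' flank,
#' padded to the read length, with a seeded random half of the reads
#' reverse-complemented and the read order shuffled. The exact per-guide
#' multiplicities are returned as the counting oracle.
#'
#' @param counts Named integer vector (names = guide ids).
#' @param manifest Design manifest supplying spacers.
#' @param flank5,flank3 Cassette context around the spacer.
#' @param read_length Output read length (default 150).
#' @param seed Integer seed.
#' @return List: `reads` (character vector), `truth` (named multiplicity
#'   vector, manifest order).
#' @export
simulate_reads <- function(counts, manifest, flank5 = SIM_FLANK5,
                           flank3 = SIM_FLANK3, read_length = 150L,
                           seed = 1L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  set.seed(seed)
  sp <- stats::setNames(manifest$spacer, manifest$guide_id)
  sp <- sp[names(counts)]
  if (anyNA(sp)) stop("counts name a guide absent from the manifest",
                      call. = FALSE)
  templ <- paste0(flank5, sp, flank3, SIM_PAD)
  templ <- substr(templ, 1L, read_length)
  reads <- rep(templ, counts)
  if (length(reads) > 0L) {
    flip <- sample(c(TRUE, FALSE), length(reads), replace = TRUE)
    reads[flip] <- revcomp(reads[flip])
    reads <- reads[sample.int(length(reads))]
  }
  list(reads = reads, truth = counts)
}

#' Simulate a drug-response expression table
#'
#' Generates matched drug/DMSO normalized read counts at two timepoints.
#' Baselines are lognormal; a drug record is
#' `(dmso + 1) * 2^(effect + eps) - 1` so that at zero noise the
#' pseudocounted fold change equals the simulated effect exactly. Ground
#' truth tiers are computed from the noiseless effects with the same rule
#' as [select_targets()].
#'
#' @param genes Character vector of gene ids.
#' @param effects `NULL` (all zero) or data.frame `gene_id`, `drug`,
#'   `effect` (log2, applied at both timepoints).
#' @param drugs Drug condition names.
#' @param timepoints Timepoint labels (default `c("3h", "6h")`).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters.
#' @param noise_sd SD of the per-record log2 noise `eps` (default 0.15;
#'   0 gives exact fold changes).
#' @param seed Integer seed.
#' @return List: `expression` (long data.frame `gene_id`, `condition`,
#'   `timepoint`, `nrc`), `truth` (per-gene tier table as from
#'   [select_targets()]).
#' @export
simulate_expression <- function(genes, effects = NULL,
                                drugs = c("imatinib", "mirin", "etoposide"),
                                timepoints = c("3h", "6h"),
                                baseline_meanlog = log(500),
                                baseline_sdlog = 1,
                                noise_sd = 0.15, seed = 1L) {
  set.seed(seed)
  eff <- expand.grid(gene_id = genes, drug = drugs,
                     stringsAsFactors = FALSE)
  eff$effect <- 0
  if (!is.null(effects)) {
    key <- paste(eff$gene_id, eff$drug)
    ek <- paste(effects$gene_id, effects$drug)
    hit <- match(key, ek)
    eff$effect[!is.na(hit)] <- effects$effect[hit[!is.na(hit)]]
  }
  rows <- list()
  for (tp in timepoints) {
    dmso <- stats::rlnorm(length(genes), baseline_meanlog, baseline_sdlog)
    names(dmso) <- genes
    rows[[paste0("dmso_", tp)]] <- data.frame(
      gene_id = genes, condition = "DMSO", timepoint = tp,
      nrc = unname(dmso))
    for (dg in drugs) {
      e <- eff$effect[eff$drug == dg][match(genes, eff$gene_id[eff$drug == dg])]
      eps <- stats::rnorm(length(genes), 0, noise_sd)
      nrc <- pmax(0, (dmso[genes] + 1) * 2^(e + eps) - 1)
      rows[[paste(dg, tp, sep = "_")]] <- data.frame(
        gene_id = genes, condition = dg, timepoint = tp, nrc = unname(nrc))
    }
  }
  expression <- do.call(rbind, rows)
  rownames(expression) <- NULL
  # noiseless truth: FC == effect at both timepoints
  fc0 <- do.call(rbind, lapply(timepoints, function(tp) {
    data.frame(gene_id = eff$gene_id, drug = eff$drug, timepoint = tp,
               fc = eff$effect)
  }))
  truth <- select_targets(fc0)
  list(expression = expression, truth = truth)
}
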