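# Top-level pipeline and command-line dispatcher. Subcommands mirror the
# analysis stages: simulate, design, count, qc, screen, expression, run.

#' Pipeline configuration
#'
#' @param manifest,metadata,counts,fastq_dir,expression Input paths
#'   (`counts` may be `NULL` when FASTQ inputs are quantified instead;
#'   metadata then needs a `fastq` column of paths relative to
#'   `fastq_dir`).
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance threshold.
#' @param strong_threshold,weak_threshold Expression selection cutoffs.
#' @param seed Seed recorded in the run log.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, metadata, counts = NULL,
                            fastq_dir = NULL, expression = NULL,
                            out_dir = ".", alpha = 0.05,
                            strong_threshold = 0.58, weak_threshold = 0,
                            seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(manifest = manifest, metadata = metadata, counts = counts,
                 fastq_dir = fastq_dir, expression = expression,
                 out_dir = out_dir, alpha = alpha,
                 strong_threshold = strong_threshold,
                 weak_threshold = weak_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the count -> qc -> screen (-> expression) pipeline
#'
#' Stages run in order; a failing stage halts the run with its name. All
#' stage outputs plus a run log (seed, package version, row counts, BH
#' family sizes) are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `counts`, `qc`, `calls` and
#'   (when expression input is configured) `fc`, `tiers`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("cas13screen %s",
                         as.character(utils::packageVersion("cas13screen"))),
                 sprintf("seed\t%d", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  manifest <- stage("read", read_manifest(config$manifest))
  metadata <- stage("read", read_metadata(config$metadata))

  counts <- stage("count", {
    if (!is.null(config$counts)) {
      read_count_matrix(config$counts)
    } else {
      if (!"fastq" %in% names(metadata)) {
        stop("metadata needs a 'fastq' column when no count table is given")
      }
      paths <- file.path(config$fastq_dir %||% ".", metadata$fastq)
      q <- quantify_libraries(stats::setNames(as.list(paths),
                                              metadata$library_id),
                              manifest)
      write_count_matrix(q$raw, file.path(config$out_dir, "counts.tsv"))
      q$raw
    }
  })
  log_lines <- c(log_lines, sprintf("counts\t%d guides x %d libraries",
                                    nrow(counts), ncol(counts)))

  qc <- stage("qc", library_qc(counts, n_designed = nrow(manifest)))
  write_tsv(qc, file.path(config$out_dir, "qc.tsv"))

  calls <- stage("screen", {
    nrm <- apply(counts, 2L, normalize_counts)
    rownames(nrm) <- rownames(counts)
    screen_calls(log2(nrm), metadata, manifest, alpha = config$alpha)
  })
  write_tsv(calls, file.path(config$out_dir, "calls.tsv"))
  fam <- table(calls$drug[calls$tested])
  log_lines <- c(log_lines,
                 sprintf("bh_family\t%s",
                         paste(names(fam), fam, sep = "=", collapse = ",")))

  out <- list(counts = counts, qc = qc, calls = calls)
  if (!is.null(config$expression)) {
    fcres <- stage("expression", {
      fc <- fc_table(read_expression(config$expression))
      tiers <- select_targets(fc, config$strong_threshold,
                              config$weak_threshold)
      list(fc = fc, tiers = tiers)
    })
    write_tsv(fcres$fc, file.path(config$out_dir, "fc.tsv"))
    write_tsv(fcres$tiers, file.path(config$out_dir, "tiers.tsv"))
    out <- c(out, fcres)
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(out)
}

cli_err_user <- function(...) {
  message("error: ", sprintf(...))
  1L
}

.cli_opts <- function(args, spec) {
  parser <- optparse::OptionParser(option_list = spec,
                                   add_help_option = TRUE)
  optparse::parse_args(parser, args = args)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `design`, `count`, `qc`, `screen`,
#' `expression`, `run`; `--version` prints the package version. Invoked by
#' the `inst/exec/cas13screen` script; callable directly for testing.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status: 0 ok, 1 user error, 2 internal error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message("usage: cas13screen <simulate|design|count|qc|screen|expression|run> [options]")
    return(1L)
  }
  if (argv[1L] %in% c("--version", "-V")) {
    cat(as.character(utils::packageVersion("cas13screen")), "\n")
    return(0L)
  }
  cmd <- argv[1L]
  rest <- argv[-1L]
  o <- function(...) optparse::make_option(...)
  run <- function(fn) {
    tryCatch(fn(), user_error = function(e) cli_err_user("%s",
                                                         conditionMessage(e)),
             error = function(e) {
               message("internal error: ", conditionMessage(e))
               2L
             })
  }
  switch(
    cmd,
    simulate = run(function() {
      op <- .cli_opts(rest, list(
        o("--config", type = "character", default = NULL,
          help = "YAML simulation config (sim_design fields)"),
        o("--out-dir", dest = "out_dir", type = "character", default = "."),
        o("--seed", type = "integer", default = 1L),
        o("--reads", action = "store_true", default = FALSE,
          help = "also emit per-library FASTQ")))
      cfg <- if (!is.null(op$config)) yaml::read_yaml(op$config) else list()
      cfg$seed <- cfg$seed %||% op$seed
      design <- do.call(sim_design, cfg)
      sm <- simulate_manifest(design)
      sc <- simulate_screen_counts(design, sm)
      dir.create(op$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(sc$manifest, file.path(op$out_dir, "manifest.tsv"))
      write_count_matrix(sc$counts, file.path(op$out_dir, "counts.tsv"))
      write_tsv(sc$metadata, file.path(op$out_dir, "meta.tsv"))
      write_tsv(sc$truth, file.path(op$out_dir, "truth.tsv"))
      ex <- simulate_expression(unique(sc$manifest$transcript_id),
                                seed = design$seed)
      write_tsv(ex$expression, file.path(op$out_dir, "expression.tsv"))
      if (op$reads) {
        for (lib in colnames(sc$counts)) {
          rd <- simulate_reads(sc$counts[, lib], sc$manifest,
                               seed = design$seed)
          write_fastq(rd$reads,
                      file.path(op$out_dir, paste0(lib, ".fastq.gz")))
        }
      }
      0L
    }),
    design = run(function() {
      op <- .cli_opts(rest, list(
        o("--fasta", type = "character"),
        o("--mask", type = "character", default = NULL),
        o("--uniqueness", type = "character", default = NULL),
        o("--pairs-vlinc", dest = "pairs_vlinc", type = "integer",
          default = 10L),
        o("--pairs-coding", dest = "pairs_coding", type = "integer",
          default = 5L),
        o("--out", type = "character", default = "manifest.tsv")))
      targets <- read_targets_fasta(op$fasta, op$pairs_vlinc,
                                    op$pairs_coding)
      masks <- if (!is.null(op$mask)) read_mask_bed(op$mask) else list()
      tracks <- if (!is.null(op$uniqueness)) read_uniqueness(op$uniqueness)
                else list()
      tabs <- lapply(targets, function(tg) {
        design_guides(tg, mask = masks[[tg$transcript_id]],
                      track = tracks[[tg$transcript_id]])
      })
      write_tsv(build_design_manifest(tabs), op$out)
      0L
    }),
    count = run(function() {
      op <- .cli_opts(rest, list(
        o("--manifest", type = "character"),
        o("--meta", type = "character"),
        o("--fastq-dir", dest = "fastq_dir", type = "character",
          default = "."),
        o("--out", type = "character", default = "counts.tsv")))
      manifest <- read_manifest(op$manifest)
      meta <- read_metadata(op$meta)
      if (!"fastq" %in% names(meta)) {
        stop("metadata needs a 'fastq' column")
      }
      q <- quantify_libraries(
        stats::setNames(as.list(file.path(op$fastq_dir, meta$fastq)),
                        meta$library_id), manifest)
      write_count_matrix(q$raw, op$out)
      0L
    }),
    qc = run(function() {
      op <- .cli_opts(rest, list(
        o("--counts", type = "character"),
        o("--manifest", type = "character"),
        o("--out", type = "character", default = "qc.tsv")))
      counts <- read_count_matrix(op$counts)
      manifest <- read_manifest(op$manifest)
      write_tsv(library_qc(counts, n_designed = nrow(manifest)), op$out)
      0L
    }),
    screen = run(function() {
      op <- .cli_opts(rest, list(
        o("--counts", type = "character", default = NULL,
          help = "raw counts (normalized internally)"),
        o("--log2", type = "character", default = NULL,
          help = "pre-computed log2 abundance matrix"),
        o("--meta", type = "character"),
        o("--manifest", type = "character"),
        o("--alpha", type = "double", default = 0.05),
        o("--out", type = "character", default = "calls.tsv")))
      lg <- if (!is.null(op$log2)) {
        read_count_matrix(op$log2)
      } else if (!is.null(op$counts)) {
        raw <- read_count_matrix(op$counts)
        nrm <- apply(raw, 2L, normalize_counts)
        rownames(nrm) <- rownames(raw)
        log2(nrm)
      } else {
        stop("one of --counts or --log2 is required")
      }
      calls <- screen_calls(lg, read_metadata(op$meta),
                            read_manifest(op$manifest), alpha = op$alpha)
      write_tsv(calls, op$out)
      0L
    }),
    expression = run(function() {
      op <- .cli_opts(rest, list(
        o("--nrc", type = "character"),
        o("--strong", type = "double", default = 0.58),
        o("--weak", type = "double", default = 0),
        o("--out", type = "character", default = "fc.tsv")))
      fc <- fc_table(read_expression(op$nrc))
      write_tsv(fc, op$out)
      write_tsv(select_targets(fc, op$strong, op$weak),
                sub("\\.tsv$", "_tiers.tsv", op$out))
      0L
    }),
    run = run(function() {
      op <- .cli_opts(rest, list(
        o("--manifest", type = "character"),
        o("--meta", type = "character"),
        o("--counts", type = "character", default = NULL),
        o("--fastq-dir", dest = "fastq_dir", type = "character",
          default = NULL),
        o("--expression", type = "character", default = NULL),
        o("--alpha", type = "double", default = 0.05),
        o("--seed", type = "integer", default = 1L),
        o("--out-dir", dest = "out_dir", type = "character", default = ".")))
      run_pipeline(pipeline_config(
        manifest = op$manifest, metadata = op$meta, counts = op$counts,
        fastq_dir = op$fastq_dir, expression = op$expression,
        out_dir = op$out_dir, alpha = op$alpha, seed = op$seed))
      0L
    }),
    cli_err_user("unknown subcommand '%s'", cmd))
}
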