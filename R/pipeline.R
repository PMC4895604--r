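# End-to-end orchestration: candidates -> error-prone sites -> training
# compilation -> forest -> predictions (-> evaluation), from one config.
#
# Every stage writes its output atomically (tempfile + rename), records
# its parameters and counts in manifest.json, and is skipped on re-run
# when its output exists and its recorded parameters are unchanged.

#' Read / write the repeat-copy coordinate table of a synthetic genome
#' @param repeats data.table `family,copy,chrom,start,end`.
#' @param path File path.
#' @export
write_repeats <- function(repeats, path) {
  dt <- data.table::as.data.table(repeats)
  write_hashed_tsv(dt[, c("family", "copy", "chrom", "start", "end"), with = FALSE],
                   path, full_precision = FALSE)
}

#' @rdname write_repeats
#' @export
read_repeats <- function(path) {
  dt <- read_hashed_tsv(path)
  for (j in c("family", "copy", "start", "end"))
    data.table::set(dt, j = j, value = as.integer(dt[[j]]))
  dt
}

# reconstruct a synthetic_genome-shaped object from FASTA + repeat table
genome_from_files <- function(reference, repeats_path = NULL) {
  seqs <- load_reference(reference)
  rep_dt <- if (!is.null(repeats_path)) read_repeats(repeats_path) else
    data.table::data.table(family = integer(0), copy = integer(0),
                           chrom = character(0), start = integer(0),
                           end = integer(0))
  structure(list(sequences = seqs,
                 chrom_lengths = stats::setNames(Biostrings::width(seqs), names(seqs)),
                 repeats = rep_dt, seed = NA_integer_),
            class = "synthetic_genome")
}

#' Load and validate a pipeline run configuration
#'
#' @param config A list or path to a YAML file.  Recognised fields:
#'   `reference`, one of `bam`/`candidates`, `db` (one or two editing-DB
#'   paths), `mes` (either `bed` or simulation parameters incl.
#'   `transcripts` and optional `repeats`), optional `test_exclusion`
#'   and `validation`, `outdir`, parameter blocks `call`, `compile`,
#'   `forest`, and `seeds` (`mes`, `vdb`, `train`).
#' @return The validated config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("reference", "db", "outdir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop_rddkit("config lacks field(s): ", paste(miss, collapse = ", "))
  if (is.null(config$bam) && is.null(config$candidates))
    stop_rddkit("config needs either 'bam' or 'candidates'")
  paths <- c(config$reference, config$bam, config$candidates,
             unlist(config$db), config$mes$bed, config$mes$transcripts,
             config$mes$repeats, config$test_exclusion, config$validation)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths))
    stop_rddkit("config references missing file(s): ",
                paste(missing_paths, collapse = ", "))
  config$call <- utils::modifyList(
    list(min_depth = 10L, min_alt = 2L, min_alt_frac = 0, min_baseq = 13L),
    config$call %||% list())
  config$compile <- utils::modifyList(
    list(match_mode = "class", exclusion_window = 0L),
    config$compile %||% list())
  config$forest <- utils::modifyList(
    list(n_trees = 100L, threshold = 0.5),
    config$forest %||% list())
  config$seeds <- utils::modifyList(
    list(mes = 100L, vdb = 1L, train = 42L),
    config$seeds %||% list())
  config
}

stage_digest <- function(params) {
  paste(deparse(params), collapse = "")
}

#' Run the full prediction pipeline
#'
#' Stages: (1) raw RDD candidate detection from the BAM (or a
#' precomputed candidate table), (2) error-prone-site calculation (or a
#' precomputed BED mask), (3) editing-DB consensus, (4) training-set
#' compilation with test-set exclusion, (5) forest training,
#' (6) prediction on targets, (7) optional evaluation against a
#' validated site list.  All seeds come from the config; two runs with
#' identical config produce byte-identical tabular outputs.
#'
#' @param config List or YAML path (see [load_run_config()]).
#' @param quiet Suppress progress logging.
#' @return Invisible list: paths of the stage outputs plus the in-memory
#'   `evaluation` (when a validation list was supplied) and `manifest`.
#' @export
rdd_run <- function(config, quiet = FALSE) {
  config <- load_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  manifest <- list(package_version = as.character(utils::packageVersion("rddkit")),
                   seeds = config$seeds, stages = list())
  run_stage <- function(name, params, outputs, compute) {
    dig <- stage_digest(params)
    prev <- old_manifest$stages[[name]]
    if (!is.null(prev) && identical(prev$digest, dig) &&
        all(file.exists(file.path(outdir, outputs)))) {
      logf("stage %-12s reused (unchanged parameters)", name)
      manifest$stages[[name]] <<- prev
      return(invisible("reused"))
    }
    res <- tryCatch(compute(), error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), failed_marker)
      stop_rddkit("stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(digest = dig, outputs = outputs,
                                     counts = res)
    logf("stage %-12s done: %s", name,
         paste(names(res), unlist(res), sep = "=", collapse = ", "))
    invisible("computed")
  }

  reference <- load_reference(config$reference)
  cand_path <- file.path(outdir, "candidates.tsv")

  # -- candidates ------------------------------------------------------------
  run_stage("candidates",
            list(bam = config$bam, candidates = config$candidates,
                 call = config$call, vdb = config$seeds$vdb),
            "candidates.tsv", function() {
    if (!is.null(config$candidates)) {
      cand <- read_candidates(config$candidates)
    } else {
      pu <- build_pileup(config$bam, reference,
                         min_baseq = config$call$min_baseq)
      cand <- call_candidates(pu, reference,
                              min_depth = config$call$min_depth,
                              min_alt = config$call$min_alt,
                              min_alt_frac = config$call$min_alt_frac,
                              vdb_seed = config$seeds$vdb)
    }
    write_candidates(cand, cand_path)
    list(candidates = nrow(cand))
  })
  candidates <- read_candidates(cand_path)

  # -- error-prone sites -----------------------------------------------------
  mes_bed <- file.path(outdir, "mes.bed")
  run_stage("mes", list(mes = config$mes, seed = config$seeds$mes),
            "mes.bed", function() {
    if (!is.null(config$mes$bed)) {
      file.copy(config$mes$bed, mes_bed, overwrite = TRUE)
      n <- length(read_bed_regions(mes_bed))
    } else {
      gen <- genome_from_files(reference, config$mes$repeats)
      tx <- read_transcripts(config$mes$transcripts)
      mes <- run_mes(gen, tx,
                     n_trials = config$mes$n_trials %||% 10L,
                     base_seed = config$seeds$mes,
                     k = config$mes$k %||% 1L,
                     rate = config$mes$rate %||% 0.01,
                     n_reads = config$mes$n_reads,
                     read_len = config$mes$read_len %||% 75L,
                     error_rate = config$mes$error_rate %||% 0.005,
                     misplacement = config$mes$misplacement %||% 0.5,
                     mapq0_frac = config$mes$mapq0_frac %||% 0.1)
      write_error_prone_bed(mes$sites, mes_bed, pad = config$mes$pad %||% 0L)
      write_hashed_tsv(mes$report, file.path(outdir, "mes_report.tsv"),
                       full_precision = FALSE)
      n <- nrow(mes$sites)
    }
    list(error_prone_sites = n)
  })
  mes_regions <- read_bed_regions(mes_bed)

  # -- training compilation --------------------------------------------------
  training_path <- file.path(outdir, "training.tsv")
  targets_path <- file.path(outdir, "targets.tsv")
  run_stage("compile", list(db = config$db, compile = config$compile,
                            exclude = config$test_exclusion),
            c("training.tsv", "targets.tsv"), function() {
    dbs <- lapply(unlist(config$db), read_editing_db)
    db <- if (length(dbs) >= 2L) consensus_db(dbs[[1]], dbs[[2]]) else dbs[[1]]
    excl <- if (!is.null(config$test_exclusion))
      read_site_list(config$test_exclusion) else NULL
    comp <- compile_training(candidates, db, mes_regions,
                             test_exclusion = excl,
                             match_mode = config$compile$match_mode,
                             exclusion_window = config$compile$exclusion_window)
    write_training_set(comp$training, training_path)
    write_candidates(comp$targets, targets_path)
    list(positives = sum(comp$training$label == "positive"),
         negatives = sum(comp$training$label == "negative"),
         targets = nrow(comp$targets),
         label_conflict = comp$excluded$label_conflict,
         test_overlap = comp$excluded$test_overlap)
  })
  training <- read_training_set(training_path)
  targets <- read_candidates(targets_path)

  # -- train -----------------------------------------------------------------
  model_path <- file.path(outdir, "model.rds")
  run_stage("train", list(forest = config$forest, seed = config$seeds$train),
            "model.rds", function() {
    model <- rdd_train(training, n_trees = config$forest$n_trees,
                       seed = config$seeds$train)
    save_predictor(model, model_path)
    model$class_counts
  })
  model <- load_predictor(model_path)

  # -- predict ---------------------------------------------------------------
  pred_path <- file.path(outdir, "predictions.tsv")
  run_stage("predict", list(threshold = config$forest$threshold,
                            seed = config$seeds$train),
            "predictions.tsv", function() {
    pred <- rdd_predict(model, targets, threshold = config$forest$threshold)
    write_hashed_tsv(pred, pred_path)
    list(targets = nrow(pred), accepted = sum(pred$accepted))
  })
  predictions <- read_hashed_tsv(pred_path)
  predictions[, "pos" := as.integer(predictions$pos)]
  predictions[, "accepted" := predictions$accepted == "TRUE"]
  predictions[, "prob" := as.numeric(predictions$prob)]

  # -- evaluate --------------------------------------------------------------
  evaluation <- NULL
  report_path <- NULL
  if (!is.null(config$validation)) {
    report_path <- file.path(outdir, "report.tsv")
    run_stage("evaluate", list(validation = config$validation),
              "report.tsv", function() {
      val <- read_site_list(config$validation)
      ev <- evaluate_predictions(predictions, val, n_candidates = nrow(candidates))
      rep <- data.table::data.table(
        metric = c("n_validated_pos", "n_validated_neg", "n_reproduced",
                   "tn", "fn", "n_unmatched", "n_candidates", "n_accepted",
                   "reproduction_rate", "npv", "reduction"),
        value = c(ev$n_validated_pos, ev$n_validated_neg, ev$n_reproduced,
                  ev$tn, ev$fn, ev$n_unmatched, ev$n_candidates,
                  ev$n_accepted, ev$reproduction_rate, ev$npv, ev$reduction))
      write_hashed_tsv(rep, report_path, full_precision = FALSE)
      list(reproduction_rate = ev$reproduction_rate, npv = ev$npv)
    })
    evaluation <- evaluate_predictions(predictions,
                                       read_site_list(config$validation),
                                       n_candidates = nrow(candidates))
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logf("run complete: %s", outdir)
  invisible(list(outdir = outdir, candidates = cand_path, mes = mes_bed,
                 training = training_path, targets = targets_path,
                 model = model_path, predictions = pred_path,
                 report = report_path, evaluation = evaluation,
                 manifest = manifest))
}
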