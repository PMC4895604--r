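# Error-prone-site calculation (the MES method).
#
# Plant random SNVs into simulated reads, align (here: fabricate with
# known truth, or any external BAM), call raw variants, and report every
# called-but-not-planted site as a systematic-artefact location.  Site
# identity is position-level: a planted site called with the wrong allele
# is still "intended".  Pooling over trials uses a recurrence threshold
# (default 1 = union, the most conservative artefact mask).

mes_report_cols <- function() {
  c("mapped_reads", "mapped_sites", "raw_snps",
    "unintended_snps", "caller_passed", "filtered")
}

#' Run one planted-SNV mis-alignment trial
#'
#' One trial of the error-prone-site simulation: plant SNVs at `rate`
#' over the transcribed positions (allele fraction 1), simulate
#' `n_reads`, produce alignments (via the truth-controlled fabricator,
#' or an `aligner` hook returning a BAM path from a FASTQ), call raw
#' variants permissively, and split the calls into intended (planted)
#' and unintended sites.
#'
#' Report-row semantics: `raw_snps` = all raw calls; `unintended_snps` =
#' raw calls at unplanted positions; `caller_passed` = unintended calls
#' that also pass the standard caller thresholds (`pass_min_depth`,
#' `pass_min_alt`, `pass_min_frac`); `filtered` = caller-passed calls
#' surviving the a-priori `region_filter` mask (equal to `caller_passed`
#' when no mask is given).
#'
#' @param genome `synthetic_genome`.
#' @param transcripts `transcript_model`.
#' @param rate Planted-SNV rate over transcribed positions.
#' @param n_reads,read_len,error_rate Read-simulation parameters.
#' @param misplacement,mapq_mis,mapq0_frac Fabricator parameters.
#' @param seed Trial seed (one per trial).
#' @param aligner Optional function(fastq_path) -> BAM path, replacing
#'   the fabricator.
#' @param region_filter Optional `GRanges` of known error-inducible
#'   regions used for the `filtered` column.
#' @param raw_min_depth,raw_min_alt Permissive raw-call thresholds.
#' @param pass_min_depth,pass_min_alt,pass_min_frac Caller-filter
#'   thresholds.
#' @param workdir Directory for the trial BAM.
#' @return List: `called` (site table), `planted`, `unintended`,
#'   `passed`, `filtered_sites`, `report` (one row), `fab` (the
#'   fabricated alignments, when the fabricator was used).
#' @export
run_mes_trial <- function(genome, transcripts, rate = 0.01, n_reads,
                          read_len = 75L, error_rate = 0.005,
                          misplacement = 0.5, mapq_mis = 20L,
                          mapq0_frac = 0.1, seed = 1L, aligner = NULL,
                          region_filter = NULL,
                          raw_min_depth = 4L, raw_min_alt = 2L,
                          pass_min_depth = 10L, pass_min_alt = 2L,
                          pass_min_frac = 0.1,
                          workdir = tempdir()) {
  planted <- plant_variants(genome, transcripts, rate, seed = derive_seed(seed, 1L))
  sim <- simulate_reads(genome, transcripts, planted, n_reads = n_reads,
                        read_len = read_len, error_rate = error_rate,
                        seed = derive_seed(seed, 2L))
  fab <- NULL
  if (is.null(aligner)) {
    bam <- file.path(workdir, sprintf("mes_trial_%d", seed))
    fab <- fabricate_alignments(sim, genome, bam, misplacement = misplacement,
                                mapq_mis = mapq_mis, mapq0_frac = mapq0_frac,
                                seed = derive_seed(seed, 3L))
    bam <- fab$bam
  } else {
    fq <- file.path(workdir, sprintf("mes_trial_%d.fastq", seed))
    write_fastq(sim, fq)
    bam <- aligner(fq)
  }
  pu <- build_pileup(bam, genome$sequences)
  if (!nrow(pu)) stop_rddkit("empty alignment: no pileup columns")
  called <- call_candidates(pu, genome$sequences, min_depth = raw_min_depth,
                            min_alt = raw_min_alt, with_features = FALSE)
  called_dt <- data.table::as.data.table(called)
  pkey <- data.table::as.data.table(planted)[, c("chrom", "pos"), with = FALSE]
  unint <- if (nrow(pkey)) called_dt[!pkey, on = c("chrom", "pos")] else called_dt
  passed <- unint[unint$ReadDepth >= pass_min_depth &
                  unint$n_alt >= pass_min_alt &
                  unint$VAF >= pass_min_frac, ]
  filt <- apply_region_filter(passed, region_filter)
  report <- data.table::data.table(
    mapped_reads = attr(pu, "n_reads", exact = TRUE),
    mapped_sites = data.table::uniqueN(pu, by = c("chrom", "pos")),
    raw_snps = nrow(called_dt),
    unintended_snps = nrow(unint),
    caller_passed = nrow(passed),
    filtered = nrow(filt))
  list(called = called_dt, planted = planted, unintended = unint,
       passed = passed, filtered_sites = filt, report = report, fab = fab)
}

#' Remove sites falling inside known regions
#'
#' @param sites Site table (`chrom`,`pos`, 1-based).
#' @param regions `GRanges` (1-based closed) or `NULL` (identity).
#' @return The surviving rows of `sites`.
#' @export
apply_region_filter <- function(sites, regions = NULL) {
  dt <- data.table::as.data.table(sites)
  if (is.null(regions) || !length(regions) || !nrow(dt)) return(dt)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  hit <- IRanges::overlapsAny(gr, regions)
  dt[!hit, ]
}

#' Pool mis-alignment trials into an error-prone site set
#'
#' A site enters the set iff it was unintended in at least `k` trials;
#' the report gains an `Average` row (arithmetic mean of the trial rows,
#' rounded to the nearest integer).
#'
#' @param trials List of [run_mes_trial()] results.
#' @param k Recurrence threshold (default 1 = union over trials).
#' @return List: `sites` (an `error_prone_sites` data.table
#'   `chrom,pos,trials_observed` with attribute `n_trials`) and `report`
#'   (trial rows plus the Average row, column `trial`).
#' @export
aggregate_trials <- function(trials, k = 1L) {
  if (!length(trials)) stop_rddkit("need at least one trial")
  n_trials <- length(trials)
  if (k < 1L || k > n_trials)
    stop_rddkit("recurrence threshold k must lie in [1, n_trials]")
  un <- data.table::rbindlist(lapply(trials, function(t)
    t$unintended[, c("chrom", "pos"), with = FALSE]))
  sites <- un[, list(trials_observed = .N), by = c("chrom", "pos")]
  sites <- sites[sites$trials_observed >= k, ]
  data.table::setkeyv(sites, c("chrom", "pos"))
  reports <- data.table::rbindlist(lapply(trials, `[[`, "report"))
  avg <- reports[, lapply(.SD, function(x) as.integer(round(mean(x))))]
  reports[, "trial" := sprintf("Trial.%d", seq_len(n_trials))]
  avg[, "trial" := "Average"]
  report <- data.table::rbindlist(list(reports, avg), use.names = TRUE)
  data.table::setcolorder(report, c("trial", mes_report_cols()))
  list(sites = structure(sites, n_trials = n_trials,
                         class = c("error_prone_sites", class(sites))),
       report = report)
}

#' Compute the average row of a trial-report table
#'
#' Arithmetic mean of each count column over the trial rows, rounded to
#' the nearest integer.
#'
#' @param report data.frame/data.table of trial rows with (a subset of)
#'   the six report columns.
#' @return One-row data.table of means.
#' @export
mes_report_average <- function(report) {
  dt <- data.table::as.data.table(report)
  num <- names(dt)[vapply(dt, is.numeric, TRUE)]
  dt[, lapply(.SD, function(x) as.integer(round(mean(x)))), .SDcols = num]
}

#' Run the full error-prone-site calculation
#'
#' `n_trials` independent trials (seeds `base_seed + 1 .. base_seed +
#' n_trials`), pooled with [aggregate_trials()].
#'
#' @inheritParams run_mes_trial
#' @param n_trials Number of trials.
#' @param base_seed Base seed; trial i uses `base_seed + i`.
#' @param k Recurrence threshold for pooling.
#' @param ... Passed to [run_mes_trial()].
#' @return As [aggregate_trials()], plus `trials` (the per-trial results).
#' @export
run_mes <- function(genome, transcripts, n_trials = 10L, base_seed = 1L,
                    k = 1L, ...) {
  trials <- lapply(seq_len(n_trials), function(i)
    run_mes_trial(genome, transcripts, seed = base_seed + i, ...))
  out <- aggregate_trials(trials, k = k)
  out$trials <- trials
  out
}

#' Export an error-prone site set as (optionally padded) BED regions
#'
#' @param sites `error_prone_sites` (or any `chrom`,`pos` table).
#' @param path BED output path.
#' @param pad Pad each site by `pad` bases on both sides before merging.
#' @export
write_error_prone_bed <- function(sites, path, pad = 0L) {
  write_bed_regions(sites_to_regions(sites, pad = pad), path)
}
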