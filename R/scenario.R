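# Self-contained synthetic study builder.
#
# Produces, under one directory, every input the pipeline needs plus the
# full ground truth: a repeat-bearing genome, spliced transcripts, two
# overlapping editing-site databases whose consensus contains the planted
# edits, an RNA-seq BAM with editing at a configurable level and
# engineered repeat mis-placements, a validation site list (held-out
# edits as positives, truth-known artefact columns as negatives), the
# matching test-exclusion list, and a ready-to-run pipeline config.
#
# The defaults are the package's reference study conditions (documented
# in the methods vignette); they are not tuning knobs.

#' Build the reference synthetic RDD study
#'
#' @param dir Output directory (created).
#' @param seed Master seed; all stage seeds derive from it.
#' @param chrom_lengths,repeat_length,repeat_copies,repeat_divergence
#'   Genome geometry.
#' @param n_transcripts Non-repeat transcripts.
#' @param n_edit_sites Planted A-to-I editing sites (non-repeat regions).
#' @param editing_level Per-read edited fraction at each site.
#' @param n_decoy_db_sites Pool of unedited editable positions shared by
#'   the two database files (their overlap lands in the consensus).
#' @param n_reads,read_len,error_rate Read simulation.
#' @param misplacement,mapq_mis,mapq0_frac Mis-alignment engineering.
#' @param validation_fraction Fraction of edit sites (and of artefact
#'   columns) held out as validation/test data.
#' @param mes Config block for the pipeline's error-prone-site stage
#'   (trials, reads per trial, planted-SNV rate).
#' @return List: `config` (YAML path), `truth` (list with `edits`,
#'   `artefact_columns`, `validation`, fabricator truth table), `paths`.
#' @export
simulate_rdd_study <- function(dir, seed = 1L,
                               chrom_lengths = c(chr1 = 12000L, chr2 = 9000L),
                               repeat_length = 1200L, repeat_copies = 2L,
                               repeat_divergence = 0.02,
                               n_transcripts = 14L,
                               n_edit_sites = 80L, editing_level = 0.5,
                               n_decoy_db_sites = 40L,
                               n_reads = 20000L, read_len = 75L,
                               error_rate = 0.005,
                               misplacement = 0.5, mapq_mis = 20L,
                               mapq0_frac = 0.2,
                               validation_fraction = 0.5,
                               mes = list(n_trials = 3L, n_reads = 12000L,
                                          rate = 0.01)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  genome <- make_genome(chrom_lengths,
                        repeats = list(list(length = repeat_length,
                                            copies = repeat_copies,
                                            divergence = repeat_divergence)),
                        seed = derive_seed(seed, 11L))
  transcripts <- make_transcripts(genome, n_transcripts = n_transcripts,
                                  seed = derive_seed(seed, 12L))
  tx_dt <- data.table::as.data.table(transcripts)
  nonrep_tx <- structure(tx_dt[!startsWith(tx_dt$transcript, "rep_tx"), ],
                         class = class(transcripts))

  edits <- plant_editing_sites(genome, nonrep_tx,
                               n_sites = n_edit_sites + n_decoy_db_sites,
                               seed = derive_seed(seed, 13L),
                               editing_level = editing_level)
  edit_dt <- data.table::as.data.table(edits)
  real_idx <- with_seed(derive_seed(seed, 14L),
                        sample.int(nrow(edit_dt), n_edit_sites))
  real_edits <- edit_dt[real_idx]
  decoys <- edit_dt[-real_idx]      # editable but never edited
  real_edits_pv <- structure(data.table::copy(real_edits),
                             type = "A-to-I",
                             class = c("planted_variants", "data.table", "data.frame"))

  sim <- simulate_reads(genome, transcripts, planted = real_edits_pv,
                        n_reads = n_reads, read_len = read_len,
                        error_rate = error_rate,
                        seed = derive_seed(seed, 15L))
  fab <- fabricate_alignments(sim, genome, p("reads"),
                              misplacement = misplacement,
                              mapq_mis = mapq_mis, mapq0_frac = mapq0_frac,
                              seed = derive_seed(seed, 16L))

  # two database files: all real edits plus a random subset of the decoy
  # pool each; the consensus keeps the edits plus the decoy overlap
  to_db <- function(x) {
    out <- x[, c("chrom", "pos", "strand"), with = FALSE]
    out[, "type" := "A-to-I"]
    out
  }
  with_seed(derive_seed(seed, 17L), {
    dA <- decoys[sample.int(nrow(decoys), round(0.75 * nrow(decoys)))]
    dB <- decoys[sample.int(nrow(decoys), round(0.60 * nrow(decoys)))]
  })
  write_editing_db(rbind(to_db(real_edits), to_db(dA)), p("dbA.tsv"))
  write_editing_db(rbind(to_db(real_edits), to_db(dB)), p("dbB.tsv"))

  artefacts <- misalignment_truth_columns(genome, fab, read_len,
                                          min_misplaced = 2L,
                                          exclude = real_edits)

  with_seed(derive_seed(seed, 18L), {
    vp <- real_edits[sample.int(nrow(real_edits),
                                round(validation_fraction * nrow(real_edits)))]
    va <- artefacts[sample.int(nrow(artefacts),
                               round(validation_fraction * nrow(artefacts)))]
  })
  validation <- rbind(
    data.table::data.table(chrom = vp$chrom, pos = vp$pos, label = "positive"),
    data.table::data.table(chrom = va$chrom, pos = va$pos, label = "negative"))
  data.table::setkeyv(validation, c("chrom", "pos"))
  write_site_list(validation, p("validation.tsv"))
  write_site_list(validation[, c("chrom", "pos"), with = FALSE],
                  p("test_exclusion.tsv"))

  write_genome_fasta(genome, p("ref.fa"))
  write_transcripts(transcripts, p("transcripts.tsv"))
  write_repeats(genome$repeats, p("repeats.tsv"))
  write_site_list(real_edits[, c("chrom", "pos", "strand", "ref", "alt"),
                             with = FALSE], p("truth_edits.tsv"))
  write_site_list(artefacts, p("truth_artefacts.tsv"))

  config <- list(
    reference = p("ref.fa"),
    bam = unname(fab$bam),
    db = list(p("dbA.tsv"), p("dbB.tsv")),
    mes = list(transcripts = p("transcripts.tsv"),
               repeats = p("repeats.tsv"),
               n_trials = mes$n_trials, n_reads = mes$n_reads,
               rate = mes$rate, read_len = read_len,
               error_rate = error_rate, misplacement = misplacement,
               mapq0_frac = mapq0_frac),
    test_exclusion = p("test_exclusion.tsv"),
    validation = p("validation.tsv"),
    outdir = p("out"),
    call = list(min_depth = 10L, min_alt = 2L, min_alt_frac = 0.1),
    compile = list(match_mode = "class", exclusion_window = 0L),
    forest = list(n_trees = 100L, threshold = 0.5),
    seeds = list(mes = derive_seed(seed, 20L), vdb = derive_seed(seed, 21L),
                 train = derive_seed(seed, 22L)))
  config_path <- p("config.yaml")
  yaml::write_yaml(config, config_path)
  list(config = config_path,
       truth = list(edits = real_edits, artefact_columns = artefacts,
                    validation = validation, alignment_truth = fab$truth),
       genome = genome, transcripts = transcripts,
       paths = list(dir = dir, bam = unname(fab$bam), reference = p("ref.fa")))
}
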