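# Truth-controlled alignment fabricator.
#
# No aligner is implemented: reads are placed at their (known) true locus,
# except that a configurable fraction of repeat-origin reads is deliberately
# placed on a homologous repeat copy with reduced mapping quality.  Because
# every mis-placement is engineered, downstream artefact columns are known
# exactly — the positive control the error-prone-site machinery is tested
# against.  A hook for a user-supplied external aligner exists via
# [write_fastq()] plus any BAM produced from it.

#' Fabricate a BAM alignment with engineered repeat mis-placements
#'
#' Non-repeat reads are placed at their true origin with `mapq_true`.
#' Reads lying entirely within a single repeat copy (and spanning no exon
#' junction) are, with probability `misplacement`, moved to the same
#' offset on a randomly chosen homologous copy, receiving `mapq_mis`
#' (a fraction `mapq0_frac` of them MAPQ 0).  Spliced reads get `N`
#' CIGAR operations across junctions.
#'
#' @param sim A `simulated_reads` object.
#' @param genome The `synthetic_genome` the reads were simulated from.
#' @param bam Output BAM path (without or with `.bam` extension).
#' @param misplacement Fraction of eligible repeat reads mis-placed, \[0,1\].
#' @param mapq_true,mapq_mis MAPQ for true / mis-placed records.
#' @param mapq0_frac Fraction of mis-placed reads assigned MAPQ 0.
#' @param seed Integer seed (mis-placement choices and read orientation).
#' @return A `fabricated_alignments` list: `bam` (sorted, indexed path)
#'   and `truth` (data.table: one row per read with true and placed locus,
#'   `misplaced`, `mapq`, `flag`).
#' @export
fabricate_alignments <- function(sim, genome, bam,
                                 misplacement = 0, mapq_true = 60L,
                                 mapq_mis = 20L, mapq0_frac = 0.1,
                                 seed = 1L) {
  if (misplacement < 0 || misplacement > 1)
    stop_rddkit("misplacement must lie in [0, 1]")
  n <- nrow(sim$reads)
  cmap <- transcript_coord_map(sim$transcripts)
  rp <- genome$repeats
  qualstr <- paste(rep(rawToChar(as.raw(sim$qual + 33L)), sim$read_len),
                   collapse = "")
  with_seed(seed, {
    rec <- vector("list", n)
    truth <- data.table::data.table(
      id = sim$reads$id, true_chrom = sim$reads$chrom,
      true_pos = sim$reads$gstart,
      placed_chrom = sim$reads$chrom, placed_pos = sim$reads$gstart,
      misplaced = FALSE, mapq = as.integer(mapq_true), flag = 0L)
    for (r in seq_len(n)) {
      rd <- sim$reads[r, ]
      m <- cmap[[rd$transcript]]
      gpos <- sort(m$gpos[rd$spliced_start:(rd$spliced_start + sim$read_len - 1L)])
      brk <- which(diff(gpos) > 1L)
      blk_start <- gpos[c(1L, brk + 1L)]
      blk_end <- gpos[c(brk, length(gpos))]
      blk_len <- blk_end - blk_start + 1L
      chrom <- rd$chrom
      pos <- gpos[1L]
      mapq <- as.integer(mapq_true)
      single_block <- length(blk_len) == 1L
      if (misplacement > 0 && single_block && nrow(rp)) {
        ins_idx <- which(rp$chrom == chrom & rp$start <= pos &
                         rp$end >= gpos[length(gpos)])
        inside <- rp[ins_idx]
        if (nrow(inside) == 1L && stats::runif(1) < misplacement) {
          fam_idx <- which(rp$family == inside$family & rp$copy != inside$copy)
          fam <- rp[fam_idx]
          if (nrow(fam)) {
            tgt <- fam[sample.int(nrow(fam), 1L), ]
            off <- pos - inside$start
            chrom <- tgt$chrom
            pos <- tgt$start + off
            mapq <- if (stats::runif(1) < mapq0_frac) 0L else as.integer(mapq_mis)
            truth[r, c("placed_chrom", "placed_pos", "misplaced", "mapq") :=
                      list(chrom, pos, TRUE, mapq)]
          }
        }
      }
      truth[r, "mapq" := mapq]
      cigar <- if (single_block) paste0(sim$read_len, "M") else {
        gaps <- blk_start[-1L] - blk_end[-length(blk_end)] - 1L
        paste0(paste0(blk_len[-length(blk_len)], "M", gaps, "N",
                      collapse = ""), blk_len[length(blk_len)], "M")
      }
      flag <- if (stats::runif(1) < 0.5) 16L else 0L  # non-stranded library
      truth[r, "flag" := flag]
      rec[[r]] <- paste(rd$id, flag, chrom, pos, mapq, cigar, "*", 0L, 0L,
                        rd$seq, qualstr, sep = "\t")
    }
    sam <- tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             paste0("@SQ\tSN:", names(genome$chrom_lengths),
                    "\tLN:", genome$chrom_lengths))
    writeLines(c(hdr, unlist(rec)), sam)
    dest <- sub("\\.bam$", "", bam)
    out <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    structure(list(bam = out, truth = truth), class = "fabricated_alignments")
  })
}

#' Truth set of mis-alignment-induced variant columns
#'
#' From the fabricator's truth table and the genome's repeat record,
#' returns the genomic columns at which mis-placed reads present a
#' non-reference base: inter-copy difference positions, restricted to
#' positions covered by at least `min_misplaced` mis-placed reads, with
#' any positions in `exclude` (e.g. planted variant sites, which are
#' "intended") removed.
#'
#' @param genome `synthetic_genome`.
#' @param fab `fabricated_alignments`.
#' @param read_len Read length used in simulation.
#' @param min_misplaced Minimum mis-placed-read coverage for a column to
#'   count as truth.
#' @param exclude Optional site table (`chrom`,`pos`) to drop.
#' @return data.table `chrom,pos,n_misplaced`.
#' @export
misalignment_truth_columns <- function(genome, fab, read_len,
                                       min_misplaced = 2L, exclude = NULL) {
  diffs <- repeat_diff_positions(genome)
  tr <- fab$truth[fab$truth$misplaced, ]
  if (!nrow(tr) || !nrow(diffs))
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  n_misplaced = integer(0)))
  cov <- tr[, list(pos = seq.int(placed_pos, placed_pos + read_len - 1L)),
            by = c("id", "placed_chrom")]
  data.table::setnames(cov, "placed_chrom", "chrom")
  cov <- cov[, list(n_misplaced = .N), by = c("chrom", "pos")]
  out <- cov[diffs[, c("chrom", "pos"), with = FALSE],
             on = c("chrom", "pos"), nomatch = NULL]
  out <- out[out$n_misplaced >= min_misplaced, ]
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- data.table::as.data.table(exclude)[, c("chrom", "pos"), with = FALSE]
    out <- out[!ex, on = c("chrom", "pos")]
  }
  unique(out, by = c("chrom", "pos"))[order(chrom, pos)]
}
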