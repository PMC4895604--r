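# Pileup construction and raw RDD candidate detection.
#
# The pileup keeps one row per (read, reference position) observation with
# everything the attribute calculations need: base, base quality, MAPQ,
# strand, 0-based offset from the 5' read start, distance to the nearest
# read end, and read length.  Built from the CIGAR-space mapping of
# GenomicAlignments rather than Rsamtools::pileup(), which does not expose
# per-observation detail.

#' Load a reference FASTA (or pass a DNAStringSet through)
#' @param reference Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @return A `DNAStringSet`, names truncated at the first whitespace.
#' @export
load_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  reference
}

#' Build a per-observation pileup from a sorted, indexed BAM
#'
#' Skips reads flagged unmapped, secondary or duplicate; skips bases with
#' quality below `min_baseq` (default 13) and `N` bases; `N` CIGAR gaps
#' contribute no observation.
#'
#' @param bam Path to a sorted, indexed BAM file.
#' @param reference FASTA path or `DNAStringSet`; sequence names and
#'   lengths must cover the BAM header.
#' @param region Optional [GenomicRanges::GRanges] restriction.
#' @param min_baseq Minimum base quality for an observation.
#' @return An `rdd_pileup` data.table keyed by `(chrom,pos)` with columns
#'   `chrom,pos,base,qual,mapq,strand,offset5p,dist_end,read_len`, plus
#'   attributes `n_reads` (records used) and `min_baseq`.
#' @export
build_pileup <- function(bam, reference, region = NULL, min_baseq = 13L) {
  reference <- load_reference(reference)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  bad <- setdiff(names(hdr), names(reference))
  if (length(bad))
    stop_rddkit("BAM chromosome(s) absent from reference: ",
                paste(bad, collapse = ", "))
  mism <- names(hdr)[hdr != Biostrings::width(reference)[match(names(hdr), names(reference))]]
  if (length(mism))
    stop_rddkit("reference length mismatch for: ", paste(mism, collapse = ", "))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- if (is.null(region))
    Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "seq", "qual"))
  else
    Rsamtools::ScanBamParam(flag = flag, what = c("mapq", "seq", "qual"),
                            which = region)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  empty <- data.table::data.table(
    chrom = character(0), pos = integer(0), base = character(0),
    qual = integer(0), mapq = integer(0), strand = character(0),
    offset5p = integer(0), dist_end = integer(0), read_len = integer(0))
  if (!length(gal)) {
    data.table::setkeyv(empty, c("chrom", "pos"))
    return(structure(empty, n_reads = 0L, min_baseq = min_baseq,
                     class = c("rdd_pileup", class(empty))))
  }
  cig <- GenomicAlignments::cigar(gal)
  ops <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = ops, pos = GenomicAlignments::start(gal))
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = ops)
  nop <- S4Vectors::elementNROWS(rr)
  op_read <- rep(seq_along(gal), nop)
  rstart <- unlist(IRanges::start(rr), use.names = FALSE)
  qstart <- unlist(IRanges::start(qr), use.names = FALSE)
  w <- unlist(IRanges::width(rr), use.names = FALSE)
  row_read <- rep(op_read, w)
  refpos <- sequence(w, from = rstart)
  qpos <- sequence(w, from = qstart)
  seqs <- as.character(S4Vectors::mcols(gal)$seq)
  rlen <- GenomicAlignments::qwidth(gal)
  offs <- cumsum(c(0L, rlen[-length(rlen)]))
  all_bases <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  all_quals <- unlist(methods::as(S4Vectors::mcols(gal)$qual, "IntegerList"),
                      use.names = FALSE)
  flat <- offs[row_read] + qpos
  is_rev <- as.character(GenomicAlignments::strand(gal)) == "-"
  read_len_row <- rlen[row_read]
  dt <- data.table::data.table(
    chrom = as.character(GenomicAlignments::seqnames(gal))[row_read],
    pos = refpos,
    base = all_bases[flat],
    qual = all_quals[flat],
    mapq = S4Vectors::mcols(gal)$mapq[row_read],
    strand = ifelse(is_rev[row_read], "-", "+"),
    offset5p = ifelse(is_rev[row_read], read_len_row - qpos, qpos - 1L),
    dist_end = pmin(qpos - 1L, read_len_row - qpos),
    read_len = read_len_row)
  dt <- dt[dt$qual >= min_baseq & dt$base != "N", ]
  data.table::setkeyv(dt, c("chrom", "pos"))
  structure(dt, n_reads = length(gal), min_baseq = min_baseq,
            class = c("rdd_pileup", class(dt)))
}

#' Detect raw RDD candidate sites from a pileup
#'
#' A position is a candidate when depth >= `min_depth` and a single
#' non-reference base occurs at least `min_alt` times with fraction at
#' least `min_alt_frac`; the variant allele is the modal non-reference
#' base (alphabetical tie-break).  Positions where two non-reference
#' bases each reach `min_alt` are dropped as multi-allelic and counted.
#'
#' @param pileup An `rdd_pileup`.
#' @param reference FASTA path or `DNAStringSet`.
#' @param min_depth,min_alt,min_alt_frac Candidate thresholds.
#' @param with_features Compute the 15 attributes per candidate.
#' @param vdb_m,vdb_seed Monte-Carlo draws and seed for the VDB attribute.
#' @return A `candidate_table` (see [write_candidates()]) with attributes
#'   `provenance` and `n_multiallelic_dropped`.  When
#'   `with_features = FALSE` the 15 attribute columns are `NA` except
#'   `ReadDepth` and `VAF`.
#' @export
call_candidates <- function(pileup, reference, min_depth = 10L, min_alt = 2L,
                            min_alt_frac = 0, with_features = TRUE,
                            vdb_m = 1000L, vdb_seed = 1L) {
  reference <- load_reference(reference)
  pu <- data.table::as.data.table(pileup)
  prov <- sprintf("call_candidates min_depth=%d min_alt=%d min_alt_frac=%g min_baseq=%s",
                  min_depth, min_alt, min_alt_frac,
                  attr(pileup, "min_baseq", exact = TRUE) %||% "NA")
  if (!nrow(pu)) {
    out <- empty_candidate_table()
    data.table::setkeyv(out, c("chrom", "pos"))
    return(structure(out, provenance = prov, n_multiallelic_dropped = 0L,
                     class = c("candidate_table", class(out))))
  }
  counts <- pu[, list(n = .N), by = c("chrom", "pos", "base")]
  ref_chars <- lapply(as.character(reference), function(s) strsplit(s, "")[[1]])
  counts[, "ref" := mapply(function(ch, p) ref_chars[[ch]][p], counts$chrom, counts$pos)]
  depth <- counts[, list(depth = sum(n)), by = c("chrom", "pos")]
  nonref <- counts[counts$base != counts$ref, ]
  data.table::setorderv(nonref, c("chrom", "pos", "n", "base"), c(1L, 1L, -1L, 1L))
  top <- nonref[!duplicated(nonref[, c("chrom", "pos")]), ]
  n_multi <- nonref[nonref$n >= min_alt,
                    list(k = .N), by = c("chrom", "pos")]
  multi <- n_multi[n_multi$k >= 2L, c("chrom", "pos")]
  cand <- top[depth, on = c("chrom", "pos"), nomatch = NULL]
  cand <- cand[cand$depth >= min_depth & cand$n >= min_alt &
               cand$n / cand$depth >= min_alt_frac, ]
  n_dropped <- nrow(cand[multi, on = c("chrom", "pos"), nomatch = NULL])
  cand <- cand[!multi, on = c("chrom", "pos")]
  refn <- counts[counts$base == counts$ref, c("chrom", "pos", "n")]
  data.table::setnames(refn, "n", "n_ref")
  cand <- refn[cand, on = c("chrom", "pos")]
  cand[is.na(cand$n_ref), "n_ref" := 0L]
  out <- cand[, list(chrom = chrom, pos = pos, ref = ref, alt = base,
                     n_ref = n_ref, n_alt = n)]
  data.table::setkeyv(out, c("chrom", "pos"))
  feat <- matrix(NA_real_, nrow(out), 15L,
                 dimnames = list(NULL, rdd_feature_names()))
  if (nrow(out)) {
    pu_key <- data.table::setkeyv(data.table::copy(pu), c("chrom", "pos"))
    for (i in seq_len(nrow(out))) {
      obs <- pu_key[list(out$chrom[i], out$pos[i])]
      if (with_features) {
        feat[i, ] <- compute_features(obs, out$ref[i], out$alt[i],
                                      vdb_m = vdb_m, vdb_seed = vdb_seed)
      } else {
        feat[i, "ReadDepth"] <- nrow(obs)
        feat[i, "VAF"] <- out$n_alt[i] / nrow(obs)
      }
    }
  }
  out <- cbind(out, data.table::as.data.table(feat))
  data.table::setkeyv(out, c("chrom", "pos"))
  structure(out, provenance = prov, n_multiallelic_dropped = n_dropped,
            class = c("candidate_table", class(out)))
}
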