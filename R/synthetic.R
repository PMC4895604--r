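# Synthetic study generator.
#
# Builds, with full truth annotation and no external data: a genome carrying
# near-identical repeat families (the substrate of systematic mis-alignment
# artefacts), spliced transcript models, planted variant sets (DNA-level
# SNVs at allele fraction 1, or RNA-level edits at a configurable editing
# level), and simulated single-end reads with independent per-base
# sequencing errors.  Everything is deterministic under a fixed seed.

#' Generate a synthetic genome with near-identical repeat families
#'
#' Random sequences per chromosome, with each repeat family planted as
#' `copies` near-identical instances of a common template: every copy
#' diverges from the template at exactly `round(divergence * length)`
#' positions chosen independently per copy.  Copy coordinates and the
#' per-copy divergence offsets are recorded, so inter-copy difference
#' positions — the truth set for mis-alignment artefact columns — are
#' recoverable exactly.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param repeats List of repeat-family specs, each a list with `length`,
#'   `copies` (>= 2 for artefact fixtures) and `divergence` in \[0, 0.2\].
#' @param seed Integer seed; same seed, same genome.
#' @return A `synthetic_genome`: list with `sequences`
#'   ([Biostrings::DNAStringSet]), `repeats` (copy coordinate table),
#'   `seed`, `chrom_lengths`.
#' @export
make_genome <- function(chrom_lengths, repeats = list(), seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)))
  for (rs in repeats) {
    if (is.null(rs$divergence) || rs$divergence < 0 || rs$divergence > 0.2)
      stop_rddkit("repeat divergence must lie in [0, 0.2]")
    if (is.null(rs$copies) || rs$copies < 1L)
      stop_rddkit("repeat family needs >= 1 copy")
  }
  with_seed(seed, {
    seqs <- lapply(chrom_lengths, function(n)
      paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""))
    # allocate copy slots round-robin across chromosomes, left to right,
    # separated by untouched spacer sequence
    copy_tab <- list()
    cursor <- stats::setNames(rep(1L, length(chrom_lengths)), names(chrom_lengths))
    fam_id <- 0L
    for (rs in repeats) {
      fam_id <- fam_id + 1L
      len <- as.integer(rs$length)
      ndiv <- round(rs$divergence * len)
      template <- sample(DNA_BASES, len, replace = TRUE)
      for (cp in seq_len(rs$copies)) {
        chrom <- names(chrom_lengths)[(cp - 1L) %% length(chrom_lengths) + 1L]
        start <- cursor[[chrom]] + 200L   # spacer before each copy
        end <- start + len - 1L
        if (end + 200L > chrom_lengths[[chrom]])
          stop_rddkit("genome too short for requested repeats on ", chrom)
        cursor[[chrom]] <- end + 1L
        copy_seq <- template
        div_off <- integer(0)
        if (ndiv > 0L) {
          div_off <- sort(sample.int(len, ndiv))
          copy_seq[div_off] <- vapply(copy_seq[div_off], function(b)
            sample(setdiff(DNA_BASES, b), 1L), "")
        }
        s <- seqs[[chrom]]
        seqs[[chrom]] <- paste0(substr(s, 1L, start - 1L),
                                paste(copy_seq, collapse = ""),
                                substr(s, end + 1L, nchar(s)))
        copy_tab[[length(copy_tab) + 1L]] <- data.table::data.table(
          family = fam_id, copy = cp, chrom = chrom,
          start = start, end = end,
          div_offsets = list(div_off))
      }
    }
    repeats_dt <- if (length(copy_tab)) data.table::rbindlist(copy_tab) else
      data.table::data.table(family = integer(0), copy = integer(0),
                             chrom = character(0), start = integer(0),
                             end = integer(0), div_offsets = list())
    structure(list(
      sequences = Biostrings::DNAStringSet(unlist(seqs)),
      repeats = repeats_dt,
      chrom_lengths = chrom_lengths,
      seed = seed), class = "synthetic_genome")
  })
}

#' Inter-copy difference positions of a repeat family
#'
#' Genomic positions (on each copy) where the copy's base differs from
#' another copy of the same family — exactly the columns at which a read
#' mis-placed between the two copies presents a non-reference base.
#'
#' @param genome A `synthetic_genome`.
#' @param family Family id (default: all families).
#' @return data.table `chrom,pos,copy,other_copy` of difference positions.
#' @export
repeat_diff_positions <- function(genome, family = NULL) {
  rp <- genome$repeats
  if (!is.null(family)) rp <- rp[rp$family %in% family, ]
  out <- list()
  for (f in unique(rp$family)) {
    fam <- rp[rp$family == f, ]
    n <- nrow(fam)
    if (n < 2L) next
    seqs <- lapply(seq_len(n), function(i)
      strsplit(as.character(Biostrings::subseq(
        genome$sequences[[fam$chrom[i]]], fam$start[i], fam$end[i])), "")[[1]])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- which(seqs[[i]] != seqs[[j]])
      if (length(d))
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = fam$chrom[i], pos = fam$start[i] + d - 1L,
          copy = fam$copy[i], other_copy = fam$copy[j], family = f)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  copy = integer(0), other_copy = integer(0),
                                  family = integer(0)))
  unique(data.table::rbindlist(out), by = c("chrom", "pos", "other_copy"))
}

#' Generate a spliced transcript annotation over a synthetic genome
#'
#' Lays non-overlapping multi-exon transcripts (random strand) over the
#' non-repeat portion of the genome and, when `cover_repeats`, one
#' single-exon `+`-strand transcript spanning each repeat copy (plus
#' flanks), so repeat regions are transcribed and can generate
#' mis-alignable reads.
#'
#' @param genome `synthetic_genome`.
#' @param n_transcripts Number of non-repeat transcripts.
#' @param exon_length,intron_length Ranges (length-2 integer vectors).
#' @param max_exons Maximum exons per transcript.
#' @param cover_repeats Add one transcript per repeat copy.
#' @param repeat_flank Flank added around repeat-copy transcripts.
#' @param seed Integer seed.
#' @return A `transcript_model`: data.table
#'   `transcript,chrom,strand,exon_rank,start,end` (1-based inclusive).
#' @export
make_transcripts <- function(genome, n_transcripts = 12L,
                             exon_length = c(150L, 400L),
                             intron_length = c(80L, 300L),
                             max_exons = 3L, cover_repeats = TRUE,
                             repeat_flank = 60L, seed = 1L) {
  with_seed(seed, {
    occupied <- lapply(genome$chrom_lengths, function(n) logical(n))
    res <- list()
    tid <- 0L
    if (cover_repeats && nrow(genome$repeats)) {
      for (i in seq_len(nrow(genome$repeats))) {
        rp <- genome$repeats[i, ]
        tid <- tid + 1L
        s <- max(1L, rp$start - repeat_flank)
        e <- min(genome$chrom_lengths[[rp$chrom]], rp$end + repeat_flank)
        res[[tid]] <- data.table::data.table(
          transcript = sprintf("rep_tx%02d", tid), chrom = rp$chrom,
          strand = "+", exon_rank = 1L, start = s, end = e)
        occupied[[rp$chrom]][s:e] <- TRUE
      }
    }
    tries <- 0L
    made <- 0L
    while (made < n_transcripts && tries < n_transcripts * 50L) {
      tries <- tries + 1L
      chrom <- sample(names(genome$chrom_lengths), 1L)
      n_ex <- sample.int(max_exons, 1L)
      ex_len <- sample(seq(exon_length[1], exon_length[2]), n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L)
        sample(seq(intron_length[1], intron_length[2]), n_ex - 1L, replace = TRUE)
      else integer(0)
      total <- sum(ex_len) + sum(in_len)
      L <- genome$chrom_lengths[[chrom]]
      if (total + 2L >= L) next
      start <- sample.int(L - total, 1L)
      ends <- start + cumsum(ex_len) + c(0L, cumsum(in_len))[seq_len(n_ex)] - 1L
      starts <- ends - ex_len + 1L
      span <- start:(ends[n_ex])
      if (any(occupied[[chrom]][span])) next
      occupied[[chrom]][span] <- TRUE
      made <- made + 1L
      tid <- tid + 1L
      res[[tid]] <- data.table::data.table(
        transcript = sprintf("tx%02d", made), chrom = chrom,
        strand = sample(c("+", "-"), 1L),
        exon_rank = seq_len(n_ex), start = starts, end = ends)
    }
    if (made < n_transcripts)
      stop_rddkit("could not place ", n_transcripts, " transcripts; genome too small")
    tm <- data.table::rbindlist(res)
    structure(tm, class = c("transcript_model", class(tm)))
  })
}

#' Write / read a transcript model TSV
#' @param transcripts A `transcript_model`.
#' @param path File path.
#' @export
write_transcripts <- function(transcripts, path) {
  write_hashed_tsv(data.table::as.data.table(transcripts), path,
                   full_precision = FALSE)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  dt <- read_hashed_tsv(path)
  for (j in c("exon_rank", "start", "end"))
    data.table::set(dt, j = j, value = as.integer(dt[[j]]))
  structure(dt, class = c("transcript_model", class(dt)))
}

# ordered genomic positions of the spliced transcript, 5'->3' on the
# transcript strand (descending genomic order for "-")
transcript_coord_map <- function(transcripts) {
  tm <- data.table::as.data.table(transcripts)
  out <- list()
  for (tx in unique(tm$transcript)) {
    e <- tm[tm$transcript == tx, ][order(exon_rank)]
    gpos <- unlist(lapply(seq_len(nrow(e)), function(i) e$start[i]:e$end[i]))
    if (e$strand[1] == "-") gpos <- rev(gpos)
    out[[tx]] <- list(chrom = e$chrom[1], strand = e$strand[1], gpos = gpos)
  }
  out
}

# transcribed genomic positions, unique per (chrom,pos)
transcribed_positions <- function(transcripts) {
  tm <- data.table::as.data.table(transcripts)
  dt <- tm[, list(pos = unlist(Map(seq.int, start, end))), by = "chrom"]
  unique(dt, by = c("chrom", "pos"))
}

#' Plant random variants over the transcribed positions
#'
#' Draws `round(rate * n_eligible)` sites uniformly without replacement
#' from the transcribed genomic positions, with the variant allele uniform
#' over the three non-reference bases.  At allele fraction `vaf = 1` every
#' overlapping read carries the variant (a DNA-level SNV, as in the
#' error-prone-site simulation); `vaf < 1` models an RNA-level edit.
#'
#' @param genome `synthetic_genome`.
#' @param transcripts `transcript_model`.
#' @param rate Fraction of transcribed positions to mutate, in (0, 0.1).
#' @param seed Integer seed.
#' @param vaf Per-read carrier probability of the variant allele.
#' @return A `planted_variants` data.table `chrom,pos,ref,alt,vaf` with
#'   attributes `rate`, `seed`.
#' @export
plant_variants <- function(genome, transcripts, rate, seed = 1L, vaf = 1) {
  if (rate <= 0 || rate >= 0.1)
    stop_rddkit("rate must lie in (0, 0.1)")
  elig <- transcribed_positions(transcripts)
  n <- round(rate * nrow(elig))
  with_seed(seed, {
    if (n == 0L) {
      out <- data.table::data.table(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    vaf = numeric(0))
    } else {
      idx <- sample.int(nrow(elig), n)
      out <- elig[idx]
      out[, "ref" := mapply(function(ch, p)
        as.character(Biostrings::subseq(genome$sequences[[ch]], p, p)),
        out$chrom, out$pos)]
      out[, "alt" := vapply(out$ref, function(r)
        sample(setdiff(DNA_BASES, r), 1L), "")]
      out[, "vaf" := vaf]
      data.table::setkeyv(out, c("chrom", "pos"))
    }
    structure(out, rate = rate, seed = seed,
              class = c("planted_variants", class(out)))
  })
}

#' Plant RNA-editing sites compatible with an edit type
#'
#' Chooses transcribed positions whose base reads as the editable base on
#' the transcript strand (A for A-to-I, C for C-to-U) and plants the edit
#' at a per-read `editing_level`.  The companion [as_editing_db()] turns
#' the truth set into a database table for the training compiler.
#'
#' @inheritParams plant_variants
#' @param n_sites Number of editing sites to plant.
#' @param editing_level Fraction of reads carrying the edited base.
#' @param type `"A-to-I"` or `"C-to-U"`.
#' @return A `planted_variants` table with an extra `strand` column.
#' @export
plant_editing_sites <- function(genome, transcripts, n_sites, seed = 1L,
                                editing_level = 0.5, type = "A-to-I") {
  tm <- data.table::as.data.table(transcripts)
  elig <- tm[, list(pos = unlist(Map(seq.int, start, end))),
             by = c("chrom", "strand")]
  elig <- unique(elig, by = c("chrom", "pos"))
  base_plus <- if (type == "A-to-I") c("A", "T") else c("C", "G")  # +,- strand
  alt_plus <- if (type == "A-to-I") c("G", "C") else c("T", "A")
  elig[, "ref" := mapply(function(ch, p)
    as.character(Biostrings::subseq(genome$sequences[[ch]], p, p)),
    elig$chrom, elig$pos)]
  ok <- (elig$strand == "+" & elig$ref == base_plus[1]) |
        (elig$strand == "-" & elig$ref == base_plus[2])
  elig <- elig[ok]
  if (nrow(elig) < n_sites)
    stop_rddkit("only ", nrow(elig), " editable positions available")
  with_seed(seed, {
    out <- elig[sample.int(nrow(elig), n_sites)]
    out[, "alt" := ifelse(out$strand == "+", alt_plus[1], alt_plus[2])]
    out[, "vaf" := editing_level]
    data.table::setkeyv(out, c("chrom", "pos"))
    structure(out[, c("chrom", "pos", "strand", "ref", "alt", "vaf"), with = FALSE],
              type = type, seed = seed,
              class = c("planted_variants", class(out)))
  })
}

#' Convert a planted editing-site truth set to an editing-DB table
#' @param edits Output of [plant_editing_sites()].
#' @param source_tag Provenance label.
#' @return An `editing_db`.
#' @export
as_editing_db <- function(edits, source_tag = "synthetic") {
  dt <- data.table::as.data.table(edits)
  out <- dt[, c("chrom", "pos", "strand"), with = FALSE]
  out[, "type" := attr(edits, "type", exact = TRUE) %||% "A-to-I"]
  data.table::setkeyv(out, c("chrom", "pos", "strand"))
  structure(out, source_tag = source_tag, n_duplicates = 0L,
            class = c("editing_db", class(out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate single-end reads from spliced transcripts
#'
#' Reads are sampled uniformly over transcripts (optionally weighted) and
#' uniformly over start positions within the spliced sequence.  Planted
#' variants are substituted per read with probability `vaf`; independent
#' per-base sequencing errors are added at `error_rate`; base qualities
#' encode the true error model (Q = -10 log10 e, capped at Q40).  Read
#' sequences are stored in forward-genome orientation with a full
#' per-base genomic-origin record, so truth is exact downstream.
#'
#' @param genome `synthetic_genome`.
#' @param transcripts `transcript_model`.
#' @param planted `planted_variants` (or NULL); multiple sets may be
#'   supplied as a list and are applied jointly.
#' @param n_reads Number of reads (> 0).
#' @param read_len Read length; must not exceed the shortest spliced
#'   transcript.
#' @param error_rate Per-base substitution error probability.
#' @param weights Optional per-transcript sampling weights.
#' @param seed Integer seed.
#' @return A `simulated_reads` object: list with `reads` (data.table
#'   `id,transcript,spliced_start,chrom,gstart,seq,n_errors`), the genomic
#'   origin map accessors, `read_len`, `error_rate`, `qual` and `seed`.
#' @export
simulate_reads <- function(genome, transcripts, planted = NULL, n_reads,
                           read_len = 75L, error_rate = 0.005,
                           weights = NULL, seed = 1L) {
  if (n_reads <= 0L) stop_rddkit("n_reads must be positive")
  cmap <- transcript_coord_map(transcripts)
  txs <- names(cmap)
  lens <- vapply(cmap, function(m) length(m$gpos), 0L)
  if (read_len > min(lens))
    stop_rddkit("read_len exceeds shortest spliced transcript (", min(lens), ")")
  if (is.null(weights)) weights <- rep(1, length(txs))
  pl <- planted
  if (!is.null(pl) && !data.table::is.data.table(pl) && is.list(pl) &&
      !inherits(pl, "planted_variants"))
    pl <- data.table::rbindlist(pl, fill = TRUE)
  q <- if (error_rate <= 0) 40L else min(40L, as.integer(round(-10 * log10(error_rate))))
  chrom_chars <- lapply(as.character(genome$sequences), function(s) strsplit(s, "")[[1]])
  with_seed(seed, {
    tx_idx <- sample.int(length(txs), n_reads, replace = TRUE, prob = weights)
    starts <- vapply(tx_idx, function(i) sample.int(lens[i] - read_len + 1L, 1L), 0L)
    seq_out <- character(n_reads)
    gstart <- integer(n_reads)
    chrom_out <- character(n_reads)
    n_err <- integer(n_reads)
    for (r in seq_len(n_reads)) {
      m <- cmap[[tx_idx[r]]]
      gpos <- m$gpos[starts[r]:(starts[r] + read_len - 1L)]
      gpos <- sort(gpos)                      # forward-genome orientation
      bases <- chrom_chars[[m$chrom]][gpos]
      if (!is.null(pl) && nrow(pl)) {
        hit <- pl[pl$chrom == m$chrom & pl$pos %in% gpos, ]
        if (nrow(hit)) {
          carry <- stats::runif(nrow(hit)) < hit$vaf
          if (any(carry)) {
            at <- match(hit$pos[carry], gpos)
            bases[at] <- hit$alt[carry]
          }
        }
      }
      err_at <- which(stats::runif(read_len) < error_rate)
      if (length(err_at)) {
        bases[err_at] <- vapply(bases[err_at], function(b)
          sample(setdiff(DNA_BASES, b), 1L), "")
      }
      n_err[r] <- length(err_at)
      seq_out[r] <- paste(bases, collapse = "")
      gstart[r] <- gpos[1L]
      chrom_out[r] <- m$chrom
    }
    reads <- data.table::data.table(
      id = sprintf("r%06d", seq_len(n_reads)),
      transcript = txs[tx_idx], spliced_start = starts,
      chrom = chrom_out, gstart = gstart, seq = seq_out, n_errors = n_err)
    structure(list(reads = reads, transcripts = transcripts,
                   read_len = read_len, error_rate = error_rate,
                   qual = q, seed = seed),
              class = "simulated_reads")
  })
}

#' Per-base genomic origin of one simulated read
#'
#' @param sim `simulated_reads`.
#' @param i Read index.
#' @return Integer vector of genomic positions (ascending), length
#'   `read_len`; discontiguous exactly at exon junctions.
#' @export
read_genomic_origin <- function(sim, i) {
  cmap <- transcript_coord_map(sim$transcripts)
  rd <- sim$reads[i, ]
  m <- cmap[[rd$transcript]]
  sort(m$gpos[rd$spliced_start:(rd$spliced_start + sim$read_len - 1L)])
}

#' Write simulated reads as FASTQ (transcript 5'->3' orientation)
#'
#' Hook for running a real external aligner on the simulated data; reads
#' from `-` strand transcripts are reverse-complemented back to transcript
#' orientation.
#' @param sim `simulated_reads`.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(sim, path) {
  tm <- data.table::as.data.table(sim$transcripts)
  strands <- tm[!duplicated(tm$transcript), ]
  st <- stats::setNames(strands$strand, strands$transcript)
  qual <- paste(rep(rawToChar(as.raw(sim$qual + 33L)), sim$read_len), collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(sim$reads))) {
    s <- sim$reads$seq[r]
    if (st[[sim$reads$transcript[r]]] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    writeLines(c(paste0("@", sim$reads$id[r]), s, "+", qual), con)
  }
  invisible(path)
}

#' Write a synthetic genome as FASTA
#' @param genome `synthetic_genome`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}
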