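# Shared fixture builders; everything is generated in code at test time.

# small editing-DB file
write_db_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("#chrom\tpos\tstrand\ttype", rows), path)
  path
}

# hand-written SAM -> sorted indexed BAM
sam_to_bam <- function(records, sq = c("chr1" = 1000L),
                       dest = tempfile()) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", paste0("@SQ\tSN:", names(sq), "\tLN:", sq))
  writeLines(c(hdr, records), sam)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
}

sam_record <- function(qname, chrom, pos, cigar, seq,
                       flag = 0L, mapq = 60L, qual = NULL) {
  if (is.null(qual)) qual <- paste(rep("I", nchar(seq)), collapse = "")  # Q40
  paste(qname, flag, chrom, pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

# one-chromosome reference
ref_fixture <- function(seq, name = "chr1") {
  r <- Biostrings::DNAStringSet(seq)
  names(r) <- name
  r
}

# observation table shaped like one pileup column
obs_column <- function(base, qual = 30L, mapq = 60L, strand = "+",
                       offset5p = NULL, read_len = 75L) {
  n <- length(base)
  if (is.null(offset5p)) offset5p <- seq_len(n) %% read_len
  data.table::data.table(
    base = base,
    qual = rep_len(qual, n), mapq = rep_len(mapq, n),
    strand = rep_len(strand, n),
    offset5p = rep_len(offset5p, n),
    dist_end = pmin(rep_len(offset5p, n),
                    rep_len(read_len, n) - 1L - rep_len(offset5p, n)),
    read_len = rep_len(read_len, n))
}

# exact two-sided Mann-Whitney p by enumeration over all rank assignments
exact_ranksum_p <- function(x_alt, x_ref) {
  n1 <- length(x_alt)
  all_v <- c(x_alt, x_ref)
  n <- length(all_v)
  r <- rank(all_v)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact two-sided Fisher p by factorial enumeration over fixed margins
exact_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0L, k - n); hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  pr <- exp(vapply(lo:hi, logp, 0))
  p_obs <- exp(logp(a))
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# tiny genome + transcripts used by several suites
small_study <- function(seed = 3L) {
  g <- make_genome(c(chr1 = 6000L, chr2 = 5000L),
                   repeats = list(list(length = 800L, copies = 2L,
                                       divergence = 0.02)), seed = seed)
  tx <- make_transcripts(g, n_transcripts = 6L, seed = seed + 1L)
  list(genome = g, transcripts = tx)
}
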