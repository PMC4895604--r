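test_that("genome generation is deterministic and honours divergence", {
  g1 <- make_genome(c(chr1 = 3000L), repeats = list(
    list(length = 500L, copies = 2L, divergence = 0)), seed = 7)
  g2 <- make_genome(c(chr1 = 3000L), repeats = list(
    list(length = 500L, copies = 2L, divergence = 0)), seed = 7)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  # divergence 0: the two copies are byte-identical
  rp <- g1$repeats
  s1 <- Biostrings::subseq(g1$sequences[[rp$chrom[1]]], rp$start[1], rp$end[1])
  s2 <- Biostrings::subseq(g1$sequences[[rp$chrom[2]]], rp$start[2], rp$end[2])
  expect_identical(as.character(s1), as.character(s2))

  # divergence 0.02 on 1000 bp: each copy differs from the template at
  # exactly 20 positions (Hamming-distance oracle via the recorded offsets)
  g3 <- make_genome(c(chr1 = 8000L), repeats = list(
    list(length = 1000L, copies = 3L, divergence = 0.02)), seed = 8)
  expect_equal(lengths(g3$repeats$div_offsets), rep(20L, 3L))
  expect_error(make_genome(c(chr1 = 300L), repeats = list(
    list(length = 500L, copies = 2L, divergence = 0.01)), seed = 1),
    "too short")
  expect_error(make_genome(c(chr1 = 3000L), repeats = list(
    list(length = 100L, copies = 2L, divergence = 0.5)), seed = 1),
    "divergence")
})

test_that("planted variant sets have exact count and uniform alt choice", {
  st <- small_study()
  elig <- nrow(unique(
    data.table::as.data.table(st$transcripts)[
      , list(pos = unlist(Map(seq.int, start, end))), by = "chrom"],
    by = c("chrom", "pos")))
  pv <- plant_variants(st$genome, st$transcripts, rate = 0.01, seed = 5)
  expect_equal(nrow(pv), round(0.01 * elig))
  expect_true(all(pv$alt != pv$ref))
  expect_error(plant_variants(st$genome, st$transcripts, rate = 0.2), "rate")

  # statistical oracle: alt uniform over the 3 non-reference choices
  draws <- data.table::rbindlist(lapply(1:120, function(s)
    plant_variants(st$genome, st$transcripts, rate = 0.05, seed = s)))
  # classify each alt as 1st/2nd/3rd available non-ref base
  rank_alt <- mapply(function(r, a) match(a, setdiff(c("A", "C", "G", "T"), r)),
                     draws$ref, draws$alt)
  p <- chisq.test(table(rank_alt), p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.001)
})

test_that("read simulation matches origin, error model and junction truth", {
  st <- small_study()
  sim0 <- simulate_reads(st$genome, st$transcripts, NULL, n_reads = 200L,
                         read_len = 60L, error_rate = 0, seed = 2)
  # error 0, nothing planted: every read equals its genomic origin
  for (r in c(1L, 50L, 200L)) {
    gpos <- read_genomic_origin(sim0, r)
    expect_true(all(diff(gpos) >= 1L))
    truth <- paste(vapply(gpos, function(p) as.character(
      Biostrings::subseq(st$genome$sequences[[sim0$reads$chrom[r]]], p, p)), ""),
      collapse = "")
    expect_identical(sim0$reads$seq[r], truth)
  }
  expect_equal(sum(sim0$reads$n_errors), 0L)

  # binomial oracle on the mismatch count at error rate 0.01
  simE <- simulate_reads(st$genome, st$transcripts, NULL, n_reads = 2000L,
                         read_len = 50L, error_rate = 0.01, seed = 3)
  n_bases <- 2000L * 50L
  mu <- n_bases * 0.01
  sigma <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(sum(simE$reads$n_errors) - mu), 3 * sigma)

  # a read spanning an exon junction has a discontiguous origin exactly there
  multi <- data.table::as.data.table(st$transcripts)[
    , list(n = max(exon_rank)), by = "transcript"]
  multi <- multi$transcript[multi$n > 1L][1]
  skip_if(is.na(multi))
  junction_seen <- FALSE
  for (r in seq_len(nrow(sim0$reads))) {
    if (sim0$reads$transcript[r] == multi) {
      gpos <- read_genomic_origin(sim0, r)
      if (any(diff(gpos) > 1L)) junction_seen <- TRUE
    }
  }
  expect_true(junction_seen ||
              all(sim0$reads$transcript != multi))  # only if tx was sampled

  expect_error(simulate_reads(st$genome, st$transcripts, NULL, n_reads = 0L),
               "n_reads")
})

test_that("fabricated alignments conserve reads and honour misplacement", {
  st <- small_study()
  sim <- simulate_reads(st$genome, st$transcripts, NULL, n_reads = 2000L,
                        read_len = 60L, error_rate = 0, seed = 6)
  # misplacement 0: every read at its true locus
  fab0 <- fabricate_alignments(sim, st$genome, tempfile(), misplacement = 0,
                               seed = 7)
  expect_equal(nrow(fab0$truth), 2000L)
  expect_false(any(fab0$truth$misplaced))
  expect_true(all(fab0$truth$placed_pos == fab0$truth$true_pos))
  cb <- Rsamtools::countBam(fab0$bam)
  expect_equal(cb$records, 2000L)
  # and downstream raw calls are empty (no artefacts, no errors, no variants)
  pu <- build_pileup(fab0$bam, st$genome$sequences)
  cand <- call_candidates(pu, st$genome$sequences, min_depth = 4L,
                          with_features = FALSE)
  expect_equal(nrow(cand), 0L)

  # misplacement 1 on a 2-copy family: all eligible family reads swapped,
  # and the divergence columns they cover appear as variant columns
  fab1 <- fabricate_alignments(sim, st$genome, tempfile(), misplacement = 1,
                               seed = 8)
  rp <- st$genome$repeats
  gend <- sim$reads$gstart + 59L
  eligible <- vapply(seq_len(nrow(sim$reads)), function(r)
    any(rp$chrom == sim$reads$chrom[r] & rp$start <= sim$reads$gstart[r] &
        rp$end >= gend[r]), TRUE)
  expect_equal(fab1$truth$misplaced, eligible)
  tc <- misalignment_truth_columns(st$genome, fab1, 60L, min_misplaced = 2L)
  pu1 <- build_pileup(fab1$bam, st$genome$sequences)
  cand1 <- call_candidates(pu1, st$genome$sequences, min_depth = 4L,
                           with_features = FALSE)
  found <- cand1[tc, on = c("chrom", "pos"), nomatch = NULL]
  expect_gte(nrow(found) / nrow(tc), 0.95)
})

test_that("same seeds give identical generators end to end", {
  st <- small_study()
  a <- simulate_reads(st$genome, st$transcripts, NULL, n_reads = 100L,
                      read_len = 60L, error_rate = 0.01, seed = 9)
  b <- simulate_reads(st$genome, st$transcripts, NULL, n_reads = 100L,
                      read_len = 60L, error_rate = 0.01, seed = 9)
  expect_identical(a$reads, b$reads)
  pv1 <- plant_variants(st$genome, st$transcripts, 0.01, seed = 4)
  pv2 <- plant_variants(st$genome, st$transcripts, 0.01, seed = 4)
  expect_identical(as.data.frame(pv1), as.data.frame(pv2))
})
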