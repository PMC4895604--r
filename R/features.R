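# The 15 read-alignment-pattern attributes and their statistical primitives.
#
# Attribute semantics follow the samtools/bcftools tradition: rank-sum
# bias tests (mapping quality, base quality, read position, tail
# distance), Fisher strand bias, RMS mapping quality, MQ0 fraction, a
# three-hypothesis genotype-likelihood segregation model, and a seeded
# Monte-Carlo variant-distance-bias statistic.  Exact parameterizations
# are fixed here so that every attribute is reproducible and testable.

#' Tie-corrected Mann-Whitney rank-sum bias test
#'
#' Two-sided Mann-Whitney U with the tie-corrected normal approximation
#' and continuity correction: `z = sign(U - mu) * max(0, |U - mu| - 0.5) / sigma`,
#' `p = 2 * pnorm(-|z|)`.  When all values are identical (`sigma = 0`) or
#' a group is empty the sentinel `z = 0, p = 1` is returned with
#' `degenerate = TRUE`.
#'
#' @param values_alt,values_ref Numeric vectors for the variant-supporting
#'   and reference-supporting groups.
#' @return List `z`, `p`, `degenerate`.
#' @export
rank_sum_bias <- function(values_alt, values_ref) {
  n1 <- length(values_alt)
  n2 <- length(values_ref)
  if (n1 == 0L || n2 == 0L)
    return(list(z = 0, p = 1, degenerate = TRUE))
  all_v <- c(values_alt, values_ref)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(all_v)
  tie_term <- sum(tie_tab^3 - tie_tab)
  s2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (s2 <= 0)
    return(list(z = 0, p = 1, degenerate = TRUE))
  z <- sign(U - mu) * max(0, abs(U - mu) - 0.5) / sqrt(s2)
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))), degenerate = FALSE)
}

#' Two-sided Fisher exact strand-bias test
#'
#' Exact p-value for the 2x2 table of (alt, ref) x (forward, reverse)
#' read counts: the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the
#' observed table's (with the customary 1e-7 relative slack).
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev Non-negative counts.
#' @return p-value in (0, 1].
#' @export
fisher_strand <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  stopifnot(alt_fwd >= 0, alt_rev >= 0, ref_fwd >= 0, ref_rev >= 0)
  m <- alt_fwd + alt_rev          # alt row total
  n <- ref_fwd + ref_rev
  k <- alt_fwd + ref_fwd          # forward column total
  if (m + n == 0L) stop_rddkit("empty 2x2 table")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  if (lo == hi) return(1)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(alt_fwd, m, n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Allele-segregation features from base qualities
#'
#' Three-hypothesis genotype-likelihood model over the ref- and
#' alt-supporting observations of one column, with per-base error
#' probabilities `e = 10^(-Q/10)`:
#' hom-ref (every alt base a sequencing error), het (each base drawn
#' 50/50 from the two alleles), and hom-alt.  With a uniform prior,
#' `SGB = ln P(hom-ref) - ln P(het)`, `FQ = -10 log10` posterior of the
#' best monomorphic hypothesis, `CallQual = -10 log10` posterior of
#' hom-ref; both phred values capped at 9999.
#'
#' @param qual_alt,qual_ref Phred base qualities of alt / ref observations.
#' @return List `SGB`, `FQ`, `CallQual`.
#' @export
segregation_features <- function(qual_alt, qual_ref) {
  e_alt <- 10^(-qual_alt / 10)
  e_ref <- 10^(-qual_ref / 10)
  e_all <- c(e_alt, e_ref)
  # log-likelihoods; error base hits one specific wrong base with prob e/3
  ll_homref <- sum(log(e_alt / 3)) + sum(log(1 - e_ref))
  ll_homalt <- sum(log(1 - e_alt)) + sum(log(e_ref / 3))
  ll_het <- sum(log(0.5 * (1 - e_all) + 0.5 * e_all / 3))
  ll <- c(homref = ll_homref, het = ll_het, homalt = ll_homalt)
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  sgb <- ll_homref - ll_het
  fq <- min(9999, -10 * log10(max(post[["homref"]], post[["homalt"]])))
  cq <- min(9999, -10 * log10(post[["homref"]]))
  list(SGB = sgb, FQ = fq, CallQual = cq)
}

#' Variant distance bias (seeded Monte-Carlo)
#'
#' Probability, under uniform placement of each alt base over its read's
#' valid offsets, that the variance of the alt-base 5' offsets is at most
#' the observed variance; estimated with `m` seeded Monte-Carlo draws as
#' `(1 + #{var_sim <= var_obs}) / (m + 1)` so the value stays in (0, 1].
#' Small VDB means the alt bases cluster at one read position — the
#' signature of splice-site mis-alignment.  Fewer than two alt
#' observations returns the sentinel `VDB = 1` with `degenerate = TRUE`.
#'
#' @param offsets 0-based 5' offsets of the alt observations.
#' @param read_lens Read length per alt observation.
#' @param m Monte-Carlo draws.
#' @param seed Integer seed (the draw is local; the global RNG state is
#'   untouched).
#' @return List `vdb`, `degenerate`.
#' @export
variant_distance_bias <- function(offsets, read_lens, m = 1000L, seed = 1L) {
  k <- length(offsets)
  if (k < 2L) return(list(vdb = 1, degenerate = TRUE))
  stopifnot(length(read_lens) == k)
  v_obs <- stats::var(offsets)
  with_seed(seed, {
    sims <- matrix(0, nrow = m, ncol = k)
    for (j in seq_len(k))
      sims[, j] <- sample.int(read_lens[j], m, replace = TRUE) - 1L
    v_sim <- apply(sims, 1L, stats::var)
    list(vdb = (1 + sum(v_sim <= v_obs)) / (m + 1), degenerate = FALSE)
  })
}

#' Compute the 15 attributes for one candidate column
#'
#' Assembles the full attribute vector from a pileup column: ReadDepth,
#' VAF, the segregation trio (SGB/FQ/CallQual), mapping-quality tests
#' (MQB z and PV3 p on MAPQ; MQ0F; RMS MQ), read-position tests (VDB;
#' RPB z on relative offsets; PV4 p on tail distances), base-quality
#' tests (BQB z, PV2 p) and the Fisher strand p (PV1).  Degenerate
#' sub-tests fall back to their defined sentinels so the vector never
#' contains missing values.
#'
#' @param obs Observation table for one `(chrom,pos)`: columns
#'   `base,qual,mapq,strand,offset5p,dist_end,read_len`.
#' @param ref,alt Reference and variant alleles (forward strand).
#' @param vdb_m,vdb_seed VDB Monte-Carlo parameters.
#' @return Named numeric vector, order [rdd_feature_names()].
#' @export
compute_features <- function(obs, ref, alt, vdb_m = 1000L, vdb_seed = 1L) {
  obs <- data.table::as.data.table(obs)
  is_alt <- obs$base == alt
  is_ref <- obs$base == ref
  a <- obs[is_alt, ]
  rf <- obs[is_ref, ]
  depth <- nrow(obs)
  mq_t <- rank_sum_bias(a$mapq, rf$mapq)
  bq_t <- rank_sum_bias(a$qual, rf$qual)
  rp_t <- rank_sum_bias(a$offset5p / pmax(1L, a$read_len - 1L),
                        rf$offset5p / pmax(1L, rf$read_len - 1L))
  td_t <- rank_sum_bias(a$dist_end, rf$dist_end)
  pv1 <- fisher_strand(sum(a$strand == "+"), sum(a$strand == "-"),
                       sum(rf$strand == "+"), sum(rf$strand == "-"))
  seg <- segregation_features(a$qual, rf$qual)
  vdb <- variant_distance_bias(a$offset5p, a$read_len, m = vdb_m, seed = vdb_seed)
  c(ReadDepth = depth,
    VAF = nrow(a) / depth,
    SGB = seg$SGB, FQ = seg$FQ, CallQual = seg$CallQual,
    PV3 = mq_t$p, MQB = mq_t$z,
    MQ0F = mean(obs$mapq == 0L),
    MQ = sqrt(mean(obs$mapq^2)),
    VDB = vdb$vdb,
    RPB = rp_t$z, PV4 = td_t$p,
    PV2 = bq_t$p, BQB = bq_t$z,
    PV1 = pv1)[rdd_feature_names()]
}
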