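test_that("rank-sum bias matches exhaustive enumeration at all sizes <= 6", {
  # enumerate every assignment of distinct values for each (n1, n2); the
  # exact two-sided p comes from the U distribution over all C(n, n1)
  # assignments.  The continuity-corrected normal approximation deviates
  # from the exact tail by at most ~0.13 at these sizes; 0.15 is asserted.
  worst <- 0
  for (n1 in 1:6) for (n2 in 1:6) {
    n <- n1 + n2
    vals <- seq_len(n)
    combs <- utils::combn(n, n1)
    mu <- n1 * n2 / 2
    us <- apply(combs, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
    for (j in seq_len(ncol(combs))) {
      alt <- vals[combs[, j]]
      ref <- vals[-combs[, j]]
      p_approx <- rank_sum_bias(alt, ref)$p
      p_exact <- mean(abs(us - mu) >= abs(us[j] - mu) - 1e-9)
      worst <- max(worst, abs(p_approx - p_exact))
    }
  }
  expect_lt(worst, 0.15)
})

test_that("rank-sum bias symmetry, ties and degenerate sentinels", {
  # identical multisets: z = 0, p = 1
  r <- rank_sum_bias(c(1, 2, 2, 3), c(3, 2, 1, 2))
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # swapping groups negates z and preserves p
  a <- c(1.5, 3, 9); b <- c(2, 2, 7, 11)
  r1 <- rank_sum_bias(a, b); r2 <- rank_sum_bias(b, a)
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$p, r2$p)
  # agreement with the reference implementation (tie-corrected, CC)
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r1$p, w$p.value, tolerance = 1e-8)
  # all-identical values and empty groups hit the sentinel
  expect_equal(rank_sum_bias(c(5, 5), c(5, 5, 5)),
               list(z = 0, p = 1, degenerate = TRUE))
  expect_equal(rank_sum_bias(numeric(0), c(1, 2))$degenerate, TRUE)
})

test_that("Fisher strand matches enumeration for all table totals <= 12", {
  for (total in 1:12) {
    comps <- expand.grid(a = 0:total, b = 0:total, c_ = 0:total)
    comps <- comps[rowSums(comps) <= total, ]
    for (i in seq_len(nrow(comps))) {
      a <- comps$a[i]; b <- comps$b[i]; c_ <- comps$c_[i]
      d <- total - a - b - c_
      p <- fisher_strand(a, b, c_, d)
      expect_equal(p, exact_fisher_p(a, b, c_, d), tolerance = 1e-9)
    }
  }
  # spot checks against the reference implementation
  for (tab in list(c(10, 0, 0, 10), c(5, 5, 5, 5), c(3, 9, 6, 2))) {
    expect_equal(fisher_strand(tab[1], tab[2], tab[3], tab[4]),
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
  expect_equal(fisher_strand(5, 5, 5, 5), 1)
  # transposition invariance
  expect_equal(fisher_strand(3, 9, 6, 2), fisher_strand(3, 6, 9, 2),
               tolerance = 1e-12)
})

test_that("segregation features match a longhand posterior oracle", {
  # depth-4 column, arbitrary qualities: compute the three likelihoods
  # by explicit products
  q_alt <- c(20, 31); q_ref <- c(35, 17)
  e_a <- 10^(-q_alt / 10); e_r <- 10^(-q_ref / 10)
  L_homref <- prod(e_a / 3) * prod(1 - e_r)
  L_homalt <- prod(1 - e_a) * prod(e_r / 3)
  L_het <- prod(0.5 * (1 - c(e_a, e_r)) + 0.5 * c(e_a, e_r) / 3)
  post <- c(L_homref, L_het, L_homalt) / (L_homref + L_het + L_homalt)
  s <- segregation_features(q_alt, q_ref)
  expect_equal(s$SGB, log(L_homref) - log(L_het), tolerance = 1e-12)
  expect_equal(s$FQ, -10 * log10(max(post[1], post[3])), tolerance = 1e-10)
  expect_equal(s$CallQual, -10 * log10(post[1]), tolerance = 1e-10)

  # all-reference column at Q30: hom-ref posterior ~ 1, both phreds ~ 0
  s0 <- segregation_features(numeric(0), rep(30, 15))
  expect_lt(s0$CallQual, 0.01)
  expect_lt(s0$FQ, 0.01)
  # 50/50 at depth 20: the het model beats the error-only model
  s1 <- segregation_features(rep(30, 10), rep(30, 10))
  expect_lt(s1$SGB, 0)
})

test_that("variant distance bias is seeded, bounded and flags clustering", {
  off <- c(10, 25, 3, 41, 60)
  v1 <- variant_distance_bias(off, rep(75L, 5), seed = 5)
  v2 <- variant_distance_bias(off, rep(75L, 5), seed = 5)
  expect_identical(v1, v2)
  expect_true(v1$vdb > 0 && v1$vdb <= 1)
  # all offsets identical over >= 5 reads: strongly clustered
  vc <- variant_distance_bias(rep(33, 6), rep(75L, 6), seed = 1)
  expect_lte(vc$vdb, 0.05)
  # single observation: sentinel
  expect_equal(variant_distance_bias(7, 75L), list(vdb = 1, degenerate = TRUE))
})

test_that("the assembled 15-attribute vector matches longhand arithmetic", {
  # homogeneous column: depth 10, 5 alt, constant MAPQ 60, no MQ0
  obs <- obs_column(base = c(rep("A", 5), rep("G", 5)), qual = 30L,
                    mapq = 60L, strand = rep(c("+", "-"), 5),
                    offset5p = c(1, 5, 9, 13, 17, 21, 25, 29, 33, 37))
  f <- compute_features(obs, ref = "A", alt = "G")
  expect_named(f, rdd_feature_names())
  expect_equal(unname(f["ReadDepth"]), 10)
  expect_equal(unname(f["VAF"]), 0.5)
  expect_equal(unname(f["MQ"]), 60)
  expect_equal(unname(f["MQ0F"]), 0)
  expect_equal(unname(f["MQB"]), 0)
  expect_equal(unname(f["PV3"]), 1)

  # crafted 12-read column: every field against an independent oracle
  obs <- data.table::data.table(
    base = c(rep("A", 8), rep("G", 4)),
    qual = c(30, 32, 34, 36, 38, 28, 26, 24, 20, 22, 24, 26),
    mapq = c(60, 60, 60, 60, 60, 60, 50, 40, 30, 20, 60, 0),
    strand = c(rep("+", 4), rep("-", 4), "+", "+", "+", "-"),
    offset5p = c(5, 10, 15, 20, 25, 30, 35, 40, 3, 6, 9, 70),
    read_len = 75L)
  obs[, "dist_end" := pmin(offset5p, read_len - 1L - offset5p)]
  f <- compute_features(obs, "A", "G", vdb_seed = 9)
  is_alt <- obs$base == "G"
  expect_equal(unname(f["ReadDepth"]), 12)
  expect_equal(unname(f["VAF"]), 4 / 12)
  expect_equal(unname(f["MQ0F"]), 1 / 12)
  expect_equal(unname(f["MQ"]), sqrt(mean(obs$mapq^2)))
  wt <- function(x, y) suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
  expect_equal(unname(f["PV3"]), wt(obs$mapq[is_alt], obs$mapq[!is_alt]),
               tolerance = 1e-8)
  expect_equal(unname(f["PV2"]), wt(obs$qual[is_alt], obs$qual[!is_alt]),
               tolerance = 1e-8)
  expect_equal(unname(f["PV4"]), wt(obs$dist_end[is_alt], obs$dist_end[!is_alt]),
               tolerance = 1e-8)
  expect_equal(unname(f["PV1"]),
               stats::fisher.test(matrix(c(3, 1, 4, 4), 2, byrow = TRUE))$p.value,
               tolerance = 1e-7)
  seg <- segregation_features(obs$qual[is_alt], obs$qual[!is_alt])
  expect_equal(unname(f["SGB"]), seg$SGB)
  expect_equal(unname(f["FQ"]), seg$FQ)
  expect_equal(unname(f["CallQual"]), seg$CallQual)
  expect_identical(unname(f["VDB"]),
                   variant_distance_bias(obs$offset5p[is_alt],
                                         obs$read_len[is_alt], seed = 9)$vdb)
  # z-statistics carry the direction of the bias
  expect_lt(unname(f["MQB"]), 0)   # alt MAPQs are lower
  expect_lt(unname(f["BQB"]), 0)   # alt base qualities are lower
  # purity: identical column gives the identical vector
  expect_identical(f, compute_features(obs, "A", "G", vdb_seed = 9))
})

test_that("rank-based p-value attributes are uniform under the null", {
  # 400 null columns with near-continuous covariates (long reads, no
  # injected bias); each rank-based p-value attribute should be
  # approximately U(0,1) (KS alpha = 0.001)
  set.seed(2024)
  n_cols <- 400L
  ps <- matrix(NA_real_, n_cols, 4L,
               dimnames = list(NULL, c("PV2", "PV3", "PV4", "VDB")))
  for (i in seq_len(n_cols)) {
    depth <- 60L
    obs <- data.table::data.table(
      base = c(rep("G", 30L), rep("A", 30L)),
      qual = stats::runif(depth, 13, 40),
      mapq = stats::runif(depth, 0, 60),
      strand = sample(c("+", "-"), depth, replace = TRUE),
      offset5p = sample.int(1000L, depth) - 1L,
      read_len = 1000L)
    obs[, "dist_end" := pmin(offset5p, read_len - 1L - offset5p)]
    f <- compute_features(obs, "A", "G", vdb_seed = i)
    ps[i, ] <- f[c("PV2", "PV3", "PV4", "VDB")]
  }
  for (col in colnames(ps)) {
    ks <- suppressWarnings(stats::ks.test(ps[, col], "punif"))
    expect_gt(ks$p.value, 0.001, label = paste("KS uniformity of", col))
  }
})
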