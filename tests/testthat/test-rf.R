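# separable-by-construction training fixture: positives look like clean
# editing columns (VAF ~ 0.5, high MQ, unbiased tests), negatives like
# mis-alignment artefacts (low MQ, MQ0 reads, biased tests)
separable_ts <- function(n_per_class = 100L, seed = 11L, flip = 0) {
  set.seed(seed)
  mk <- function(n, positive) {
    data.table::data.table(
      chrom = "chr1",
      pos = seq_len(n) + if (positive) 0L else 100000L,
      ref = "A", alt = "G", n_ref = 10L, n_alt = 10L,
      ReadDepth = round(runif(n, 30, 80)),
      VAF = if (positive) runif(n, 0.35, 0.65) else runif(n, 0.1, 0.35),
      SGB = rnorm(n, if (positive) -30 else -5, 3),
      FQ = runif(n, 0, 50), CallQual = runif(n, 100, 999),
      PV3 = if (positive) runif(n, 0.2, 1) else runif(n, 0, 0.01),
      MQB = rnorm(n, if (positive) 0 else -4, 0.3),
      MQ0F = if (positive) 0 else runif(n, 0.1, 0.4),
      MQ = if (positive) 60 else runif(n, 15, 35),
      VDB = runif(n, 0.05, 1),
      RPB = rnorm(n), PV4 = runif(n), PV2 = runif(n),
      BQB = rnorm(n), PV1 = runif(n))
  }
  pos <- mk(n_per_class, TRUE)
  neg <- mk(n_per_class, FALSE)
  dt <- data.table::rbindlist(list(pos, neg))
  dt[, "label" := rep(c("positive", "negative"), each = n_per_class)]
  if (flip > 0) {  # optional label noise
    i <- sample.int(nrow(dt), flip)
    dt[i, "label" := ifelse(dt$label[i] == "positive", "negative", "positive")]
  }
  dt[, "label_source" := ifelse(dt$label == "positive", "db_consensus", "mes")]
  structure(dt, class = c("rdd_training_set", class(dt)))
}

test_that("training separates a separable fixture and is deterministic", {
  ts <- separable_ts(100L)
  model <- rdd_train(ts, seed = 5)
  expect_s3_class(model, "rdd_predictor")
  expect_identical(model$feature_names, rdd_feature_names())
  pred <- rdd_predict(model, ts)
  acc <- mean((pred$prob >= 0.5) == (ts$label == "positive"))
  expect_equal(acc, 1.0)

  # determinism: same seed, identical probe predictions
  probe <- separable_ts(30L, seed = 77L)
  m2 <- rdd_train(ts, seed = 5)
  expect_identical(rdd_predict(m2, probe)$prob, rdd_predict(model, probe)$prob)

  # single-class input errors; constant columns only warn
  bad <- ts[ts$label == "positive", ]
  expect_error(rdd_train(bad), "non-empty")
  const_ts <- data.table::copy(ts)
  const_ts[, "PV1" := 0.5]
  expect_warning(rdd_train(const_ts, seed = 5), "constant attribute")
})

test_that("prediction thresholds and schema checks behave", {
  ts <- separable_ts(60L)
  model <- rdd_train(ts, seed = 2)
  p0 <- rdd_predict(model, ts, threshold = 0)
  expect_true(all(p0$accepted))
  p2 <- rdd_predict(model, ts, threshold = 1.01)
  expect_false(any(p2$accepted))
  expect_equal(nrow(p0), nrow(ts))
  broken <- data.table::as.data.table(ts)[, !"MQ"]
  expect_error(rdd_predict(model, broken), "MQ")
})

test_that("model persistence round-trips", {
  ts <- separable_ts(40L)
  model <- rdd_train(ts, seed = 4)
  p <- tempfile(fileext = ".rds")
  save_predictor(model, p)
  back <- load_predictor(p)
  expect_identical(back$feature_names, model$feature_names)
  expect_identical(rdd_predict(back, ts)$prob, rdd_predict(model, ts)$prob)
  saveRDS(list(), p)
  expect_error(load_predictor(p), "rdd_predictor")
})

test_that("information gain obeys its limits and longhand arithmetic", {
  ts <- separable_ts(50L)
  ig <- information_gain(ts)
  h_class <- 1  # balanced classes
  expect_true(all(ig >= 0 & ig <= h_class + 1e-12))
  # constant attribute: IG = 0
  ts2 <- data.table::copy(ts)
  ts2[, "PV1" := 0.5]
  expect_equal(unname(information_gain(ts2)["PV1"]), 0)
  # perfectly predictive attribute: IG = H(class) = 1 bit
  ts2[, "MQ" := ifelse(ts2$label == "positive", 60, 20)]
  expect_equal(unname(information_gain(ts2)["MQ"]), 1)

  # 20-example hand-built table, 2-bin split: longhand entropy oracle.
  # distinct VAF values so the equal-frequency split is the exact median
  hand <- data.table::copy(separable_ts(10L, seed = 1L))
  hand[, "VAF" := (1:20) / 20]   # positives 1..10, negatives 11..20
  hand[, "label" := c("negative", "negative", "positive", rep("negative", 7),
                      rep("positive", 7), "negative", "negative", "positive")]
  ig2 <- information_gain(hand, bins = 2L)
  ent <- function(k, n) { p <- c(k, n - k) / n; p <- p[p > 0]; -sum(p * log2(p)) }
  cut_at <- unname(stats::quantile(hand$VAF, 0.5))
  lo <- hand$VAF <= cut_at
  expected <- ent(sum(hand$label == "positive"), 20) -
    mean(lo) * ent(sum(hand$label[lo] == "positive"), sum(lo)) -
    mean(!lo) * ent(sum(hand$label[!lo] == "positive"), sum(!lo))
  expect_equal(unname(ig2["VAF"]), expected, tolerance = 1e-12)
})

test_that("label permutation drives information gain toward zero", {
  ts <- separable_ts(100L)
  base_ig <- information_gain(ts)
  expect_gt(max(base_ig), 0.5)  # the fixture is informative
  set.seed(99)
  igs <- replicate(20, {
    sh <- data.table::copy(ts)
    sh[, "label" := sample(sh$label)]
    information_gain(sh)
  })
  # every attribute's IG collapses: per-attribute median over 20 shuffles
  per_attr_median <- apply(igs, 1L, stats::median)
  expect_true(all(per_attr_median < 0.05))
})

test_that("the importance report ranks the six categories", {
  tsA <- separable_ts(80L, seed = 21L)
  tsB <- separable_ts(80L, seed = 22L)
  rep <- importance_report(list(DataA = tsA, DataB = tsB))
  cats <- rep$categories
  expect_equal(nrow(cats), 6L)
  expect_setequal(cats$Category, unique(unname(rdd_feature_categories())))
  # ranks are a permutation of 1..6 up to tie-averaging
  expect_equal(sum(cats$RankA), sum(1:6))
  expect_equal(sum(cats$RankB), sum(1:6))
  expect_equal(cats$RankMean, (cats$RankA + cats$RankB) / 2)
  expect_equal(nrow(rep$attributes), 15L)
  # the fixture's discriminative categories outrank read strand (noise)
  rs_rank <- cats$RankMean[cats$Category == "Read strand"]
  mq_rank <- cats$RankMean[cats$Category == "Mapping quality"]
  expect_gt(rs_rank, mq_rank)
})
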