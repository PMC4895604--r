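# helper: a candidate table with constant valid features
cand_fixture <- function(chrom, pos, ref = "A", alt = "G") {
  n <- length(pos)
  feat <- stats::setNames(as.data.frame(matrix(0.5, n, 15)), rdd_feature_names())
  feat$ReadDepth <- 20
  feat$VAF <- 0.4
  dt <- data.table::as.data.table(cbind(
    data.frame(chrom = rep_len(chrom, n), pos = pos, ref = rep_len(ref, n),
               alt = rep_len(alt, n), n_ref = 12L, n_alt = 8L,
               stringsAsFactors = FALSE), feat))
  data.table::setkeyv(dt, c("chrom", "pos"))
  structure(dt, class = c("candidate_table", class(dt)))
}

db_of <- function(pos, strand = "+", type = "A-to-I") {
  dt <- data.table::data.table(chrom = "chr1", pos = as.integer(pos),
                               strand = strand, type = type)
  structure(dt, class = c("editing_db", class(dt)))
}

test_that("compilation partitions candidates exactly as labelled", {
  # hand-partition oracle: 10 candidates; 3 DB-only hits of which one is
  # test-listed, 2 MES-only hits, 1 site in both DB and MES; expected
  # 2 positives, 2 negatives, 1 conflict-excluded, 1 test-excluded,
  # 5 targets (the test-excluded site among them)
  cand <- cand_fixture("chr1", 1:10 * 10L)            # pos 10..100, A>G
  db <- db_of(c(10, 20, 30, 60))
  mes <- data.table::data.table(chrom = "chr1", pos = c(40L, 50L, 60L))
  excl <- data.table::data.table(chrom = "chr1", pos = 30L)
  comp <- compile_training(cand, db, mes, test_exclusion = excl)
  tr <- comp$training
  expect_setequal(tr$pos[tr$label == "positive"], c(10L, 20L))
  expect_setequal(tr$pos[tr$label == "negative"], c(40L, 50L))
  expect_equal(comp$excluded$label_conflict, 1L)      # site 60
  expect_equal(comp$excluded$test_overlap, 1L)        # site 30
  expect_equal(nrow(comp$targets), 5L)
  expect_setequal(comp$targets$pos, c(30L, 70L, 80L, 90L, 100L))
  # partition: training + conflict + targets = all candidates
  expect_equal(nrow(tr) + comp$excluded$label_conflict + nrow(comp$targets),
               nrow(cand))
  # the test-excluded site remains a prediction target
  expect_true(30L %in% comp$targets$pos)
  expect_false(30L %in% tr$pos)
  expect_equal(unique(tr$label_source[tr$label == "positive"]), "db_consensus")
  expect_equal(unique(tr$label_source[tr$label == "negative"]), "mes")
})

test_that("DB matching respects substitution-class compatibility", {
  cand <- cand_fixture("chr1", c(10L, 20L), ref = c("A", "C"), alt = c("G", "T"))
  # A-to-I on "+" matches A>G but not C>T
  comp <- compile_training(cand, db_of(c(10, 20)),
                           data.table::data.table(chrom = "chr1", pos = 10000L),
                           on_empty_class = "warn") |> suppressWarnings()
  expect_equal(comp$training$pos[comp$training$label == "positive"], 10L)
  # C-to-U matches the C>T candidate instead
  comp2 <- suppressWarnings(compile_training(
    cand, db_of(c(10, 20), type = "C-to-U"),
    data.table::data.table(chrom = "chr1", pos = 10000L),
    on_empty_class = "warn"))
  expect_equal(comp2$training$pos[comp2$training$label == "positive"], 20L)
  # a "-" strand A-to-I row matches a forward T>C candidate
  cand3 <- cand_fixture("chr1", 30L, ref = "T", alt = "C")
  comp3 <- suppressWarnings(compile_training(
    cand3, db_of(30, strand = "-"),
    data.table::data.table(chrom = "chr1", pos = 10000L),
    on_empty_class = "warn"))
  expect_equal(sum(comp3$training$label == "positive"), 1L)
  # position-only mode ignores the class check
  comp4 <- suppressWarnings(compile_training(
    cand, db_of(c(10, 20)), data.table::data.table(chrom = "chr1", pos = 10000L),
    match_mode = "position", on_empty_class = "warn"))
  expect_equal(sum(comp4$training$label == "positive"), 2L)
})

test_that("empty training classes raise, and compilation is order-independent", {
  cand <- cand_fixture("chr1", 1:5 * 10L)
  expect_error(compile_training(cand, db_of(999), db_of(888)), "positive")
  # order independence (set semantics)
  db <- db_of(c(10, 20))
  mes <- data.table::data.table(chrom = "chr1", pos = c(30L, 40L))
  c1 <- compile_training(cand, db, mes)
  c2 <- compile_training(cand[5:1, ], db, mes)
  expect_equal(data.table::setkeyv(data.table::as.data.table(c1$training), "pos"),
               data.table::setkeyv(data.table::as.data.table(c2$training), "pos"))
})

test_that("class balancing downsamples the majority deterministically", {
  cand <- cand_fixture("chr1", 1:110 * 3L)
  db <- db_of(1:100 * 3L)
  mes <- data.table::data.table(chrom = "chr1", pos = 101:110 * 3L)
  ts <- compile_training(cand, db, mes)$training
  expect_equal(unname(table(ts$label)["positive"]), 100L)
  bal <- class_balance(ts, "downsample_majority", seed = 3)
  expect_equal(as.integer(table(bal$label)), c(10L, 10L))
  bal2 <- class_balance(ts, "downsample_majority", seed = 3)
  expect_identical(as.data.frame(bal), as.data.frame(bal2))
  # balanced input is returned unchanged
  expect_identical(class_balance(bal, "downsample_majority", seed = 1), bal)
  expect_identical(class_balance(ts, "none"), ts)
})
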