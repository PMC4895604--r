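# Condition-specific training-set compilation.
#
# Positive examples: candidates matching the editing-DB consensus (by
# site and, in the default mode, substitution-class compatibility).
# Negative examples: candidates at error-prone (mis-alignment) sites.
# Candidates matching both are dropped as label conflicts; candidates on
# a supplied test-exclusion list are withheld from TRAINING only and
# remain prediction targets.  Every candidate lands in exactly one of
# {positive, negative, conflict-excluded, target}.

#' Compile training examples and prediction targets
#'
#' @param candidates A `candidate_table` with complete attribute columns.
#' @param positives An `editing_db` (typically the consensus of two
#'   databases).
#' @param negatives An `error_prone_sites` table (any `chrom`,`pos`
#'   table), or a `GRanges` region mask (candidates inside any region
#'   are negative).
#' @param test_exclusion Optional site table (`chrom`,`pos`); matching
#'   candidates are excluded from training (window `exclusion_window`)
#'   but kept as targets.
#' @param match_mode `"class"` (default): a candidate matches a DB row on
#'   `(chrom,pos)` when its ref>alt alleles are compatible with the row's
#'   edit type on the row's strand; `"position"`: `(chrom,pos)` only.
#' @param exclusion_window Half-width (bases) of the test-exclusion
#'   window; 0 = exact site identity.
#' @param on_empty_class `"error"` (default) or `"warn"`: reaction when a
#'   training class comes out empty.
#' @return A list of class `rdd_training_compilation`:
#'   `training` (`rdd_training_set`: site + label + label_source +
#'   attribute columns), `targets` (candidate rows to predict), and
#'   `excluded` counts by reason.
#' @export
compile_training <- function(candidates, positives, negatives,
                             test_exclusion = NULL,
                             match_mode = c("class", "position"),
                             exclusion_window = 0L,
                             on_empty_class = c("error", "warn")) {
  match_mode <- match.arg(match_mode)
  on_empty_class <- match.arg(on_empty_class)
  cand <- data.table::as.data.table(candidates)
  check_site_cols(cand, c("chrom", "pos", "ref", "alt", rdd_feature_names()))
  if (anyNA(cand[, rdd_feature_names(), with = FALSE]))
    stop_rddkit("candidates carry incomplete attribute vectors")
  db <- data.table::as.data.table(positives)
  is_pos <- rep(FALSE, nrow(cand))
  if (nrow(db)) {
    if (match_mode == "position") {
      is_pos <- !is.na(db[cand, on = c("chrom", "pos"), which = TRUE, mult = "first"])
    } else {
      db2 <- data.table::copy(db)
      if ("alt" %in% names(db2)) data.table::setnames(db2, "alt", "db_alt")
      else db2[, "db_alt" := NA_character_]
      hits <- db2[cand[, c("chrom", "pos", "ref", "alt"), with = FALSE],
                  on = c("chrom", "pos"), nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hits)) {
        ok <- ifelse(!is.na(hits$db_alt) & nzchar(hits$db_alt),
                     hits$alt == hits$db_alt,  # explicit allele rows
                     edit_type_compatible(hits$ref, hits$alt,
                                          hits$strand, hits$type))
        okhits <- unique(hits[ok, c("chrom", "pos"), with = FALSE])
        is_pos <- !is.na(okhits[cand, on = c("chrom", "pos"),
                                which = TRUE, mult = "first"])
      }
    }
  }
  is_neg <- if (methods::is(negatives, "GRanges")) {
    if (length(negatives)) {
      gr_c <- GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$pos, cand$pos))
      IRanges::overlapsAny(gr_c, negatives)
    } else rep(FALSE, nrow(cand))
  } else {
    neg <- data.table::as.data.table(negatives)
    if (nrow(neg))
      !is.na(neg[cand, on = c("chrom", "pos"), which = TRUE, mult = "first"])
    else rep(FALSE, nrow(cand))
  }
  conflict <- is_pos & is_neg
  is_pos <- is_pos & !conflict
  is_neg <- is_neg & !conflict
  in_test <- rep(FALSE, nrow(cand))
  if (!is.null(test_exclusion)) {
    ex <- data.table::as.data.table(test_exclusion)
    check_site_cols(ex)
    if (nrow(ex)) {
      gr_ex <- GenomicRanges::GRanges(
        ex$chrom, IRanges::IRanges(pmax(1L, ex$pos - exclusion_window),
                                   ex$pos + exclusion_window))
      gr_c <- GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$pos, cand$pos))
      in_test <- IRanges::overlapsAny(gr_c, gr_ex)
    }
  }
  test_excluded <- in_test & (is_pos | is_neg)
  train_pos <- is_pos & !in_test
  train_neg <- is_neg & !in_test
  training <- cand[train_pos | train_neg, ]
  training[, "label" := ifelse(train_pos[train_pos | train_neg], "positive", "negative")]
  training[, "label_source" := ifelse(training$label == "positive",
                                      "db_consensus", "mes")]
  targets <- cand[!(train_pos | train_neg | conflict), ]
  excluded <- list(label_conflict = sum(conflict),
                   test_overlap = sum(test_excluded))
  msg <- NULL
  if (!sum(train_pos)) msg <- "no positive training examples"
  if (!sum(train_neg)) msg <- c(msg, "no negative training examples")
  if (!is.null(msg)) {
    txt <- paste0(paste(msg, collapse = "; "),
                  " (candidates=", nrow(cand),
                  ", positives=", sum(train_pos),
                  ", negatives=", sum(train_neg), ")")
    if (on_empty_class == "error") stop_rddkit(txt) else warning(txt, call. = FALSE)
  }
  structure(list(
    training = structure(training, class = c("rdd_training_set", class(training))),
    targets = targets,
    excluded = excluded), class = "rdd_training_compilation")
}

#' Rebalance a training set
#'
#' @param ts An `rdd_training_set`.
#' @param strategy `"none"` or `"downsample_majority"` (majority class
#'   sampled without replacement down to the minority size).
#' @param seed Integer seed.
#' @return An `rdd_training_set`.
#' @export
class_balance <- function(ts, strategy = c("none", "downsample_majority"),
                          seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(ts)
  dt <- data.table::as.data.table(ts)
  tab <- table(dt$label)
  if (length(tab) < 2L || tab[1L] == tab[2L]) return(ts)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  keep_min <- dt[dt$label == minority, ]
  maj <- dt[dt$label == majority, ]
  with_seed(seed, {
    maj <- maj[sample.int(nrow(maj), min(tab)), ]
  })
  out <- data.table::rbindlist(list(keep_min, maj))
  data.table::setkeyv(out, c("chrom", "pos"))
  structure(out, class = c("rdd_training_set", class(out)))
}

#' Write / read a training-set TSV
#' @param ts `rdd_training_set`.
#' @param path File path.
#' @export
write_training_set <- function(ts, path) {
  write_hashed_tsv(data.table::as.data.table(ts), path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  dt <- read_hashed_tsv(path)
  miss <- setdiff(c("chrom", "pos", "label", rdd_feature_names()), names(dt))
  if (length(miss))
    stop_rddkit("training set schema error: missing ", paste(miss, collapse = ", "))
  dt[, "pos" := as.integer(dt$pos)]
  for (j in rdd_feature_names()) data.table::set(dt, j = j, value = as.numeric(dt[[j]]))
  structure(dt, class = c("rdd_training_set", class(dt)))
}
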