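# Random-Forest classifier over the 15 attributes, plus the
# information-gain category ranking used to inspect what the model learns.

#' Train the RDD classifier
#'
#' Random Forest on the 15 attributes; defaults: 100 trees, unlimited
#' depth, floor(sqrt(15)) attributes per split, fixed seed.  Feature
#' order is persisted with the model and enforced at prediction time.
#'
#' @param ts An `rdd_training_set` (both classes non-empty).
#' @param n_trees,mtry,max_nodes Forest hyperparameters (`max_nodes =
#'   NULL` grows trees to purity).
#' @param seed Integer seed; training is deterministic under a fixed seed.
#' @return An `rdd_predictor`: list with `forest`, `feature_names`,
#'   `hyper`, `seed`, `class_counts`, `format_version`.
#' @export
rdd_train <- function(ts, n_trees = 100L, mtry = floor(sqrt(15)),
                      max_nodes = NULL, seed = 1L) {
  dt <- data.table::as.data.table(ts)
  if (!all(c("label", rdd_feature_names()) %in% names(dt)))
    stop_rddkit("training set lacks label or attribute columns")
  tab <- table(factor(dt$label, levels = c("negative", "positive")))
  if (any(tab == 0L))
    stop_rddkit("both classes must be non-empty (negative=", tab[["negative"]],
                ", positive=", tab[["positive"]], ")")
  x <- as.data.frame(dt[, rdd_feature_names(), with = FALSE])
  const <- names(x)[vapply(x, function(v) length(unique(v)) == 1L, TRUE)]
  if (length(const))
    warning("constant attribute column(s): ", paste(const, collapse = ", "),
            call. = FALSE)
  y <- factor(dt$label, levels = c("negative", "positive"))
  forest <- with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                               maxnodes = max_nodes))
  structure(list(forest = forest, feature_names = rdd_feature_names(),
                 hyper = list(n_trees = n_trees, mtry = mtry,
                              max_nodes = max_nodes),
                 seed = seed,
                 class_counts = as.list(tab),
                 format_version = 1L),
            class = "rdd_predictor")
}

#' Persist / restore a trained predictor
#'
#' Single self-describing file embedding the forest, feature order,
#' hyperparameters and seed.
#' @param model An `rdd_predictor`.
#' @param path File path.
#' @export
save_predictor <- function(model, path) {
  stopifnot(inherits(model, "rdd_predictor"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rdd_predictor") || is.null(model$format_version))
    stop_rddkit("not an rdd_predictor file: ", path)
  model
}

#' Predict true editing versus artefact on target sites
#'
#' @param model An `rdd_predictor`.
#' @param targets Candidate rows with the 15 attribute columns.
#' @param threshold Acceptance threshold on the positive-class
#'   probability (accepted iff probability >= threshold).
#' @return data.table: target site columns + `prob` and `accepted`.
#' @export
rdd_predict <- function(model, targets, threshold = 0.5) {
  stopifnot(inherits(model, "rdd_predictor"))
  dt <- data.table::as.data.table(targets)
  miss <- setdiff(model$feature_names, names(dt))
  if (length(miss))
    stop_rddkit("target table lacks attribute column(s): ",
                paste(miss, collapse = ", "))
  out <- dt[, intersect(c("chrom", "pos", "ref", "alt"), names(dt)), with = FALSE]
  if (nrow(dt)) {
    x <- as.data.frame(dt[, model$feature_names, with = FALSE])
    prob <- stats::predict(model$forest, newdata = x, type = "prob")[, "positive"]
  } else prob <- numeric(0)
  out[, "prob" := as.numeric(prob)]
  out[, "accepted" := out$prob >= threshold]
  out[]
}

entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of each attribute against the class label
#'
#' `IG(attr) = H(class) - sum_bins p(bin) H(class | bin)` with
#' equal-frequency discretization of continuous attributes into at most
#' `bins` bins (unique quantile breaks).
#'
#' @param ts An `rdd_training_set` (>= 2 examples per class).
#' @param bins Number of equal-frequency bins.
#' @return Named numeric vector of IG values (bits), one per attribute.
#' @export
information_gain <- function(ts, bins = 10L) {
  dt <- data.table::as.data.table(ts)
  if (min(table(dt$label)) < 2L)
    stop_rddkit("need >= 2 examples per class")
  h0 <- entropy_bits(dt$label)
  vapply(rdd_feature_names(), function(f) {
    v <- dt[[f]]
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L),
                                 names = FALSE, type = 7))
    if (length(br) < 2L) return(0)  # constant attribute
    b <- cut(v, breaks = br, include.lowest = TRUE)
    cond <- sum(vapply(levels(b), function(lv) {
      sel <- b == lv
      if (!any(sel)) return(0)
      mean(sel) * entropy_bits(dt$label[sel])
    }, 0))
    max(0, h0 - cond)
  }, 0)
}

#' Category-level importance report (information-gain ranking)
#'
#' Aggregates per-attribute information gain into the six attribute
#' categories and ranks categories per dataset (descending score; ties
#' get mean ranks), with a mean-rank column across datasets.
#'
#' @param ts_list One `rdd_training_set` or a (optionally named) list of
#'   them (one per dataset/condition).
#' @param bins Discretization bins for [information_gain()].
#' @param agg Category aggregation over member attributes: `"max"`
#'   (default) or `"mean"`.
#' @return List of class `rdd_importance_report`: `attributes`
#'   (per-dataset attribute IG table) and `categories` (per-dataset
#'   category score, per-dataset rank, `RankMean`).
#' @export
importance_report <- function(ts_list, bins = 10L, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  if (inherits(ts_list, "rdd_training_set") || data.table::is.data.table(ts_list))
    ts_list <- list(ts_list)
  if (is.null(names(ts_list)) || any(!nzchar(names(ts_list))))
    names(ts_list) <- paste0("Data", LETTERS[seq_along(ts_list)])
  cats <- rdd_feature_categories()
  afun <- if (agg == "max") max else mean
  ig_tab <- lapply(ts_list, information_gain, bins = bins)
  cat_levels <- unique(unname(cats))
  cat_scores <- lapply(ig_tab, function(ig)
    vapply(cat_levels, function(cc) afun(ig[names(cats)[cats == cc]]), 0))
  categories <- data.table::data.table(Category = cat_levels)
  for (d in names(ts_list)) categories[, (d) := cat_scores[[d]]]
  rank_cols <- character(0)
  for (d in names(ts_list)) {
    rc <- paste0("Rank", sub("^Data", "", d))
    categories[, (rc) := rank(-categories[[d]], ties.method = "average")]
    rank_cols <- c(rank_cols, rc)
  }
  categories[, "RankMean" := rowMeans(categories[, rank_cols, with = FALSE])]
  data.table::setorderv(categories, "RankMean")
  attributes <- data.table::data.table(
    Attribute = rdd_feature_names(),
    Category = unname(cats[rdd_feature_names()]))
  for (d in names(ts_list))
    attributes[, (d) := ig_tab[[d]][rdd_feature_names()]]
  structure(list(attributes = attributes, categories = categories),
            class = "rdd_importance_report")
}
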