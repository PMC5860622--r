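# Discretization, random forest training with per-tree class downsampling,
# out-of-bag evaluation, cutoff selection and Gini importance.

#' Default discretization scheme
#'
#' Fixed, per-feature bins for the 19 features. The published bin edges are
#' not available, so these defaults are this package's own documented
#' choice: E-values binned on log10 thresholds (an exact 0.0 gets its own
#' bin; log-transforms use `max(evalue, 1e-300)` to avoid -Inf), coverage
#' and NTO in five equal bins over \[0, 1\], meta-alignment score in four
#' ranges, path length and domain-interaction score as small categorical
#' ranges, booleans passed through. Every feature has a sentinel
#' `"missing"` bin absorbing `NA`.
#'
#' @return Object of class `discretization_scheme`: named list mapping each
#'   feature to a bin specification.
#' @export
default_scheme <- function() {
  ev <- list(type = "evalue",
             levels = c("zero", "le1e-100", "le1e-50", "le1e-20", "le1e-10",
                        "gt1e-10", "missing"))
  unit <- list(type = "unit",
               levels = c("q1", "q2", "q3", "q4", "q5", "missing"))
  meta <- list(type = "metascore",
               levels = c("neg", "lo", "mid", "hi", "missing"))
  path <- list(type = "path",
               levels = c("-1", "0", "1", "2", "3+", "missing"))
  count <- list(type = "count", levels = c("0", "1", "2", "3+", "missing"))
  bool <- list(type = "bool", levels = c("0", "1"))
  spec <- list(
    path_length = path, dom_int_score = count,
    nto_mf = unit, nto_bp = unit, nto_cc = unit,
    blast_evalue_a = ev, blast_evalue_b = ev,
    eggnog_evalue_a = ev, eggnog_evalue_b = ev,
    blast_qcov_a = unit, blast_qcov_b = unit,
    pfam_metascore_a = meta, pfam_metascore_b = meta,
    blast_brh_a = bool, blast_brh_b = bool,
    eggnog_brh_a = bool, eggnog_brh_b = bool,
    pfam_brh_a = bool, pfam_brh_b = bool)
  structure(spec, class = "discretization_scheme")
}

bin_one <- function(x, spec) {
  lev <- spec$levels
  lab <- switch(spec$type,
    evalue = ifelse(is.na(x), "missing",
             ifelse(x == 0, "zero",
             ifelse(x <= 1e-100, "le1e-100",
             ifelse(x <= 1e-50, "le1e-50",
             ifelse(x <= 1e-20, "le1e-20",
             ifelse(x <= 1e-10, "le1e-10", "gt1e-10")))))),
    unit = ifelse(is.na(x), "missing",
                  paste0("q", pmin(5L, floor(pmax(0, pmin(1, x)) * 5) + 1L))),
    metascore = ifelse(is.na(x), "missing",
                ifelse(x < 0, "neg",
                ifelse(x < 30, "lo",
                ifelse(x < 90, "mid", "hi")))),
    path = ifelse(is.na(x), "missing",
           ifelse(x < 0, "-1",
           ifelse(x >= 3, "3+", as.character(as.integer(x))))),
    count = ifelse(is.na(x), "missing",
            ifelse(x >= 3, "3+", as.character(as.integer(x)))),
    bool = as.character(as.integer(!is.na(x) & as.logical(x))),
    stop("unknown bin type ", spec$type))
  factor(lab, levels = lev)
}

#' Discretize raw feature vectors
#'
#' Maps each raw feature value to its bin per the scheme; booleans pass
#' through as \{0, 1\}. `NA`s land in the sentinel bin, so every raw value
#' maps to exactly one bin.
#'
#' @param features Feature data frame from [compute_pair_features()] (extra
#'   id columns are ignored).
#' @param scheme A discretization scheme (default [default_scheme()]).
#' @return Data frame of factors, one column per feature of the scheme,
#'   with fixed levels.
#' @export
discretize <- function(features, scheme = default_scheme()) {
  missing_cols <- setdiff(names(scheme), names(features))
  if (length(missing_cols) > 0L) {
    stop("feature column(s) absent: ", paste(missing_cols, collapse = ", "))
  }
  out <- lapply(names(scheme), function(f) bin_one(features[[f]], scheme[[f]]))
  names(out) <- names(scheme)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Train the interaction random forest
#'
#' Fits a random forest on discretized features with per-tree class
#' downsampling: each tree's bootstrap draws all positives (with
#' replacement) and `neg_pos_ratio` times as many negatives, via stratified
#' sampling. Out-of-bag votes (fraction of OOB trees voting "interacting")
#' are recorded for every training pair. Deterministic given the seed.
#'
#' @param features Raw feature data frame (discretized internally) or an
#'   already-discretized factor data frame.
#' @param labels Logical (or 0/1) vector: `TRUE` for interacting pairs.
#' @param n_trees Number of trees (default 1000).
#' @param neg_pos_ratio Per-tree non-interacting:interacting ratio
#'   (default 5).
#' @param seed Integer RNG seed.
#' @param scheme Discretization scheme.
#' @param exclude Feature names to drop before training (used for ablation
#'   experiments).
#' @return Object of class `interolog_model`: the fitted forest plus
#'   `oob_votes`, `labels`, the scheme and roster used, and the training
#'   configuration.
#' @export
train_classifier <- function(features, labels, n_trees = 1000L,
                             neg_pos_ratio = 5L, seed = 1L,
                             scheme = default_scheme(), exclude = character(0)) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  x <- if (all(vapply(features[intersect(names(scheme), names(features))],
                      is.factor, logical(1))) &&
           all(names(scheme) %in% names(features))) {
    features[names(scheme)]
  } else discretize(features, scheme)
  x <- x[setdiff(names(x), exclude)]
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  samp <- c(neg = min(neg_pos_ratio * n_pos, n_neg), pos = n_pos)
  set.seed(seed)
  forest <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, strata = y, sampsize = samp,
    replace = TRUE, keep.forest = TRUE)
  structure(list(forest = forest, scheme = scheme,
                 feature_names = names(x),
                 oob_votes = unname(forest$votes[, "pos"]),
                 labels = labels, n_trees = n_trees,
                 neg_pos_ratio = neg_pos_ratio, seed = seed),
            class = "interolog_model")
}

#' Vote fractions for new pairs
#'
#' @param model An `interolog_model`.
#' @param features Raw feature data frame.
#' @return Numeric vector in \[0, 1\]: fraction of trees voting
#'   "interacting" for each row.
#' @export
predict_votes <- function(model, features) {
  x <- discretize(features, model$scheme)[model$feature_names]
  v <- stats::predict(model$forest, newdata = x, type = "vote")
  unname(v[, "pos"])
}

#' Confusion-matrix performance at a vote cutoff
#'
#' A pair is predicted interacting iff its vote fraction is >= `cutoff`.
#' Precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), error = (FP+FN)/N. A metric with a zero denominator is
#' reported as 0 and flagged.
#'
#' @param votes Numeric vote fractions (OOB votes for training pairs).
#' @param labels Logical truth.
#' @param cutoff Vote threshold.
#' @return List of class `performance_report`: `precision`, `sensitivity`,
#'   `specificity`, `oob_error`, `cutoff`, and `degenerate` (names of
#'   zero-denominator metrics).
#' @export
oob_metrics <- function(votes, labels, cutoff) {
  labels <- as.logical(labels)
  keep <- !is.na(votes)
  votes <- votes[keep]; labels <- labels[keep]
  pred <- votes >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  safe <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- c(if (tp + fp == 0) "precision",
                  if (tp + fn == 0) "sensitivity",
                  if (tn + fp == 0) "specificity")
  structure(list(precision = safe(tp, tp + fp),
                 sensitivity = safe(tp, tp + fn),
                 specificity = safe(tn, tn + fp),
                 oob_error = safe(fp + fn, tp + fp + fn + tn),
                 cutoff = cutoff,
                 degenerate = degenerate %||% character(0)),
            class = "performance_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the vote cutoff maximizing the F-measure
#'
#' Scans a regular cutoff grid and returns the value maximizing
#' F1 = 2PR/(P+R); ties go to the largest cutoff (the more specific
#' classifier).
#'
#' @param votes,labels As in [oob_metrics()].
#' @param step Grid step (default 0.01).
#' @return The selected cutoff.
#' @export
select_cutoff <- function(votes, labels, step = 0.01) {
  # round away accumulated floating-point error so a vote exactly at a
  # grid value compares as >= that cutoff
  grid <- round(seq(0, 1, by = step), 10)
  f1 <- vapply(grid, function(ct) {
    m <- oob_metrics(votes, labels, ct)
    p <- m$precision; r <- m$sensitivity
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  best <- max(f1)
  grid[max(which(f1 == best))]
}

#' Area under the ROC curve of the vote ranking
#'
#' Computed with the Mann-Whitney rank formulation (ties counted one
#' half), which equals the trapezoidal area under the ROC traced over all
#' vote cutoffs.
#'
#' @param votes,labels As in [oob_metrics()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(votes, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(votes)
  votes <- votes[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(votes)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Gini importance of the trained forest
#'
#' Mean decrease in Gini impurity per feature, ranked descending.
#'
#' @param model An `interolog_model`.
#' @return Data frame (`feature`, `gini`) sorted by decreasing importance.
#' @export
gini_importance <- function(model) {
  imp <- model$forest$importance[, "MeanDecreaseGini"]
  out <- data.frame(feature = names(imp), gini = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gini, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
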