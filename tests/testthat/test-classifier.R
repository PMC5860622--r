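# Discretization, forest training with downsampling, OOB metrics, cutoff
# selection, ROC-AUC and Gini importance.

raw_features <- function(n, path = 1L) {
  data.frame(
    path_length = rep(path, n), dom_int_score = rep(0L, n),
    nto_mf = runif(n), nto_bp = runif(n), nto_cc = runif(n),
    blast_evalue_a = 10^-runif(n, 10, 120), blast_evalue_b = 10^-runif(n, 10, 120),
    eggnog_evalue_a = 10^-runif(n, 10, 120), eggnog_evalue_b = 10^-runif(n, 10, 120),
    blast_qcov_a = runif(n), blast_qcov_b = runif(n),
    pfam_metascore_a = runif(n, -10, 120), pfam_metascore_b = runif(n, -10, 120),
    blast_brh_a = runif(n) > 0.5, blast_brh_b = runif(n) > 0.5,
    eggnog_brh_a = runif(n) > 0.5, eggnog_brh_b = runif(n) > 0.5,
    pfam_brh_a = runif(n) > 0.5, pfam_brh_b = runif(n) > 0.5)
}

test_that("discretization maps raw values to fixed bins with sentinels", {
  sch <- default_scheme()
  x <- raw_features(1)
  x$blast_evalue_a <- 1e-60; x$eggnog_evalue_a <- 0
  x$eggnog_evalue_b <- NA; x$nto_mf <- 0; x$nto_bp <- 1
  x$pfam_metascore_a <- -3; x$pfam_metascore_b <- NA
  x$path_length <- 2L; x$dom_int_score <- 7L
  d <- discretize(x, sch)
  expect_equal(as.character(d$blast_evalue_a), "le1e-50")
  expect_equal(as.character(d$eggnog_evalue_a), "zero")
  expect_equal(as.character(d$eggnog_evalue_b), "missing")
  expect_equal(as.character(d$nto_mf), "q1")   # 0 falls in the lowest bin
  expect_equal(as.character(d$nto_bp), "q5")
  expect_equal(as.character(d$pfam_metascore_a), "neg")
  expect_equal(as.character(d$pfam_metascore_b), "missing")
  expect_equal(as.character(d$path_length), "2")
  expect_equal(as.character(d$dom_int_score), "3+")
  expect_true(all(vapply(d, is.factor, logical(1))))
  # every value lands in exactly one level of the declared set
  for (f in names(sch)) expect_true(as.character(d[[f]]) %in% sch[[f]]$levels)
  # discretizing a discretized frame is a no-op (train accepts either)
  expect_equal(discretize(x, sch), d)
})

class_features <- function(n, path, ev_exp, unit_lo, meta, brh) {
  # every feature separates the classes, so each tree split is informative
  data.frame(
    path_length = rep(path, n), dom_int_score = rep(if (path == 1L) 2L else 0L, n),
    nto_mf = runif(n, unit_lo, unit_lo + 0.2),
    nto_bp = runif(n, unit_lo, unit_lo + 0.2),
    nto_cc = runif(n, unit_lo, unit_lo + 0.2),
    blast_evalue_a = 10^-runif(n, ev_exp, ev_exp + 30),
    blast_evalue_b = 10^-runif(n, ev_exp, ev_exp + 30),
    eggnog_evalue_a = 10^-runif(n, ev_exp, ev_exp + 30),
    eggnog_evalue_b = 10^-runif(n, ev_exp, ev_exp + 30),
    blast_qcov_a = runif(n, unit_lo, unit_lo + 0.2),
    blast_qcov_b = runif(n, unit_lo, unit_lo + 0.2),
    pfam_metascore_a = rep(meta, n), pfam_metascore_b = rep(meta, n),
    blast_brh_a = rep(brh, n), blast_brh_b = rep(brh, n),
    eggnog_brh_a = rep(brh, n), eggnog_brh_b = rep(brh, n),
    pfam_brh_a = rep(brh, n), pfam_brh_b = rep(brh, n))
}

separable_set <- function(n_pos = 60, n_neg = 200, seed = 99) {
  set.seed(seed)
  pos <- class_features(n_pos, 1L, 80, 0.8, 100, TRUE)
  neg <- class_features(n_neg, -1L, 11, 0, 10, FALSE)
  list(x = rbind(pos, neg), y = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}

test_that("training is deterministic and separates a planted signal", {
  s <- separable_set()
  m1 <- train_classifier(s$x, s$y, n_trees = 200, seed = 42)
  m2 <- train_classifier(s$x, s$y, n_trees = 200, seed = 42)
  expect_identical(m1$oob_votes, m2$oob_votes)
  expect_true(all(m1$oob_votes[s$y] >= 0.9, na.rm = TRUE))
  expect_true(all(m1$oob_votes[!s$y] <= 0.1, na.rm = TRUE))
  expect_equal(m1$forest$ntree, 200)
  expect_error(train_classifier(s$x, rep(TRUE, nrow(s$x))), "both classes")
})

test_that("a single tree yields votes in {0, 1} or never-OOB", {
  s <- separable_set(20, 40)
  m <- train_classifier(s$x, s$y, n_trees = 1, seed = 7)
  v <- m$oob_votes
  expect_true(all(is.nan(v) | v %in% c(0, 1)))
})

test_that("OOB metrics reproduce a hand-computed confusion matrix", {
  # TP=2 FP=2 FN=2 TN=14
  votes <- c(0.9, 0.8, 0.7, 0.65, 0.2, 0.1, rep(0.05, 14))
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, rep(FALSE, 14))
  m <- oob_metrics(votes, labels, 0.6)
  expect_equal(m$precision, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.875)
  expect_equal(m$oob_error, 0.2)

  perfect <- oob_metrics(c(0.9, 0.9, 0.1), c(TRUE, TRUE, FALSE), 0.6)
  expect_equal(perfect$precision, 1); expect_equal(perfect$oob_error, 0)
  # boundary cutoffs
  expect_equal(oob_metrics(votes, labels, 0)$sensitivity, 1)
  expect_equal(oob_metrics(votes, labels, 1.01)$specificity, 1)
  zero <- oob_metrics(c(0.1, 0.1), c(TRUE, FALSE), 0.6)
  expect_equal(zero$precision, 0)
  expect_true("precision" %in% zero$degenerate)
})

test_that("cutoff selection maximizes F1 on the grid, largest tie wins", {
  f1_oracle <- function(votes, labels, ct) {
    tp <- sum(votes >= ct & labels); fp <- sum(votes >= ct & !labels)
    fn <- sum(votes < ct & labels)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  set.seed(31)
  for (trial in 1:8) {
    votes <- round(runif(40), 2)
    labels <- runif(40) < 0.3
    if (length(unique(labels)) < 2) next
    got <- select_cutoff(votes, labels)
    grid <- seq(0, 1, by = 0.01)
    f1 <- vapply(grid, function(ct) f1_oracle(votes, labels, ct), numeric(1))
    expect_equal(got, grid[max(which(f1 == max(f1)))])
  }
  # perfect split at 0.55: the best grid cutoff is the largest one at or
  # below the lowest positive vote
  votes <- c(0.2, 0.3, 0.5, 0.7, 0.8)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(select_cutoff(votes, labels), 0.7)
  expect_equal(select_cutoff(c(0.2, 0.8), c(TRUE, TRUE)), 0.2)
})

test_that("ROC AUC equals pairwise concordance and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
  set.seed(13)
  for (trial in 1:6) {
    votes <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # ties included
    labels <- runif(30) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(votes, labels), auc_oracle(votes, labels))
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(roc_auc(plogis(5 * votes - 2), labels),
                 roc_auc(votes, labels))
  }
})

test_that("Gini importance ranks the planted feature first", {
  # only path_length separates the classes; every other feature is noise
  set.seed(12)
  x <- rbind(raw_features(60, path = 1L), raw_features(200, path = -1L))
  y <- rep(c(TRUE, FALSE), c(60, 200))
  m <- train_classifier(x, y, n_trees = 300, seed = 5)
  imp <- gini_importance(m)
  expect_equal(imp$feature[1], "path_length")
  expect_gt(sum(imp$gini), 0)
  # a constant feature carries no impurity reduction
  x2 <- x; x2$dom_int_score <- 1L
  m2 <- train_classifier(x2, y, n_trees = 100, seed = 5)
  imp2 <- gini_importance(m2)
  expect_equal(imp2$gini[imp2$feature == "dom_int_score"], 0)
})
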