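# independent plain-loop MDR oracle: per fold, rebuild the cell risk map
# with data-frame bookkeeping and average the balanced accuracies
oracle_mdr_tba <- function(X, active, combo, fold) {
  cells <- apply(X[, combo, drop = FALSE], 1, paste, collapse = "")
  bas <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    A <- sum(active[tr])
    I <- sum(!active[tr])
    risk <- new.env()
    for (cell in unique(cells[tr])) {
      a <- sum(active[tr] & cells[tr] == cell)
      i <- sum(!active[tr] & cells[tr] == cell)
      assign(cell, a / max(i, 1e-12) > A / I && a > 0, envir = risk)
    }
    pred <- vapply(cells[!tr], function(cell) {
      if (exists(cell, envir = risk)) get(cell, envir = risk) else FALSE
    }, logical(1))
    sens <- mean(pred[active[!tr]])
    spec <- mean(!pred[!active[!tr]])
    (sens + spec) / 2
  }, numeric(1))
  mean(bas)
}

test_that("a perfectly predictive attribute scores Tba = 1", {
  X <- cbind(good = rep(c(1L, 0L), each = 20),
             bad = rbinom(40, 1, 0.5))
  lab <- rep(c("active", "inactive"), each = 20)
  res <- mdr_score(X, lab, "good", folds = 5, seed = 1)
  expect_equal(res$tba, 1)
  expect_equal(res$fold_ba, rep(1, 5))
})

test_that("an attribute independent of labels scores near 0.5", {
  set.seed(606)
  tbas <- vapply(1:12, function(s) {
    X <- cbind(f = rbinom(200, 1, 0.5))
    lab <- rep(c("active", "inactive"), each = 100)
    mdr_score(X, lab, 1L, folds = 10, seed = s)$tba
  }, numeric(1))
  se <- stats::sd(tbas) / sqrt(length(tbas))
  expect_lt(abs(mean(tbas) - 0.5), 3 * se + 0.01)
})

test_that("two-attribute toy Tba equals the hand-computed per-fold oracle", {
  # 8 genes, 2 attributes, fixed 2-fold assignment; worked by hand:
  # fold 1 test -> sens 1/2, spec 1/2; fold 2 test -> sens 0, spec 1
  X <- cbind(a = c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L),
             b = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
  lab <- rep(c("active", "inactive"), each = 4)
  fold <- rep(c(1L, 2L), 4)
  res <- mdr_score(X, lab, c("a", "b"), fold_assignment = fold)
  expect_equal(res$fold_ba, c(0.5, 0.5))
  expect_equal(res$tba, 0.5)
  expect_equal(res$tba, oracle_mdr_tba(X, lab == "active", c("a", "b"), fold))
})

test_that("mdr_score matches the independent oracle on random data", {
  set.seed(607)
  for (rep in 1:10) {
    n <- 60
    X <- matrix(rbinom(n * 4, 1, runif(1, 0.3, 0.7)), n, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    active <- rbinom(n, 1, 0.5) == 1
    if (sum(active) < 3 || sum(!active) < 3) next
    fold <- histact:::.stratified_folds(active, 3, seed = rep)
    for (size in 1:3) {
      combo <- sort(sample(4, size))
      res <- mdr_score(X, active, combo, fold_assignment = fold)
      expect_equal(res$tba, oracle_mdr_tba(X, active, combo, fold),
                   tolerance = 1e-12)
    }
  }
})

test_that("mdr_score is invariant to attribute order within a combo", {
  dat <- sim_small(91L, 300L)
  cols <- feature_columns(dat$fm, region = "TSS")
  X <- dat$fm$x[, cols[1:6], drop = FALSE]
  active <- dat$labels == "active"
  fold <- histact:::.stratified_folds(active, 5, seed = 2)
  a <- mdr_score(X, active, c(1L, 3L, 5L), fold_assignment = fold)
  b <- mdr_score(X, active, c(5L, 1L, 3L), fold_assignment = fold)
  expect_equal(a$tba, b$tba)
  expect_equal(a$combo, b$combo)
})

test_that("search equals brute-force enumeration and honours the budget", {
  dat <- sim_small(92L, 200L)
  active <- dat$labels == "active"
  # restrict to 8 modifications at TSS for a full-enumeration oracle
  keep <- dat$fm$modification %in% c("H2BK5ac", "H2AK5ac", "H3K4me3",
                                     "H3K9ac", "H4K5ac", "H3R2me1",
                                     "H2AZ", "H4K91ac")
  fm8 <- dat$fm
  fm8$x <- fm8$x[, keep, drop = FALSE]
  fm8$region <- fm8$region[keep]
  fm8$modification <- fm8$modification[keep]
  fm8$modifications <- sort(unique(fm8$modification))

  res <- mdr_search(fm8, dat$labels, "TSS", k_max = 3, folds = 5, seed = 3)
  # independent oracle: same fold assignment, all combinations re-scored
  set.seed(3)
  fold <- histact:::.stratified_folds(active, 5, seed = 3)
  cols <- feature_columns(fm8, region = "TSS")
  X <- fm8$x[, cols, drop = FALSE]
  for (size in 1:3) {
    combos <- utils::combn(8, size)
    tbas <- apply(combos, 2, function(cb)
      oracle_mdr_tba(X, active, cb, fold))
    expect_equal(res[[size]]$tba, max(tbas), tolerance = 1e-12)
    expect_equal(sort(match(res[[size]]$combo, colnames(X))),
                 sort(combos[, which.max(tbas)]))
    expect_equal(res[[size]]$candidates, ncol(combos))
  }
  # k_max = 1 is the max over single-attribute scores by definition
  singles <- vapply(seq_len(ncol(X)), function(j)
    mdr_score(X, active, j, fold_assignment = fold)$tba, numeric(1))
  expect_equal(mdr_search(fm8, dat$labels, "TSS", k_max = 1, folds = 5,
                          seed = 3)[[1]]$tba, max(singles))

  expect_error(mdr_search(dat$fm, dat$labels, "TSS", k_max = 5,
                          max_combos = 100), "max_combos")
})

test_that("the planted mark wins the single-attribute search at TSS", {
  dat <- sim_small(93L, 1000L)
  res <- mdr_search(dat$fm, dat$labels, "TSS", k_max = 1, folds = 10,
                    seed = 5)
  expect_equal(res[[1]]$combo, "TSS:H2BK5ac")
  expect_gt(res[[1]]$tba, 0.7)
})

test_that("MDR best single attribute agrees with the CART root at TSS", {
  hits <- vapply(1:10, function(s) {
    dat <- sim_small(700L + s, 400L)
    cols <- feature_columns(dat$fm, region = "TSS")
    root <- tree_node_features(
      grow_tree(dat$fm$x[, cols], dat$labels, k = 1))[1]
    best <- mdr_search(dat$fm, dat$labels, "TSS", k_max = 1, folds = 5,
                       seed = s)[[1]]$combo
    root == best
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
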