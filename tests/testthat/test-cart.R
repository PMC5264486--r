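test_that("a perfectly separating feature yields a one-node perfect tree", {
  X <- cbind(sep = c(1L, 1L, 1L, 0L, 0L, 0L),
             junk = c(1L, 0L, 1L, 0L, 1L, 0L))
  lab <- rep(c("active", "inactive"), each = 3)
  tr <- grow_tree(X, lab, k = 1)
  expect_equal(tr$k, 1L)
  expect_equal(tree_node_features(tr), "sep")
  expect_equal(accuracy_frequency(predict(tr, X), lab), 1)
  expect_equal(predict(tr, X, type = "label"), c(rep("active", 3),
                                                 rep("inactive", 3)))
})

test_that("toy fixture root equals the hand-worked best Gini split", {
  toy <- toy_tree_data()
  tr <- grow_tree(toy$X, toy$labels, k = 1)
  expect_equal(tree_node_features(tr), "f2")
  expect_equal(tree_node_features(tr),
               colnames(toy$X)[oracle_root_split(toy$X, toy$labels == "active")])
  # manual routing oracle for the k=1 tree: f2=1 -> active leaf (2A/0I),
  # f2=0 -> inactive leaf (2A/4I)
  expect_equal(assign_index(tr, toy$X),
               ifelse(toy$X[, "f2"] == 1L, 1L, -1L))
})

test_that("root split equals the exhaustive best-Gini oracle on random data", {
  set.seed(202)
  for (rep in 1:150) {
    n <- sample(4:12, 1)
    f <- sample(2:6, 1)
    X <- matrix(rbinom(n * f, 1, runif(1, 0.2, 0.8)), n, f,
                dimnames = list(NULL, paste0("f", 1:f)))
    active <- rbinom(n, 1, 0.5) == 1
    if (all(active) || all(!active)) next
    want <- oracle_root_split(X, active)
    if (is.null(want)) {
      expect_warning(tr <- grow_tree(X, active, k = 1), NA)
      expect_equal(tr$k, 0L)
    } else {
      tr <- grow_tree(X, active, k = 1)
      expect_equal(tree_node_features(tr), colnames(X)[want])
    }
  }
})

test_that("root split agrees with rpart on a clear-margin fixture", {
  skip_if_not_installed("rpart")
  dat <- sim_small(61L, 400L)
  cols <- feature_columns(dat$fm, region = "TSS")
  X <- dat$fm$x[, cols, drop = FALSE]
  df <- data.frame(y = factor(dat$labels), X)  # syntactic column names
  rp <- rpart::rpart(y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                    minsplit = 2))
  tr <- grow_tree(X, dat$labels, k = 1)
  expect_equal(make.names(tree_node_features(tr)),
               as.character(rp$frame$var[1]))
})

test_that("nested growth makes training accuracy non-decreasing in k", {
  dat <- sim_small(62L, 300L)
  full <- grow_tree(dat$fm, dat$labels, k = 8)
  accs <- vapply(0:full$k, function(k) {
    accuracy_frequency(predict(prune_tree(full, k), dat$fm), dat$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
  # prune_tree(k) reproduces grow_tree(k) exactly
  for (k in c(1, 3, 5)) {
    direct <- grow_tree(dat$fm, dat$labels, k = k)
    pruned <- prune_tree(full, k)
    expect_equal(tree_node_features(pruned), tree_node_features(direct))
    expect_equal(predict(pruned, dat$fm), predict(direct, dat$fm))
  }
})

test_that("unbounded growth reproduces consistent training labels exactly", {
  set.seed(77)
  X <- matrix(rbinom(30 * 6, 1, 0.5), 30, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  # force label consistency: identical feature rows share a label
  key <- apply(X, 1, paste, collapse = "")
  active <- (as.integer(factor(key)) %% 2L) == 1L
  if (all(active) || all(!active)) active[1] <- !active[1]
  tr <- grow_tree(X, active, k = 100)
  expect_equal(predict(tr, X) == 1L, active)
})

test_that("degenerate label sets return a single-leaf tree with warning", {
  X <- cbind(f1 = c(1L, 0L, 1L))
  expect_warning(tr <- grow_tree(X, rep("active", 3), k = 2), "single-leaf")
  expect_equal(tr$k, 0L)
  expect_equal(predict(tr, X), rep(1L, 3))
  expect_error(grow_tree(X, c("active", "inactive", "active"), k = 0), "k must be")
})

test_that("index assignment demands the tree's features", {
  toy <- toy_tree_data()
  tr <- grow_tree(toy$X, toy$labels, k = 2)
  expect_error(assign_index(tr, toy$X[, c("f1", "f3")]), "missing")
  # single-leaf active tree sends everything to +1
  expect_warning(leaf <- grow_tree(toy$X, rep("active", 8), k = 1))
  expect_equal(assign_index(leaf, toy$X), rep(1L, 8))
})

test_that("designation correlation is Pearson on the +1/-1 vectors", {
  a <- c(1L, 1L, -1L, -1L)
  expect_equal(designation_correlation(a, a), 1)
  expect_equal(designation_correlation(a, -a), -1)
  expect_equal(designation_correlation(a, c(1L, -1L, 1L, -1L)), 0)
  expect_warning(r <- designation_correlation(a, rep(1L, 4)), "zero variance")
  expect_true(is.na(r))
  expect_error(designation_correlation(a, c(1L, 0L, 1L, -1L)), "\\+1/-1")
})

test_that("successive nested trees correlate increasingly strongly", {
  dat <- sim_small(63L, 1000L)
  full <- grow_tree(dat$fm, dat$labels, k = 7)
  idx <- lapply(1:full$k, function(k)
    assign_index(prune_tree(full, k), dat$fm))
  cors <- vapply(seq_len(length(idx) - 1), function(i)
    designation_correlation(idx[[i]], idx[[i + 1]]), numeric(1))
  expect_true(all(cors > 0.5))
  # late additions change designations less than early ones
  expect_gt(mean(utils::tail(cors, 2)), mean(utils::head(cors, 2)) - 0.05)
})

test_that("permutation significance separates signal from noise", {
  # perfectly separable data: no permutation can beat the observed accuracy
  X <- cbind(sep = rep(c(1L, 0L), each = 10),
             f2 = rbinom(20, 1, 0.5))
  lab <- rep(c("active", "inactive"), each = 10)
  sig <- tree_significance(X, lab, k = 1, B = 49, seed = 1)
  expect_equal(sig$observed, 1)
  expect_equal(sig$p_value, 1 / 50)

  # planted-signal preset: clearly significant
  dat <- sim_small(64L, 200L)
  cols <- feature_columns(dat$fm, region = c("TSS", "TSS-1"))
  sig <- tree_significance(dat$fm$x[, cols], dat$labels, k = 2, B = 49,
                           seed = 2)
  expect_lte(sig$p_value, 0.05)
  expect_error(tree_significance(X, lab, k = 1, B = 10), "B >= 19")
})
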