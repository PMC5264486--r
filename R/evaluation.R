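## Evaluation designs: per-region trees, random train/test splits over all
## regions, and single-modification trees with a cross-modification
## ranking. "Prediction accuracy frequency" is the fraction of genes whose
## tree-based +1/-1 designation matches the threshold-based
## active/inactive label.

#' Prediction accuracy frequency
#'
#' @param index +1/-1 tree-based gene designations.
#' @param labels Aligned `"active"`/`"inactive"` (or logical) labels.
#' @return Fraction in `[0, 1]` of genes where +1 coincides with active.
#' @export
accuracy_frequency <- function(index, labels) {
  index <- .check_index(index)
  active <- .as_active(labels)
  if (length(index) != length(active)) stop("length mismatch")
  mean((index == 1L) == active)
}

.eval_report <- function(design, table, trees, seed = NA_integer_,
                         split = NULL, extra = list()) {
  structure(c(list(design = design, table = table, trees = trees,
                   seed = seed, split = split), extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report: %s\n", x$design))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Per-region tree evaluation
#'
#' Grows trees restricted to one region's modification columns and
#' reports, for each node count in `k_list`, the prediction accuracy
#' frequency over all genes. Trees of different sizes come from the same
#' nested best-first sequence, so accuracy is non-decreasing in k.
#'
#' @param fm A `region_features` object.
#' @param labels Activity labels for all genes in `fm`.
#' @param region Region label (e.g. `"TSS"`).
#' @param k_list Internal node counts to evaluate.
#' @param min_leaf Passed to [grow_tree()].
#' @return An `eval_report` with an accuracy table and the largest tree.
#' @export
per_region_eval <- function(fm, labels, region, k_list = 1:7, min_leaf = 1L) {
  stopifnot(inherits(fm, "region_features"))
  cols <- feature_columns(fm, region = region)
  X <- fm$x[, cols, drop = FALSE]
  kmax <- max(k_list)
  full <- suppressWarnings(grow_tree(X, labels, kmax, min_leaf))
  acc <- vapply(k_list, function(k) {
    accuracy_frequency(predict(prune_tree(full, k), X), labels)
  }, numeric(1))
  .eval_report(sprintf("per_region (%s)", region),
               data.frame(region = region, k = k_list, accuracy = acc),
               list(full), extra = list(region = region))
}

#' Random train/test evaluation over all regions
#'
#' Splits genes uniformly at random into train and test sets, grows the
#' nested tree sequence on the training genes over all (region,
#' modification) features, and reports train and test prediction accuracy
#' frequency per node count. The split membership is recorded so a fixed
#' seed reproduces the report byte for byte.
#'
#' @param fm A `region_features` object.
#' @param labels Activity labels.
#' @param frac Training fraction in (0, 1).
#' @param k_list Internal node counts to evaluate.
#' @param seed RNG seed for the split.
#' @param min_leaf Passed to [grow_tree()].
#' @return An `eval_report`; `$split` holds the sorted training gene ids.
#' @export
train_test_eval <- function(fm, labels, frac = 0.5, k_list = 1:7,
                            seed = 1L, min_leaf = 1L) {
  stopifnot(inherits(fm, "region_features"), frac > 0, frac < 1)
  active <- .as_active(labels)
  n <- nrow(fm$x)
  set.seed(seed)
  train <- sort(sample.int(n, round(frac * n)))
  test <- setdiff(seq_len(n), train)
  if (length(unique(active[train])) < 2L)
    stop("a class is absent from the training split")
  kmax <- max(k_list)
  full <- suppressWarnings(grow_tree(fm$x[train, , drop = FALSE],
                                     active[train], kmax, min_leaf))
  rows <- lapply(k_list, function(k) {
    tr <- prune_tree(full, k)
    data.frame(k = k,
               train_accuracy = accuracy_frequency(
                 predict(tr, fm$x[train, , drop = FALSE]), active[train]),
               test_accuracy = accuracy_frequency(
                 predict(tr, fm$x[test, , drop = FALSE]), active[test]))
  })
  .eval_report("train_test", do.call(rbind, rows), list(full), seed = seed,
               split = fm$gene_ids[train])
}

#' Single-modification tree evaluation
#'
#' Restricts the feature matrix to one modification's 24 region columns,
#' grows a k-node tree on all genes, and reports its prediction accuracy
#' frequency — the design behind ranking all 39 marks against each other.
#'
#' @param fm A `region_features` object.
#' @param labels Activity labels.
#' @param modification Modification name.
#' @param k Internal node count (default 5).
#' @param min_leaf Passed to [grow_tree()].
#' @return An `eval_report`.
#' @export
single_modification_eval <- function(fm, labels, modification, k = 5L,
                                     min_leaf = 1L) {
  stopifnot(inherits(fm, "region_features"))
  cols <- feature_columns(fm, modification = modification)
  X <- fm$x[, cols, drop = FALSE]
  tr <- suppressWarnings(grow_tree(X, labels, k, min_leaf))
  acc <- accuracy_frequency(predict(tr, X), labels)
  .eval_report(sprintf("single_modification (%s)", modification),
               data.frame(modification = modification, k = k, accuracy = acc),
               list(tr), extra = list(modification = modification))
}

#' Rank all modifications by single-modification tree accuracy
#'
#' Runs [single_modification_eval()] for every modification in the matrix
#' and sorts by decreasing accuracy (ties alphabetical), giving a ranking
#' of marks by their standalone predictive power.
#'
#' @param fm A `region_features` object.
#' @param labels Activity labels.
#' @param k Internal node count per tree.
#' @param min_leaf Passed to [grow_tree()].
#' @return Data frame with columns `modification`, `accuracy`, best first.
#' @export
rank_modifications <- function(fm, labels, k = 5L, min_leaf = 1L) {
  acc <- vapply(fm$modifications, function(m) {
    single_modification_eval(fm, labels, m, k, min_leaf)$table$accuracy
  }, numeric(1))
  out <- data.frame(modification = fm$modifications, accuracy = unname(acc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$accuracy, out$modification), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as TSV
#'
#' Commented header lines (design, seed, split identity digest) followed
#' by the accuracy table.
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# design\t%s", report$design), con)
  if (!is.na(report$seed))
    writeLines(sprintf("# seed\t%d", report$seed), con)
  if (!is.null(report$split))
    writeLines(sprintf("# train_genes\t%s",
                       paste(report$split, collapse = ",")), con)
  tab <- report$table
  for (j in seq_along(tab))
    if (is.numeric(tab[[j]])) tab[[j]] <- format(tab[[j]], digits = 15)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
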