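## Exhaustive multifactor dimensionality reduction (MDR).
##
## For a combination of binary attributes, genes fall into 2^m cells.
## Within each cross-validation training set a cell is called high-risk
## when its active:inactive ratio exceeds the overall training ratio
## (empty and tied cells are low-risk); test genes are classified by their
## cell's risk, and the combination is scored by the mean testing balanced
## accuracy (Tba) over folds.

## stratified fold assignment: within each class, shuffled genes are dealt
## round-robin into folds
.stratified_folds <- function(active, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(active) < folds || sum(!active) < folds)
    stop(sprintf("need at least %d genes of each class for %d-fold CV",
                 folds, folds))
  fold <- integer(length(active))
  for (cls in c(TRUE, FALSE)) {
    i <- which(active == cls)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  fold
}

.resolve_combo <- function(fm_or_x, combo) {
  if (inherits(fm_or_x, "region_features")) {
    X <- fm_or_x$x
  } else X <- as.matrix(fm_or_x)
  if (is.character(combo)) {
    j <- match(combo, colnames(X))
    if (anyNA(j)) stop(sprintf("unknown attribute: %s",
                               paste(combo[is.na(j)], collapse = ", ")))
    combo <- j
  }
  list(X = X, combo = as.integer(combo))
}

#' Score one attribute combination by cross-validated balanced accuracy
#'
#' @param features Binary feature matrix or `region_features`.
#' @param labels Activity labels.
#' @param combo Attribute combination: column names or indices (order
#'   within the combination does not matter).
#' @param folds Cross-validation folds (stratified by class).
#' @param seed RNG seed for the fold assignment.
#' @param fold_assignment Optional precomputed fold vector (overrides
#'   `folds`/`seed`); used by [mdr_search()] so every combination is
#'   scored on identical folds.
#' @return An `mdr_result`: the combination (canonically ordered labels),
#'   per-fold testing balanced accuracies, their mean `tba`, and the
#'   high/low risk call per cell fitted on all genes.
#' @export
mdr_score <- function(features, labels, combo, folds = 10L, seed = NULL,
                      fold_assignment = NULL) {
  rc <- .resolve_combo(features, combo)
  X <- rc$X
  combo <- sort(rc$combo)
  m <- length(combo)
  if (m < 1L) stop("combination must have at least one attribute")
  active <- .as_active(labels)
  fold <- if (is.null(fold_assignment)) {
    .stratified_folds(active, folds, seed)
  } else fold_assignment
  folds <- max(fold)

  key <- as.integer(X[, combo, drop = FALSE] %*% (2^(seq_len(m) - 1L))) + 1L
  ncell <- 2L^m
  ba <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(active[!tr])) < 2L || length(unique(active[tr])) < 2L)
      stop("a fold lacks one of the classes")
    a <- tabulate(key[tr & active], nbins = ncell)
    i <- tabulate(key[tr & !active], nbins = ncell)
    A <- sum(a); I <- sum(i)
    high <- a * I > i * A   # strict: ties and empty cells are low-risk
    pred <- high[key[!tr]]
    sens <- mean(pred[active[!tr]])
    spec <- mean(!pred[!active[!tr]])
    ba[f] <- (sens + spec) / 2
  }
  a_all <- tabulate(key[active], nbins = ncell)
  i_all <- tabulate(key[!active], nbins = ncell)
  high_all <- a_all * sum(i_all) > i_all * sum(a_all)
  lab <- colnames(X)[combo]
  if (is.null(lab)) lab <- paste0("f", combo)
  structure(list(combo = lab, combo_idx = combo, fold_ba = ba,
                 tba = mean(ba), folds = folds,
                 risk = data.frame(cell = seq_len(ncell) - 1L,
                                   n_active = a_all, n_inactive = i_all,
                                   high_risk = high_all)),
            class = "mdr_result")
}

#' @export
print.mdr_result <- function(x, ...) {
  cat(sprintf("MDR combination {%s}: mean testing balanced accuracy %.4f over %d folds\n",
              paste(x$combo, collapse = ", "), x$tba, x$folds))
  invisible(x)
}

#' Exhaustive MDR search within one gene region
#'
#' Enumerates every combination of 1 to `k_max` modifications among the
#' region's columns, scores each by [mdr_score()] on a shared fold
#' assignment, and keeps the best mean testing balanced accuracy per
#' combination size (ties go to the lexicographically first combination
#' in canonical order).
#'
#' @param fm A `region_features` object.
#' @param labels Activity labels.
#' @param region Region label restricting the attribute pool.
#' @param k_max Largest combination size.
#' @param folds,seed Cross-validation design.
#' @param max_combos Guard on the total number of combinations; exceeding
#'   it errors with advice to lower `k_max` or subset modifications.
#' @return List of `mdr_result`, one per size 1..`k_max`, each carrying a
#'   `$candidates` count.
#' @export
mdr_search <- function(fm, labels, region, k_max = 5L, folds = 10L,
                       seed = 1L, max_combos = 1e5) {
  stopifnot(inherits(fm, "region_features"))
  cols <- feature_columns(fm, region = region)
  nmod <- length(cols)
  if (k_max > nmod) stop("k_max exceeds the number of modifications")
  total <- sum(choose(nmod, seq_len(k_max)))
  if (total > max_combos)
    stop(sprintf("search of %.0f combinations exceeds max_combos = %.0f; lower k_max or subset modifications",
                 total, max_combos))
  active <- .as_active(labels)
  fold <- .stratified_folds(active, folds, seed)
  X <- fm$x[, cols, drop = FALSE]
  out <- vector("list", k_max)
  for (size in seq_len(k_max)) {
    combos <- utils::combn(nmod, size)
    best <- NULL
    for (j in seq_len(ncol(combos))) {
      res <- mdr_score(X, active, combos[, j], fold_assignment = fold)
      if (is.null(best) || res$tba > best$tba) best <- res
    }
    best$candidates <- ncol(combos)
    best$region <- region
    out[[size]] <- best
  }
  out
}

#' Tabulate MDR search results in report form
#'
#' @param results List of `mdr_result` from [mdr_search()].
#' @return Data frame with one row per combination size: the region, the
#'   attribute combination and its mean testing balanced accuracy.
#' @export
mdr_report <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(region = if (is.null(r$region)) NA_character_ else r$region,
               size = length(r$combo),
               combination = paste(r$combo, collapse = ","),
               tba = r$tba, stringsAsFactors = FALSE)
  }))
}
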