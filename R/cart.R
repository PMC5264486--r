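## CART-style binary classification trees on (region, modification)
## presence/absence features.
##
## Growth is best-first: at each step the frontier leaf whose best single
## split gives the largest total Gini impurity decrease is split, so the
## k-node tree is nested inside the (k+1)-node tree and "pruning to k
## nodes" is exact and well defined. "Node" counts internal split tests.

.majority_label <- function(n_active, n_inactive) {
  # tie goes to inactive: the active call must be strictly evidence-driven
  if (n_active > n_inactive) "active" else "inactive"
}

## count-weighted Gini impurity of an (active, inactive) count pair;
## vectorized, 0 for empty nodes
.gini_count <- function(a, i) {
  n <- a + i
  out <- numeric(length(n))
  nz <- n > 0
  out[nz] <- n[nz] - (a[nz]^2 + i[nz]^2) / n[nz]
  out
}

## Best single split of the gene subset `idx`; returns NULL when no split
## strictly decreases impurity. Ties between features break to the
## smallest canonical column index (which.max takes the first maximum).
.best_split <- function(X, active, idx, min_leaf) {
  n <- length(idx)
  A <- sum(active[idx])
  I <- n - A
  if (A == 0L || I == 0L) return(NULL)
  Xs <- X[idx, , drop = FALSE]
  n1 <- colSums(Xs)
  a1 <- colSums(Xs * active[idx])
  i1 <- n1 - a1
  a0 <- A - a1
  i0 <- I - i1
  dec <- .gini_count(A, I) - .gini_count(a1, i1) - .gini_count(a0, i0)
  dec[n1 < min_leaf | (n - n1) < min_leaf] <- -Inf
  m <- max(dec)
  if (!is.finite(m) || m <= 1e-10) return(NULL)
  # exact rational ties surface as few-ulp float differences; lump them and
  # break to the smallest canonical feature index
  j <- which(dec >= m - 1e-8 * (m + 1))[1]
  list(feature = j, decrease = dec[j])
}

new_cart_tree <- function(nodes, feature_labels, k, call = NULL) {
  structure(list(nodes = nodes, feature_labels = feature_labels,
                 k = k, call = call),
            class = "cart_tree")
}

.as_feature_matrix <- function(features) {
  if (inherits(features, "region_features")) features$x else as.matrix(features)
}

.as_active <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  if (!all(lab %in% c("active", "inactive")))
    stop("labels must be 'active'/'inactive' (or logical)")
  lab == "active"
}

#' Grow a k-node binary decision tree on presence/absence features
#'
#' Fits a CART-style classification tree distinguishing active from
#' inactive genes. Candidate splits are all binary features; the split
#' criterion is the total (count-weighted) Gini impurity decrease. Growth
#' is best-first — the frontier leaf offering the globally largest decrease
#' is split next — and stops after `k` internal nodes or when no split
#' decreases impurity, whichever comes first. Leaf labels are the training
#' majority class, with ties assigned inactive. Because growth is
#' best-first, [prune_tree()] recovers every smaller tree of the nested
#' sequence exactly.
#'
#' @param features Binary feature matrix (genes x features) or a
#'   `region_features` object.
#' @param labels Gene activity labels: `"active"`/`"inactive"` or logical
#'   (TRUE = active).
#' @param k Maximum number of internal split nodes (>= 1).
#' @param min_leaf Minimum training genes per child leaf.
#' @return A `cart_tree` object. `$k` is the realized internal node count
#'   (may be < requested `k` when growth stalls).
#' @export
#' @examples
#' X <- cbind(f1 = c(1, 1, 0, 0), f2 = c(1, 0, 1, 0))
#' tr <- grow_tree(X, c("active", "active", "inactive", "inactive"), k = 1)
#' predict(tr, X)
grow_tree <- function(features, labels, k, min_leaf = 1L) {
  X <- .as_feature_matrix(features)
  active <- .as_active(labels)
  if (length(active) != nrow(X))
    stop("labels length must match feature matrix rows")
  if (!all(X %in% c(0L, 1L))) stop("features must be binary 0/1")
  if (k < 1L) stop("k must be >= 1")
  feature_labels <- colnames(X)
  if (is.null(feature_labels)) feature_labels <- paste0("f", seq_len(ncol(X)))

  nodes <- list()
  new_node <- function(idx) {
    a <- sum(active[idx]); i <- length(idx) - a
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(leaf = TRUE, feature = NA_integer_,
                         pos = NA_integer_, neg = NA_integer_,
                         n_active = a, n_inactive = i,
                         label = .majority_label(a, i),
                         split_order = NA_integer_)
    id
  }
  root <- new_node(seq_len(nrow(X)))
  if (all(active) || all(!active)) {
    warning("all labels identical; returning single-leaf tree (k = 0)")
    return(new_cart_tree(nodes, feature_labels, 0L, match.call()))
  }

  # frontier: per-leaf gene subsets and cached best splits
  frontier_idx <- list()
  frontier_idx[[root]] <- seq_len(nrow(X))
  frontier_split <- list()
  frontier_split[[root]] <- .best_split(X, active, frontier_idx[[root]], min_leaf)

  n_internal <- 0L
  while (n_internal < k) {
    open <- which(vapply(seq_along(nodes), function(i) {
      !is.null(frontier_idx[i][[1]]) && !is.null(frontier_split[i][[1]])
    }, logical(1)))
    if (length(open) == 0L) break
    decs <- vapply(open, function(i) frontier_split[[i]]$decrease, numeric(1))
    sizes <- vapply(open, function(i) length(frontier_idx[[i]]), numeric(1))
    # largest decrease; ties -> leaf with more samples, then earliest leaf
    best <- open[order(-decs, -sizes, open)][1]
    sp <- frontier_split[[best]]
    idx <- frontier_idx[[best]]
    on <- idx[X[idx, sp$feature] == 1L]
    off <- idx[X[idx, sp$feature] == 0L]
    pos <- new_node(on)
    neg <- new_node(off)
    n_internal <- n_internal + 1L
    nodes[[best]]$leaf <- FALSE
    nodes[[best]]$feature <- sp$feature
    nodes[[best]]$pos <- pos
    nodes[[best]]$neg <- neg
    nodes[[best]]$split_order <- n_internal
    frontier_idx[best] <- list(NULL)
    frontier_split[best] <- list(NULL)
    frontier_idx[[pos]] <- on
    frontier_split[pos] <- list(.best_split(X, active, on, min_leaf))
    frontier_idx[[neg]] <- off
    frontier_split[neg] <- list(.best_split(X, active, off, min_leaf))
  }
  new_cart_tree(nodes, feature_labels, n_internal, match.call())
}

#' Prune a best-first tree back to its nested k-node subtree
#'
#' Internal nodes are numbered in the order they were split; pruning keeps
#' the first `k` and collapses everything below them into leaves, exactly
#' reproducing the tree that growth would have returned at that size.
#'
#' @param tree A `cart_tree`.
#' @param k Internal node count of the pruned tree (0 gives the root leaf).
#' @return A `cart_tree` with `k` internal nodes.
#' @export
prune_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cart_tree"), k >= 0)
  if (k >= tree$k) return(tree)
  nodes <- list()
  copy <- function(id) {
    nd <- tree$nodes[[id]]
    out_id <- length(nodes) + 1L
    nodes[[out_id]] <<- list()  # reserve
    if (nd$leaf || nd$split_order > k) {
      nodes[[out_id]] <<- list(leaf = TRUE, feature = NA_integer_,
                               pos = NA_integer_, neg = NA_integer_,
                               n_active = nd$n_active,
                               n_inactive = nd$n_inactive,
                               label = .majority_label(nd$n_active, nd$n_inactive),
                               split_order = NA_integer_)
    } else {
      pos <- copy(nd$pos)
      neg <- copy(nd$neg)
      nodes[[out_id]] <<- list(leaf = FALSE, feature = nd$feature,
                               pos = pos, neg = neg,
                               n_active = nd$n_active,
                               n_inactive = nd$n_inactive,
                               label = nd$label,
                               split_order = nd$split_order)
    }
    out_id
  }
  copy(1L)
  new_cart_tree(nodes, tree$feature_labels, as.integer(k), tree$call)
}

## route genes to leaves; returns leaf node id per gene
.route <- function(tree, X) {
  out <- integer(nrow(X))
  recur <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[rows] <<- id
    } else {
      on <- X[rows, nd$feature] == 1L
      if (any(on)) recur(nd$pos, rows[on])
      if (any(!on)) recur(nd$neg, rows[!on])
    }
  }
  if (nrow(X) > 0L) recur(1L, seq_len(nrow(X)))
  out
}

.match_features <- function(tree, features) {
  X <- .as_feature_matrix(features)
  if (!is.null(colnames(X)) && all(tree$feature_labels %in% colnames(X))) {
    X <- X[, tree$feature_labels, drop = FALSE]
  } else if (ncol(X) < length(tree$feature_labels) ||
             (!is.null(colnames(X)) &&
              !all(tree$feature_labels %in% colnames(X)))) {
    miss <- setdiff(tree$feature_labels,
                    if (is.null(colnames(X))) character(0) else colnames(X))
    stop(sprintf("features missing from input: %s",
                 paste(utils::head(miss, 3), collapse = ", ")))
  }
  X
}

#' Predict activity designations from a fitted tree
#'
#' @param object A `cart_tree`.
#' @param newdata Feature matrix or `region_features` covering the tree's
#'   features (matched by column name).
#' @param type `"index"` for the +1/-1 gene index (+1 = routed to an
#'   active-majority leaf), `"label"` for `"active"`/`"inactive"`.
#' @param ... Unused.
#' @return Integer +1/-1 vector or character label vector.
#' @export
predict.cart_tree <- function(object, newdata, type = c("index", "label"), ...) {
  type <- match.arg(type)
  X <- .match_features(object, newdata)
  leaf <- .route(object, X)
  lab <- vapply(leaf, function(i) object$nodes[[i]]$label, "")
  if (type == "label") lab else ifelse(lab == "active", 1L, -1L)
}

#' Assign the +1/-1 activity index from a fitted tree
#'
#' Convenience wrapper for `predict(tree, features, type = "index")`:
#' each gene receives +1 when routed to an active-majority leaf, else -1.
#'
#' @param tree A `cart_tree`.
#' @param features Feature matrix or `region_features`.
#' @return Integer vector of +1/-1.
#' @export
assign_index <- function(tree, features) {
  predict(tree, features, type = "index")
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("CART-style tree with %d internal node(s)\n", x$k))
  recur <- function(id, prefix, branch) {
    nd <- x$nodes[[id]]
    if (nd$leaf) {
      cat(sprintf("%s%s[%s] (%d active / %d inactive)\n", prefix, branch,
                  nd$label, nd$n_active, nd$n_inactive))
    } else {
      cat(sprintf("%s%s%s (split %d; %d active / %d inactive)\n", prefix,
                  branch, x$feature_labels[nd$feature], nd$split_order,
                  nd$n_active, nd$n_inactive))
      recur(nd$pos, paste0(prefix, "  "), "+ ")
      recur(nd$neg, paste0(prefix, "  "), "- ")
    }
  }
  recur(1L, "", "")
  invisible(x)
}

#' @export
summary.cart_tree <- function(object, ...) {
  feats <- vapply(object$nodes, function(nd)
    if (nd$leaf) NA_integer_ else nd$feature, integer(1))
  ord <- vapply(object$nodes, function(nd)
    if (nd$leaf) NA_integer_ else nd$split_order, integer(1))
  internal <- !is.na(feats)
  out <- data.frame(split_order = ord[internal],
                    feature = object$feature_labels[feats[internal]],
                    n_active = vapply(object$nodes[internal], `[[`, 0, "n_active"),
                    n_inactive = vapply(object$nodes[internal], `[[`, 0, "n_inactive"))
  out <- out[order(out$split_order), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(k = object$k, splits = out), class = "summary.cart_tree")
}

#' @export
print.summary.cart_tree <- function(x, ...) {
  cat(sprintf("Tree with %d internal node(s); splits in growth order:\n", x$k))
  print(x$splits)
  invisible(x)
}

#' Features used at the internal nodes, in growth order
#' @param tree A `cart_tree`.
#' @return Character vector of `REGION:MOD` labels, one per internal node.
#' @export
tree_node_features <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  summary(tree)$splits$feature
}

#' Pearson correlation between two +1/-1 designation vectors
#'
#' Used to compare the gene designations of trees of increasing size and
#' pick the most parsimonious tree: successive designations that correlate
#' near 1 indicate that further nodes add little information.
#'
#' @param a,b Integer +1/-1 vectors of equal length.
#' @return Pearson correlation, or `NA` (with a warning) when either
#'   vector has zero variance.
#' @export
designation_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!all(a %in% c(-1L, 1L)) || !all(b %in% c(-1L, 1L)))
    stop("designation vectors must contain only +1/-1")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance in a designation vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Permutation significance of a k-node tree
#'
#' Tests whether the tree's training accuracy exceeds what label
#' permutation alone achieves: labels are permuted `B` times, a k-node
#' tree is regrown on each permutation, and
#' `p = (1 + #permuted accuracy >= observed) / (B + 1)`.
#'
#' @param features Binary feature matrix or `region_features`.
#' @param labels Activity labels.
#' @param k Internal node count.
#' @param B Number of permutations (>= 19).
#' @param seed Optional RNG seed.
#' @param min_leaf Passed to [grow_tree()].
#' @return List with `p_value`, `observed` training accuracy, and the
#'   vector of permuted accuracies.
#' @export
tree_significance <- function(features, labels, k, B = 200L, seed = NULL,
                              min_leaf = 1L) {
  stopifnot(B >= 19)
  X <- .as_feature_matrix(features)
  active <- .as_active(labels)
  if (!is.null(seed)) set.seed(seed)
  acc <- function(lab) {
    tr <- suppressWarnings(grow_tree(X, lab, k, min_leaf))
    mean((predict(tr, X) == 1L) == lab)
  }
  observed <- acc(active)
  perm <- vapply(seq_len(B), function(b) acc(sample(active)), numeric(1))
  list(p_value = (1 + sum(perm >= observed)) / (B + 1),
       observed = observed, permuted = perm, B = as.integer(B))
}
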