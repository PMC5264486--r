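# Shared fixtures and a per-session cache for the heavier simulated
# replicates, so several test files can reuse the same pipeline runs.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# 8-gene, 3-feature worked tree fixture (also shipped as
# inst/extdata/toy_features.tsv). Best root split is f2 by hand:
# count-weighted Gini decreases are f1 = 1, f2 = 4/3, f3 = 0.
toy_tree_data <- function() {
  X <- cbind(f1 = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L),
             f2 = c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
             f3 = c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L))
  list(X = X,
       labels = rep(c("active", "inactive"), each = 4L))
}

# independent exhaustive best-Gini oracle: plain double loop, no shared
# code with grow_tree
oracle_root_split <- function(X, active) {
  gini_n <- function(a, i) {
    n <- a + i
    if (n == 0) return(0)
    p <- a / n
    n * 2 * p * (1 - p)
  }
  A <- sum(active)
  I <- length(active) - A
  parent <- gini_n(A, I)
  best <- NULL
  best_dec <- 0
  for (j in seq_len(ncol(X))) {
    on <- X[, j] == 1L
    dec <- parent - gini_n(sum(active[on]), sum(on) - sum(active[on])) -
      gini_n(sum(active[!on]), sum(!on) - sum(active[!on]))
    if (dec > best_dec + 1e-12) {
      best <- j
      best_dec <- dec
    }
  }
  best  # NULL when nothing improves
}

# small simulated dataset with the default planted structure
sim_small <- function(seed = 101L, n = 400L) {
  cached(sprintf("sim_small_%d_%d", seed, n), {
    sim <- simulate_dataset(sim_config(n_genes = n, seed = seed))
    fm <- simulate_features(sim)
    list(sim = sim, fm = fm,
         labels = ifelse(sim$states == 1L, "active", "inactive"))
  })
}

# Full-pipeline replicate at the acceptance problem size, reduced to the
# small summary the agreement/recovery checks consume (keeps 20 cached
# replicates cheap in memory).
cd4_replicate_summary <- function(seed, n = 5000L) {
  cached(sprintf("cd4_rep_%d_%d", seed, n), {
    sim <- simulate_dataset(sim_config(n_genes = n, seed = seed))
    fm <- simulate_features(sim)
    labels <- ifelse(sim$states == 1L, "active", "inactive")
    tree <- grow_tree(fm, labels, k = 5L)
    avg <- rowMeans(sim$expression)
    ord <- order(-avg)
    idx <- assign_index(tree, fm)[ord]
    expr_sorted <- avg[ord]
    th_cum <- cumulative_threshold(idx, expr_sorted)
    th_p <- pvalue_threshold(idx, expr_sorted)
    ranking <- rank_modifications(fm, labels, k = 5L)
    rm(fm)
    list(n = n, seed = seed,
         boundary = sum(sim$states),
         nodes = tree_node_features(tree),
         g_cum = th_cum$g_max, g_pval = th_p$g_max,
         top_modification = ranking$modification[1])
  })
}
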