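## Expression-ranked gene groups and occurrence-frequency profiles.

#' Partition genes into expression-ranked groups
#'
#' Genes are sorted by decreasing average expression (stable tie-break on
#' gene id) and cut into `G` consecutive groups of near-equal size: the
#' first `n mod G` groups get `ceiling(n / G)` genes, the rest
#' `floor(n / G)`. With 18,729 genes and the default `G = 19` this yields
#' 14 groups of 986 and 5 of 985.
#'
#' @param expr Genes x samples log2 expression matrix with gene row
#'   names, or a named per-gene average vector.
#' @param G Number of groups (>= 2).
#' @return A `gene_partition`: list with `gene_ids` (rank order), `group`
#'   (group index per ranked gene), `sizes`, `mean_expression` (aligned),
#'   and `G`.
#' @export
partition_genes <- function(expr, G = 19L) {
  if (is.matrix(expr)) {
    avg <- rowMeans(expr)
  } else {
    avg <- expr
  }
  if (is.null(names(avg))) names(avg) <- paste0("g", seq_along(avg))
  n <- length(avg)
  if (G < 2L) stop("G must be >= 2")
  if (n < G) stop(sprintf("need at least G = %d genes, got %d", G, n))
  o <- order(-avg, names(avg), method = "radix")
  q <- n %/% G
  r <- n %% G
  sizes <- c(rep(q + 1L, r), rep(q, G - r))
  structure(list(gene_ids = names(avg)[o],
                 group = rep(seq_len(G), times = sizes),
                 sizes = sizes,
                 mean_expression = unname(avg[o]),
                 G = as.integer(G)),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("Gene partition: %d genes in %d expression-ranked groups (sizes %s)\n",
              length(x$gene_ids), x$G,
              paste(unique(x$sizes), collapse = "/")))
  invisible(x)
}

#' Occurrence-frequency profile of a modification at a region
#'
#' For each expression group g, counts the genes carrying the modification
#' at the region (`N_g`) and reports the occurrence frequency
#' `F_g = N_g / N_all`, where `N_all` is the total occurrence count over
#' all groups. A mark distributed evenly over `G = 19` groups has every
#' `F_g` at the random expectation `1/19 = 0.053`.
#'
#' @param fm A `region_features` object.
#' @param part A `gene_partition` over the same genes.
#' @param modification,region The feature to profile.
#' @return A `freq_profile`: list with `counts` (N_g), `total` (N_all),
#'   `freq` (F_g, `NA` and `defined = FALSE` when N_all = 0), plus the
#'   identifying fields.
#' @export
occurrence_frequency <- function(fm, part, modification, region) {
  stopifnot(inherits(fm, "region_features"), inherits(part, "gene_partition"))
  col <- feature_columns(fm, region = region, modification = modification)
  if (length(col) != 1L) stop("(region, modification) is not a feature of fm")
  v <- fm$x[match(part$gene_ids, fm$gene_ids), col]
  if (anyNA(v)) stop("partition contains genes absent from the feature matrix")
  counts <- vapply(seq_len(part$G),
                   function(g) sum(v[part$group == g]), numeric(1))
  total <- sum(counts)
  defined <- total > 0
  structure(list(modification = modification, region = region,
                 counts = counts, total = total,
                 freq = if (defined) counts / total else rep(NA_real_, part$G),
                 defined = defined, G = part$G),
            class = "freq_profile")
}

#' @export
print.freq_profile <- function(x, ...) {
  cat(sprintf("Occurrence-frequency profile: %s at %s (%d groups, N_all = %d)\n",
              x$modification, x$region, x$G, as.integer(x$total)))
  if (x$defined) print(round(x$freq, 4)) else cat("  undefined (N_all = 0)\n")
  invisible(x)
}

#' Transition point of a set of frequency profiles
#'
#' The expression group at which modification-frequency curves converge
#' towards the uniform value `1/G`, operationalized as the group index
#' minimizing the mean absolute deviation of the profiles' `F_g` from
#' `1/G` (ties break to the smaller, i.e. more highly expressed, group).
#' With a planted mixture of active and inactive genes the transition
#' point tracks the mixture boundary group.
#'
#' @param profiles List of `freq_profile` objects over the same partition;
#'   undefined profiles are dropped, and at least two defined ones are
#'   required.
#' @return Integer group index.
#' @export
transition_point <- function(profiles) {
  if (inherits(profiles, "freq_profile")) profiles <- list(profiles)
  defined <- Filter(function(p) isTRUE(p$defined), profiles)
  if (length(defined) == 0L) stop("all profiles are undefined")
  if (length(defined) < 2L) stop("need at least two defined profiles")
  G <- defined[[1]]$G
  if (!all(vapply(defined, function(p) as.integer(p$G), 0L) == G))
    stop("profiles span different partitions")
  fmat <- vapply(defined, function(p) p$freq, numeric(G))
  dev <- rowMeans(abs(fmat - 1 / G))
  which.min(dev)  # first minimum = smaller g on ties
}
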