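## Activity-threshold derivation from the +1/-1 gene index.
##
## Genes are ordered by decreasing average expression. The running sum
## Y(g) = sum_{i<=g} x_i rises while +1 (modification pattern present)
## dominates and falls once -1 dominates; its maximizer g_max marks the
## change point, and the expression value there becomes the log2 activity
## threshold. Genes at ranks <= g_max are called active (the threshold
## gene inclusive), the rest inactive.

.check_index <- function(index) {
  if (length(index) == 0L) stop("empty index vector")
  if (!all(index %in% c(-1L, 1L))) stop("index values must be +1 or -1")
  as.integer(index)
}

.threshold_result <- function(index, expression, gene_ids, g_max, Y, method) {
  n <- length(index)
  labels <- rep("inactive", n)
  labels[seq_len(g_max)] <- "active"
  cc <- concordance(index, labels)
  structure(list(index = index, Y = Y, g_max = g_max, Y_max = Y[g_max],
                 threshold_log2 = unname(expression[g_max]), labels = labels,
                 gene_ids = gene_ids, expression = expression,
                 concordance_above = cc[["frac_above"]],
                 concordance_below = cc[["frac_below"]],
                 method = method),
            class = "activity_threshold")
}

#' Cumulative-sum activity threshold
#'
#' Computes `Y(g) = sum_{i=1..g} x_i` over genes ranked by decreasing
#' expression and sets the activity threshold at
#' `g_max = argmax Y(g)` (smallest such rank on ties, keeping the active
#' set minimal). The gene at `g_max` and all higher-ranked genes are
#' labelled active; the threshold is the expression value at `g_max`.
#'
#' @param index +1/-1 gene index, ordered by decreasing expression
#'   (see [assign_index()]).
#' @param expression Aligned vector of average log2 expression values,
#'   non-increasing.
#' @param gene_ids Optional aligned gene ids.
#' @return An `activity_threshold` object with the Y curve, `g_max`,
#'   `Y_max`, `threshold_log2`, per-gene labels, and the concordance
#'   fractions between index and label above/below the threshold.
#' @export
#' @examples
#' idx <- c(1L, 1L, -1L, 1L, -1L, -1L)
#' cumulative_threshold(idx, expression = 6:1)
cumulative_threshold <- function(index, expression = NULL, gene_ids = NULL) {
  index <- .check_index(index)
  n <- length(index)
  if (is.null(expression)) expression <- rep(NA_real_, n)
  stopifnot(length(expression) == n)
  if (!anyNA(expression) && is.unsorted(-expression))
    warning("expression is not non-increasing; ranks and values disagree")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  Y <- cumsum(index)
  g_max <- which.max(Y)  # first maximum = smallest g
  .threshold_result(index, expression, gene_ids, g_max, Y, "cumulative")
}

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

## Exact two-sided binomial log p-value, replicating the
## minimum-likelihood rejection-region rule of stats::binom.test but
## computed in log space so the rank scan below never underflows.
## Cross-checked against binom.test in the unit tests.
.binom_logp2 <- function(x, n, p) {
  if (p <= 0) return(if (x == 0) 0 else -Inf)
  if (p >= 1) return(if (x == n) 0 else -Inf)
  m <- n * p
  if (abs(x - m) < 1e-9) return(0)
  ld <- stats::dbinom(x, n, p, log = TRUE)
  lrel <- log1p(1e-7)
  if (x < m) {
    i <- seq.int(ceiling(m), n)
    y <- sum(stats::dbinom(i, n, p, log = TRUE) <= ld + lrel)
    lo <- stats::pbinom(x, n, p, log.p = TRUE)
    hi <- stats::pbinom(n - y, n, p, lower.tail = FALSE, log.p = TRUE)
  } else {
    i <- seq.int(0, floor(m))
    y <- sum(stats::dbinom(i, n, p, log = TRUE) <= ld + lrel)
    lo <- stats::pbinom(y - 1, n, p, log.p = TRUE)
    hi <- stats::pbinom(x - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  }
  min(0, .logsumexp2(lo, hi))
}

.binom_p2 <- function(x, n, p) exp(.binom_logp2(x, n, p))

#' P-minimization activity threshold
#'
#' Alternative change-point procedure: for every candidate rank `g`, the
#' +1 proportion among ranks `<= g` and the +1 proportion among ranks
#' `> g` are each compared with the overall +1 proportion by an exact
#' two-sided binomial test, and the rank minimizing the sum of the two
#' p-values (smallest rank on ties) sets the threshold. On informative
#' index vectors this identifies essentially the same threshold as
#' [cumulative_threshold()].
#'
#' @inheritParams cumulative_threshold
#' @return An `activity_threshold` object (with an extra `p_sum` curve).
#' @export
pvalue_threshold <- function(index, expression = NULL, gene_ids = NULL) {
  index <- .check_index(index)
  n <- length(index)
  if (n < 4L) stop("need at least 4 genes")
  pos <- index == 1L
  if (all(pos) || all(!pos))
    stop("degenerate index (all +1 or all -1); no threshold is defined")
  if (is.null(expression)) expression <- rep(NA_real_, n)
  stopifnot(length(expression) == n)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  p_all <- mean(pos)
  cum <- cumsum(pos)
  total <- cum[n]
  # log of the p-value sum: ordering-identical to the plain sum but immune
  # to underflow when both tests are astronomically significant
  log_p_sum <- vapply(seq_len(n - 1L), function(g) {
    .logsumexp2(.binom_logp2(cum[g], g, p_all),
                .binom_logp2(total - cum[g], n - g, p_all))
  }, numeric(1))
  g_min <- which.min(log_p_sum)
  res <- .threshold_result(index, expression, gene_ids, g_min,
                           cumsum(index), "pvalue")
  res$p_sum <- exp(log_p_sum)
  res$log_p_sum <- log_p_sum
  res
}

#' Concordance between index and activity labels
#'
#' Fraction of threshold-active genes carrying index +1 and of
#' threshold-inactive genes carrying index -1.
#'
#' @param index +1/-1 vector.
#' @param labels Aligned `"active"`/`"inactive"` labels.
#' @return Named numeric vector `frac_above`, `frac_below`; `NA` (flagged
#'   by a warning) for an empty class.
#' @export
concordance <- function(index, labels) {
  index <- .check_index(index)
  stopifnot(length(labels) == length(index))
  act <- labels == "active"
  if (!any(act) || all(act))
    warning("empty active or inactive class; concordance partially undefined")
  c(frac_above = if (any(act)) mean(index[act] == 1L) else NA_real_,
    frac_below = if (any(!act)) mean(index[!act] == -1L) else NA_real_)
}

#' @export
print.activity_threshold <- function(x, ...) {
  n <- length(x$index)
  cat(sprintf("Activity threshold (%s procedure) over %d genes\n",
              x$method, n))
  cat(sprintf("  g_max = %d  Y_max = %d\n", x$g_max, x$Y_max))
  if (!is.na(x$threshold_log2))
    cat(sprintf("  log2 expression threshold = %.3f\n", x$threshold_log2))
  cat(sprintf("  active: %d (%.2f%%)  inactive: %d (%.2f%%)\n",
              x$g_max, 100 * x$g_max / n, n - x$g_max,
              100 * (n - x$g_max) / n))
  cat(sprintf("  index concordance: %.2f%% (+1 | active), %.2f%% (-1 | inactive)\n",
              100 * x$concordance_above, 100 * x$concordance_below))
  invisible(x)
}

#' Plot the cumulative-sum curve of an activity threshold
#'
#' @param x An `activity_threshold` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.activity_threshold <- function(x, ...) {
  graphics::plot(seq_along(x$Y), x$Y, type = "l",
                 xlab = "gene rank (decreasing expression)",
                 ylab = "Y(g)", ...)
  graphics::abline(v = x$g_max, lty = 2)
  graphics::points(x$g_max, x$Y_max, pch = 19)
  invisible(x)
}
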