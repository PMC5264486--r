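## Synthetic CD4-like inputs with planted, recoverable structure.
##
## Each gene carries a latent Bernoulli active state; expression is a
## log2-scale two-component Gaussian mixture conditioned on that state,
## and modification presence at each of the 24 regions is Bernoulli with
## state-conditional probabilities. One strongly informative mark is
## planted at TSS-proximal regions and one moderately informative mark at
## TTS regions, over a weakly informative background — the minimal
## structure the downstream tree/threshold/MDR analysis presumes.

## the 39 CD4+ T-cell marks profiled genome-wide (20 methylations,
## 18 acetylations, and the variant H2AZ counted as the 39th)
cd4_modifications <- function() {
  c("H2AK5ac", "H2AK9ac", "H2AZ", "H2BK120ac", "H2BK12ac", "H2BK20ac",
    "H2BK5ac", "H2BK5me1", "H3K14ac", "H3K18ac", "H3K23ac", "H3K27ac",
    "H3K27me1", "H3K27me2", "H3K27me3", "H3K36ac", "H3K36me1", "H3K36me3",
    "H3K4ac", "H3K4me1", "H3K4me2", "H3K4me3", "H3K79me1", "H3K79me2",
    "H3K79me3", "H3K9ac", "H3K9me1", "H3K9me2", "H3K9me3", "H3R2me1",
    "H3R2me2", "H4K12ac", "H4K16ac", "H4K20me1", "H4K20me3", "H4K5ac",
    "H4K8ac", "H4K91ac", "H4R3me2")
}

#' Simulation configuration
#'
#' Builds the generative configuration for [simulate_dataset()]. The
#' `"cd4_like"` preset plants the strongly informative mark H2BK5ac
#' (presence probability 0.8 in active genes vs 0.2 in inactive) at the
#' four TSS-proximal regions TSS, TSS-1, TSS-2, TSS-3, a moderately
#' informative H3K36me3 (0.6 vs 0.3) at TTS and TTS+1, and leaves the
#' remaining 37 marks as weak background (0.35 vs 0.30 everywhere), so
#' the tree, threshold and MDR stages have a known ground truth.
#'
#' @param preset Currently `"cd4_like"`.
#' @param n_genes Number of genes.
#' @param n_samples Expression samples (averaging is sample-count-agnostic).
#' @param pi_active Latent active-state probability.
#' @param mu_active,mu_inactive,sigma Log2 expression mixture parameters
#'   (`mu_active > mu_inactive`).
#' @param modifications Modification names (default: the 39 CD4 marks).
#' @param enrichment Data frame `modification`, `region`, `p_active`,
#'   `p_inactive` overriding the baseline presence probabilities for
#'   specific (mark, region) pairs.
#' @param baseline_active,baseline_inactive Presence probabilities for all
#'   pairs not listed in `enrichment`.
#' @param bin_size Bin width in bp.
#' @param count_model `"binary"` emits count 1 where a mark is present;
#'   `"poisson"` emits `1 + rpois(lambda)` so binarization thresholds have
#'   something to cut.
#' @param lambda Poisson mean for `count_model = "poisson"`.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(preset = "cd4_like",
                       n_genes = 2000L,
                       n_samples = 8L,
                       pi_active = 0.5,
                       mu_active = 8,
                       mu_inactive = 4,
                       sigma = 1,
                       modifications = cd4_modifications(),
                       enrichment = NULL,
                       baseline_active = 0.35,
                       baseline_inactive = 0.30,
                       bin_size = 200L,
                       count_model = c("binary", "poisson"),
                       lambda = 2,
                       seed = 1L) {
  preset <- match.arg(preset)
  count_model <- match.arg(count_model)
  if (pi_active <= 0 || pi_active >= 1) stop("pi_active must be in (0, 1)")
  if (mu_active <= mu_inactive) stop("mu_active must exceed mu_inactive")
  if (is.null(enrichment)) {
    enrichment <- data.frame(
      modification = c(rep("H2BK5ac", 4), rep("H3K36me3", 2)),
      region = c("TSS", "TSS-1", "TSS-2", "TSS-3", "TTS", "TTS+1"),
      p_active = c(rep(0.8, 4), rep(0.6, 2)),
      p_inactive = c(rep(0.2, 4), rep(0.3, 2)),
      stringsAsFactors = FALSE)
  }
  probs <- c(enrichment$p_active, enrichment$p_inactive,
             baseline_active, baseline_inactive)
  if (any(probs < 0 | probs > 1)) stop("presence probabilities must be in [0, 1]")
  if (!all(enrichment$modification %in% modifications))
    stop("enrichment names a modification outside the universe")
  if (!all(enrichment$region %in% region_layout()))
    stop("enrichment names an unknown region")
  structure(list(preset = preset, n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples), pi_active = pi_active,
                 mu_active = mu_active, mu_inactive = mu_inactive,
                 sigma = sigma, modifications = sort(modifications),
                 enrichment = enrichment,
                 baseline_active = baseline_active,
                 baseline_inactive = baseline_inactive,
                 bin_size = as.integer(bin_size), count_model = count_model,
                 lambda = lambda, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config ('%s'): %d genes, %d marks, %d samples\n",
              x$preset, x$n_genes, length(x$modifications), x$n_samples))
  cat(sprintf("  pi_active = %.2f; expression N(%.1f, %.1f) / N(%.1f, %.1f)\n",
              x$pi_active, x$mu_active, x$sigma, x$mu_inactive, x$sigma))
  cat(sprintf("  %d enriched (mark, region) pairs over %.2f/%.2f background\n",
              nrow(x$enrichment), x$baseline_active, x$baseline_inactive))
  invisible(x)
}

## state-conditional presence probability matrices, regions x marks
.presence_probs <- function(config) {
  layout <- region_layout()
  mods <- config$modifications
  pa <- matrix(config$baseline_active, length(layout), length(mods),
               dimnames = list(layout, mods))
  pi_ <- matrix(config$baseline_inactive, length(layout), length(mods),
                dimnames = list(layout, mods))
  e <- config$enrichment
  idx <- cbind(match(e$region, layout), match(e$modification, mods))
  pa[idx] <- e$p_active
  pi_[idx] <- e$p_inactive
  list(active = pa, inactive = pi_)
}

#' Simulate a full input dataset
#'
#' Places `n_genes` non-overlapping genes (random strand) on one synthetic
#' chromosome, draws a latent active state per gene, log2 expression per
#' sample from the state's Gaussian component, and modification presence
#' at each of the 24 regions from the state-conditional Bernoulli
#' probabilities. Present marks are emitted as signal records (count 1, or
#' Poisson-inflated); absent bins are implicit zeros.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_dataset` with `annotation` (gene data
#'   frame), `signals` (signal records), `expression` (genes x samples
#'   log2 matrix), `states` (latent 1/0 active vector, named by gene), and
#'   `config`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 50, seed = 7))
#' table(sim$states)
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  layout <- region_layout()
  mods <- config$modifications
  bs <- config$bin_size

  ## gene placement: each gene owns a 26-bin window [b0, b0 + 25] holding
  ## its full 24-region footprint, windows separated by a 2-bin gap
  stride <- 28L
  b0 <- 10L + (seq_len(n) - 1L) * stride
  strand <- sample(c("+", "-"), n, replace = TRUE)
  plus <- strand == "+"
  tss_bin <- ifelse(plus, b0 + 10L, b0 + 15L)
  tts_bin <- ifelse(plus, b0 + 15L, b0 + 10L)
  annotation <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = "chrS",
    strand = strand,
    tss = tss_bin * bs + bs %/% 2L,
    tts = tts_bin * bs + bs %/% 2L,
    stringsAsFactors = FALSE)
  validate_annotation(annotation)
  bins <- .gene_region_bins(annotation$tss, annotation$tts, plus, bs)
  if (any(bins < 0L)) stop("gene footprint extends before chromosome start")
  # each footprint must stay inside its own 26-bin window (disjoint by design)
  lo <- apply(bins, 1, min)
  hi <- apply(bins, 1, max)
  if (any(lo < b0) || any(hi > b0 + 25L))
    stop("overlapping gene footprints")

  z <- stats::rbinom(n, 1L, config$pi_active)
  expr <- matrix(stats::rnorm(n * config$n_samples,
                              mean = ifelse(z == 1L, config$mu_active,
                                            config$mu_inactive),
                              sd = config$sigma),
                 nrow = n, ncol = config$n_samples,
                 dimnames = list(annotation$gene_id,
                                 sprintf("s%02d", seq_len(config$n_samples))))

  pr <- .presence_probs(config)
  nr <- length(layout)
  nm <- length(mods)
  ## presence array flattened as gene x (region, mod); draw per state
  p_by_gene <- ifelse(rep(z, times = nr * nm) == 1L,
                      rep(as.vector(pr$active), each = n),
                      rep(as.vector(pr$inactive), each = n))
  present <- stats::runif(n * nr * nm) < p_by_gene
  dim(present) <- c(n, nr, nm)

  hit <- which(present, arr.ind = TRUE)
  count <- if (config$count_model == "poisson") {
    1L + stats::rpois(nrow(hit), config$lambda)
  } else rep(1L, nrow(hit))
  signals <- data.frame(
    chrom = rep("chrS", nrow(hit)),
    bin_start = bins[cbind(hit[, 1], hit[, 2])] * bs,
    modification = mods[hit[, 3]],
    count = count,
    stringsAsFactors = FALSE)
  ## anchor the full chromosome extent so absent trailing bins exist as 0s
  signals <- rbind(signals,
                   data.frame(chrom = "chrS", bin_start = max(bins) * bs,
                              modification = mods[1], count = 0L,
                              stringsAsFactors = FALSE))
  o <- order(signals$bin_start, signals$modification)
  signals <- signals[o, , drop = FALSE]
  rownames(signals) <- NULL

  structure(list(annotation = annotation, signals = signals,
                 expression = expr,
                 states = stats::setNames(z, annotation$gene_id),
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset ('%s', seed %d): %d genes (%d active), %s signal records, %d samples\n",
              x$config$preset, x$config$seed, length(x$states),
              sum(x$states), format(nrow(x$signals), big.mark = ","),
              ncol(x$expression)))
  invisible(x)
}

#' Feature matrix straight from a simulated dataset
#'
#' Convenience pipeline step: binarize the simulated signal records and
#' assemble the gene-by-(region, modification) matrix over the configured
#' modification universe.
#'
#' @param sim A `sim_dataset`.
#' @param threshold Binarization count threshold (see [binarize()]).
#' @return A `region_features` object.
#' @export
simulate_features <- function(sim, threshold = 0L) {
  stopifnot(inherits(sim, "sim_dataset"))
  bsm <- binarize(sim$signals, threshold = threshold,
                  bin_size = sim$config$bin_size,
                  modifications = sim$config$modifications)
  build_feature_matrix(bsm, sim$annotation,
                       modifications = sim$config$modifications)
}

#' Write a simulated dataset to a directory
#'
#' Emits `annotation.tsv`, `signals.tsv`, `expression.tsv` and
#' `states.tsv` in the formats the readers in this package accept.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_signal_table(sim$signals, file.path(dir, "signals.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  utils::write.table(data.frame(gene_id = names(sim$states),
                                state = sim$states),
                     file.path(dir, "states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
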