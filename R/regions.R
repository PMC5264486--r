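#' Canonical 24-region layout around TSS and TTS
#'
#' Genes are profiled at five localities covering 24 nucleosome-sized
#' (200 bp) gene regions: ten bins upstream of the transcription start site
#' (`TSS-10` ... `TSS-1`), the bin containing the TSS itself, two bins
#' downstream (`TSS+1`, `TSS+2`), the bin containing the transcription
#' termination site, and ten bins past it (`TTS+1` ... `TTS+10`).
#' "Upstream"/"downstream" are relative to the direction of transcription,
#' so the layout is strand-aware.
#'
#' @return Character vector of the 24 region labels in canonical order.
#' @export
#' @examples
#' region_layout()
region_layout <- function() {
  c(paste0("TSS-", 10:1), "TSS", "TSS+1", "TSS+2",
    "TTS", paste0("TTS+", 1:10))
}

## signed bin offsets from the TSS bin (first 13) and TTS bin (last 11),
## in transcription direction; multiplied by -1 on the minus strand
.region_offsets <- function() {
  list(tss = c(-(10:1), 0L, 1L, 2L), tts = c(0L, 1:10))
}

#' Map a gene to its 24 region bins
#'
#' Computes, for one annotated gene, the genomic 200 bp bin index of each of
#' the 24 canonical regions. The TSS region is the bin containing the TSS
#' coordinate; `TSS-k` lies k bins upstream (against the direction of
#' transcription), `TSS+k` downstream; `TTS+k` lies k bins past the TTS bin
#' in the direction of transcription. Bins that fall before the chromosome
#' start are flagged missing.
#'
#' @param gene A one-row data frame (or list) with fields `gene_id`,
#'   `chrom`, `strand` (`"+"` or `"-"`), `tss`, `tts` (bp coordinates).
#' @param layout Region labels, normally [region_layout()].
#' @param bin_size Bin width in bp (default 200).
#' @return A data frame with columns `region`, `chrom`, `bin`, `missing`.
#'   `bin` is the 0-based bin index (`floor(position / bin_size)`); missing
#'   regions carry `NA` bins.
#' @export
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
#'                 tss = 1000, tts = 5000)
#' gene_regions(g, region_layout())
gene_regions <- function(gene, layout = region_layout(), bin_size = 200) {
  stopifnot(bin_size > 0)
  strand <- as.character(gene$strand)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  bins <- drop(.gene_region_bins(as.integer(gene$tss), as.integer(gene$tts),
                                 strand == "+", bin_size))
  data.frame(region = layout,
             chrom = rep(as.character(gene$chrom), length(layout)),
             bin = ifelse(bins < 0L, NA_integer_, bins),
             missing = bins < 0L,
             stringsAsFactors = FALSE)
}

## vectorized core: tss/tts are coordinate vectors, plus_strand logical.
## Returns an n x 24 integer matrix of bin indices (can be negative).
.gene_region_bins <- function(tss, tts, plus_strand, bin_size = 200) {
  off <- .region_offsets()
  sgn <- ifelse(plus_strand, 1L, -1L)
  tss_bin <- tss %/% bin_size
  tts_bin <- tts %/% bin_size
  cbind(outer(sgn, off$tss) + tss_bin,
        outer(sgn, off$tts) + tts_bin)
}

#' Binarize signal records into a bin-by-modification matrix
#'
#' Builds the genome-anchored binary matrix (MATRIX 1 of the analysis):
#' one row per 200 bp bin, one column per modification, entries 1 where the
#' ChIP tag count exceeds `threshold` and 0 elsewhere. The default
#' `threshold = 0` reproduces the presence/absence rule (any positive count,
#' including the occasional count of several hundred, collapses to 1).
#' Bins absent from the input are implicitly 0.
#'
#' @param records Signal records: a data frame with columns `chrom`,
#'   `bin_start` (bp, multiple of `bin_size`), `modification`, `count`.
#' @param threshold Count threshold; an entry is 1 iff `count > threshold`.
#' @param bin_size Bin width in bp.
#' @param modifications Optional character vector fixing the modification
#'   universe (columns); defaults to the sorted set observed in `records`.
#' @return An object of class `bin_signals`: per-chromosome 0/1 integer
#'   matrices (rows are bins 0..max, columns modifications in sorted order).
#' @export
binarize <- function(records, threshold = 0L, bin_size = 200,
                     modifications = NULL) {
  stopifnot(threshold >= 0)
  validate_signal_records(records, bin_size)
  mods <- if (is.null(modifications)) {
    sort(unique(as.character(records$modification)))
  } else sort(unique(as.character(modifications)))
  if (!all(records$modification %in% mods))
    stop("records contain modifications outside the supplied universe")
  chroms <- list()
  keep <- records$count > threshold
  rec <- records[keep, , drop = FALSE]
  for (ch in unique(as.character(records$chrom))) {
    sub <- rec[rec$chrom == ch, , drop = FALSE]
    allbins <- records$bin_start[records$chrom == ch] %/% bin_size
    nb <- max(allbins) + 1L
    m <- matrix(0L, nrow = nb, ncol = length(mods),
                dimnames = list(NULL, mods))
    if (nrow(sub) > 0L) {
      m[cbind(sub$bin_start %/% bin_size + 1L,
              match(as.character(sub$modification), mods))] <- 1L
    }
    chroms[[ch]] <- m
  }
  structure(list(chroms = chroms, modifications = mods,
                 bin_size = bin_size, threshold = as.integer(threshold)),
            class = "bin_signals")
}

#' @export
print.bin_signals <- function(x, ...) {
  nb <- vapply(x$chroms, nrow, integer(1))
  cat("Binary bin-by-modification signal matrix (MATRIX 1)\n")
  cat(sprintf("  %d chromosome(s), %s bins, %d modifications, %d bp bins\n",
              length(x$chroms), format(sum(nb), big.mark = ","),
              length(x$modifications), x$bin_size))
  cat(sprintf("  binarization: count > %d\n", x$threshold))
  invisible(x)
}

#' Build the gene-by-(region, modification) feature matrix
#'
#' Assembles MATRIX 2: one row per gene and one binary column per
#' (region, modification) pair, with regions in canonical layout order and
#' modifications alphabetical within each region (so 39 modifications over
#' 24 regions give 936 features). The entry for a gene and feature is the
#' binarized signal at the gene's region bin. Regions falling off the
#' chromosome start contribute 0 with a mask bit set; genes on chromosomes
#' absent from the signal matrix get an all-zero row, a full mask, and a
#' warning.
#'
#' @param bsm A `bin_signals` object from [binarize()].
#' @param genes Gene annotation data frame (`gene_id`, `chrom`, `strand`,
#'   `tss`, `tts`).
#' @param layout Region labels, normally [region_layout()].
#' @param modifications Modification universe; defaults to
#'   `bsm$modifications`.
#' @return An object of class `region_features` with elements `x`
#'   (genes x features 0/1 integer matrix, `"REGION:MOD"` column names),
#'   `gene_ids`, `region`, `modification` (per-column descriptors), and
#'   `mask` (logical matrix flagging missing regions).
#' @export
build_feature_matrix <- function(bsm, genes, layout = region_layout(),
                                 modifications = NULL) {
  stopifnot(inherits(bsm, "bin_signals"))
  mods <- if (is.null(modifications)) bsm$modifications
          else sort(unique(as.character(modifications)))
  if (length(mods) == 0L) stop("modification list is empty")
  validate_annotation(genes)
  n <- nrow(genes)
  nr <- length(layout)
  nm <- length(mods)
  feat_region <- rep(layout, each = nm)
  feat_mod <- rep(mods, times = nr)
  labels <- paste0(feat_region, ":", feat_mod)

  bins <- .gene_region_bins(as.integer(genes$tss), as.integer(genes$tts),
                            as.character(genes$strand) == "+", bsm$bin_size)
  x <- matrix(0L, nrow = n, ncol = nr * nm,
              dimnames = list(genes$gene_id, labels))
  mask <- matrix(FALSE, nrow = n, ncol = nr,
                 dimnames = list(genes$gene_id, layout))
  chrom <- as.character(genes$chrom)
  absent <- !(chrom %in% names(bsm$chroms))
  if (any(absent)) {
    warning(sprintf("%d gene(s) on chromosomes absent from the signal matrix; emitting all-zero rows", sum(absent)))
    mask[absent, ] <- TRUE
  }
  have_cols <- lapply(bsm$chroms, function(m) match(mods, colnames(m)))
  for (ch in unique(chrom[!absent])) {
    gi <- which(chrom == ch)
    m <- bsm$chroms[[ch]]
    nb <- nrow(m)
    mcol <- have_cols[[ch]]
    for (r in seq_len(nr)) {
      b <- bins[gi, r]
      off <- b < 0L | b >= nb
      mask[gi[off], r] <- mask[gi[off], r] | (b[off] < 0L)
      ok <- which(!off)
      if (length(ok) > 0L) {
        cols <- (r - 1L) * nm + seq_len(nm)
        for (j in seq_len(nm)) {
          if (!is.na(mcol[j]))
            x[gi[ok], cols[j]] <- m[b[ok] + 1L, mcol[j]]
        }
      }
    }
  }
  structure(list(x = x, gene_ids = genes$gene_id, region = feat_region,
                 modification = feat_mod, mask = mask, layout = layout,
                 modifications = mods),
            class = "region_features")
}

#' @export
print.region_features <- function(x, ...) {
  cat("Gene-by-(region, modification) binary feature matrix (MATRIX 2)\n")
  cat(sprintf("  %d genes x %d features (%d regions x %d modifications)\n",
              nrow(x$x), ncol(x$x), length(x$layout), length(x$modifications)))
  if (any(x$mask))
    cat(sprintf("  %d masked (off-chromosome) gene-region cells\n", sum(x$mask)))
  invisible(x)
}

#' Select feature columns by region and/or modification
#'
#' @param fm A `region_features` object.
#' @param region,modification Optional filters; `NULL` keeps all.
#' @return Integer vector of column indices into `fm$x`, in canonical order.
#' @export
feature_columns <- function(fm, region = NULL, modification = NULL) {
  stopifnot(inherits(fm, "region_features"))
  keep <- rep(TRUE, ncol(fm$x))
  if (!is.null(region)) {
    if (!all(region %in% fm$layout)) stop("unknown region label")
    keep <- keep & fm$region %in% region
  }
  if (!is.null(modification)) {
    if (!all(modification %in% fm$modification))
      stop(sprintf("unknown modification '%s'",
                   paste(setdiff(modification, fm$modification), collapse = ", ")))
    keep <- keep & fm$modification %in% modification
  }
  which(keep)
}
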