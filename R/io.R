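## Validators shared by the readers and the in-memory constructors.

validate_signal_records <- function(records, bin_size) {
  need <- c("chrom", "bin_start", "modification", "count")
  if (!all(need %in% names(records)))
    stop("signal records need columns chrom, bin_start, modification, count")
  if (any(records$count < 0)) stop("negative tag count")
  if (any(records$bin_start %% bin_size != 0))
    stop(sprintf("bin_start not a multiple of bin_size (%d)", bin_size))
  invisible(records)
}

validate_annotation <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "tts")
  if (!all(need %in% names(genes)))
    stop("annotation needs columns gene_id, chrom, strand, tss, tts")
  if (anyDuplicated(genes$gene_id))
    stop(sprintf("duplicate gene id: %s",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$tss == genes$tts)) stop("tss must differ from tts")
  plus <- genes$strand == "+"
  if (any(plus & genes$tss > genes$tts))
    stop("plus-strand gene with tss > tts")
  if (any(!plus & genes$tss < genes$tts))
    stop("minus-strand gene with tss < tts")
  invisible(genes)
}

#' Read a per-bin histone-modification signal table
#'
#' Parses a TSV with header columns `chrom`, `bin_start`, `modification`,
#' `count` (additional columns are ignored). `bin_start` is the 0-based bp
#' start of a `bin_size`-wide genomic bin; `count` is a non-negative ChIP
#' tag count.
#'
#' @param path File path.
#' @param bin_size Bin width in bp; every `bin_start` must be a multiple.
#' @return Data frame of validated signal records.
#' @export
read_signal_table <- function(path, bin_size = 200) {
  stopifnot(bin_size > 0)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "bin_start", "modification", "count")
  if (!all(need %in% names(tab)))
    stop("signal table must have columns chrom, bin_start, modification, count")
  tab <- tab[need]
  bs <- suppressWarnings(as.integer(tab$bin_start))
  ct <- suppressWarnings(as.integer(tab$count))
  bad <- which(is.na(bs) | is.na(ct))[1]
  if (!is.na(bad))
    stop(sprintf("malformed row at line %d of %s", bad + 1L, path))
  bad <- which(ct < 0)[1]
  if (!is.na(bad))
    stop(sprintf("negative count at line %d of %s", bad + 1L, path))
  bad <- which(bs %% bin_size != 0)[1]
  if (!is.na(bad))
    stop(sprintf("bin_start not a multiple of %d at line %d of %s",
                 bin_size, bad + 1L, path))
  data.frame(chrom = as.character(tab$chrom), bin_start = bs,
             modification = as.character(tab$modification), count = ct,
             stringsAsFactors = FALSE)
}

#' Write a signal table
#' @param records Signal record data frame.
#' @param path File path.
#' @export
write_signal_table <- function(records, path) {
  utils::write.table(records[c("chrom", "bin_start", "modification", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation
#'
#' Accepts either a headered TSV with columns `gene_id`, `chrom`, `strand`,
#' `tss`, `tts`, or a headerless BED6-like file (`chrom start end name
#' score strand`, 0-based half-open) from which TSS/TTS are derived
#' strand-aware (`+`: tss = start, tts = end - 1; `-`: tss = end - 1,
#' tts = start). Minus-strand genes therefore carry `tss > tts`.
#'
#' @param path File path.
#' @return Validated annotation data frame.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("gene_id", first, fixed = TRUE)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = as.character(tab$gene_id),
                        chrom = as.character(tab$chrom),
                        strand = as.character(tab$strand),
                        tss = as.integer(tab$tss), tts = as.integer(tab$tts),
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 6) stop("BED-like annotation needs 6 columns")
    plus <- tab[[6]] == "+"
    genes <- data.frame(gene_id = as.character(tab[[4]]),
                        chrom = as.character(tab[[1]]),
                        strand = as.character(tab[[6]]),
                        tss = as.integer(ifelse(plus, tab[[2]], tab[[3]] - 1L)),
                        tts = as.integer(ifelse(plus, tab[[3]] - 1L, tab[[2]])),
                        stringsAsFactors = FALSE)
  }
  validate_annotation(genes)
}

#' Write gene annotation as headered TSV
#' @param genes Annotation data frame.
#' @param path File path.
#' @export
write_annotation <- function(genes, path) {
  validate_annotation(genes)
  utils::write.table(genes[c("gene_id", "chrom", "strand", "tss", "tts")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and column-concatenate expression tables
#'
#' Each file is a TSV with a `gene_id` column followed by one column per
#' sample of log2-scale normalized expression values (RMA convention; the
#' pipeline never re-logs). Files are joined on the intersection of their
#' gene ids, in the gene order of the first file.
#'
#' @param paths Character vector of one or more file paths.
#' @return Numeric matrix, genes x samples, with gene ids as row names.
#' @export
read_expression <- function(paths) {
  stopifnot(length(paths) >= 1)
  tabs <- lapply(paths, utils::read.delim, stringsAsFactors = FALSE)
  for (i in seq_along(tabs)) {
    if (!"gene_id" %in% names(tabs[[i]]))
      stop(sprintf("expression file %s lacks a gene_id column", paths[i]))
    if (anyDuplicated(tabs[[i]]$gene_id))
      stop(sprintf("duplicate gene id in %s", paths[i]))
  }
  genes <- tabs[[1]]$gene_id
  for (t in tabs[-1]) genes <- genes[genes %in% t$gene_id]
  if (length(genes) == 0L) stop("expression files share no gene ids")
  mats <- lapply(tabs, function(t) {
    m <- as.matrix(t[match(genes, t$gene_id), setdiff(names(t), "gene_id"),
                     drop = FALSE])
    storage.mode(m) <- "double"
    m
  })
  out <- do.call(cbind, mats)
  if (any(!is.finite(out))) stop("non-finite expression values")
  rownames(out) <- genes
  out
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix with gene row names.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region feature matrix as TSV
#'
#' One row per gene, one `REGION:MOD` column per feature; masked
#' (off-chromosome) cells are written as `NA` so the mask round-trips.
#'
#' @param fm A `region_features` object.
#' @param path File path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "region_features"))
  x <- fm$x
  maskwide <- fm$mask[, match(fm$region, fm$layout), drop = FALSE]
  x[maskwide] <- NA_integer_
  df <- data.frame(gene_id = fm$gene_ids, x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region feature matrix written by [write_feature_matrix()]
#' @param path File path.
#' @param layout Region labels, normally [region_layout()].
#' @return A `region_features` object.
#' @export
read_feature_matrix <- function(path, layout = region_layout()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df$gene_id)
  x <- as.matrix(df[setdiff(names(df), "gene_id")])
  storage.mode(x) <- "integer"
  lab <- colnames(x)
  parts <- regmatches(lab, regexpr(":", lab), invert = TRUE)
  region <- vapply(parts, `[`, "", 1)
  modification <- vapply(parts, `[`, "", 2)
  if (!all(region %in% layout)) stop("unknown region label in feature matrix")
  mask <- matrix(FALSE, nrow(x), length(layout),
                 dimnames = list(gene_ids, layout))
  for (r in layout) {
    cols <- which(region == r)
    if (length(cols))
      mask[, r] <- apply(is.na(x[, cols, drop = FALSE]), 1, any)
  }
  x[is.na(x)] <- 0L
  rownames(x) <- gene_ids
  structure(list(x = x, gene_ids = gene_ids, region = region,
                 modification = modification, mask = mask, layout = layout,
                 modifications = sort(unique(modification))),
            class = "region_features")
}

#' Serialize a decision tree to JSON text
#'
#' Nested JSON with explicit `REGION:MOD` feature labels; internal nodes
#' carry `pos`/`neg` children for feature present/absent, leaves carry the
#' class label and training counts.
#'
#' @param tree A `cart_tree` object.
#' @param path File path.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "cart_tree"))
  as_list <- function(id) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      list(label = nd$label,
           n_active = nd$n_active, n_inactive = nd$n_inactive)
    } else {
      list(feature = tree$feature_labels[nd$feature],
           split_order = nd$split_order,
           n_active = nd$n_active, n_inactive = nd$n_inactive,
           pos = as_list(nd$pos), neg = as_list(nd$neg))
    }
  }
  obj <- list(k = tree$k, feature_labels = tree$feature_labels,
              root = as_list(1L))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Read a decision tree written by [write_tree()]
#' @param path File path.
#' @return A `cart_tree` object.
#' @export
read_tree <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = FALSE)
  labels <- unlist(obj$feature_labels)
  nodes <- list()
  build <- function(o) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()  # reserve slot
    if (is.null(o$feature)) {
      nodes[[id]] <<- list(leaf = TRUE, feature = NA_integer_,
                           pos = NA_integer_, neg = NA_integer_,
                           n_active = o$n_active, n_inactive = o$n_inactive,
                           label = o$label, split_order = NA_integer_)
    } else {
      pos <- build(o$pos)
      neg <- build(o$neg)
      nodes[[id]] <<- list(leaf = FALSE,
                           feature = match(o$feature, labels),
                           pos = pos, neg = neg,
                           n_active = o$n_active, n_inactive = o$n_inactive,
                           label = .majority_label(o$n_active, o$n_inactive),
                           split_order = o$split_order)
    }
    id
  }
  build(obj$root)
  new_cart_tree(nodes, labels, obj$k)
}

#' Write a threshold report
#'
#' Summary block (commented header lines) followed by a per-gene TSV of
#' rank, gene id, expression, +1/-1 index, running Y value and
#' active/inactive label.
#'
#' @param res An `activity_threshold` object.
#' @param path File path.
#' @export
write_threshold_report <- function(res, path) {
  stopifnot(inherits(res, "activity_threshold"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, digits = 15)
  writeLines(c(sprintf("# method\t%s", res$method),
               sprintf("# g_max\t%d", res$g_max),
               sprintf("# Y_max\t%d", res$Y_max),
               sprintf("# threshold_log2\t%s", num(res$threshold_log2)),
               sprintf("# concordance_above\t%s", num(res$concordance_above)),
               sprintf("# concordance_below\t%s", num(res$concordance_below))),
             con)
  df <- data.frame(rank = seq_along(res$index), gene_id = res$gene_ids,
                   expression = num(res$expression), index = res$index,
                   Y = res$Y, label = res$labels, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a threshold report written by [write_threshold_report()]
#' @param path File path.
#' @return An `activity_threshold` object.
#' @export
read_threshold_report <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  df <- utils::read.delim(textConnection(lines[!startsWith(lines, "# ")]),
                          stringsAsFactors = FALSE)
  structure(list(index = as.integer(df$index), Y = as.integer(df$Y),
                 g_max = as.integer(meta[["g_max"]]),
                 Y_max = as.integer(meta[["Y_max"]]),
                 threshold_log2 = as.numeric(meta[["threshold_log2"]]),
                 labels = df$label, gene_ids = as.character(df$gene_id),
                 expression = as.numeric(df$expression),
                 concordance_above = as.numeric(meta[["concordance_above"]]),
                 concordance_below = as.numeric(meta[["concordance_below"]]),
                 method = meta[["method"]]),
            class = "activity_threshold")
}
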