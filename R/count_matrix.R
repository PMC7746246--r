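#' Construct a gene x sample count matrix with sample metadata
#'
#' @param counts non-negative integer matrix, genes in rows (unique
#'   rownames), samples in columns.
#' @param meta data.frame with one row per sample: sample_id, phase
#'   (`pre` or `post`), capture label, replicate label. Order must match the
#'   matrix columns.
#' @return object of class `count_matrix` with a `library_size` element
#'   (column sums).
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique rownames (gene_ids)")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative")
  }
  need <- c("sample_id", "phase", "capture", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(meta) != ncol(counts)) {
    stop("metadata rows (", nrow(meta), ") != matrix columns (",
         ncol(counts), ")")
  }
  if (!all(meta$phase %in% c("pre", "post"))) {
    stop("phase must be 'pre' or 'post'")
  }
  colnames(counts) <- meta$sample_id
  structure(
    list(counts = counts, meta = meta, library_size = colSums(counts)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$meta$phase == "pre"), "pre /",
      sum(x$meta$phase == "post"), "post )\n")
  invisible(x)
}

#' Counts-per-million normalization
#'
#' cpm[g, s] = counts[g, s] / library_size[s] * 1e6, so every used column
#' sums to one million.
#'
#' @param counts `count_matrix` or plain matrix.
#' @param library_size per-sample totals when `counts` is a plain matrix;
#'   defaults to column sums.
#' @return numeric matrix of CPM values.
#' @export
cpm_normalize <- function(counts, library_size = NULL) {
  if (inherits(counts, "count_matrix")) {
    m <- counts$counts
    library_size <- counts$library_size
  } else {
    m <- as.matrix(counts)
    if (is.null(library_size)) library_size <- colSums(m)
  }
  zero <- library_size <= 0
  if (any(zero)) {
    nm <- colnames(m)[which(zero)[1]]
    stop("zero library size for sample ",
         if (is.null(nm)) which(zero)[1] else nm)
  }
  sweep(m, 2, library_size, "/") * 1e6
}

#' Subset sample columns of a count matrix by metadata
#' @param cm `count_matrix`.
#' @param phase optional phase filter.
#' @param capture optional capture filter.
#' @return `count_matrix` restricted to matching samples.
#' @export
subset_samples <- function(cm, phase = NULL, capture = NULL) {
  keep <- rep(TRUE, nrow(cm$meta))
  if (!is.null(phase)) keep <- keep & cm$meta$phase %in% phase
  if (!is.null(capture)) keep <- keep & cm$meta$capture %in% capture
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$meta[keep, , drop = FALSE])
}

#' Read / write a count matrix as TSV
#'
#' The counts table has gene_id in the first column and one column per
#' sample; the metadata table has sample_id, phase, capture, replicate.
#'
#' @param counts_path,meta_path file paths.
#' @return `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  count_matrix(m, meta)
}

#' @rdname read_count_matrix
#' @param cm `count_matrix` to write.
#' @export
write_count_matrix <- function(cm, counts_path, meta_path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
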