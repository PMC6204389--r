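#' Gene-level count dataset
#'
#' Bundles a raw count matrix (genes x samples) with per-gene lengths and
#' per-sample metadata. This is the entry container for the preprocessing
#' stage: filtering, TMM normalisation, RPKM computation and differential
#' expression calls all start from a `count_dataset`.
#'
#' @param counts integer-like matrix of nonnegative counts, genes in rows,
#'   samples in columns; `rownames` are gene ids, `colnames` sample ids.
#' @param gene_lengths named numeric vector of gene lengths in bp (exon-union
#'   lengths when derived from a genome annotation); names must cover the
#'   rownames of `counts`.
#' @param sample_meta data.frame with columns `sample`, `condition`,
#'   `timepoint`, `replicate`; one row per column of `counts`.
#'
#' @return An object of class `count_dataset`: a list with elements
#'   `counts`, `gene_lengths`, `sample_meta`.
#' @examples
#' cm <- matrix(rpois(20, 50), 5, 4,
#'              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' md <- data.frame(sample = paste0("s", 1:4),
#'                  condition = c("fructose", "bagasse", "bagasse", "bagasse"),
#'                  timepoint = c(24, 6, 12, 24), replicate = 1L)
#' ds <- count_dataset(cm, setNames(rep(1000, 5), rownames(cm)), md)
#' ds
#' @export
count_dataset <- function(counts, gene_lengths, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop2("duplicate gene or sample ids in counts")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop2("counts must be finite and nonnegative")
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss) > 0)
    stop2("missing gene length for: %s", paste(utils::head(miss, 5), collapse = ", "))
  gl <- gene_lengths[rownames(counts)]
  if (any(gl <= 0)) stop2("gene lengths must be positive")
  sample_meta <- as.data.frame(sample_meta)
  need <- c("sample", "condition", "timepoint", "replicate")
  if (!all(need %in% names(sample_meta)))
    stop2("sample_meta needs columns: %s", paste(need, collapse = ", "))
  if (!setequal(sample_meta$sample, colnames(counts)) ||
      nrow(sample_meta) != ncol(counts))
    stop2("sample_meta rows must match count matrix columns one-to-one")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, gene_lengths = gl, sample_meta = sample_meta),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- condition_groups(x$sample_meta)
  tab <- table(grp)
  cat("  groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  library sizes: %s .. %s\n",
              format(min(colSums(x$counts)), big.mark = ","),
              format(max(colSums(x$counts)), big.mark = ",")))
  invisible(x)
}

# condition_timepoint group label, e.g. "bagasse_6h"
condition_groups <- function(sample_meta) {
  sprintf("%s_%sh", sample_meta$condition, sample_meta$timepoint)
}

#' Read a count dataset from TSV files
#'
#' @param counts_file TSV, first column gene id, remaining columns samples.
#' @param meta_file TSV with columns sample, condition, timepoint, replicate.
#' @param lengths_file TSV with columns gene, length.
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(counts_file, meta_file, lengths_file) {
  cm <- utils::read.delim(counts_file, check.names = FALSE)
  counts <- as.matrix(cm[, -1, drop = FALSE])
  rownames(counts) <- cm[[1]]
  meta <- utils::read.delim(meta_file)
  len <- utils::read.delim(lengths_file)
  count_dataset(counts, stats::setNames(len$length, len$gene), meta)
}

#' Write a count dataset to TSV files
#'
#' @param ds A [count_dataset()].
#' @param dir output directory (created if absent); writes `counts.tsv`,
#'   `sample_meta.tsv` and `gene_lengths.tsv`.
#' @return `dir`, invisibly.
#' @export
write_count_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "count_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene = rownames(ds$counts), ds$counts, check.names = FALSE)
  utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$sample_meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(ds$gene_lengths), length = ds$gene_lengths),
    file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
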