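# Expression preprocessing: CPM, low-abundance filtering, TMM normalisation,
# RPKM and fold-change differential expression calls.

#' Counts per million
#'
#' Scales each sample's counts by its library size: `cpm = count / (libsize/1e6)`.
#' CPM here is always computed on raw library sizes, because the low-abundance
#' filter is applied before between-sample normalisation.
#'
#' @param x a [count_dataset()] or a count matrix with dimnames.
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm <- function(x) {
  counts <- if (inherits(x, "count_dataset")) x$counts else as.matrix(x)
  libs <- colSums(counts)
  zero <- libs == 0
  if (any(zero))
    stop2("zero library size in sample(s): %s",
          paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, libs / 1e6, "/")
}

#' Filter genes by minimum CPM support
#'
#' Keeps genes with CPM at or above `min_cpm` in at least `min_samples`
#' samples (both bounds inclusive), the standard low-abundance filter for
#' RNA-seq counts ahead of network construction. Gene order is preserved and
#' the operation is idempotent.
#'
#' @param ds a [count_dataset()].
#' @param min_cpm minimum CPM (default 1).
#' @param min_samples minimum number of samples meeting `min_cpm` (default 3).
#' @return the filtered [count_dataset()].
#' @export
filter_low_expression <- function(ds, min_cpm = 1, min_samples = 3) {
  stopifnot(inherits(ds, "count_dataset"))
  if (min_samples > ncol(ds$counts))
    stop2("min_samples (%d) exceeds sample count (%d)",
          min_samples, ncol(ds$counts))
  keep <- rowSums(cpm(ds) >= min_cpm) >= min_samples
  count_dataset(ds$counts[keep, , drop = FALSE],
                ds$gene_lengths[keep], ds$sample_meta)
}

#' Trimmed mean of M-values normalisation factors
#'
#' Computes per-sample scaling factors by the TMM method: for each sample
#' versus a reference, per-gene log2 expression ratios (M) and average log2
#' expression (A) are formed over genes with nonzero counts in both samples,
#' the most extreme 30% of M-values and 5% of A-values are trimmed, and the
#' factor is the weighted mean of the remaining M-values (weights = inverse
#' asymptotic binomial variances), exponentiated. Factors are rescaled to
#' geometric mean 1. The reference sample, unless given, is the one whose
#' upper-quartile count fraction is closest to the mean upper quartile.
#'
#' @param ds a [count_dataset()] or count matrix.
#' @param reference sample id to normalise against, or `"auto"`.
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @return named numeric vector of normalisation factors, geometric mean 1.
#' @export
tmm_factors <- function(ds, reference = "auto", trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(ds, "count_dataset")) ds$counts else as.matrix(ds)
  if (ncol(counts) < 2) stop2("TMM needs at least 2 samples")
  libs <- colSums(counts)
  if (identical(reference, "auto")) {
    f75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(reference, colnames(counts))
    if (is.na(ref)) stop2("unknown reference sample '%s'", reference)
  }
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    tmm_pair(counts[, s], counts[, ref], libs[s], libs[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# single-pair TMM factor (sample s against reference r)
tmm_pair <- function(ys, yr, ns, nr, trim_m, trim_a) {
  keep <- ys > 0 & yr > 0
  if (!any(keep))
    stop2("sample shares no co-expressed nonzero genes with the reference")
  ys <- ys[keep]; yr <- yr[keep]
  m <- log2((ys / ns) / (yr / nr))
  a <- 0.5 * log2((ys / ns) * (yr / nr))
  w <- (ns - ys) / (ns * ys) + (nr - yr) / (nr * yr)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  n <- length(m)
  if (n == 0) return(1)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' RPKM expression matrix
#'
#' Reads per kilobase of gene length per million reads of (effective)
#' library: `rpkm = count / (effective_lib/1e6) / (length/1e3)` with
#' `effective_lib = libsize * factor`. With `factors` from [tmm_factors()]
#' this is TMM-normalised RPKM.
#'
#' @param ds a [count_dataset()].
#' @param factors per-sample normalisation factors (default: TMM).
#' @return object of class `expr_matrix`: list with `values` (RPKM matrix),
#'   `norm_factors` and the sample metadata.
#' @export
rpkm <- function(ds, factors = tmm_factors(ds)) {
  stopifnot(inherits(ds, "count_dataset"))
  if (any(factors <= 0) || length(factors) != ncol(ds$counts))
    stop2("factors must be positive, one per sample")
  eff <- colSums(ds$counts) * factors
  v <- sweep(ds$counts, 2, eff / 1e6, "/")
  v <- sweep(v, 1, ds$gene_lengths / 1e3, "/")
  structure(list(values = v, norm_factors = factors,
                 sample_meta = ds$sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (normalised)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Fold-change differential expression calls
#'
#' Calls a gene differentially expressed at a treatment group when the log2
#' ratio of its mean normalised expression over the control group mean
#' reaches 1 in magnitude (two-fold rule): `up` at log2fc >= 1, `down` at
#' log2fc <= -1. A pseudocount guards zero denominators. The overall status
#' is `up`/`down` if any treatment timepoint qualifies, `mixed` if both
#' directions occur across timepoints.
#'
#' @param expr an `expr_matrix` from [rpkm()] (or a list with `values` and
#'   `sample_meta`).
#' @param control group label of the control condition, as
#'   `"<condition>_<timepoint>h"` (e.g. `"fructose_24h"`).
#' @param pseudo pseudocount added to both means (default 0.25).
#' @param lfc_cutoff log2 fold-change magnitude for a call (default 1).
#' @return data.frame of class `de_result` with columns `gene`, `group`,
#'   `log2fc`, `status`; attribute `overall` holds the per-gene overall
#'   status data.frame.
#' @export
call_de <- function(expr, control, pseudo = 0.25, lfc_cutoff = 1) {
  v <- expr$values
  grp <- condition_groups(expr$sample_meta)
  if (!control %in% grp)
    stop2("control group '%s' not among: %s", control,
          paste(unique(grp), collapse = ", "))
  means <- vapply(unique(grp), function(g)
    rowMeans(v[, grp == g, drop = FALSE]), numeric(nrow(v)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(v), unique(grp)))
  trt <- setdiff(colnames(means), control)
  res <- do.call(rbind, lapply(trt, function(g) {
    lfc <- log2((means[, g] + pseudo) / (means[, control] + pseudo))
    status <- ifelse(lfc >= lfc_cutoff, "up",
                     ifelse(lfc <= -lfc_cutoff, "down", "none"))
    data.frame(gene = rownames(v), group = g, log2fc = lfc, status = status,
               row.names = NULL)
  }))
  overall <- vapply(split(res$status, res$gene), function(s) {
    if (any(s == "up") && any(s == "down")) "mixed"
    else if (any(s == "up")) "up"
    else if (any(s == "down")) "down"
    else "none"
  }, character(1))
  overall <- data.frame(gene = names(overall), overall_status = unname(overall))
  attr(res, "overall") <- overall[match(rownames(v), overall$gene), ]
  class(res) <- c("de_result", "data.frame")
  res
}

#' Per-gene overall DE status
#'
#' @param de a `de_result` from [call_de()].
#' @return data.frame with columns `gene`, `overall_status`.
#' @export
de_overall <- function(de) {
  ov <- attr(de, "overall")
  if (is.null(ov)) {
    if (!all(c("gene", "overall_status") %in% names(de)))
      stop2("no overall DE status available")
    ov <- de[, c("gene", "overall_status")]
  }
  rownames(ov) <- NULL
  ov
}
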