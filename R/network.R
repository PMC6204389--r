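# Signed weighted co-expression network construction: Pearson correlation,
# signed soft-threshold adjacency, scale-free fit, topological overlap,
# average-linkage module detection, eigengene merging and edge export.

#' Pairwise Pearson correlation across samples
#'
#' @param values expression matrix, genes in rows, samples in columns
#'   (at least 3 samples). Zero-variance genes get correlation 0 against
#'   everything (with a warning) rather than NA.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 3) stop2("need at least 3 samples for correlations")
  sds <- apply(values, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  cc <- suppressWarnings(stats::cor(t(values)))
  if (any(flat)) {
    warn2("%d zero-variance gene(s); their correlations set to 0", sum(flat))
    cc[flat, ] <- 0
    cc[, flat] <- 0
  }
  diag(cc) <- 1
  cc
}

#' Signed soft-threshold adjacency
#'
#' Maps correlation to adjacency by `adj = (0.5 * (1 + cor))^beta`: perfectly
#' anti-correlated pairs get adjacency 0, perfectly correlated pairs 1, and
#' the soft power `beta` sharpens the contrast (a signed network).
#'
#' @param cor correlation value(s) or matrix, entries in \[-1, 1\].
#' @param beta soft power, integer >= 1.
#' @return adjacency of the same shape, entries in \[0, 1\].
#' @examples
#' signed_adjacency(0.8, 26)   # ~0.0646: the weight of a cor-0.8 edge
#' @export
signed_adjacency <- function(cor, beta) {
  if (length(beta) != 1 || beta < 1) stop2("beta must be a single value >= 1")
  if (any(cor < -1 - 1e-12 | cor > 1 + 1e-12, na.rm = TRUE))
    stop2("correlations outside [-1, 1]")
  (0.5 * (1 + pmin(pmax(cor, -1), 1)))^beta
}

# log-log regression of the connectivity distribution against a power law:
# k binned into 10 equal-width bins, log10(freq) ~ log10(mean k) over
# nonempty bins; returns -sign(slope) * R^2 ("signed R^2", positive when the
# fit decays as scale-free topology requires).
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) == 0) stop2("degenerate connectivity: no positive values")
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  if (br[1] == br[n_bins + 1])
    stop2("degenerate connectivity: all values identical")
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mk <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(mk) & mk > 0
  if (sum(ok) < 2) stop2("degenerate connectivity: fewer than 2 occupied bins")
  fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  unname(-sign(slope) * r2)
}

#' Choose the soft power for scale-free topology
#'
#' For each candidate `beta`, builds the signed adjacency, computes the
#' connectivity `k_i = sum_j adj(i,j)` (j != i) and measures how well the
#' connectivity distribution follows a power law (signed R^2 of the log-log
#' frequency fit). The chosen power is the smallest candidate whose signed
#' R^2 reaches `target_r2`; if none does, the candidate maximising the
#' signed R^2 is returned with a warning.
#'
#' @param values expression matrix (genes x samples) or a precomputed
#'   correlation matrix (`is_cor = TRUE`).
#' @param betas candidate powers (default 1..30).
#' @param target_r2 scale-free fit target (default 0.85).
#' @param is_cor set `TRUE` when `values` is already a correlation matrix.
#' @return object of class `soft_threshold_fit`: data.frame `fit` with
#'   columns `beta`, `signed_r2`, `mean_connectivity`, plus `chosen_beta`
#'   and `reached_target`.
#' @export
pick_soft_threshold <- function(values, betas = 1:30, target_r2 = 0.85,
                                is_cor = FALSE) {
  if (length(betas) == 0) stop2("no candidate betas")
  cc <- if (is_cor) values else correlation_matrix(values)
  base <- 0.5 * (1 + cc)
  diag(base) <- 0
  rows <- lapply(betas, function(b) {
    k <- rowSums(base^b)
    data.frame(beta = b, signed_r2 = scale_free_fit(k),
               mean_connectivity = mean(k))
  })
  fit <- do.call(rbind, rows)
  hit <- which(fit$signed_r2 >= target_r2)
  if (length(hit) > 0) {
    chosen <- fit$beta[hit[1]]; reached <- TRUE
  } else {
    chosen <- fit$beta[which.max(fit$signed_r2)]; reached <- FALSE
    warn2("no candidate beta reached signed R^2 %.2f; using beta = %d (R^2 = %.2f)",
          target_r2, chosen, max(fit$signed_r2))
  }
  structure(list(fit = fit, chosen_beta = chosen, reached_target = reached,
                 target_r2 = target_r2),
            class = "soft_threshold_fit")
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat(sprintf("soft threshold fit: chosen beta = %d (target signed R^2 %.2f%s)\n",
              x$chosen_beta, x$target_r2,
              if (x$reached_target) ", reached" else ", NOT reached"))
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu` (self-adjacency excluded).
#' Two genes overlap strongly when they share the same weighted neighbours,
#' even if their direct edge is weak; TOM is the similarity clustered for
#' module detection.
#'
#' @param adj symmetric adjacency matrix, entries in \[0, 1\] (diagonal
#'   ignored).
#' @return symmetric TOM matrix, entries in \[0, 1\], unit diagonal.
#' @export
tom_matrix <- function(adj) {
  adj <- as.matrix(adj)
  if (any(adj < 0 | adj > 1)) stop2("adjacency entries outside [0, 1]")
  a <- adj
  diag(a) <- 0
  l <- a %*% a                      # diag(a)=0 removes u = i and u = j terms
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom
}

#' Average-linkage module detection on topological overlap
#'
#' Clusters genes by average-linkage hierarchical clustering of the
#' dissimilarity `1 - TOM`, cuts the tree at a static height, and assigns
#' clusters smaller than `min_size` to the background. Retained modules are
#' labelled `M1`, `M2`, ... in decreasing size order; background genes get
#' the label `"grey"`.
#'
#' The default `cut_height = "auto"` places the cut in the middle of the
#' largest gap between consecutive sorted merge heights (searched above the
#' lower quarter of merges). Module-internal merges happen well below the
#' heights at which unrelated genes attach, and the location of that gap
#' moves with the soft power, so a data-driven static cut is used instead
#' of one fixed height.
#'
#' @param tom TOM matrix from [tom_matrix()].
#' @param min_size minimum module size (default 30).
#' @param cut_height static cut height on the 1-TOM scale, in (0, 1\], or
#'   `"auto"` (default) for the largest-gap rule.
#' @return object of class `module_partition`: list with
#'   `module_of_gene` (named character), `module_sizes`, `hclust` tree,
#'   `cut_height`, and (after [merge_modules()]) `eigengenes` and
#'   `merge_history`.
#' @export
cluster_and_cut <- function(tom, min_size = 30, cut_height = "auto") {
  diss <- 1 - tom
  diag(diss) <- 0
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  hc$height <- cummax(round(hc$height, 10))  # guard tie-induced inversions
  if (identical(cut_height, "auto")) {
    cut_height <- gap_cut_height(hc$height)
  } else if (cut_height <= 0 || cut_height > 1) {
    stop2("cut_height must be in (0, 1]")
  }
  cl <- stats::cutree(hc, h = cut_height)
  labels <- relabel_modules(cl, rownames(tom), min_size)
  new_module_partition(labels, hc, cut_height, min_size)
}

new_module_partition <- function(labels, hc, cut_height, min_size) {
  structure(list(module_of_gene = labels,
                 module_sizes = module_sizes(labels),
                 hclust = hc, cut_height = cut_height, min_size = min_size,
                 eigengenes = NULL, merge_history = NULL),
            class = "module_partition")
}

# largest gap between consecutive sorted merge heights, searched above the
# lower quarter of merges; returns the gap midpoint
gap_cut_height <- function(heights) {
  h <- sort(heights)
  n <- length(h)
  if (n < 2) return(max(h, 0.5))
  i0 <- max(1, floor(n * 0.25))
  gaps <- diff(h)
  i <- (i0 - 1) + which.max(gaps[i0:(n - 1)])
  (h[i] + h[i + 1]) / 2
}

# rename raw cluster ids: M1.. by decreasing size, "grey" for clusters
# below min_size
relabel_modules <- function(cl, genes, min_size) {
  tab <- sort(table(cl), decreasing = TRUE)
  keep <- names(tab)[tab >= min_size]
  lab <- rep("grey", length(cl))
  for (i in seq_along(keep)) lab[cl == keep[i]] <- paste0("M", i)
  stats::setNames(lab, genes)
}

module_sizes <- function(labels) {
  tab <- table(labels[labels != "grey"])
  sort(tab, decreasing = TRUE)
}

#' Module eigengene
#'
#' First principal component of the module's gene-standardised expression
#' submatrix: a per-sample summary profile. The sign is oriented so that the
#' mean gene-eigengene correlation is positive; the vector has unit norm.
#'
#' @param values expression matrix (genes x samples).
#' @param genes gene ids of the module members.
#' @return list with `eigengene` (named per-sample vector, unit norm) and
#'   `var_explained` (fraction of standardised variance captured).
#' @export
module_eigengene <- function(values, genes) {
  if (length(genes) == 0) stop2("empty module")
  sub <- values[genes, , drop = FALSE]
  if (ncol(sub) < 2) stop2("eigengene needs at least 2 samples")
  z <- t(scale(t(sub)))                 # standardise each gene
  z[!is.finite(z)] <- 0                 # flat genes contribute nothing
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  cors <- suppressWarnings(stats::cor(t(sub), eg))
  if (mean(cors, na.rm = TRUE) < 0) eg <- -eg
  stats::setNames(eg, colnames(values))
  list(eigengene = stats::setNames(eg, colnames(values)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

# eigengenes for every retained module
all_eigengenes <- function(values, labels) {
  mods <- setdiff(unique(labels), "grey")
  out <- lapply(mods, function(m)
    module_eigengene(values, names(labels)[labels == m])$eigengene)
  stats::setNames(out, mods)
}

#' Merge similar modules by eigengene correlation
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor` is strictly below `merge_threshold` (0.15
#' corresponds to eigengene correlation above 0.85), recomputing eigengenes
#' after every merge until no pair qualifies. The merged module keeps the
#' larger constituent's label.
#'
#' @param values expression matrix (genes x samples).
#' @param partition a `module_partition` from [cluster_and_cut()].
#' @param merge_threshold eigengene dissimilarity below which modules merge
#'   (default 0.15, strict inequality).
#' @return the updated `module_partition` with `eigengenes` and
#'   `merge_history` filled in.
#' @export
merge_modules <- function(values, partition, merge_threshold = 0.15) {
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$module_of_gene
  history <- list()
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    eg <- all_eigengenes(values, labels)
    em <- do.call(cbind, eg)
    diss <- 1 - stats::cor(em)
    diag(diss) <- Inf
    ix <- arrayInd(which.min(diss), dim(diss))
    # strict inequality, with a tolerance so that a dissimilarity exactly at
    # the threshold (up to rounding) never merges
    if (diss[ix] >= merge_threshold - 1e-9) break
    a <- colnames(diss)[ix[1]]; b <- colnames(diss)[ix[2]]
    na <- sum(labels == a); nb <- sum(labels == b)
    keep <- if (na >= nb) a else b
    drop <- if (na >= nb) b else a
    labels[labels == drop] <- keep
    history[[length(history) + 1]] <-
      data.frame(merged = drop, into = keep, dissimilarity = diss[ix])
  }
  partition$module_of_gene <- labels
  partition$module_sizes <- module_sizes(labels)
  partition$eigengenes <- all_eigengenes(values, labels)
  partition$merge_history <-
    if (length(history)) do.call(rbind, history) else
      data.frame(merged = character(), into = character(),
                 dissimilarity = numeric())
  partition
}

#' @export
print.module_partition <- function(x, ...) {
  n <- length(x$module_sizes)
  cat(sprintf("module_partition: %d module(s), %d background gene(s)\n",
              n, sum(x$module_of_gene == "grey")))
  if (n > 0) {
    sz <- x$module_sizes
    cat("  ", paste(sprintf("%s(%d)", names(sz), sz), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Refine module membership by eigengene correlation
#'
#' Reassigns every gene to the module whose eigengene it correlates with
#' best, provided that correlation (the gene's module membership, kME)
#' reaches `kme_threshold`; genes below it for every module become
#' background. Modules falling under `min_size` are dissolved. The step is
#' iterated (eigengenes recomputed) until labels stabilise. This prunes
#' weakly attached genes that hierarchical clustering absorbs into a module
#' and reclaims genes of the module core that the static cut left out.
#'
#' @param values expression matrix (genes x samples).
#' @param partition `module_partition` (or named label vector).
#' @param kme_threshold minimum gene-eigengene correlation for membership
#'   (default 0.7).
#' @param min_size minimum module size (default 30).
#' @param max_iter iteration cap (default 5).
#' @return the refined `module_partition` (or label vector, matching the
#'   input type).
#' @export
refine_membership <- function(values, partition, kme_threshold = 0.7,
                              min_size = 30, max_iter = 5) {
  is_part <- inherits(partition, "module_partition")
  lab <- if (is_part) partition$module_of_gene else partition
  for (it in seq_len(max_iter)) {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) == 0) break
    eg <- vapply(mods, function(m)
      module_eigengene(values, names(lab)[lab == m])$eigengene,
      numeric(ncol(values)))
    km <- suppressWarnings(stats::cor(t(values), eg))
    km[!is.finite(km)] <- 0
    best <- max.col(km, ties.method = "first")
    bestv <- km[cbind(seq_len(nrow(km)), best)]
    new_lab <- ifelse(bestv >= kme_threshold, mods[best], "grey")
    names(new_lab) <- rownames(values)
    tab <- table(new_lab[new_lab != "grey"])
    new_lab[new_lab %in% names(tab)[tab < min_size]] <- "grey"
    if (identical(unname(new_lab[names(lab)]), unname(lab))) break
    lab <- new_lab[names(lab)]
  }
  if (!is_part) return(lab)
  partition$module_of_gene <- lab
  partition$module_sizes <- module_sizes(lab)
  partition$eigengenes <- all_eigengenes(values, lab)
  partition
}

#' Export high-correlation within-module edges
#'
#' Emits the undirected edge list of gene pairs that belong to the same
#' retained module and whose absolute Pearson correlation strictly exceeds
#' `cor_cutoff` (default 0.8; at soft power 26 this corresponds to adjacency
#' above ~0.064). Each pair appears once; no self-edges.
#'
#' @param cor correlation matrix.
#' @param partition `module_partition` with final labels, or a named
#'   gene -> module label vector.
#' @param cor_cutoff absolute-correlation threshold (strict, default 0.8).
#' @param beta soft power used to annotate each edge with its adjacency.
#' @return data.frame with columns `gene_a`, `gene_b`, `cor`, `adj`,
#'   `module`.
#' @export
export_edges <- function(cor, partition, cor_cutoff = 0.8, beta = 26) {
  labels <- if (inherits(partition, "module_partition"))
    partition$module_of_gene else partition
  labels <- labels[rownames(cor)]
  names(labels) <- rownames(cor)
  out <- list()
  for (m in setdiff(unique(labels), "grey")) {
    g <- names(labels)[labels == m]
    sub <- cor[g, g, drop = FALSE]
    hit <- which(abs(sub) > cor_cutoff & upper.tri(sub), arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[m]] <- data.frame(gene_a = g[hit[, 1]], gene_b = g[hit[, 2]],
                           cor = sub[hit],
                           adj = signed_adjacency(sub[hit], beta),
                           module = m, row.names = NULL)
  }
  if (length(out) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      cor = numeric(), adj = numeric(), module = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
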