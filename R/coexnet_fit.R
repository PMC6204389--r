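#' Fit a signed weighted co-expression network
#'
#' The package's central fit: from a normalised expression matrix it computes
#' pairwise Pearson correlations, selects (or accepts) a soft power for a
#' signed scale-free adjacency `(0.5*(1+cor))^beta`, forms the topological
#' overlap matrix, detects modules by average-linkage clustering with a
#' static cut and a minimum module size, merges modules whose eigengenes are
#' nearly collinear, and exports the high-correlation within-module edge
#' list.
#'
#' @param values expression matrix (genes x samples; e.g. `rpkm(ds)$values`)
#'   or an `expr_matrix`.
#' @param beta soft power: a positive integer, or `"auto"` to select the
#'   smallest power on `betas` reaching `target_r2` (see
#'   [pick_soft_threshold()]).
#' @param betas candidate powers for automatic selection (default 1..30).
#' @param target_r2 scale-free fit target for automatic selection
#'   (default 0.85).
#' @param min_module_size smallest retained module (default 30 genes).
#' @param cut_height static tree-cut height on the 1-TOM scale, or
#'   `"auto"` (default) for the largest-gap rule of [cluster_and_cut()].
#' @param merge_threshold eigengene dissimilarity below which modules merge
#'   (default 0.15).
#' @param kme_threshold minimum gene-eigengene correlation kept by the
#'   membership refinement stage (default 0.7; see [refine_membership()]).
#' @param edge_cor absolute-correlation cutoff for the exported edge list
#'   (default 0.8, strict).
#' @param keep_tom keep the TOM matrix in the returned object (default TRUE;
#'   set FALSE to save memory on large gene sets).
#' @return object of class `coexnet`: list with `cor`, `beta`, `adj` (not
#'   stored; recompute via [signed_adjacency()]), `tom` (optional),
#'   `soft_fit`, `partition` (a `module_partition`), `edges`, `params`.
#' @seealso [mcode_complexes()], [find_hubs()], [module_summary()]
#' @export
coexpression_network <- function(values, beta = "auto", betas = 1:30,
                                 target_r2 = 0.85, min_module_size = 30,
                                 cut_height = "auto", merge_threshold = 0.15,
                                 kme_threshold = 0.7,
                                 edge_cor = 0.8, keep_tom = TRUE) {
  if (inherits(values, "expr_matrix")) values <- values$values
  values <- as.matrix(values)
  cc <- correlation_matrix(values)
  soft_fit <- NULL
  if (identical(beta, "auto")) {
    soft_fit <- pick_soft_threshold(cc, betas = betas, target_r2 = target_r2,
                                    is_cor = TRUE)
    beta <- soft_fit$chosen_beta
  }
  adj <- signed_adjacency(cc, beta)
  tom <- tom_matrix(adj)
  if (identical(cut_height, "auto")) {
    # candidate search: among quantile cut heights keep the one that retains
    # the most genes after merging and kME refinement (mixtures and
    # fragmented cores both shed genes under refinement)
    diss <- 1 - tom
    diag(diss) <- 0
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    hc$height <- cummax(round(hc$height, 10))
    cands <- unique(stats::quantile(hc$height, seq(0.5, 0.99, by = 0.05)))
    best <- NULL
    for (h in cands) {
      lab <- relabel_modules(stats::cutree(hc, h = h), rownames(tom),
                             min_module_size)
      p <- new_module_partition(lab, hc, h, min_module_size)
      p <- merge_modules(values, p, merge_threshold = merge_threshold)
      p <- refine_membership(values, p, kme_threshold = kme_threshold,
                             min_size = min_module_size)
      score <- sum(p$module_of_gene != "grey")
      if (is.null(best) || score > best$score)
        best <- list(score = score, partition = p)
    }
    partition <- best$partition
  } else {
    partition <- cluster_and_cut(tom, min_size = min_module_size,
                                 cut_height = cut_height)
    partition <- merge_modules(values, partition,
                               merge_threshold = merge_threshold)
    partition <- refine_membership(values, partition,
                                   kme_threshold = kme_threshold,
                                   min_size = min_module_size)
  }
  edges <- export_edges(cc, partition, cor_cutoff = edge_cor, beta = beta)
  structure(list(cor = cc, beta = beta, tom = if (keep_tom) tom,
                 soft_fit = soft_fit, partition = partition, edges = edges,
                 n_samples = ncol(values),
                 params = list(min_module_size = min_module_size,
                               cut_height = partition$cut_height,
                               merge_threshold = merge_threshold,
                               kme_threshold = kme_threshold,
                               edge_cor = edge_cor, target_r2 = target_r2)),
            class = "coexnet")
}

#' @export
print.coexnet <- function(x, ...) {
  cat(sprintf("coexnet: %d genes, %d samples, beta = %d\n",
              nrow(x$cor), x$n_samples, x$beta))
  print(x$partition)
  cat(sprintf("  %d edge(s) at |cor| > %.2f\n",
              nrow(x$edges), x$params$edge_cor))
  invisible(x)
}

#' @export
summary.coexnet <- function(object, ...) {
  sz <- object$partition$module_sizes
  per_mod <- if (length(sz) > 0) {
    data.frame(module = names(sz), genes = as.integer(sz),
               edges = vapply(names(sz), function(m)
                 sum(object$edges$module == m), integer(1)),
               row.names = NULL)
  } else data.frame(module = character(), genes = integer(), edges = integer())
  out <- list(n_genes = nrow(object$cor), n_samples = object$n_samples,
              beta = object$beta,
              reached_target = if (!is.null(object$soft_fit))
                object$soft_fit$reached_target else NA,
              modules = per_mod,
              n_background = sum(object$partition$module_of_gene == "grey"),
              params = object$params)
  class(out) <- "summary.coexnet"
  out
}

#' @export
print.summary.coexnet <- function(x, ...) {
  cat(sprintf("Signed co-expression network (%d genes, %d samples)\n",
              x$n_genes, x$n_samples))
  cat(sprintf("  soft power beta = %d%s\n", x$beta,
              if (isTRUE(x$reached_target)) " (scale-free target reached)"
              else if (isFALSE(x$reached_target)) " (best available fit)" else ""))
  cat(sprintf("  %d module(s), %d background gene(s)\n",
              nrow(x$modules), x$n_background))
  if (nrow(x$modules) > 0) print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Module labels of a fitted network
#'
#' @param fit a `coexnet`.
#' @return named character vector gene -> module label (`"grey"` =
#'   background).
#' @export
module_labels <- function(fit) {
  stopifnot(inherits(fit, "coexnet"))
  fit$partition$module_of_gene
}

#' @export
plot.coexnet <- function(x, which = c("dendrogram", "soft"), ...) {
  which <- match.arg(which)
  if (which == "dendrogram") {
    plot(x$partition$hclust, labels = FALSE, hang = -1,
         main = "Gene dendrogram (1 - TOM, average linkage)",
         xlab = "", sub = "")
    graphics::abline(h = x$partition$cut_height, col = "red", lty = 2)
  } else {
    if (is.null(x$soft_fit)) stop2("no soft-threshold fit stored (beta was fixed)")
    f <- x$soft_fit$fit
    plot(f$beta, f$signed_r2, type = "b", xlab = "soft power beta",
         ylab = "signed scale-free R^2", main = "Soft-threshold selection")
    graphics::abline(h = x$soft_fit$target_r2, col = "red", lty = 2)
  }
  invisible(x)
}

#' Write network artifacts to TSV files
#'
#' Writes the edge list (`edges.tsv`), the gene-module partition
#' (`modules.tsv`) and, when present, the soft-threshold fit table
#' (`soft_threshold.tsv`).
#'
#' @param fit a `coexnet`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_network <- function(fit, dir) {
  stopifnot(inherits(fit, "coexnet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  part <- data.frame(gene = names(fit$partition$module_of_gene),
                     module = unname(fit$partition$module_of_gene))
  utils::write.table(part, file.path(dir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(fit$soft_fit))
    utils::write.table(fit$soft_fit$fit, file.path(dir, "soft_threshold.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
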