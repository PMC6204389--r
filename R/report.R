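# Integration reports: per-module summary tables, hub cross-tabulations and
# focal-gene neighbourhood reports combining the network, DE, hub and
# motif layers.

#' Summarise per-module DEG counts with grand-total percentages
#'
#' Takes per-module node, edge and up/down DEG counts and adds the
#' percentage columns and the total row. Percentages are computed against
#' the supplied grand totals of up- and downregulated genes (not against
#' module sizes) and rounded half-up to one decimal; the total row sums the
#' counts and computes its percentages from the summed counts.
#'
#' @param rows data.frame with columns `module`, `nodes`, `edges`, `up`,
#'   `down`.
#' @param totals length-2 vector `c(total_up, total_down)`: grand totals of
#'   up/down DEGs in the transcriptome.
#' @return data.frame with added `up_pct`, `down_pct` and a final `Total`
#'   row.
#' @export
summarize_module_counts <- function(rows, totals) {
  if (any(totals <= 0)) stop2("totals must be positive")
  rows <- rows[, c("module", "nodes", "edges", "up", "down")]
  out <- rbind(rows,
               data.frame(module = "Total", nodes = sum(rows$nodes),
                          edges = sum(rows$edges), up = sum(rows$up),
                          down = sum(rows$down)))
  out$up_pct <- round_half_up(100 * out$up / totals[1], 1)
  out$down_pct <- round_half_up(100 * out$down / totals[2], 1)
  rownames(out) <- NULL
  out
}

#' Per-module summary of nodes, edges and DEG content
#'
#' Counts, for every retained module, its genes, its exported
#' high-correlation edges and its up/down differentially expressed genes
#' (by overall status), then delegates to [summarize_module_counts()] for
#' percentages against the transcriptome-wide DEG totals.
#'
#' @param partition `module_partition` (or named gene -> module vector).
#' @param edges exported edge list (column `module`).
#' @param de `de_result` from [call_de()].
#' @param totals `c(total_up, total_down)`; by default the overall up/down
#'   counts of `de` itself (supply the transcriptome-wide totals when the
#'   network covers only a subset).
#' @return data.frame as from [summarize_module_counts()], modules in
#'   decreasing node order.
#' @export
module_summary <- function(partition, edges, de, totals = NULL) {
  labels <- if (inherits(partition, "module_partition"))
    partition$module_of_gene else partition
  ov <- de_overall(de)
  status <- stats::setNames(ov$overall_status, ov$gene)
  if (is.null(totals))
    totals <- c(sum(ov$overall_status == "up"),
                sum(ov$overall_status == "down"))
  mods <- setdiff(unique(labels), c("grey", "background"))
  rows <- do.call(rbind, lapply(mods, function(m) {
    g <- names(labels)[labels == m]
    st <- status[intersect(g, names(status))]
    data.frame(module = m, nodes = length(g),
               edges = sum(edges$module == m),
               up = sum(st == "up", na.rm = TRUE),
               down = sum(st == "down", na.rm = TRUE))
  }))
  if (is.null(rows))
    rows <- data.frame(module = character(), nodes = integer(),
                       edges = integer(), up = integer(), down = integer())
  rows <- rows[order(-rows$nodes), ]
  summarize_module_counts(rows, totals)
}

#' Hub cross-tabulation with DE status and predicted binding sites
#'
#' For each module's hub genes: how many are differentially expressed in
#' the module's direction (percentage of hubs, rounded to the nearest
#' integer) and how many of those DE hubs carry at least one predicted
#' binding site (percentage of the DE hubs, one decimal).
#'
#' @param hubs `hub_set` from [find_hubs()].
#' @param de `de_result` from [call_de()].
#' @param xbs named logical vector from [genes_with_xbs()].
#' @return data.frame with columns `module`, `n_hubs`, `n_de`, `pct_de`,
#'   `n_de_xbs`, `pct_de_xbs`.
#' @export
hub_crosstab <- function(hubs, de, xbs) {
  ov <- de_overall(de)
  status <- stats::setNames(ov$overall_status, ov$gene)
  hub_nodes <- hubs$nodes[hubs$nodes$is_hub, , drop = FALSE]
  mods <- unique(hubs$modules$module)
  out <- do.call(rbind, lapply(mods, function(m) {
    g <- hub_nodes$gene[hub_nodes$module == m]
    st <- status[g]
    is_de <- !is.na(st) & st %in% c("up", "down")
    n_de <- sum(is_de)
    de_with_xbs <- sum(xbs[g[is_de]], na.rm = TRUE)
    data.frame(module = m, n_hubs = length(g), n_de = n_de,
               pct_de = if (length(g) > 0)
                 round_half_up(100 * n_de / length(g)) else NA,
               n_de_xbs = de_with_xbs,
               pct_de_xbs = if (n_de > 0)
                 round_half_up(100 * de_with_xbs / n_de, 1) else NA)
  }))
  if (is.null(out))
    out <- data.frame(module = character(), n_hubs = integer(),
                      n_de = integer(), pct_de = numeric(),
                      n_de_xbs = integer(), pct_de_xbs = numeric())
  rownames(out) <- NULL
  out
}

#' Neighbourhood report of a focal gene
#'
#' Retrieves every gene sharing an exported edge with the focal gene and
#' tallies DE status, predicted binding-site presence and (optional)
#' functional classes - the working unit for questions like "which genes
#' co-expressed with a master regulator respond to the substrate and carry
#' its binding site?".
#'
#' @param focal focal gene id (must appear in the edge list).
#' @param edges exported edge list.
#' @param de `de_result`.
#' @param xbs named logical vector from [genes_with_xbs()].
#' @param classes optional named character vector gene -> functional class.
#' @return object of class `neighborhood_report`: list with `focal`,
#'   `module`, `neighbors` (data.frame `gene`, `overall_status`,
#'   `has_xbs`, `class`), and tallies `n_neighbors`, `n_up`, `n_down`,
#'   `n_with_xbs`, `class_counts`.
#' @export
focal_neighborhood <- function(focal, edges, de, xbs = NULL, classes = NULL) {
  on_a <- edges$gene_b[edges$gene_a == focal]
  on_b <- edges$gene_a[edges$gene_b == focal]
  if (!(focal %in% edges$gene_a | focal %in% edges$gene_b))
    stop2("focal gene '%s' absent from the edge list", focal)
  nb <- sort(unique(c(on_a, on_b)))
  module <- unique(edges$module[edges$gene_a == focal | edges$gene_b == focal])
  ov <- de_overall(de)
  status <- stats::setNames(ov$overall_status, ov$gene)[nb]
  has_xbs <- if (is.null(xbs)) rep(NA, length(nb)) else unname(xbs[nb])
  cls <- if (is.null(classes)) rep(NA_character_, length(nb))
         else unname(classes[nb])
  tab <- data.frame(gene = nb, overall_status = unname(status),
                    has_xbs = has_xbs, class = cls, row.names = NULL)
  structure(list(focal = focal, module = module, neighbors = tab,
                 n_neighbors = length(nb),
                 n_up = sum(status == "up", na.rm = TRUE),
                 n_down = sum(status == "down", na.rm = TRUE),
                 n_with_xbs = sum(has_xbs, na.rm = TRUE),
                 class_counts = if (!is.null(classes))
                   table(cls, useNA = "no") else NULL),
            class = "neighborhood_report")
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat(sprintf("neighborhood of %s (module %s): %d neighbor(s)\n",
              x$focal, paste(x$module, collapse = ","), x$n_neighbors))
  cat(sprintf("  up: %d, down: %d, with binding site: %d\n",
              x$n_up, x$n_down, x$n_with_xbs))
  if (!is.null(x$class_counts) && length(x$class_counts) > 0) {
    cc <- x$class_counts
    cat("  classes:", paste(sprintf("%s(%d)", names(cc), cc),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run-level analysis configuration
#'
#' One place for every pipeline threshold, writable as YAML alongside the
#' result tables so a run is self-describing.
#'
#' @param ... overrides of the defaults.
#' @return named list of thresholds.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_cpm = 1, min_samples = 3, lfc_cutoff = 1, de_pseudo = 0.25,
              beta = "auto", target_r2 = 0.85, min_module_size = 30,
              cut_height = "auto", merge_threshold = 0.15, edge_cor = 0.8,
              mcode = list(degree_cutoff = 2, node_score_cutoff = 0.2,
                           k_core = 2, max_depth = 100, haircut = TRUE),
              hub_percentile = 90, go_q = 0.05, kog_p = 1e-3,
              scan_p = 1e-4, promoter_length = 1500)
  utils::modifyList(cfg, list(...))
}

#' @rdname pipeline_config
#' @param config list from `pipeline_config()`.
#' @param path YAML output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
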