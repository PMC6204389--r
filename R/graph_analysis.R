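# Dense-subgraph detection (MCODE) and hub identification on the exported
# module graphs.

# build an igraph from an exported edge list (optionally one module's slice)
edge_graph <- function(edges, module = NULL) {
  if (!is.null(module)) edges <- edges[edges$module == module, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  igraph::simplify(g)
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weight
#'
#' Local density score of a node: the highest core number `k` of the node's
#' closed neighbourhood multiplied by the density `2E/(V(V-1))` of that
#' highest k-core. Nodes embedded in cliques score high; isolated nodes
#' score 0.
#'
#' @param graph an igraph graph (or edge list data.frame with `gene_a`,
#'   `gene_b`).
#' @param node node name.
#' @return numeric weight.
#' @export
mcode_vertex_weight <- function(graph, node) {
  g <- if (igraph::is_igraph(graph)) graph else edge_graph(graph)
  if (!node %in% igraph::V(g)$name) stop2("node '%s' not in graph", node)
  nb <- igraph::neighbors(g, node)$name
  if (length(nb) == 0) return(0)
  sub <- igraph::induced_subgraph(g, c(node, nb))
  core <- igraph::coreness(sub)
  kmax <- max(core)
  if (kmax == 0) return(0)
  core_sub <- igraph::induced_subgraph(sub, names(core)[core >= kmax])
  kmax * graph_density(core_sub)
}

mcode_weights <- function(g) {
  vapply(igraph::V(g)$name, function(v) mcode_vertex_weight(g, v), numeric(1))
}

#' MCODE dense-subgraph complexes
#'
#' Detects densely connected complexes following the MCODE procedure:
#' vertices are weighted by [mcode_vertex_weight()]; complexes are grown from
#' unvisited seeds in decreasing weight order (lexicographic node id on
#' ties), admitting unvisited neighbours whose weight exceeds
#' `(1 - node_score_cutoff) * seed_weight`, up to `max_depth` steps from the
#' seed. Complexes lacking a `k_core` are discarded and the haircut strips
#' singly connected members. Complexes are ranked by score = density x size.
#'
#' @param graph igraph graph or edge list data.frame.
#' @param degree_cutoff nodes of smaller degree are never seeds (default 2).
#' @param node_score_cutoff admission slack relative to the seed weight
#'   (default 0.2).
#' @param k_core minimum core a complex must contain (default 2).
#' @param max_depth growth radius from the seed (default 100).
#' @param haircut remove degree-1 members from final complexes
#'   (default TRUE).
#' @return list of subclusters, each a list with `members` (sorted node
#'   names), `score`, `seed`; ordered by decreasing score.
#' @export
mcode_complexes <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                            k_core = 2, max_depth = 100, haircut = TRUE) {
  g <- if (igraph::is_igraph(graph)) graph else edge_graph(graph)
  if (igraph::vcount(g) == 0) return(list())
  w <- mcode_weights(g)
  deg <- igraph::degree(g)
  ord <- names(w)[order(-w, names(w))]
  visited <- character(0)
  complexes <- list()
  for (seed in ord) {
    if (seed %in% visited) next
    if (deg[seed] < degree_cutoff) next
    if (w[seed] <= 0) next
    thr <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in igraph::neighbors(g, v)$name) {
          if (u %in% members || u %in% visited) next
          if (w[u] > thr) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    visited <- c(visited, members)
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) < k_core) next
    if (haircut) {
      repeat {
        d <- igraph::degree(sub)
        drop <- names(d)[d < 2]
        if (length(drop) == 0 || igraph::vcount(sub) - length(drop) < 2) break
        sub <- igraph::induced_subgraph(sub,
                                        setdiff(igraph::V(sub)$name, drop))
      }
    }
    if (igraph::vcount(sub) < 2) next
    complexes[[length(complexes) + 1]] <-
      list(members = sort(igraph::V(sub)$name),
           score = graph_density(sub) * igraph::vcount(sub),
           seed = seed)
  }
  complexes[order(-vapply(complexes, `[[`, numeric(1), "score"))]
}

#' Shortest-path betweenness centrality
#'
#' Unnormalised betweenness over unweighted shortest paths (Brandes
#' accumulation, via igraph). Disconnected graphs are handled per component.
#'
#' @param graph igraph graph or edge list data.frame.
#' @return named numeric vector, node -> betweenness.
#' @export
betweenness_centrality <- function(graph) {
  g <- if (igraph::is_igraph(graph)) graph else edge_graph(graph)
  igraph::betweenness(g, directed = FALSE, weights = NA)
}

#' Degree-percentile hub identification
#'
#' A hub is a node whose degree strictly exceeds the nearest-rank
#' `percentile`-th percentile of its module's degree distribution (default
#' the 90th). As a centrality diagnostic the Pearson correlation of degree
#' versus betweenness is reported per module (hubs in co-expression graphs
#' are expected to show a positive relation); a non-positive correlation
#' triggers a warning but does not filter hubs.
#'
#' @param edges exported edge list (columns `gene_a`, `gene_b`, `module`).
#' @param percentile degree percentile for the cutoff (default 90).
#' @param scope `"module"` (default) computes the cutoff per module;
#'   `"global"` uses the degree distribution of the whole edge list.
#' @param min_nodes modules with fewer nodes yield no hubs, with a warning
#'   (default 10).
#' @return object of class `hub_set`: list with `nodes` (data.frame `gene`,
#'   `module`, `degree`, `betweenness`, `is_hub`) and `modules` (data.frame
#'   `module`, `n_nodes`, `cutoff`, `n_hubs`, `degree_betweenness_cor`).
#' @export
find_hubs <- function(edges, percentile = 90, scope = c("module", "global"),
                      min_nodes = 10) {
  scope <- match.arg(scope)
  mods <- unique(edges$module)
  global_cut <- if (scope == "global") {
    nearest_rank_percentile(igraph::degree(edge_graph(edges)), percentile)
  } else NA
  nodes <- list(); modules <- list()
  for (m in mods) {
    g <- edge_graph(edges, m)
    deg <- igraph::degree(g)
    btw <- betweenness_centrality(g)
    if (length(deg) < min_nodes) {
      warn2("module %s has %d nodes (< %d): no hubs called", m, length(deg),
            min_nodes)
      cut <- NA; hub <- rep(FALSE, length(deg))
    } else {
      cut <- if (scope == "global") global_cut
             else nearest_rank_percentile(deg, percentile)
      hub <- deg > cut
    }
    db_cor <- if (length(deg) >= 3 && stats::sd(deg) > 0 && stats::sd(btw) > 0)
      stats::cor(deg, btw) else NA
    if (!is.na(db_cor) && db_cor <= 0)
      warn2("module %s: degree-betweenness correlation %.2f <= 0", m, db_cor)
    nodes[[m]] <- data.frame(gene = names(deg), module = m,
                             degree = as.integer(deg),
                             betweenness = unname(btw[names(deg)]),
                             is_hub = unname(hub), row.names = NULL)
    modules[[m]] <- data.frame(module = m, n_nodes = length(deg),
                               cutoff = cut, n_hubs = sum(hub),
                               degree_betweenness_cor = db_cor,
                               row.names = NULL)
  }
  structure(list(nodes = if (length(nodes)) do.call(rbind, c(nodes, make.row.names = FALSE))
                 else data.frame(),
                 modules = if (length(modules)) do.call(rbind, c(modules, make.row.names = FALSE))
                 else data.frame(),
                 percentile = percentile, scope = scope),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set (%s scope, %gth percentile): %d hub(s) in %d module(s)\n",
              x$scope, x$percentile, sum(x$nodes$is_hub), nrow(x$modules)))
  if (nrow(x$modules) > 0) print(x$modules, row.names = FALSE)
  invisible(x)
}

#' Write MCODE subclusters and hubs to TSV
#'
#' @param complexes list from [mcode_complexes()].
#' @param hubs a `hub_set` from [find_hubs()].
#' @param dir output directory; writes `subclusters.tsv` and `hubs.tsv`.
#' @param module optional module label recorded with each subcluster.
#' @return `dir`, invisibly.
#' @export
write_graph_analysis <- function(complexes, hubs, dir, module = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- if (length(complexes)) do.call(rbind, lapply(seq_along(complexes),
    function(i) data.frame(cluster = i, module = module,
                           score = complexes[[i]]$score,
                           n_members = length(complexes[[i]]$members),
                           members = paste(complexes[[i]]$members,
                                           collapse = ","))))
    else data.frame(cluster = integer(), module = character(),
                    score = numeric(), n_members = integer(),
                    members = character())
  utils::write.table(sc, file.path(dir, "subclusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hubs$nodes, file.path(dir, "hubs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
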