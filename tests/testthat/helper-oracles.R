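# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately use naive loops and
# plain R so they share no code path with the implementation under test.

# topological overlap by triple loop
tom_brute <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# unnormalised betweenness by explicit shortest-path enumeration
betweenness_brute <- function(adj_list) {
  nodes <- names(adj_list)
  bet <- stats::setNames(rep(0, length(nodes)), nodes)
  bfs_dist <- function(s) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (u in adj_list[[v]]) if (!is.finite(d[u])) {
        d[u] <- d[v] + 1; q <- c(q, u)
      }
    }
    d
  }
  all_paths <- function(s, t, d) {
    # enumerate all shortest s->t paths walking back from t
    walk <- function(u) {
      if (u == s) return(list(s))
      preds <- adj_list[[u]][d[adj_list[[u]]] == d[u] - 1]
      out <- list()
      for (p in preds) for (pp in walk(p)) out <- c(out, list(c(pp, u)))
      out
    }
    walk(t)
  }
  for (si in seq_along(nodes)) for (ti in seq_along(nodes)) {
    if (si >= ti) next
    s <- nodes[si]; t <- nodes[ti]
    d <- bfs_dist(s)
    if (!is.finite(d[t])) next
    paths <- all_paths(s, t, d)
    for (v in nodes) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      bet[v] <- bet[v] + through / length(paths)
    }
  }
  bet
}

# hypergeometric upper tail by enumerating every draw (N <= 12)
hyper_brute <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)       # first K elements carry the annotation
  mean(hits >= k)
}

# igraph edge list -> adjacency list for the betweenness oracle
as_adj_list <- function(el) {
  nodes <- sort(unique(c(el[, 1], el[, 2])))
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    out[[a]] <- union(out[[a]], b)
    out[[b]] <- union(out[[b]], a)
  }
  out
}

# adjusted Rand index between two label vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# an expression matrix whose module eigengenes have a prescribed pairwise
# correlation: two noiseless rank-1 modules built on profiles with cor rho
two_module_expr <- function(rho, n_samples = 10, genes_per_module = 5,
                            seed = 42) {
  set.seed(seed)
  p <- scale(rnorm(n_samples))[, 1]
  r <- rnorm(n_samples)
  r <- scale(r - p * sum(r * p) / sum(p * p))[, 1]   # orthogonal to p
  q <- rho * p + sqrt(1 - rho^2) * r
  vals <- rbind(
    t(vapply(seq_len(genes_per_module), function(i) 2 + i * p,
             numeric(n_samples))),
    t(vapply(seq_len(genes_per_module), function(i) 3 + i * q,
             numeric(n_samples))))
  rownames(vals) <- c(paste0("a", seq_len(genes_per_module)),
                      paste0("b", seq_len(genes_per_module)))
  colnames(vals) <- paste0("s", seq_len(n_samples))
  vals
}

# minimal DE-result stand-in: per-gene overall status only
fake_de <- function(genes, overall_status) {
  res <- data.frame(gene = genes, group = "trt", log2fc = NA_real_,
                    status = overall_status)
  attr(res, "overall") <- data.frame(gene = genes,
                                     overall_status = overall_status)
  class(res) <- c("de_result", "data.frame")
  res
}

# random 0-order sequences
random_seqs <- function(n, len, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
          collapse = ""), character(1))
}
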