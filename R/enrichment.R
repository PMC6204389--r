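# Hypergeometric over-representation tests with Benjamini-Hochberg FDR
# control, for GO-like and KOG-like annotation tables.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a query of size
#' `n` drawn without replacement from a background of `N` genes of which `K`
#' carry the annotation:
#' `p = sum_{i=k..min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k observed hits in the query.
#' @param K annotated genes in the background.
#' @param n query size.
#' @param N background size.
#' @return upper-tail p-value in (0, 1\].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0)) stop2("negative arguments")
  if (any(K > N) || any(n > N)) stop2("K and n must not exceed N")
  if (any(k > pmin(K, n))) stop2("k must not exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; input order is
#' preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop2("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build an annotation set from a gene-term table
#'
#' @param table data.frame with columns `gene`, `term` (and optionally
#'   `namespace`, `description`), or a TSV path.
#' @param background character vector of background gene ids; terms are
#'   intersected with it and empty terms dropped. Annotated genes outside
#'   the background are dropped with a warning.
#' @return object of class `annotation_set`: list with `terms` (term ->
#'   gene-id vector), `meta`, `background`.
#' @export
annotation_set <- function(table, background) {
  if (is.character(table) && length(table) == 1)
    table <- utils::read.delim(table)
  stopifnot(all(c("gene", "term") %in% names(table)))
  background <- unique(as.character(background))
  out_bg <- setdiff(unique(table$gene), background)
  if (length(out_bg) > 0) {
    warn2("%d annotated gene(s) outside the background dropped", length(out_bg))
    table <- table[table$gene %in% background, , drop = FALSE]
  }
  terms <- lapply(split(as.character(table$gene), table$term), unique)
  terms <- terms[vapply(terms, length, integer(1)) > 0]
  meta <- unique(table[, intersect(c("term", "namespace", "description"),
                                   names(table)), drop = FALSE])
  structure(list(terms = terms, meta = meta, background = background),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d term(s) over %d background gene(s)\n",
              length(x$terms), length(x$background)))
  invisible(x)
}

#' Hypergeometric term enrichment of a gene set
#'
#' Tests every annotation term with at least one hit in the query against
#' the background by the hypergeometric upper tail, then applies
#' Benjamini-Hochberg correction across the tested terms. Two significance
#' modes mirror common practice: `"go"` calls a term significant at
#' q <= `alpha` (default 0.05); `"kog"` additionally requires the raw
#' p <= `p_cutoff` (default 1e-3). Queries below `min_query` genes return an
#' empty result flagged `below_min_size` (subclusters are conventionally
#' only tested from 10 genes up).
#'
#' @param query character vector of gene ids (must lie in the background).
#' @param ann an [annotation_set()].
#' @param mode `"go"` or `"kog"`.
#' @param alpha FDR threshold on q (default 0.05).
#' @param p_cutoff raw-p threshold used in `"kog"` mode (default 1e-3).
#' @param min_query minimum query size (default 1; use 10 for subcluster
#'   enrichment).
#' @return data.frame of class `enrichment_result` with columns `term`,
#'   `k`, `K`, `n`, `N`, `p`, `q`, `significant`, sorted by p; attribute
#'   `below_min_size` flags short-circuited queries.
#' @export
enrich <- function(query, ann, mode = c("go", "kog"), alpha = 0.05,
                   p_cutoff = 1e-3, min_query = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(ann, "annotation_set"))
  query <- unique(as.character(query))
  missing <- setdiff(query, ann$background)
  if (length(missing) > 0)
    stop2("query gene(s) not in background: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  empty <- data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical())
  if (length(query) < min_query) {
    attr(empty, "below_min_size") <- TRUE
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  N <- length(ann$background)
  n <- length(query)
  rows <- lapply(names(ann$terms), function(t) {
    genes <- ann$terms[[t]]
    k <- length(intersect(genes, query))
    if (k == 0) return(NULL)
    data.frame(term = t, k = k, K = length(genes), n = n, N = N,
               p = hypergeometric_tail(k, length(genes), n, N))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    attr(empty, "below_min_size") <- FALSE
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$significant <- if (mode == "go") res$q <= alpha
                     else res$p <= p_cutoff & res$q <= alpha
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  attr(res, "below_min_size") <- FALSE
  class(res) <- c("enrichment_result", "data.frame")
  res
}
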