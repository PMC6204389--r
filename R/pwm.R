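# Position weight matrices: construction from aligned sites or a count
# matrix, exact score distributions under a 0-order background, and p-value
# lookup. Scores are log-odds in bits, discretised on a fixed grid so that
# scanning and the null distribution use identical score values.

BASES <- c("A", "C", "G", "T")
SCORE_BIN <- 1e-3  # bits

#' Build a position weight matrix
#'
#' From aligned equal-length binding-site sequences (or a ready 4 x width
#' count matrix) builds per-position frequencies with a background-weighted
#' pseudocount and log2-odds scores against a 0-order background. With a
#' uniform background the pseudocount rule adds `pseudocount` to every cell
#' (cell `b` receives `pseudocount * 4 * background[b]` in general), so one
#' site "GGCAAA" at pseudocount 1 gives the consensus base frequency
#' (1+1)/(1+4) = 0.4.
#'
#' @param sites character vector of equal-length A/C/G/T sequences, or NULL.
#' @param counts 4 x width nonnegative matrix (rows A, C, G, T), used when
#'   `sites` is NULL.
#' @param pseudocount nonnegative pseudocount (default 1); 0 is rejected
#'   when any cell count is 0 (log-odds would be -Inf).
#' @param background length-4 base probability vector (A, C, G, T), summing
#'   to 1; default uniform.
#' @return object of class `pwm`: list with `width`, `counts`, `freq`,
#'   `log_odds` (bits), `background`, `pseudocount`, `consensus`, and
#'   `score_pvalue` (the exact null score distribution, see
#'   [score_distribution()]).
#' @export
build_pwm <- function(sites = NULL, counts = NULL, pseudocount = 1,
                      background = rep(0.25, 4)) {
  background <- unname(background)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop2("background must be 4 positive probabilities summing to 1")
  if (!is.null(sites)) {
    sites <- toupper(sites)
    if (length(sites) == 0) stop2("no sites supplied")
    if (length(unique(nchar(sites))) != 1) stop2("sites have unequal lengths")
    chars <- strsplit(sites, "")
    if (!all(unlist(chars) %in% BASES))
      stop2("sites contain non-ACGT characters")
    w <- nchar(sites[1])
    counts <- vapply(seq_len(w), function(j)
      tabulate(factor(vapply(chars, `[[`, character(1), j), levels = BASES),
               nbins = 4), integer(4))
  } else if (is.null(counts)) {
    stop2("supply either sites or counts")
  } else {
    counts <- as.matrix(counts)
    if (nrow(counts) != 4 || any(counts < 0))
      stop2("counts must be a 4 x width nonnegative matrix (rows A,C,G,T)")
  }
  w <- ncol(counts)
  if (w < 4) stop2("motif width must be at least 4")
  if (w < 6 || w > 10)
    warn2("motif width %d outside the usual 6-10 range", w)
  if (pseudocount < 0) stop2("pseudocount must be nonnegative")
  if (pseudocount == 0 && any(counts == 0))
    stop2("pseudocount 0 with zero counts gives -Inf log-odds; use > 0")
  rownames(counts) <- BASES
  pseudo <- pseudocount * 4 * background
  freq <- sweep(counts + pseudo, 2, colSums(counts) + 4 * pseudocount, "/")
  log_odds <- log2(freq / background)
  pwm <- structure(list(width = w, counts = counts, freq = freq,
                        log_odds = log_odds, background = background,
                        pseudocount = pseudocount,
                        consensus = paste(BASES[apply(freq, 2, which.max)],
                                          collapse = "")),
                   class = "pwm")
  pwm$score_pvalue <- score_distribution(pwm)
  pwm
}

#' @export
print.pwm <- function(x, ...) {
  ic <- sum(x$freq * log2(x$freq / x$background))
  cat(sprintf("pwm: width %d, consensus %s, information content %.1f bits\n",
              x$width, x$consensus, ic))
  invisible(x)
}

# integer (grid) log-odds scores; all scoring goes through this grid
pwm_int_scores <- function(pwm) {
  round(pwm$log_odds / SCORE_BIN)
}

#' Exact null distribution of PWM scores
#'
#' Distribution of the log-odds score of a random background word, exact up
#' to the score discretisation (bins of 0.001 bits): full enumeration of the
#' `4^width` words for widths up to 8, positionwise convolution (dynamic
#' programming over the integer score grid) beyond. `p(score)` is the
#' probability that a background word scores at least that high.
#'
#' @param pwm a [build_pwm()] object.
#' @param method `"auto"` (default), `"enumeration"` or `"dp"`.
#' @return data.frame with columns `score` (bits, ascending), `prob`,
#'   `tailp`.
#' @export
score_distribution <- function(pwm, method = c("auto", "enumeration", "dp")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (pwm$width <= 8) "enumeration" else "dp"
  s <- pwm_int_scores(pwm)
  if (method == "enumeration") {
    grid <- as.matrix(expand.grid(rep(list(1:4), pwm$width)))
    sc <- vapply(seq_len(nrow(grid)), function(i)
      sum(s[cbind(grid[i, ], seq_len(pwm$width))]), numeric(1))
    pr <- apply(matrix(pwm$background[grid], nrow(grid)), 1, prod)
    agg <- tapply(pr, sc, sum)
  } else {
    dist <- c(`0` = 1)
    for (j in seq_len(pwm$width)) {
      keys <- as.numeric(names(dist))
      new_keys <- as.vector(outer(keys, s[, j], "+"))
      new_p <- as.vector(outer(unname(dist), pwm$background, "*"))
      agg_j <- tapply(new_p, new_keys, sum)
      dist <- agg_j
    }
    agg <- dist
  }
  score <- as.numeric(names(agg)) * SCORE_BIN
  ord <- order(score)
  prob <- as.numeric(agg)[ord]
  score <- score[ord]
  data.frame(score = score, prob = prob, tailp = rev(cumsum(rev(prob))))
}

#' PWM score p-value
#'
#' @param pwm a [build_pwm()] object.
#' @param score score(s) in bits (on the package's score grid).
#' @return probability that a background word scores >= `score`.
#' @export
pwm_pvalue <- function(pwm, score) {
  tab <- pwm$score_pvalue
  # scores live on the discretisation grid; snap within the accumulated
  # rounding error of one word so that exact (undiscretised) scores of the
  # same word resolve to the same grid level
  tol <- SCORE_BIN * (pwm$width / 2 + 1)
  idx <- findInterval(score - tol, tab$score) + 1
  out <- ifelse(idx > nrow(tab), 0, tab$tailp[pmin(idx, nrow(tab))])
  unname(out)
}

#' Read a PWM from MEME minimal format or a count-matrix TSV
#'
#' Accepts either a MEME minimal-format motif file (the first motif's
#' letter-probability matrix, scaled by `nsites` into counts) or a plain TSV
#' with 4 rows (A, C, G, T; optional first column of base labels).
#'
#' @param path file path.
#' @param ... passed to [build_pwm()] (`pseudocount`, `background`).
#' @return a `pwm`.
#' @export
read_pwm <- function(path, ...) {
  lines <- readLines(path)
  if (any(grepl("^MEME version", lines))) {
    i <- grep("^letter-probability matrix", lines)[1]
    if (is.na(i)) stop2("no letter-probability matrix in %s", path)
    nsites <- sub(".*nsites= *([0-9]+).*", "\\1", lines[i])
    nsites <- if (grepl("^[0-9]+$", nsites)) as.integer(nsites) else 20L
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[i]))
    block <- lines[(i + 1):(i + w)]
    probs <- t(vapply(strsplit(trimws(block), "\\s+"),
                      function(x) as.numeric(x[1:4]), numeric(4)))
    counts <- t(probs) * nsites
    rownames(counts) <- BASES
    build_pwm(counts = counts, ...)
  } else {
    tab <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (is.character(tab[[1]])) {
      rn <- toupper(tab[[1]]); tab <- tab[, -1, drop = FALSE]
      tab <- tab[match(BASES, rn), , drop = FALSE]
    }
    build_pwm(counts = as.matrix(tab), ...)
  }
}

#' Synthetic Xyr1-like binding-site sequences
#'
#' A synthetic set of 22 aligned 10-bp sites built around the Xyr1 consensus
#' GGC(A/T)(A/T)(A/T) with fixed flanks and occasional off-consensus bases.
#' This is a stand-in constructed for examples and validation - it is not a
#' motif derived from experimental binding data - but its information
#' content (> 10 bits) and width match what a fungal transcription-factor
#' PWM scan operates on.
#'
#' @return character vector of 22 sequences.
#' @export
synthetic_xbs_sites <- function() {
  c("ATGGCAAATC", "ATGGCTAATC", "ATGGCATATC", "ATGGCTTATC",
    "ATGGCAATTC", "ATGGCTATTC", "ATGGCAAATC", "ATGGCTTTTC",
    "ATGGCAAATC", "ATGGCATTTC", "ATGGCTAATC", "ATGGCAAATG",
    "ATGGCTAATC", "ATGGCAATTC", "ACGGCAAATC", "ATGGCTATTC",
    "ATGGCAAATC", "ATGGCATATC", "GTGGCAAATC", "ATGGCTAATC",
    "ATGGCAAATT", "ATGGCTTATC")
}

#' 0-order base composition of a sequence set
#'
#' @param x `DNAStringSet`, character vector of sequences, or a
#'   `promoter_set`. N bases are ignored.
#' @return named probability vector over A, C, G, T.
#' @export
base_composition <- function(x) {
  if (inherits(x, "promoter_set")) x <- x$seq
  if (inherits(x, "DNAStringSet"))
    x <- as.character(x)
  tab <- table(factor(unlist(strsplit(toupper(paste(x, collapse = "")), "")),
                      levels = BASES))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, BASES)
}
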