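# PWM scanning of promoter sets on both strands with exact p-values.

# encode an uppercase sequence as 1..4 (A,C,G,T), NA for anything else
encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES)
}

# integer grid scores of all windows of `code` under integer score matrix
# `si` (4 x w); windows containing NA (e.g. N bases) give NA
window_scores <- function(code, si) {
  w <- ncol(si)
  n <- length(code) - w + 1
  if (n < 1) return(numeric(0))
  total <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    b <- code[j:(j + n - 1)]
    bad <- bad | is.na(b)
    total <- total + ifelse(is.na(b), 0, si[cbind(b, j)])
  }
  total[bad] <- NA
  total
}

#' Scan promoters for PWM matches
#'
#' Scores every window of every promoter on the gene's sense strand and (by
#' default) on the reverse strand, and reports matches whose exact
#' background p-value is at or below `p_threshold`. Windows containing N
#' are skipped. Offsets follow the upstream convention: the reported offset
#' is the position of the match's 5'-most base on the sense orientation,
#' with -1 the base immediately adjacent to the ATG, so a hit "at -420"
#' starts 420 bp upstream of the start codon.
#'
#' @param pwm a [build_pwm()] object.
#' @param promoters a `promoter_set` from [extract_promoters()] (or a named
#'   character vector of sequences).
#' @param p_threshold match p-value threshold (default 1e-4).
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param background `"promoters"` (default) rebuilds the PWM log-odds
#'   against the 0-order composition of the scanned promoter set; `"pwm"`
#'   keeps the background the PWM was built with.
#' @return data.frame of class `motif_hits` with columns `gene`, `offset`,
#'   `strand` (relative to the gene), `score` (bits), `p_value`; attribute
#'   `n_windows` holds the number of scored strand-windows (the denominator
#'   of the scan's null rate).
#' @export
scan_promoters <- function(pwm, promoters, p_threshold = 1e-4,
                           both_strands = TRUE,
                           background = c("promoters", "pwm")) {
  background <- match.arg(background)
  seqs <- if (inherits(promoters, "promoter_set"))
    stats::setNames(as.character(promoters$seq), promoters$info$gene)
  else promoters
  if (is.null(names(seqs))) stop2("promoter sequences must be named by gene")
  if (background == "promoters") {
    comp <- base_composition(seqs)
    if (any(comp == 0)) comp <- (comp + 1e-4) / sum(comp + 1e-4)
    pwm <- build_pwm(counts = pwm$counts, pseudocount = pwm$pseudocount,
                     background = comp)
  }
  si <- pwm_int_scores(pwm)
  # reverse-strand matrix: scoring the sense window with this equals scoring
  # its reverse complement with the PWM
  si_rc <- si[4:1, ncol(si):1, drop = FALSE]
  w <- pwm$width
  hits <- list(); n_windows <- 0
  for (g in names(seqs)) {
    code <- encode_seq(seqs[[g]])
    P <- length(code)
    if (P < w) next
    sc_f <- window_scores(code, si)
    mats <- list(`+` = sc_f)
    if (both_strands) mats$`-` <- window_scores(code, si_rc)
    for (strand in names(mats)) {
      sc <- mats[[strand]]
      ok <- !is.na(sc)
      n_windows <- n_windows + sum(ok)
      if (!any(ok)) next
      pv <- rep(NA_real_, length(sc))
      pv[ok] <- pwm_pvalue(pwm, sc[ok] * SCORE_BIN)
      sel <- which(ok & pv <= p_threshold)
      if (length(sel) == 0) next
      hits[[length(hits) + 1]] <-
        data.frame(gene = g, offset = sel - P - 1L, strand = strand,
                   score = sc[sel] * SCORE_BIN, p_value = pv[sel],
                   row.names = NULL)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(), offset = integer(), strand = character(),
               score = numeric(), p_value = numeric())
  out <- out[order(out$gene, out$offset), ]
  rownames(out) <- NULL
  attr(out, "n_windows") <- n_windows
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Genes carrying at least one predicted binding site
#'
#' @param hits a `motif_hits` data.frame from [scan_promoters()].
#' @param genes optional gene universe; when given, the result covers every
#'   gene (FALSE for genes without hits).
#' @return named logical vector, gene -> has >= 1 hit.
#' @export
genes_with_xbs <- function(hits, genes = NULL) {
  with_hit <- unique(hits$gene)
  if (is.null(genes)) genes <- with_hit
  stats::setNames(genes %in% with_hit, genes)
}

#' Write motif hits to TSV
#'
#' @param hits `motif_hits` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
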