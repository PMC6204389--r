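# Promoter extraction: the 1.5 kb of sense-strand sequence immediately
# upstream of each gene's start codon, taken from a genome FASTA and a gene
# model table (or GFF3).

#' Read gene models from a GFF3 file
#'
#' Imports the annotation with rtracklayer and reduces it to one row per
#' gene: contig, strand and the coding span. The `gene` feature span is
#' taken as the CDS span (ATG at the 5' end); annotations whose gene
#' features include UTRs should instead supply a model table with explicit
#' CDS coordinates.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene`, `contig`, `strand`, `start`,
#'   `end` (1-based inclusive).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  data.frame(gene = as.character(id),
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             row.names = NULL)
}

#' Extract upstream promoter sequences
#'
#' For a plus-strand gene with start codon at position `s`, the promoter is
#' the genomic window `[max(1, s - length), s - 1]` as-is; for a
#' minus-strand gene with start codon at position `e` (the CDS end
#' coordinate), it is `[e + 1, min(contig_end, e + length)]`
#' reverse-complemented. Either way the returned sequence reads 5'->3' on
#' the gene's sense strand, ending at the base immediately upstream of the
#' ATG. Promoters shortened by a contig edge are flagged truncated.
#'
#' @param genome `DNAStringSet` (or FASTA path) of contigs.
#' @param models gene-model data.frame from [read_gene_models()] (columns
#'   `gene`, `contig`, `strand`, `start`, `end`).
#' @param length promoter length in bp (default 1500).
#' @return object of class `promoter_set`: list with `seq` (named
#'   `DNAStringSet`) and `info` (data.frame `gene`, `contig`, `strand`,
#'   `atg`, `window_start`, `window_end`, `length`, `truncated`).
#' @export
extract_promoters <- function(genome, models, length = 1500) {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(models$contig, names(genome))
  if (length(miss) > 0)
    stop2("contig(s) missing from genome: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  n <- nrow(models)
  seqs <- character(n); info <- vector("list", n)
  for (i in seq_len(n)) {
    ctg <- genome[[models$contig[i]]]
    L <- Biostrings::nchar(ctg)
    if (models$strand[i] == "+") {
      atg <- models$start[i]
      ws <- max(1, atg - length); we <- atg - 1
      if (we < ws) { ws <- 1; we <- 0 }
      s <- if (we >= ws) as.character(Biostrings::subseq(ctg, ws, we)) else ""
    } else {
      atg <- models$end[i]
      ws <- atg + 1; we <- min(L, atg + length)
      s <- if (we >= ws)
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(ctg, ws, we))) else ""
      if (we < ws) { ws <- 1; we <- 0 }
    }
    seqs[i] <- s
    info[[i]] <- data.frame(gene = models$gene[i], contig = models$contig[i],
                            strand = models$strand[i], atg = atg,
                            window_start = ws, window_end = we,
                            length = nchar(s), truncated = nchar(s) < length)
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- models$gene
  structure(list(seq = ss, info = do.call(rbind, info),
                 promoter_length = length),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoter(s), target length %d bp (%d truncated)\n",
              length(x$seq), x$promoter_length, sum(x$info$truncated)))
  invisible(x)
}

#' Write promoters to FASTA
#'
#' Headers follow `gene|<offset_from>..<offset_to>` with offsets relative to
#' the ATG (-1 = base immediately upstream).
#'
#' @param promoters a `promoter_set`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  ss <- promoters$seq
  names(ss) <- sprintf("%s|%d..-1", promoters$info$gene,
                       -promoters$info$length)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
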