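test_that("PWM construction follows the pseudocount rule", {
  p <- suppressWarnings(build_pwm("GGCAAA"))
  expect_equal(unname(p$freq["G", 1]), 0.4)
  expect_equal(unname(p$freq[c("A", "C", "T"), 1]), rep(0.2, 3))
  expect_equal(unname(colSums(p$freq)), rep(1, 6), tolerance = 1e-12)
  # uniform counts column gives zero log-odds under uniform background
  cnt <- matrix(5, 4, 6)
  p2 <- suppressWarnings(build_pwm(counts = cnt))
  expect_equal(unname(p2$log_odds), matrix(0, 4, 6))
  # zero pseudocount with a zero count is rejected
  expect_error(suppressWarnings(build_pwm("GGCAAA", pseudocount = 0)),
               "pseudocount")
  expect_error(build_pwm(c("ACGT", "ACG")), "unequal")
  expect_error(build_pwm("ACGNACGT"), "non-ACGT")
})

test_that("exact score distribution matches word enumeration", {
  # analogue of the dinucleotide worked example at the minimum width:
  # a single site, uniform background; only the consensus word reaches the
  # maximal score, so its tail probability is 1/4^w
  p4 <- suppressWarnings(build_pwm("AAAA"))
  smax <- sum(apply(p4$log_odds, 2, max))
  expect_equal(pwm_pvalue(p4, smax), 1 / 256, tolerance = 1e-9)
  # minimum score has p = 1
  expect_equal(pwm_pvalue(p4, min(p4$score_pvalue$score)), 1)
  # p-value map is monotone non-increasing in score
  expect_true(all(diff(p4$score_pvalue$tailp) <= 0))

  # DP equals enumeration: independent oracle over all 4^w words using the
  # frequency matrix directly (bracketed to absorb score discretisation)
  set.seed(17)
  for (w in c(4, 5, 6)) {
    cnt <- matrix(rpois(4 * w, 3), 4, w)
    bgp <- c(0.3, 0.2, 0.2, 0.3)
    pwm <- suppressWarnings(build_pwm(counts = cnt, background = bgp))
    dp <- score_distribution(pwm, method = "dp")
    words <- as.matrix(expand.grid(rep(list(1:4), w)))
    wscore <- rowSums(matrix(log2(pwm$freq / pwm$background)[
      cbind(as.vector(words), rep(seq_len(w), each = nrow(words)))],
      nrow(words)))
    wprob <- apply(matrix(bgp[words], nrow(words)), 1, prod)
    oracle_tail <- function(s) sum(wprob[wscore >= s])
    for (qs in quantile(wscore, c(0.05, 0.3, 0.6, 0.9, 1))) {
      p_dp <- pwm_pvalue(pwm, qs)
      expect_lte(p_dp, oracle_tail(qs - 0.005) + 1e-12)
      expect_gte(p_dp, oracle_tail(qs + 0.005) - 1e-12)
    }
    # and the dp and enumeration routes agree with each other exactly
    en <- score_distribution(pwm, method = "enumeration")
    expect_equal(dp$score, en$score, tolerance = 1e-9)
    expect_equal(dp$tailp, en$tailp, tolerance = 1e-12)
  }
})

test_that("consensus scores maximally and its p-value is the match mass", {
  pwm <- build_pwm(synthetic_xbs_sites())
  si <- pwm$log_odds
  cons_score <- sum(si[cbind(match(strsplit(pwm$consensus, "")[[1]],
                                   c("A", "C", "G", "T")),
                             seq_len(pwm$width))])
  expect_equal(cons_score, sum(apply(si, 2, max)), tolerance = 1e-9)
  # information content is high enough for confident single-hit detection
  expect_gte(sum(pwm$freq * log2(pwm$freq / pwm$background)), 10)
  expect_lte(pwm_pvalue(pwm, cons_score - 1e-6), 1e-4)
})

test_that("promoter extraction follows the strand-aware window convention", {
  set.seed(23)
  contig <- random_seqs(1, 5000, seed = 23)
  marker <- "ACGTTGCAAGGT"
  # plus-strand gene, ATG at 2001: window 501..2000
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  models <- data.frame(gene = "gp", contig = "chr1", strand = "+",
                       start = 2001, end = 2300)
  pr <- extract_promoters(genome, models, length = 1500)
  expect_equal(pr$info$window_start, 501)
  expect_equal(pr$info$window_end, 2000)
  expect_equal(as.character(pr$seq[["gp"]]), substr(contig, 501, 2000))
  expect_false(pr$info$truncated)

  # truncation at the contig edge: ATG at 800 gives 1..799
  models2 <- data.frame(gene = "gt", contig = "chr1", strand = "+",
                        start = 800, end = 1100)
  pr2 <- extract_promoters(genome, models2, length = 1500)
  expect_equal(pr2$info$length, 799)
  expect_true(pr2$info$truncated)

  # minus-strand gene: promoter = revcomp of the window downstream of the
  # CDS end; plant a marker to pin the orientation
  ctg2 <- contig
  substr(ctg2, 1301, 1300 + nchar(marker)) <- marker
  genome2 <- Biostrings::DNAStringSet(c(chr2 = ctg2))
  models3 <- data.frame(gene = "gm", contig = "chr2", strand = "-",
                        start = 1000, end = 1300)
  pr3 <- extract_promoters(genome2, models3, length = 1500)
  expect_equal(as.character(pr3$seq[["gm"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(ctg2, 1301, 2800)))))
  # base at genomic position e+1 is promoter position -1 (the last base)
  expect_equal(substr(as.character(pr3$seq[["gm"]]), 1500, 1500),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(ctg2, 1301, 1301)))))
  expect_error(extract_promoters(genome, data.frame(
    gene = "gx", contig = "nope", strand = "+", start = 10, end = 20)),
    "missing")
})

test_that("scanning finds planted sites at their recorded offsets", {
  pwm <- build_pwm(synthetic_xbs_sites())
  pro <- random_seqs(1, 1500, seed = 29)
  substr(pro, 1500 + 1 - 420, 1500 + 1 - 420 + 9) <- pwm$consensus
  hits <- scan_promoters(pwm, c(gene1 = pro), background = "pwm")
  expect_true(any(hits$gene == "gene1" & hits$offset == -420 &
                    hits$strand == "+"))
  # all-N promoter yields nothing
  h0 <- scan_promoters(pwm, c(g = paste(rep("N", 100), collapse = "")),
                       background = "pwm")
  expect_equal(nrow(h0), 0)
  expect_equal(attr(h0, "n_windows"), 0)
})

test_that("reverse-complement symmetry of the two-strand scan", {
  pwm <- build_pwm(synthetic_xbs_sites())
  s <- random_seqs(1, 300, seed = 37)
  substr(s, 50, 59) <- pwm$consensus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_promoters(pwm, c(g = s), background = "pwm")
  h2 <- scan_promoters(pwm, c(g = rc), background = "pwm")
  expect_equal(nrow(h1), nrow(h2))
  # the same matches reappear with strand labels swapped and identical
  # scores (offsets remap through the reverse complement)
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
  count <- function(h, s) sum(h$strand == s)
  expect_equal(count(h1, "+"), count(h2, "-"))
  expect_equal(count(h1, "-"), count(h2, "+"))
})

test_that("genes_with_xbs flags exactly the genes with hits", {
  hits <- data.frame(gene = c("a", "a", "b"), offset = c(-5, -9, -20),
                     strand = "+", score = 1, p_value = 1e-5)
  flags <- genes_with_xbs(hits, genes = c("a", "b", "c"))
  expect_equal(flags, c(a = TRUE, b = TRUE, c = FALSE))
  expect_equal(sum(flags), length(unique(hits$gene)))
})

test_that("PWM files round-trip through MEME minimal and TSV formats", {
  pwm <- build_pwm(synthetic_xbs_sites())
  dir <- withr::local_tempdir()
  # MEME minimal format written by hand
  meme <- file.path(dir, "m.meme")
  freq <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF XBS1", sprintf(
                 "letter-probability matrix: alength= 4 w= %d nsites= 22",
                 pwm$width),
               apply(freq, 2, function(col)
                 paste(sprintf("%.6f", col), collapse = " "))), meme)
  back <- read_pwm(meme)
  expect_equal(back$width, pwm$width)
  expect_equal(back$freq, pwm$freq, tolerance = 1e-4)

  tsv <- file.path(dir, "m.tsv")
  write.table(cbind(rownames(pwm$counts), as.data.frame(pwm$counts)), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  back2 <- read_pwm(tsv)
  expect_equal(unname(back2$counts), unname(pwm$counts))
})
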