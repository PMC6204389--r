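# Synthetic-data generators: count matrices with planted co-expression
# modules and differential expression, genomes with planted promoter motif
# instances, and annotation tables with planted term enrichments. Every
# generator exports its ground truth so parameter-recovery tests can score
# the pipeline.

#' Simulation configuration
#'
#' Captures the study design the generators emulate: a control sugar
#' sampled at one time point and an inducing substrate sampled along a
#' short time course, with replicated libraries, latent-factor
#' co-expression modules, fold-change responsive modules and
#' motif-carrying promoters.
#'
#' @param n_genes total genes (default 1200).
#' @param module_sizes sizes of the planted modules (default six modules of
#'   100; the remainder is unstructured background).
#' @param module_directions per-module response: `"up"`, `"down"` or
#'   `"none"` (default cycles up/down/none over the modules).
#' @param conditions data.frame with columns `condition`, `timepoint`
#'   (default: fructose at 24 h as control; bagasse at 6, 12, 24 h).
#' @param control group label of the control condition (default
#'   `"fructose_24h"`).
#' @param replicates_per_condition libraries per condition (default 3).
#' @param within_module_cor target within-module Pearson correlation on the
#'   latent (log) scale, in (0, 1\] (default 0.8).
#' @param de_fold multiplicative substrate/control effect for responsive
#'   modules (default 4).
#' @param dispersion count overdispersion (gamma-Poisson; 0 = Poisson-like;
#'   default 0.05).
#' @param anticor_fraction fraction of each module's genes given negative
#'   loadings, to exercise signed-network behaviour (default 0).
#' @param gene_length_range bp interval for simulated gene lengths
#'   (default 500-5000).
#' @param library_size_range interval of per-library total counts (default
#'   5e6-1.5e7); column sums land inside it by construction.
#' @param promoter_length promoter length in bp (default 1500).
#' @param motif_plant_fraction fraction of genes receiving a planted motif
#'   instance (default 0.3).
#' @param seed master seed; all generator randomness derives from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1200,
                       module_sizes = rep(100, 6),
                       module_directions = NULL,
                       conditions = data.frame(
                         condition = c("fructose", "bagasse", "bagasse", "bagasse"),
                         timepoint = c(24, 6, 12, 24)),
                       control = "fructose_24h",
                       replicates_per_condition = 3,
                       within_module_cor = 0.8,
                       de_fold = 4,
                       dispersion = 0.05,
                       anticor_fraction = 0,
                       gene_length_range = c(500, 5000),
                       library_size_range = c(5e6, 1.5e7),
                       promoter_length = 1500,
                       motif_plant_fraction = 0.3,
                       seed = 1) {
  if (sum(module_sizes) > n_genes)
    stop2("sum of module sizes (%d) exceeds n_genes (%d)",
          sum(module_sizes), n_genes)
  if (length(module_sizes) > 0 && any(module_sizes < 1))
    stop2("module sizes must be positive")
  if (is.null(module_directions))
    module_directions <- rep(c("up", "down", "none"),
                             length.out = length(module_sizes))
  stopifnot(length(module_directions) == length(module_sizes),
            all(module_directions %in% c("up", "down", "none")))
  if (replicates_per_condition < 1) stop2("replicates must be >= 1")
  if (within_module_cor <= 0 || within_module_cor > 1)
    stop2("within_module_cor must be in (0, 1]")
  if (dispersion < 0) stop2("dispersion must be >= 0")
  if (diff(gene_length_range) < 0 || diff(library_size_range) < 0)
    stop2("ranges must be nonempty")
  if (motif_plant_fraction < 0 || motif_plant_fraction > 1)
    stop2("motif_plant_fraction must be in [0, 1]")
  structure(list(n_genes = n_genes, module_sizes = module_sizes,
                 module_directions = module_directions,
                 conditions = conditions, control = control,
                 replicates_per_condition = replicates_per_condition,
                 within_module_cor = within_module_cor, de_fold = de_fold,
                 dispersion = dispersion,
                 anticor_fraction = anticor_fraction,
                 gene_length_range = gene_length_range,
                 library_size_range = library_size_range,
                 promoter_length = promoter_length,
                 motif_plant_fraction = motif_plant_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d module(s), %d samples, seed %d\n",
              x$n_genes, length(x$module_sizes),
              nrow(x$conditions) * x$replicates_per_condition, x$seed))
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#'
#' @param path YAML file.
#' @return [sim_config()] for the reader; `path` invisibly for the writer.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, lapply(yaml::read_yaml(path), function(x)
    if (is.list(x)) as.data.frame(x) else x))
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$conditions <- as.list(x$conditions)
  yaml::write_yaml(x, path)
  invisible(path)
}

sim_sample_meta <- function(config) {
  cond <- config$conditions
  reps <- config$replicates_per_condition
  meta <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i)
    data.frame(condition = cond$condition[i], timepoint = cond$timepoint[i],
               replicate = seq_len(reps))))
  meta$sample <- sprintf("%s_%sh_r%d", meta$condition, meta$timepoint,
                         meta$replicate)
  meta[, c("sample", "condition", "timepoint", "replicate")]
}

#' Simulate a count matrix with planted co-expression modules
#'
#' Genes in a module share a latent per-sample profile (one factor per
#' module) scaled by positive per-gene loadings, plus gene-level noise
#' calibrated so the expected within-module correlation of the latent log
#' expression matches `within_module_cor`. Responsive modules add
#' `log2(de_fold)` to the substrate samples. Counts are gamma-Poisson
#' around the latent intensities, drawn as one multinomial per library so
#' that every column sum lands exactly inside `library_size_range`.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [count_dataset()]) and `truth` (class
#'   `truth_bundle`): `module_of_gene`, `de_status` (gene x substrate-group
#'   matrix of up/down/none), `eigenprofiles` (module x sample latent
#'   profiles), `loadings`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "expression"))
  meta <- sim_sample_meta(config)
  n_s <- nrow(meta)
  grp <- condition_groups(meta)
  substrate <- grp != config$control
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  n_mod <- length(config$module_sizes)
  module_of_gene <- rep("background", config$n_genes)
  idx <- 0
  for (m in seq_len(n_mod)) {
    module_of_gene[idx + seq_len(config$module_sizes[m])] <- paste0("mod", m)
    idx <- idx + config$module_sizes[m]
  }
  names(module_of_gene) <- genes

  r <- config$within_module_cor
  sd_f <- 0.7   # log2-scale per-sample profile spread
  sd_e <- sd_f * sqrt((1 - r) / max(r, 1e-8))
  lfc <- log2(config$de_fold)

  profiles <- matrix(0, nrow = n_mod, ncol = n_s,
                     dimnames = list(if (n_mod) paste0("mod", seq_len(n_mod)),
                                     meta$sample))
  for (m in seq_len(n_mod)) {
    f <- stats::rnorm(n_s)
    f <- (f - mean(f)) / stats::sd(f) * sd_f  # realized sd = sd_f exactly
    if (config$module_directions[m] == "up") f[substrate] <- f[substrate] + lfc
    if (config$module_directions[m] == "down") f[substrate] <- f[substrate] - lfc
    profiles[m, ] <- f
  }

  base <- stats::rnorm(config$n_genes, 4, 1.5)      # log2 relative abundance
  loadings <- stats::setNames(stats::runif(config$n_genes, 0.8, 1.2), genes)
  if (config$anticor_fraction > 0) {
    for (m in seq_len(n_mod)) {
      mg <- which(module_of_gene == paste0("mod", m))
      n_neg <- floor(length(mg) * config$anticor_fraction)
      if (n_neg > 0) loadings[mg[seq_len(n_neg)]] <- -loadings[mg[seq_len(n_neg)]]
    }
  }
  x <- matrix(stats::rnorm(config$n_genes * n_s, 0, sd_e),
              config$n_genes, n_s)
  for (m in seq_len(n_mod)) {
    mg <- module_of_gene == paste0("mod", m)
    x[mg, ] <- x[mg, ] + outer(loadings[mg], profiles[m, ])
  }
  # background genes vary independently at the noise level of module genes
  # (stable non-responsive transcripts; correlation is scale-free, so their
  # pairwise correlations are null regardless of this sd)
  bg <- module_of_gene == "background"
  if (any(bg))
    x[bg, ] <- x[bg, ] + matrix(stats::rnorm(sum(bg) * n_s, 0, sd_e),
                                sum(bg), n_s)
  x <- x + base

  lengths <- stats::setNames(
    round(stats::runif(config$n_genes, config$gene_length_range[1],
                       config$gene_length_range[2])), genes)
  # expected reads scale with expression and gene length
  intensity <- 2^x * (lengths / 1e3)
  if (config$dispersion > 0) {
    shape <- 1 / config$dispersion
    intensity <- intensity *
      matrix(stats::rgamma(length(intensity), shape = shape, rate = shape),
             nrow(intensity))
  }
  libs <- round(stats::runif(n_s, config$library_size_range[1],
                             config$library_size_range[2]))
  counts <- vapply(seq_len(n_s), function(s)
    stats::rmultinom(1, libs[s], intensity[, s])[, 1], numeric(config$n_genes))
  dimnames(counts) <- list(genes, meta$sample)

  sub_groups <- unique(grp[substrate])
  de_status <- matrix("none", config$n_genes, length(sub_groups),
                      dimnames = list(genes, sub_groups))
  for (m in seq_len(n_mod)) {
    dir <- config$module_directions[m]
    if (dir == "none") next
    mg <- module_of_gene == paste0("mod", m)
    pos <- loadings >= 0
    de_status[mg & pos, ] <- dir
    de_status[mg & !pos, ] <- if (dir == "up") "down" else "up"
  }

  truth <- structure(list(module_of_gene = module_of_gene,
                          de_status = de_status,
                          eigenprofiles = profiles, loadings = loadings),
                     class = "truth_bundle")
  list(dataset = count_dataset(counts, lengths, meta), truth = truth)
}

#' Simulate a genome with planted promoter motif instances
#'
#' Lays the given genes out on multi-gene contigs, alternating strands,
#' with a promoter slot of `promoter_length` bp upstream of each start
#' codon and a short coding stub downstream. Promoter sequence is drawn
#' from a 0-order background; for a planted fraction of genes one motif
#' instance (the PWM consensus, or a PWM-sampled word) is written at a
#' recorded offset upstream of the ATG.
#'
#' @param genes character vector of gene ids.
#' @param config a [sim_config()] (`promoter_length`,
#'   `motif_plant_fraction`, `seed`).
#' @param pwm the motif to plant (default the PWM of
#'   [synthetic_xbs_sites()]).
#' @param background 0-order base composition of promoter sequence
#'   (default uniform).
#' @param sample_sites plant PWM-sampled words instead of the consensus
#'   (default FALSE).
#' @param genes_per_contig genes per simulated contig (default 10).
#' @return list with `genome` (`DNAStringSet`), `models` (gene-model
#'   data.frame as in [read_gene_models()]), `planted` (data.frame `gene`,
#'   `offset`, `strand`).
#' @export
simulate_genome <- function(genes, config, pwm = build_pwm(synthetic_xbs_sites()),
                            background = rep(0.25, 4), sample_sites = FALSE,
                            genes_per_contig = 10) {
  stopifnot(inherits(config, "sim_config"))
  w <- pwm$width
  plen <- config$promoter_length
  if (plen < w) stop2("promoter_length (%d) < motif width (%d)", plen, w)
  set.seed(substream_seed(config$seed, "genome"))
  n <- length(genes)
  planted_genes <- genes[stats::runif(n) < config$motif_plant_fraction]
  cds_len <- 300
  gap <- 50
  slot <- plen + cds_len + gap
  contig_of <- ceiling(seq_len(n) / genes_per_contig)
  rand_seq <- function(k) paste(sample(BASES, k, replace = TRUE,
                                       prob = background), collapse = "")
  plant_word <- function() {
    if (!sample_sites) return(pwm$consensus)
    paste(vapply(seq_len(w), function(j)
      sample(BASES, 1, prob = pwm$freq[, j]), character(1)), collapse = "")
  }
  contigs <- character(max(contig_of))
  models <- vector("list", n)
  planted <- list()
  for (ci in seq_len(max(contig_of))) {
    gs <- genes[contig_of == ci]
    parts <- character(0)
    pos <- 0
    for (k in seq_along(gs)) {
      g <- gs[k]
      strand <- if (k %% 2 == 1) "+" else "-"
      promoter <- rand_seq(plen)
      offset <- NA
      if (g %in% planted_genes) {
        offset <- -sample(seq(w, plen), 1)      # offset in [-plen, -w]
        p <- plen + 1 + offset                  # 1-based position in promoter
        substr(promoter, p, p + w - 1) <- plant_word()
        planted[[length(planted) + 1]] <-
          data.frame(gene = g, offset = offset, strand = "+")
      }
      cds <- paste0("ATG", rand_seq(cds_len - 6), "TAA")
      if (strand == "+") {
        seg <- paste0(promoter, cds)
        start <- pos + plen + 1
        end <- pos + plen + cds_len
      } else {
        seg <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(paste0(promoter, cds))))
        start <- pos + 1
        end <- pos + cds_len
      }
      seg <- paste0(seg, rand_seq(gap))
      models[[match(g, genes)]] <-
        data.frame(gene = g, contig = paste0("contig", ci), strand = strand,
                   start = start, end = end)
      parts <- c(parts, seg)
      pos <- pos + slot
    }
    contigs[ci] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- paste0("contig", seq_along(contigs))
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene = character(), offset = integer(), strand = character())
  list(genome = genome, models = do.call(rbind, models), planted = planted)
}

#' Simulate a gene-term annotation table with planted enrichments
#'
#' Terms are assigned to genes independently at term-specific background
#' frequencies, except that each module's designated term is enriched
#' `enrichment_fold`-fold (capped at probability 1) among that module's
#' genes. With `enrichment_fold = 1` the table carries no signal.
#'
#' @param truth a `truth_bundle` from [simulate_expression()].
#' @param n_terms number of terms (default 20).
#' @param enrichment_fold frequency multiplier inside the planted module
#'   (>= 1, default 8).
#' @param seed integer seed.
#' @param freq_range background term frequency interval (default
#'   0.02-0.10).
#' @return list with `table` (data.frame `gene`, `term`) and
#'   `enriched_terms` (module -> term id).
#' @export
simulate_annotations <- function(truth, n_terms = 20, enrichment_fold = 8,
                                 seed = 1, freq_range = c(0.02, 0.10)) {
  if (enrichment_fold < 1) stop2("enrichment_fold must be >= 1")
  set.seed(substream_seed(seed, "annotations"))
  genes <- names(truth$module_of_gene)
  if (n_terms == 0)
    return(list(table = data.frame(gene = character(), term = character()),
                enriched_terms = character(0)))
  terms <- sprintf("T%03d", seq_len(n_terms))
  freqs <- stats::runif(n_terms, freq_range[1], freq_range[2])
  mods <- setdiff(unique(truth$module_of_gene), "background")
  enriched <- stats::setNames(terms[seq_along(mods) %% n_terms + 1], mods)
  rows <- list()
  for (t in seq_len(n_terms)) {
    p <- rep(freqs[t], length(genes))
    hot <- names(enriched)[enriched == terms[t]]
    if (length(hot) > 0)
      p[truth$module_of_gene %in% hot] <-
        pmin(1, freqs[t] * enrichment_fold)
    hit <- stats::runif(length(genes)) < p
    if (any(hit))
      rows[[t]] <- data.frame(gene = genes[hit], term = terms[t])
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), term = character())
  list(table = tab, enriched_terms = enriched)
}

#' Write a simulated genome and annotation
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory; writes `genome.fa` and `genes.gff3`.
#' @return `dir`, invisibly.
#' @export
write_simulated_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$models, file.path(dir, "genes.gff3"))
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (one exon genes) with 1-based
#' inclusive coordinates.
#'
#' @param models data.frame with `gene`, `contig`, `strand`, `start`,
#'   `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    base <- sprintf("%s\tcoexminer\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s",
                    m$contig, m$start, m$end, m$strand)
    writeLines(c(
      sprintf(base, "gene", ".", sprintf("ID=%s", m$gene)),
      sprintf(base, "mRNA", ".", sprintf("ID=%s.t1;Parent=%s", m$gene, m$gene)),
      sprintf(base, "CDS", "0", sprintf("ID=%s.cds;Parent=%s.t1", m$gene, m$gene))
    ), con)
  }
  invisible(path)
}
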