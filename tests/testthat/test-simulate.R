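test_that("expression generator is deterministic and validates its config", {
  cfg <- sim_config(n_genes = 100, module_sizes = c(30, 30), seed = 1)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$dataset$counts, b$dataset$counts)
  expect_identical(a$truth$module_of_gene, b$truth$module_of_gene)
  c2 <- simulate_expression(sim_config(n_genes = 100, module_sizes = c(30, 30),
                                       seed = 2))
  expect_false(identical(a$dataset$counts, c2$dataset$counts))
  expect_error(sim_config(n_genes = 50, module_sizes = c(30, 30)),
               "exceeds")
  expect_error(sim_config(within_module_cor = 0), "within_module_cor")
})

test_that("count marginals and dimensions honour the config", {
  cfg <- sim_config(n_genes = 200, module_sizes = c(50, 50),
                    library_size_range = c(1e6, 2e6), seed = 3)
  sim <- simulate_expression(cfg)
  cs <- colSums(sim$dataset$counts)
  expect_true(all(cs >= 1e6 & cs <= 2e6))
  expect_equal(dim(sim$dataset$counts), c(200, 12))
  expect_true(all(sim$dataset$counts >= 0))
  expect_true(all(sim$dataset$counts == floor(sim$dataset$counts)))
  lens <- sim$dataset$gene_lengths
  expect_true(all(lens >= 500 & lens <= 5000))
})

test_that("noise-free module genes are near-perfectly correlated", {
  # the module must be a minority of the library: per-sample normalisation
  # cancels whatever latent signal is common to the whole transcriptome
  cfg <- sim_config(n_genes = 110, module_sizes = 10,
                    within_module_cor = 0.999999, dispersion = 0,
                    library_size_range = c(5e7, 5e7), seed = 4)
  sim <- simulate_expression(cfg)
  v <- log2(cpm(sim$dataset) + 1)
  mod <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == "mod1"]
  cc <- cor(t(v[mod, ]))
  expect_true(all(cc[upper.tri(cc)] > 0.99))
})

test_that("planted fold change is recovered on the normalised scale", {
  # average over 20 seeds: mean log2 fold change of an up module with
  # de_fold 4 should sit near 2. The responsive module is kept to a modest
  # share of the transcriptome, as in real designs; a single unbalanced
  # module holding ~25% of the library exceeds what trimmed-mean
  # normalisation (ours or edgeR's, which agree) can correct.
  lfcs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 400, module_sizes = 50,
                      module_directions = "up", seed = s)
    sim <- simulate_expression(cfg)
    ex <- rpkm(sim$dataset)
    de <- call_de(ex, "fructose_24h")
    up_genes <- names(sim$truth$module_of_gene)[
      sim$truth$module_of_gene == "mod1"]
    mean(de$log2fc[de$gene %in% up_genes])
  }, numeric(1))
  expect_lt(abs(mean(lfcs) - 2), 0.3)
})

test_that("anti-correlated members flip sign within a signed module", {
  cfg <- sim_config(n_genes = 200, module_sizes = 40, anticor_fraction = 0.25,
                    seed = 8)
  sim <- simulate_expression(cfg)
  v <- log2(cpm(sim$dataset) + 1)
  neg <- names(sim$truth$loadings)[sim$truth$loadings < 0]
  pos <- setdiff(names(sim$truth$module_of_gene)[
    sim$truth$module_of_gene == "mod1"], neg)
  cc <- cor(t(v[c(pos[1], neg[1]), ]))
  expect_lt(cc[1, 2], -0.5)
})

test_that("genome generator plants recoverable motif instances", {
  pwm <- build_pwm(synthetic_xbs_sites())
  cfg <- sim_config(n_genes = 40, module_sizes = integer(0),
                    motif_plant_fraction = 0.5, seed = 5)
  genes <- sprintf("g%03d", 1:40)
  g <- simulate_genome(genes, cfg, pwm = pwm)
  expect_identical(g$models$gene, genes)
  expect_true(all(c("+", "-") %in% g$models$strand))
  expect_true(all(g$planted$offset <= -pwm$width &
                    g$planted$offset >= -1500))
  # determinism
  g2 <- simulate_genome(genes, cfg, pwm = pwm)
  expect_identical(as.character(g$genome), as.character(g2$genome))

  pr <- extract_promoters(g$genome, g$models)
  expect_true(all(pr$info$length == 1500))
  # every planted instance is found at its recorded offset
  hits <- scan_promoters(pwm, pr, background = "pwm")
  found <- mapply(function(gg, oo)
    any(hits$gene == gg & hits$offset == oo & hits$strand == "+"),
    g$planted$gene, g$planted$offset)
  expect_true(all(found))
  # promoter width below motif width is a configuration error
  cfg_bad <- sim_config(n_genes = 5, module_sizes = integer(0),
                        promoter_length = 6, seed = 1)
  expect_error(simulate_genome(letters[1:5], cfg_bad, pwm = pwm),
               "promoter_length")
})

test_that("genome round-trips through FASTA and GFF3", {
  cfg <- sim_config(n_genes = 12, module_sizes = integer(0), seed = 6)
  genes <- sprintf("g%02d", 1:12)
  g <- simulate_genome(genes, cfg)
  dir <- withr::local_tempdir()
  write_simulated_genome(g, dir)
  models <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(models[order(models$gene), c("gene", "contig", "strand",
                                            "start", "end")],
               g$models[order(g$models$gene), ], ignore_attr = TRUE)
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  pr1 <- extract_promoters(genome, models)
  pr2 <- extract_promoters(g$genome, g$models)
  expect_equal(as.character(pr1$seq)[order(names(pr1$seq))],
               as.character(pr2$seq)[order(names(pr2$seq))])
})

test_that("annotation generator plants term enrichment at the stated fold", {
  cfg <- sim_config(n_genes = 600, module_sizes = rep(100, 3), seed = 7)
  sim <- simulate_expression(cfg)
  ann <- simulate_annotations(sim$truth, n_terms = 15, enrichment_fold = 8,
                              seed = 7)
  expect_equal(length(ann$enriched_terms), 3)
  bg <- names(sim$truth$module_of_gene)
  as_ <- annotation_set(ann$table, bg)
  for (m in names(ann$enriched_terms)) {
    genes <- bg[sim$truth$module_of_gene == m]
    res <- enrich(genes, as_)
    expect_equal(res$term[1], ann$enriched_terms[[m]])
  }
  # n_terms = 0: empty table, enrichment returns empty without error
  ann0 <- simulate_annotations(sim$truth, n_terms = 0, seed = 1)
  expect_equal(nrow(ann0$table), 0)
  as0 <- annotation_set(ann0$table, bg)
  expect_equal(nrow(enrich(bg[1:50], as0)), 0)
})

test_that("sim_config round-trips through YAML", {
  cfg <- sim_config(n_genes = 77, module_sizes = c(30, 40), seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back, cfg)
})
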