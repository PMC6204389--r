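test_that("correlation matrix handles duplicates, negation and flat genes", {
  x <- c(1, 2, 3, 4)
  vals <- rbind(a = x, b = x, c = -x, d = c(1, 2, 3, 5), flat = rep(2, 4))
  colnames(vals) <- paste0("s", 1:4)
  expect_warning(cc <- correlation_matrix(vals), "zero-variance")
  expect_equal(cc["a", "b"], 1.0)
  expect_equal(cc["a", "c"], -1.0)
  # closed-form Pearson for x=[1,2,3,4], y=[1,2,3,5]
  r <- sum((x - mean(x)) * (c(1, 2, 3, 5) - 2.75)) /
    sqrt(sum((x - mean(x))^2) * sum((c(1, 2, 3, 5) - 2.75)^2))
  expect_equal(cc["a", "d"], r, tolerance = 1e-12)
  expect_equal(unname(cc["flat", c("a", "b", "c", "d")]), rep(0, 4))
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_error(correlation_matrix(vals[, 1:2]), "3 samples")
})

test_that("signed adjacency maps correlation to [0,1] as (0.5(1+cor))^beta", {
  expect_equal(signed_adjacency(1, 26), 1)
  expect_equal(signed_adjacency(-1, 26), 0)
  expect_equal(signed_adjacency(0, 2), 0.25)
  expect_equal(signed_adjacency(0.8, 26), 0.9^26, tolerance = 1e-15)
  # monotone increasing in cor for fixed beta
  cors <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(signed_adjacency(cors, 7)) > 0))
  expect_error(signed_adjacency(0.5, 0), "beta")
  expect_error(signed_adjacency(1.5, 2), "outside")
})

test_that("TOM matches the brute-force triple loop on random matrices", {
  # hand example: 3 nodes all pairwise adjacency 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  t3 <- tom_matrix(a3)
  expect_equal(t3[1, 2], 0.5, tolerance = 1e-15)

  set.seed(11)
  for (i in 1:5) {
    r <- matrix(runif(100), 10, 10)
    adj <- (r + t(r)) / 2
    diag(adj) <- 1
    dimnames(adj) <- list(paste0("g", 1:10), paste0("g", 1:10))
    expect_equal(unname(tom_matrix(adj)), unname(tom_brute(adj)),
                 tolerance = 1e-12)
  }

  # perfect overlap and isolated pair
  a <- matrix(1, 4, 4)
  expect_equal(tom_matrix(a)[1, 2], 1)
  iso <- diag(2)
  expect_equal(tom_matrix(iso)[1, 2], 0)
  expect_error(tom_matrix(matrix(2, 2, 2)), "outside")
})

test_that("soft threshold selection fits scale-free topology", {
  # the log-log fit machinery recognises power-law connectivity
  set.seed(3)
  k <- round(1000 * (1:400)^-1.6 * runif(400, 0.8, 1.2)) + 1
  expect_gte(scale_free_fit(k), 0.9)
  expect_error(scale_free_fit(rep(5, 100)), "identical")

  # mean connectivity is non-increasing in beta; chosen beta honours target
  sim <- simulate_expression(sim_config(n_genes = 150, module_sizes = c(50, 50),
                                        seed = 2))
  v <- log2(rpkm(sim$dataset)$values + 1)
  fit <- suppressWarnings(pick_soft_threshold(v, betas = c(1, 2, 4, 8, 16)))
  expect_true(all(diff(fit$fit$mean_connectivity) < 0))
  if (fit$reached_target)
    expect_equal(fit$chosen_beta,
                 min(fit$fit$beta[fit$fit$signed_r2 >= 0.85]))

  # identical expression for all genes degenerates
  flat <- matrix(rep(c(1, 5, 2, 8), each = 20), 20, 4)
  rownames(flat) <- paste0("g", 1:20); colnames(flat) <- paste0("s", 1:4)
  expect_error(suppressWarnings(pick_soft_threshold(flat)), "degenerate|identical")
})

test_that("static cut keeps blocks of >= min_size and greys the rest", {
  block_tom <- function(sizes, within = 0.8, between = 0.01) {
    n <- sum(sizes)
    tom <- matrix(between, n, n)
    at <- 0
    for (s in sizes) { tom[at + 1:s, at + 1:s] <- within; at <- at + s }
    diag(tom) <- 1
    dimnames(tom) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom
  }
  p <- cluster_and_cut(block_tom(c(40, 35)), min_size = 30, cut_height = 0.5)
  expect_equal(length(p$module_sizes), 2)
  expect_equal(sort(as.integer(p$module_sizes)), c(35, 40))

  p2 <- cluster_and_cut(block_tom(c(40, 10)), min_size = 30, cut_height = 0.5)
  expect_equal(length(p2$module_sizes), 1)
  expect_equal(sum(p2$module_of_gene == "grey"), 10)

  # identity-like TOM: no structure, no modules
  p3 <- cluster_and_cut(block_tom(rep(1, 40), within = 1, between = 0.01),
                        min_size = 30, cut_height = 0.5)
  expect_equal(length(p3$module_sizes), 0)

  expect_error(cluster_and_cut(block_tom(c(40, 35)), cut_height = 1.5),
               "cut_height")
})

test_that("module eigengene is the oriented first principal component", {
  prof <- c(1, 5, 2, 8, 3, 9)
  vals <- t(vapply(1:6, function(i) i * prof + i, numeric(6)))
  rownames(vals) <- paste0("g", 1:6); colnames(vals) <- paste0("s", 1:6)
  eg <- module_eigengene(vals, rownames(vals))
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengene, prof)), 1, tolerance = 1e-12)
  # orientation: positive mean gene-eigengene correlation
  expect_gt(mean(cor(t(vals), eg$eigengene)), 0)
  # flipping all genes flips the eigengene
  eg2 <- module_eigengene(-vals, rownames(vals))
  expect_equal(eg2$eigengene, -eg$eigengene, tolerance = 1e-9)
  expect_gt(mean(cor(t(-vals), eg2$eigengene)), 0)
  expect_error(module_eigengene(vals[, 1, drop = FALSE], rownames(vals)),
               "2 samples")

  # recovers a planted latent profile at low noise
  sim <- simulate_expression(sim_config(n_genes = 80, module_sizes = 40,
                                        dispersion = 0.01, seed = 5))
  v <- log2(rpkm(sim$dataset)$values + 1)
  genes <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene == "mod1"]
  eg3 <- module_eigengene(v, genes)
  expect_gte(abs(cor(eg3$eigengene, sim$truth$eigenprofiles["mod1", ])), 0.95)
})

test_that("modules merge below eigengene dissimilarity 0.15, strictly", {
  run_merge <- function(rho) {
    vals <- two_module_expr(rho)
    lab <- stats::setNames(rep(c("A", "B"), each = 5), rownames(vals))
    p <- structure(list(module_of_gene = lab,
                        module_sizes = table(lab), hclust = NULL,
                        cut_height = NA, min_size = 1),
                   class = "module_partition")
    merge_modules(vals, p, merge_threshold = 0.15)
  }
  expect_equal(length(run_merge(0.90)$module_sizes), 1)  # diss 0.10 < 0.15
  expect_equal(length(run_merge(0.80)$module_sizes), 2)  # diss 0.20
  expect_equal(length(run_merge(0.85)$module_sizes), 2)  # boundary: strict
  # merged module keeps the larger constituent's label
  vals <- two_module_expr(0.95)
  lab <- stats::setNames(c(rep("A", 6), rep("B", 4)), rownames(vals))
  p <- structure(list(module_of_gene = lab, module_sizes = table(lab),
                      hclust = NULL, cut_height = NA, min_size = 1),
                 class = "module_partition")
  m <- merge_modules(vals, p, merge_threshold = 0.15)
  expect_equal(unique(unname(m$module_of_gene)), "A")
})

test_that("edge export is strict, absolute and within-module", {
  cc <- diag(4)
  dimnames(cc) <- list(paste0("g", 1:4), paste0("g", 1:4))
  cc["g1", "g2"] <- cc["g2", "g1"] <- 0.8       # exactly at the cutoff
  cc["g1", "g3"] <- cc["g3", "g1"] <- -0.85     # absolute value counts
  cc["g2", "g4"] <- cc["g4", "g2"] <- 0.95      # crosses modules
  labels <- c(g1 = "M1", g2 = "M1", g3 = "M1", g4 = "M2")
  ed <- export_edges(cc, labels, cor_cutoff = 0.8, beta = 26)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$gene_a, ed$gene_b), c("g1", "g3"))
  expect_equal(ed$cor, -0.85)
  expect_equal(ed$adj, signed_adjacency(-0.85, 26))
  expect_equal(ed$module, "M1")
})

test_that("kME refinement prunes weak members and reclaims core genes", {
  sim <- simulate_expression(sim_config(n_genes = 300,
                                        module_sizes = c(60, 60), seed = 6))
  v <- log2(rpkm(sim$dataset)$values + 1)
  truth <- sim$truth$module_of_gene
  # corrupt the true partition: drop 10 core genes, absorb 15 background
  lab <- ifelse(truth == "background", "grey", truth)
  names(lab) <- names(truth)
  core1 <- names(lab)[lab == "mod1"]
  lab[core1[1:10]] <- "grey"
  bg <- names(lab)[lab == "grey"][1:15]
  lab[bg] <- "mod2"
  ref <- refine_membership(v, lab, kme_threshold = 0.7, min_size = 30)
  expect_gt(ari(ref, truth), ari(lab, truth))
  expect_true(all(ref[core1[1:10]] == "mod1"))
})

test_that("the full network fit is deterministic and self-consistent", {
  sim <- simulate_expression(sim_config(n_genes = 250,
                                        module_sizes = c(60, 60), seed = 4))
  v <- log2(rpkm(sim$dataset)$values + 1)
  f1 <- suppressWarnings(coexpression_network(v, betas = c(4, 8, 12)))
  f2 <- suppressWarnings(coexpression_network(v, betas = c(4, 8, 12)))
  expect_identical(module_labels(f1), module_labels(f2))
  expect_identical(f1$edges, f2$edges)
  # invariants: symmetric matrices in range; adjacency at cor 0 is 0.5^beta
  expect_true(all(f1$tom >= 0 & f1$tom <= 1))
  expect_lt(max(abs(f1$cor - t(f1$cor))), 1e-10)
  expect_equal(signed_adjacency(0, f1$beta), 0.5^f1$beta)
  # every exported edge joins two genes of its own module
  lab <- module_labels(f1)
  if (nrow(f1$edges) > 0) {
    expect_true(all(lab[f1$edges$gene_a] == f1$edges$module))
    expect_true(all(lab[f1$edges$gene_b] == f1$edges$module))
    expect_true(all(abs(f1$edges$cor) > 0.8))
  }
  s <- summary(f1)
  expect_s3_class(s, "summary.coexnet")
  expect_equal(sum(s$modules$genes) + s$n_background, nrow(v))
})
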