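test_that("spatial Spearman is monotone-invariant and matches brute force", {
  g <- tiny_grid()
  sig <- smooth_field(g, 10, seed = 1)
  expect_equal(spatial_spearman(sig, exp(sig))$rho, 1)
  expect_equal(spatial_spearman(sig, -sig)$rho, -1)

  # 12-voxel toy with ties against the brute-force oracle
  x <- c(1, 2, 2, 3, 5, 5, 5, 7, 8, 9, 9, 10)
  y <- c(2, 1, 4, 4, 4, 6, 5, 8, 8, 7, 10, 10)
  expect_equal(spatial_spearman(x, y, min_voxels = 5)$rho,
               spearman_bruteforce(x, y), tolerance = 1e-14)

  # oracle agreement on larger instances with ties
  set.seed(2)
  for (r in 1:5) {
    a <- sample(1:50, 1000, replace = TRUE)
    b <- a + sample(1:30, 1000, replace = TRUE)
    expect_equal(spatial_spearman(a, b, min_voxels = 5)$rho,
                 spearman_bruteforce(a, b), tolerance = 1e-12)
  }

  small <- spatial_spearman(sig[1:5], sig[1:5])
  expect_true(small$skipped)
  expect_true(is.na(small$rho))
})

test_that("z-approximated permutation p-values have their closed forms", {
  null <- rnorm(500, mean = 0.02, sd = 0.1)
  at_mean <- permutation_pvalues(mean(null), null)
  expect_equal(at_mean$z, 0)
  expect_equal(at_mean$p, 1)
  at_crit <- permutation_pvalues(mean(null) + 1.959964 * sd(null), null)
  expect_equal(at_crit$p, 0.05, tolerance = 1e-6)
  expect_warning(res <- permutation_pvalues(0.5, rep(0.1, 200)),
                 "zero spread")
  expect_true(is.na(res$p))
})

test_that("BH and Bonferroni adjustments match hand computations", {
  # BH step-up: p_(i) * m / i = 0.04 for every i
  bh <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH")
  expect_equal(bh$p_adj, rep(0.04, 4))
  # Bonferroni is plain multiplication, capped at 1
  bf <- adjust_pvalues(rep(1e-4, 336), "bonferroni")
  expect_equal(bf$p_adj[1], 0.0336)
  # single p returns unchanged under both methods
  expect_equal(adjust_pvalues(0.2, "BH")$p_adj, 0.2)
  expect_equal(adjust_pvalues(0.2, "bonferroni")$p_adj, 0.2)
  expect_equal(nrow(adjust_pvalues(numeric(0), "BH")), 0)

  # BH adjusted values are monotone in the raw p-values
  set.seed(3)
  p <- sort(runif(50))
  adj <- adjust_pvalues(p, "BH")$p_adj
  expect_true(all(diff(adj) >= -1e-15))
  # BH rejections contain the Bonferroni rejections at equal alpha
  rej_bh <- adjust_pvalues(p, "BH", 0.05)$significant
  rej_bf <- adjust_pvalues(p, "bonferroni", 0.05)$significant
  expect_true(all(rej_bh[rej_bf]))
})

test_that("similarity tables carry coherent inference columns", {
  g <- tiny_grid()
  sig <- smooth_field(g, 12, seed = 4)
  genes <- lapply(1:6, function(i) {
    make_gene_map(g, sprintf("G%d", i), 10,
                  target_map = if (i == 1) sig else NULL,
                  planted_rho = if (i == 1) 0.9 else 0, seed = 40 + i)
  })
  names(genes) <- vapply(genes, `[[`, "", "gene_symbol")
  surr <- generate_surrogates(sig, g, n = 120, seed = 5,
                              knn_grid = c(5, 20, 60))
  tb <- similarity_table(sig, genes, surr)
  expect_equal(nrow(tb), 6)
  expect_true(all(abs(tb$rho) <= 1))
  expect_true(all(tb$p > 0 & tb$p <= 1))
  expect_true(all(tb$p <= tb$p_bonf + 1e-15))
  # the planted gene is the strongest and detected
  expect_equal(which.max(tb$rho), 1)
  expect_lt(tb$p[1], 0.05)
  # z/p consistency with the cross-checked direct computation
  direct <- permutation_pvalues(
    tb$rho[2],
    apply(surr$values, 1, cor, y = genes[[2]]$values,
          method = "spearman"))
  expect_equal(tb$z[2], direct$z, tolerance = 1e-10)
  expect_equal(tb$null_mean[2], direct$null_mean, tolerance = 1e-10)
})

test_that("regional similarity restricts surrogates to region voxels", {
  g <- tiny_grid()
  sig <- smooth_field(g, 12, seed = 6)
  genes <- list(G1 = make_gene_map(g, "G1", 10, seed = 7))
  surr <- generate_surrogates(sig, g, n = 60, seed = 8, knn_grid = c(5, 20))
  parc <- make_parcellation(g, 6, seed = 9)
  tb <- similarity_table(sig, genes, surr, parcellation = parc,
                         min_voxels = 10)
  expect_equal(nrow(tb), 6)
  expect_true(all(startsWith(tb$scope, "region:")))
  rid <- parc$region_ids[1]
  idx <- which(parc$labels == rid)
  manual <- cor(sig[idx], genes$G1$values[idx], method = "spearman")
  expect_equal(tb$rho[tb$scope == paste0("region:", rid)], manual,
               tolerance = 1e-12)
  expect_equal(tb$n_voxels[1], length(which(parc$labels ==
                                              parc$region_ids[1])))
})
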