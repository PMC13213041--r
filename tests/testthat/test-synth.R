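test_that("component basis generation is deterministic and well formed", {
  g <- tiny_grid()
  b1 <- make_ic_basis(25, g, smoothness_mm = 8, seed = 5)
  b2 <- make_ic_basis(25, g, smoothness_mm = 8, seed = 5)
  expect_identical(b1$maps, b2$maps)
  expect_equal(ncol(b1$maps), 25)
  expect_true(all(is.finite(b1$maps)))
  b3 <- make_ic_basis(25, g, smoothness_mm = 8, seed = 6)
  expect_false(identical(b1$maps, b3$maps))
  expect_error(make_ic_basis(1, g), ">= 2")
  expect_error(make_ic_basis(4, g, smoothness_mm = 0), "> 0")
})

test_that("smoothness controls the variogram of generated fields", {
  g <- sphere_grid(c(16, 16, 16))
  rough <- make_ic_basis(2, g, smoothness_mm = 0.5, seed = 3,
                         envelope_fwhm_mm = Inf)
  smooth <- make_ic_basis(2, g, smoothness_mm = 14, seed = 3,
                          envelope_fwhm_mm = Inf)
  vg_r <- suppressWarnings(
    empirical_variogram(rough$maps[, 1], g, subsample = 300, seed = 1))
  vg_s <- suppressWarnings(
    empirical_variogram(smooth$maps[, 1], g, subsample = 300, seed = 1))
  # sub-voxel kernel: variogram flat (no spatial structure)
  expect_gt(vg_r$gamma[1] / vg_r$gamma[nrow(vg_r)], 0.75)
  expect_lt(vg_r$gamma[1] / vg_r$gamma[nrow(vg_r)], 1.3)
  # wide kernel: strong short-range structure
  expect_lt(vg_s$gamma[1] / vg_s$gamma[nrow(vg_s)], 0.3)
})

test_that("cohort simulation plants FC differences where requested", {
  k <- 4
  # null case: identical covariances -> between-group FC difference ~ 0
  covs <- list(groupA = group_covariance(k, 0.2),
               groupB = group_covariance(k, 0.2))
  ch <- simulate_cohort(k, covs, c(60, 60), n_timepoints = 200,
                        noise_sd = 0, seed = 7)
  fc12 <- vapply(ch$timeseries, function(ts) cor(ts[, 1], ts[, 2]),
                 numeric(1))
  dA <- mean(fc12[ch$subjects$label == "groupA"])
  dB <- mean(fc12[ch$subjects$label == "groupB"])
  expect_lt(abs(dA - dB), 0.05)

  # planted r = 0.6 vs 0.2 -> estimated FC difference ~ 0.4
  cohort <- planted_cohort(k = k, n = c(120, 120), t_len = 400,
                           seed = 8)
  # noise_sd = 0.3 attenuates correlations; compare on the noiseless scale
  ch2 <- simulate_cohort(k, list(
    groupA = group_covariance(k, 0.2),
    groupB = group_covariance(k, 0.2, data.frame(i = 1, j = 2, r = 0.6))),
    c(120, 120), n_timepoints = 400, noise_sd = 0, seed = 8)
  fc12 <- vapply(ch2$timeseries, function(ts) cor(ts[, 1], ts[, 2]),
                 numeric(1))
  delta <- mean(fc12[ch2$subjects$label == "groupB"]) -
    mean(fc12[ch2$subjects$label == "groupA"])
  expect_equal(delta, 0.4, tolerance = 0.05)
})

test_that("cohort bookkeeping matches the requested design", {
  k <- 3
  covs <- list(TEHC = group_covariance(k), PTSDnoCI = group_covariance(k),
               PTSDCI = group_covariance(k))
  ch <- simulate_cohort(k, covs, c(30, 19, 22), n_timepoints = 40, seed = 1)
  expect_equal(nrow(ch$subjects), 71)
  expect_equal(as.vector(table(ch$subjects$label)[c("TEHC", "PTSDnoCI",
                                                    "PTSDCI")]),
               c(30, 19, 22))
  bad <- list(A = matrix(c(1, 2, 2, 1), 2), B = diag(2))
  expect_error(simulate_cohort(2, bad, c(3, 3), n_timepoints = 30),
               "group 'A'")
  expect_error(simulate_cohort(5, list(A = diag(5)), 3, n_timepoints = 4),
               "K \\+ 2")
})

test_that("gene maps honour planted correlations and determinism", {
  g <- tiny_grid()
  target <- smooth_field(g, 10, seed = 2)
  exact <- make_gene_map(g, "T1", 10, target_map = target, planted_rho = 1,
                         seed = 3)
  expect_equal(suppressWarnings(cor(exact$values, target,
                                    method = "spearman")), 1)
  m1 <- make_gene_map(g, "G", 10, seed = 9)
  m2 <- make_gene_map(g, "G", 10, seed = 9)
  expect_identical(m1$values, m2$values)

  # planted_rho = 0: Spearman vs target centred at zero over many seeds
  rhos <- vapply(1:120, function(s) {
    m <- make_gene_map(g, "G", 10, target_map = target, planted_rho = 0,
                       seed = 100 + s)
    cor(m$values, target, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))

  g2 <- sphere_grid(c(10, 10, 10))
  expect_error(make_gene_map(g2, "G", 10, target_map = target,
                             planted_rho = 0.5), "grid")
})

test_that("planted rho is achieved on average at intermediate values", {
  g <- tiny_grid()
  target <- smooth_field(g, 10, seed = 4)
  r <- vapply(1:60, function(s) {
    m <- make_gene_map(g, "G", 10, target_map = target, planted_rho = 0.5,
                       seed = 500 + s)
    cor(m$values, target)   # Pearson: the mixing construction's scale
  }, numeric(1))
  expect_equal(mean(r), 0.5, tolerance = 0.05)
})

test_that("parcellation partitions the mask into contiguous regions", {
  g <- tiny_grid()
  V <- sum(g$mask)
  p1 <- make_parcellation(g, 1, seed = 1)
  expect_equal(unique(p1$labels), 1L)

  p <- make_parcellation(g, 12, seed = 2)
  expect_equal(length(p$labels), V)           # union of regions = mask
  expect_equal(sort(unique(p$labels)), 1:12)  # all regions nonempty
  expect_equal(sum(table(p$labels)), V)       # disjoint by construction

  big <- sphere_grid(c(20, 20, 20))
  p90 <- make_parcellation(big, 90, seed = 3)
  expect_equal(length(p90$region_ids), 90)
  expect_error(make_parcellation(g, V + 1), "between 1 and")
})

test_that("path-data generator matches its analytic covariance", {
  m <- path_model(c("X -> Y", "Y -> Z"))
  # all coefficients zero -> diagonal population covariance
  S0 <- simulate_path_data(m, c("X -> Y" = 0, "Y -> Z" = 0), 1,
                           population = TRUE)
  expect_equal(S0, diag(3), ignore_attr = TRUE)

  # chain: population cov(X, Z) = a * b
  S <- simulate_path_data(m, c("X -> Y" = 0.5, "Y -> Z" = -0.3), 1,
                          population = TRUE)
  expect_equal(S["X", "Z"], 0.5 * -0.3)
  expect_equal(S["X", "Y"], 0.5)
  expect_equal(S["Y", "Y"], 1 + 0.5^2)

  # sample covariances within 3 Monte-Carlo SEs of the closed form
  n <- 1e5
  dat <- simulate_path_data(m, c("X -> Y" = 0.5, "Y -> Z" = -0.3), 1,
                            n_obs = n, seed = 12)
  Shat <- cov(dat)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((S[i, i] * S[j, j] + S[i, j]^2) / (n - 1))
    expect_lt(abs(Shat[i, j] - S[i, j]), 3 * se)
  }
  expect_error(simulate_path_data(m, c("X -> Y" = 0.5), 1),
               "missing coefficient")
  expect_error(simulate_path_data(m, c("X -> Y" = 1, "Y -> Z" = 1), -1),
               "> 0")
})

test_that("path model specification rejects cycles and malformed input", {
  expect_error(path_model(c("A -> B", "B -> A")), "cyclic")
  expect_error(path_model("A - B"), "malformed")
  expect_error(path_model(c("A -> B", "A -> B")), "duplicate")
  m <- path_model(c("A -> B", "B -> C", "A -> C"))
  expect_equal(m$exogenous, "A")
  expect_equal(m$order[1], "A")
})
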