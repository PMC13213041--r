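# Shared tiny fixtures, built in code at test time.

tiny_grid <- function(shape = c(12, 12, 12)) sphere_grid(shape)

tiny_basis <- function(k = 4, grid = tiny_grid(), seed = 11) {
  make_ic_basis(k, grid, smoothness_mm = 8, seed = seed)
}

# two-group cohort with one planted FC difference on edge (1,2)
planted_cohort <- function(k = 4, n = c(10, 10), t_len = 120,
                           r_low = 0.2, r_high = 0.6, seed = 21) {
  covA <- group_covariance(k, base_r = r_low)
  covB <- group_covariance(k, base_r = r_low,
                           edges = data.frame(i = 1, j = 2, r = r_high))
  simulate_cohort(k, list(groupA = covA, groupB = covB), n,
                  n_timepoints = t_len, noise_sd = 0.3, seed = seed)
}

# brute-force Spearman oracle: average ranks then Pearson, no shortcuts
spearman_bruteforce <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# smoothed random field on a grid, as a plain in-mask vector
smooth_field <- function(grid, fwhm_mm = 10, seed = 1) {
  make_gene_map(grid, "FIELD", correlation_length_mm = fwhm_mm,
                seed = seed)$values
}
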