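# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or closed form, never by calling the code under test.

# Exact one-sided signed-rank p by full enumeration of all 2^n sign patterns.
brute_force_signrank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  switch(alternative,
    greater = mean(w_all >= w_obs),
    less = mean(w_all <= w_obs),
    two.sided = min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
  )
}

# Closed-form simple-regression OLS.
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  list(a = a, b = b, s = sqrt(sum(res^2) / (n - 2)))
}

# Tiny uniform volume on a stated grid.
make_volume <- function(value, dim = c(8, 8, 8), spacing = c(4, 4, 4), unit = "suv") {
  voxel_volume(array(value, dim = dim), spacing = spacing, unit = unit)
}

# voi_mask over every voxel of a volume (used as an isocontour search region).
full_region <- function(vol) {
  d <- dim(vol$data)
  idx <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  suvshift:::new_voi_mask(idx, d, vol$spacing, "manual")
}

# Single-patient truth for phantom tests, constants chosen freely.
phantom_patient <- function(lesions = NULL) {
  list(
    aorta = list(suv_ac = 2.21, suv_factor = 1.0878, mu_ac = 0.0992, mu_factor = 1.0998),
    liver = list(suv_ac = 2.87, suv_factor = 1.0786, mu_ac = 0.0998, mu_factor = 1.0461),
    muscle = list(suv_ac = 0.70, suv_factor = 1.004, mu_ac = 0.0981, mu_factor = 1.0071),
    vertebra_L5 = list(suv_ac = 1.80, suv_factor = 1.020, mu_ac = 0.1215, mu_factor = 1.0403),
    lesions = lesions
  )
}
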