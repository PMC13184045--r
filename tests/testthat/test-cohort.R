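test_that("generator config validates cohort counts and quartile ordering", {
  cfg <- generator_config()
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n_patients, 21L)
  expect_equal(cfg$total_lesions, 66L)
  expect_error(generator_config(n_with_lesions = 22), "exceed")
  expect_error(generator_config(total_lesions = 5), "invalid cohort counts")
})

test_that("generate_cohort is deterministic and honours the configured counts", {
  cfg <- generator_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)

  expect_equal(nrow(a$patients), 21L)
  expect_equal(sum(a$patients$has_lesions), 18L)
  expect_equal(nrow(a$truth$lesions), 66L)
  expect_true(all(table(a$truth$lesions$patient_id) >= 1))
  expect_equal(length(unique(a$truth$lesions$patient_id)), 18L)
  # measurement table: 21 patients x 4 organs x 2 recons + 66 lesions x 2
  expect_equal(nrow(a$measurements), 21 * 4 * 2 + 66 * 2)
  expect_true(all(a$measurements$suv_max >= a$measurements$suv_mean))
  expect_true(all(a$patients$weight > 0))
  expect_equal(a$patients$injected_activity, 3 * a$patients$weight)

  # a different seed changes the draw
  expect_false(identical(generate_cohort(generator_config(seed = 124))$measurements,
                         a$measurements))
})

test_that("every emitted measurement is derivable from the cohort truth", {
  co <- generate_cohort(generator_config(seed = 77))
  m <- co$measurements
  org <- co$truth$organs
  for (r in sample(which(m$unit_type != "lesion"), 20)) {
    row <- m[r, ]
    t <- org[org$patient_id == row$patient_id & org$organ == row$unit_type, ]
    f <- if (row$recon == "AC") 1 else t$suv_factor
    expect_equal(row$suv_max, t$suv_ac * f)
    fmu <- if (row$recon == "AC") 1 else t$mu_factor
    expect_equal(row$mu_mean, t$mu_ac * fmu)
  }
  les <- co$truth$lesions
  lm <- m[m$unit_type == "lesion", ]
  wide <- merge(lm[lm$recon == "AC", c("unit_id", "suv_max")],
                lm[lm$recon == "CE", c("unit_id", "suv_max")],
                by = "unit_id", suffixes = c("_ac", "_ce"))
  expect_equal(wide$suv_max_ce / wide$suv_max_ac,
               les$suv_factor[match(wide$unit_id, les$lesion_id)])
})

test_that("sample_bias_factor: degenerate dispersion, median recovery, truncation", {
  cfg0 <- generator_config(suv_factor_sigma = c(aorta = 0, liver = 0, muscle = 0,
                                                vertebra_L5 = 0))
  expect_equal(sample_bias_factor("aorta", cfg0, 5), rep(1.0878, 5))

  cfg <- generator_config()
  set.seed(99)
  draws <- sample_bias_factor("aorta", cfg, 1e5)
  expect_lt(abs(median(draws) - 1.0878), 0.002)
  expect_true(all(draws > 0))

  set.seed(100)
  mu_draws <- sample_bias_factor("mu_aorta", cfg, 1e5)
  expect_lt(abs(median(mu_draws) - 1.1040), 0.002)

  set.seed(101)
  r_draws <- sample_bias_factor("suvr_ratio", cfg, 1e5)
  expect_lt(abs(median(r_draws) - 0.9510), 0.002)

  trunc_cfg <- generator_config(truncate_positive = TRUE)
  set.seed(102)
  t_draws <- sample_bias_factor("aorta", trunc_cfg, 1e5)
  expect_gt(min(t_draws), 1)

  expect_error(sample_bias_factor("spleen", cfg), "unknown tissue")
  expect_error(sample_bias_factor("mu_spleen", cfg), "unknown tissue")
})

test_that("truncate_positive makes every CE value strictly exceed its AC pair", {
  co <- generate_cohort(generator_config(truncate_positive = TRUE, seed = 5))
  m <- co$measurements
  for (col in c("suv_max", "mu_mean")) {
    wide <- merge(m[m$recon == "AC", c("unit_id", col)],
                  m[m$recon == "CE", c("unit_id", col)],
                  by = "unit_id", suffixes = c("_ac", "_ce"))
    wide <- wide[!is.na(wide[[paste0(col, "_ac")]]), ]
    expect_true(all(wide[[paste0(col, "_ce")]] > wide[[paste0(col, "_ac")]]),
                info = col)
  }
})

test_that("generate_phantom builds piecewise-constant volumes that recover truth", {
  lesions <- data.frame(suv_ac = c(5.68, 8.0), suv_factor = c(1.05, 1.06),
                        volume_ccm = c(6, 10))
  ph <- generate_phantom(phantom_patient(lesions))

  labels <- suvshift:::PHANTOM_LABELS
  # noise off: organ voxels are exactly the truth constants
  aorta_vox <- ph$suv_ac$data[ph$organ_mask$data == labels[["aorta"]]]
  expect_true(all(aorta_vox == 2.21))
  expect_true(all(ph$suv_ce$data[ph$organ_mask$data == labels[["aorta"]]]
                  == 2.21 * 1.0878))

  # organ_mean_mu recovers the truth attenuation values on both maps
  for (org in c("aorta", "liver", "muscle", "vertebra_L5")) {
    tv <- phantom_patient()[[org]]
    m_ac <- organ_mean_mu(ph$mu_ac, ph$organ_mask, labels[[org]], organ = org)
    m_ce <- organ_mean_mu(ph$mu_ce, ph$organ_mask, labels[[org]], organ = org)
    expect_equal(m_ac$mean_mu, tv$mu_ac, tolerance = 1e-12)
    expect_equal(m_ce$mean_mu, tv$mu_ac * tv$mu_factor, tolerance = 1e-12)
  }

  # lesion SUVmax recovered through the VOI machinery (round-trip)
  les_mask <- suvshift:::new_voi_mask(which(ph$lesion_mask$data == 1L, arr.ind = TRUE),
                                      dim(ph$suv_ac$data), ph$suv_ac$spacing, "manual")
  st <- voi_stats(ph$suv_ac, les_mask)
  expect_equal(st$suv_max, 5.68)
  expect_equal(st$suv_mean, 5.68) # piecewise constant

  # degenerate geometry errors
  tiny <- data.frame(suv_ac = 5, suv_factor = 1.05, volume_ccm = 0.03) # r < 4 mm
  expect_error(generate_phantom(phantom_patient(tiny)), "radius smaller")
  overlap_spec <- phantom_spec(lesion_centers = rbind(c(76, 92, 140))) # inside liver
  one <- data.frame(suv_ac = 5, suv_factor = 1.05, volume_ccm = 6)
  expect_error(generate_phantom(phantom_patient(one), overlap_spec), "overlap")
})

test_that("phantom noise is seeded and optional", {
  one <- data.frame(suv_ac = 5, suv_factor = 1.05, volume_ccm = 6)
  spec <- phantom_spec(noise_sd = 0.1)
  a <- generate_phantom(phantom_patient(one), spec, seed = 42)
  b <- generate_phantom(phantom_patient(one), spec, seed = 42)
  expect_identical(a$suv_ac$data, b$suv_ac$data)
  c2 <- generate_phantom(phantom_patient(one), spec, seed = 43)
  expect_false(identical(a$suv_ac$data, c2$suv_ac$data))
})

test_that("lor_bias_field: identity, closed-form line integral, ray oracle", {
  # equal maps -> bias identically 1
  mu_a <- make_volume(0.1, dim = c(6, 6, 6), unit = "mu")
  b0 <- lor_bias_field(mu_a, mu_a, n_directions = 4)
  expect_true(all(abs(b0$data - 1) < 1e-12))

  # single axial direction, uniform dmu = 0.005 /cm over a 20 cm path:
  # 50 slices at 4 mm -> box extent 200 mm -> bias = exp(0.1)
  d <- c(3, 3, 50)
  mu_ac <- voxel_volume(array(0.096, dim = d), spacing = c(4, 4, 4), unit = "mu")
  mu_ce <- voxel_volume(array(0.101, dim = d), spacing = c(4, 4, 4), unit = "mu")
  bz <- lor_bias_field(mu_ac, mu_ce, directions = rbind(c(0, 0, 1)))
  expect_equal(unique(round(as.vector(bz$data), 10)), round(exp(0.1), 10))

  # wider acceptance angle cannot decrease the center bias when dmu >= 0,
  # and the direction-grid result matches a brute-force dense ray oracle
  set.seed(55)
  d8 <- c(8, 8, 8)
  dmu <- array(runif(prod(d8), 0, 0.01), dim = d8)
  mu1 <- voxel_volume(array(0.09, dim = d8), spacing = c(4, 4, 4), unit = "mu")
  mu2 <- voxel_volume(mu1$data + dmu, spacing = c(4, 4, 4), unit = "mu")
  b52 <- lor_bias_field(mu1, mu2, acceptance_angle = 52, n_directions = 16)
  b18 <- lor_bias_field(mu1, mu2, acceptance_angle = 18, n_directions = 16)
  expect_true(all(b52$data >= 1))
  expect_true(all(b18$data >= 1))

  # oracle: same direction set, independent dense-step ray integration
  dirs <- suvshift:::lor_direction_grid(52, 16)
  center <- c(4, 4, 4)
  p <- (center - 1) * 4
  oracle <- mean(apply(dirs, 1, function(u) {
    tt <- suvshift:::ray_box_range(p, u, -c(2, 2, 2), (d8 - 1) * 4 + 2)
    ts <- seq(tt[1], tt[2], length.out = 4001)
    ts <- (ts[-1] + ts[-length(ts)]) / 2
    vals <- vapply(ts, function(t) {
      idx <- pmin(pmax(round((p + t * u) / 4) + 1, 1), d8)
      dmu[idx[1], idx[2], idx[3]]
    }, numeric(1))
    exp(sum(vals) * (tt[2] - tt[1]) / 4000 / 10)
  }))
  expect_equal(b52$data[4, 4, 4], oracle, tolerance = 0.002)

  expect_error(lor_bias_field(mu1, make_volume(0.09, dim = c(4, 4, 4), unit = "mu")),
               "grid mismatch")
  expect_error(lor_bias_field(mu1, mu2, acceptance_angle = 120), "acceptance_angle")
  expect_error(lor_bias_field(mu1, mu2, n_directions = 0), "n_directions")
})
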