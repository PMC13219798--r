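test_that("size-based growth follows the inverse power law", {
  cfg <- mu_config(s = -0.25, mu_ref = 1, V_ref = 1)
  expect_equal(mu_from_size(1, cfg), 1)
  expect_equal(mu_from_size(16, cfg), 0.5)
  V <- sort(runif(10, 5, 500))
  mu <- mu_from_size(V, mu_config())
  expect_true(all(diff(mu) < 0))  # strictly decreasing in volume
  expect_error(mu_from_size(-1), "positive")
  expect_error(mu_config(s = 0.2), "s < 0")
})

test_that("size-based growth is scale consistent and rank preserving", {
  set.seed(501)
  V <- runif(15, 10, 400)
  cfg <- mu_config()
  mu1 <- mu_from_size(V, cfg)
  mu2 <- mu_from_size(7 * V, cfg)
  expect_equal(mu2 / mu1, rep(7^cfg$s, 15))
  expect_equal(rank(mu1), rank(mu2))
})

test_that("phosphate growth response is Michaelis-Menten", {
  cfg <- mu_config(mu_max = 1, K_PO4 = 0.1)
  expect_equal(mu_from_po4(0.1, cfg), 0.5)
  expect_equal(mu_from_po4(0, cfg), 0)
  expect_equal(mu_from_po4(0.5, cfg), 0.83333, tolerance = 1e-5)
  # saturating and concave
  p <- seq(0, 2, by = 0.1)
  mu <- mu_from_po4(p, cfg)
  expect_true(all(diff(mu) > 0))
  expect_true(all(diff(diff(mu)) < 0))
  expect_error(mu_from_po4(-0.1, cfg), ">= 0")
})

test_that("environmental growth responses clamp at zero", {
  cfg <- mu_config(sst_slope = 0.05, sst_intercept = 0)
  expect_equal(mu_from_env(10, "sst", cfg), 0.5)
  expect_equal(mu_from_env(0, "sst", cfg), 0)
  cfg2 <- mu_config(co2_slope = 0.04, co2_intercept = -1)
  expect_equal(mu_from_env(10, "co2", cfg2), 0)  # negative raw clamps to 0
})

test_that("profile comparison reports correlation and rank concordance", {
  x <- c(0.2, 0.5, 0.9, 1.1, 0.7)
  same <- compare_mu_profiles(x, x)
  expect_equal(same$pearson_r, 1)
  mono <- seq(0.2, 1.0, length.out = 5)
  rev <- compare_mu_profiles(mono, base::rev(mono))
  expect_equal(rev$pearson_r, -1, tolerance = 1e-12)
  expect_equal(rev$rank_r, -1)
  expect_error(compare_mu_profiles(x, x[1:3]), "mismatch")
})

test_that("size-based growth recovers the generator's true growth profile", {
  tr <- make_transect(seed = 1)
  mi <- morphometric_indices(tr$morpho)
  mu <- mu_size_profile(mi$indices)
  sg <- mu[mu$taxon == "small Gephyrocapsa", ]
  truth <- tr$truth$table[tr$truth$table$taxon == "small Gephyrocapsa", ]
  j <- merge(sg, truth, by = "sample_id")
  cmp <- compare_mu_profiles(j$mu_size, j$mu_true)
  expect_gt(cmp$pearson_r, 0.8)
  expect_lt(cmp$p_value, 0.05)
})

test_that("nutrient growth proxy agrees with truth only inside the thermal niche", {
  tr <- make_transect(seed = 3)
  cfg <- mu_config()
  truth <- tr$truth$table[tr$truth$table$taxon == "small Gephyrocapsa", ]
  env <- tr$env[match(truth$sample_id, tr$env$sample_id), ]
  mu_po4 <- mu_from_po4(env$po4, cfg)
  taxa <- default_taxon_params()
  opt <- taxa$sst_opt[taxa$taxon == "small Gephyrocapsa"]
  wid <- taxa$sst_width[taxa$taxon == "small Gephyrocapsa"]
  inside <- abs(env$sst - opt) < wid
  cmp <- compare_mu_profiles(mu_po4[inside], truth$mu_true[inside])
  expect_gt(cmp$rank_r, 0)
  # beyond the cold edge of the optimum the nutrient proxy overestimates:
  # phosphate is high but true growth has collapsed
  cold <- env$sst < opt - 1.5 * wid
  if (any(cold)) {
    expect_true(all(rank(mu_po4)[cold] > rank(truth$mu_true)[cold]))
  }
})
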