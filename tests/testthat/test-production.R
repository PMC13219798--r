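test_that("taxon production is the bilinear N times mean mass", {
  expect_equal(taxon_production(0, 1.5), 0)
  expect_equal(taxon_production(6e8, 1.5), 9e8)
  expect_equal(taxon_production(2 * 6e8, 2 * 1.5), 4 * 9e8)
  expect_error(taxon_production(-1, 1), "non-negative")
  expect_error(taxon_production(1, 0), "positive")
})

test_that("group contributions close to 100 percent and drop massless taxa", {
  prod <- tibble::tibble(
    sample_id = rep("S01", 5),
    taxon = default_taxonomy()$taxon,
    pic_poc_group = default_taxonomy()$pic_poc_group,
    cp = c(6e8, 3e8, 0.4e8, 0.3e8, 0.3e8)
  )
  g <- group_contributions(prod)
  expect_equal(g$pct_low + g$pct_high, 100, tolerance = 1e-9)
  expect_equal(g$pct_low, 90)
  prod$cp[4] <- NA
  expect_warning(g2 <- group_contributions(prod), "excluded")
  expect_equal(g2$cp_high, 0.7e8)
  allzero <- prod; allzero$cp <- 0
  expect_error(suppressWarnings(group_contributions(allzero)), "all-zero")
})

test_that("boundary detection interpolates 50 percent crossings", {
  b <- detect_boundary(c(50, 45, 35, 30), c(70, 60, 40, 30))
  expect_equal(b$crossings, 40.0)
  expect_equal(b$primary, 40.0)
  none <- detect_boundary(c(50, 40, 30), c(60, 60, 60))
  expect_length(none$crossings, 0)
  expect_true(is.na(none$primary))
  onsample <- detect_boundary(c(50, 40, 30), c(70, 50, 30))
  expect_equal(onsample$primary, 40.0)
  expect_error(detect_boundary(c(50, 40), c(60, 40)), ">= 3")
  expect_error(detect_boundary(c(50, 40, 30), c(60, 40, 30), window = 2),
               "odd")
})

test_that("multiple crossings are all reported with the sharpest primary", {
  lat <- c(50, 45, 40, 35, 30)
  pct <- c(55, 45, 52, 20, 10)  # two descending crossings, second sharper
  b <- detect_boundary(lat, pct)
  expect_length(b$crossings, 3)
  # sharpest gradient is the 52 -> 20 drop between 40 and 35
  expect_gt(b$primary, 35); expect_lt(b$primary, 40)
})

test_that("contributions and boundary are invariant to per-sample CP scaling", {
  tr <- make_transect(seed = 4)
  ab <- census_abundances(tr$census)
  mi <- morphometric_indices(tr$morpho)
  ps <- production_summary(ab, mi$indices, tr$samples)
  scaled <- ps$taxon
  fac <- stats::setNames(runif(length(unique(scaled$sample_id)), 0.5, 2),
                         unique(scaled$sample_id))
  scaled$cp <- scaled$cp * fac[scaled$sample_id]
  g2 <- group_contributions(scaled)
  g1 <- ps$groups
  expect_equal(g2$pct_high[match(g1$sample_id, g2$sample_id)], g1$pct_high,
               tolerance = 1e-9)
  b2 <- detect_boundary(g1$latitude, g2$pct_high[match(g1$sample_id, g2$sample_id)])
  expect_equal(b2$primary, ps$boundary$primary)
})

test_that("boundary characterization interpolates environmental fields", {
  env <- tibble::tibble(latitude = c(50, 40, 30),
                        sst = c(10, 15, 20), po4 = c(0.9, 0.5, 0.2))
  at_sample <- characterize_boundary(40, env)
  expect_equal(at_sample$sst, 15)
  midway <- characterize_boundary(45, env)
  expect_equal(midway$sst, 12.5)       # arithmetic mean of bracketing pair
  expect_equal(midway$po4, 0.7)
  expect_error(characterize_boundary(60, env), "extrapolation")
})

test_that("boundary environment on synthetic defaults sits in the calibrated band", {
  tr <- make_transect(seed = 6)
  ab <- census_abundances(tr$census)
  mi <- morphometric_indices(tr$morpho)
  ps <- production_summary(ab, mi$indices, tr$samples, env = tr$env)
  expect_gt(ps$boundary_env$sst, 12)
  expect_lt(ps$boundary_env$sst, 18)
})
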