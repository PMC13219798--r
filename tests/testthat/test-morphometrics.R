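test_that("mean thickness is mass over density times area", {
  expect_equal(mean_thickness(2.7, 1), 1.0)
  expect_equal(mean_thickness(5.4, 4), 0.5)
  expect_equal(mean_thickness(2.7, 2), mean_thickness(2.7, 1) / 2)
  expect_error(mean_thickness(-1, 1), "positive")
})

test_that("allometry fit recovers exact power-law exponents", {
  L <- seq(2, 5, length.out = 30)
  f1 <- fit_allometry(L, 0.1 * L)
  expect_equal(f1$beta, 1.0, tolerance = 1e-6)
  f07 <- fit_allometry(L, 0.1 * L^0.7)
  expect_equal(f07$beta, 0.7, tolerance = 1e-6)
  expect_equal(f07$L_ref, exp(mean(log(L))))
  expect_equal(f07$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_allometry(rep(3, 20), rep(0.3, 20)), "variance")
  expect_error(fit_allometry(L[1:5], 0.1 * L[1:5]), "10")
})

test_that("SN thickness removes the fitted size trend", {
  expect_equal(sn_thickness(0.4, 6, list(beta = 1, L_ref = 3)), 0.2)
  fit <- list(beta = 0.8, L_ref = 3.2)
  expect_equal(sn_thickness(0.37, fit$L_ref, fit), 0.37)  # identity at L_ref
  expect_equal(sn_thickness(0.4, 6, list(beta = 0, L_ref = 3)), 0.4)
  # decorrelation on noiseless power-law data
  set.seed(401)
  L <- rlnorm(200, log(3), 0.2)
  Th <- 0.08 * L^0.85
  fit <- fit_allometry(L, Th)
  sn <- sn_thickness(Th, L, fit)
  expect_lt(abs(cor(sn, L)), 0.05)
})

test_that("elliptical shape factor matches its definition and is scale invariant", {
  expect_equal(elliptical_shape_factor(2.7, 1, 1), 1.0)
  expect_equal(elliptical_shape_factor(162, 9, 8), 162 / (2.7 * 81 * 8))
  set.seed(402)
  for (i in 1:10) {
    L <- runif(1, 2, 10); W <- L * runif(1, 0.5, 1); m <- runif(1, 1, 100)
    s <- runif(1, 0.5, 3)
    expect_equal(elliptical_shape_factor(s^3 * m, s * L, s * W),
                 elliptical_shape_factor(m, L, W))
  }
  # reduces to the circular factor when W = L
  expect_equal(elliptical_shape_factor(27, 2, 2), 27 / (2.7 * 8))
})

test_that("cell diameter mapping is linear and monotone", {
  expect_equal(cell_diameter_from_coccolith(2.5, list(alpha = 0, beta = 2)), 5)
  expect_warning(d <- cell_diameter_from_coccolith(3, list(alpha = 4, beta = 0)),
                 "constant")
  expect_equal(d, 4)
  L <- sort(runif(10, 1, 10))
  d <- cell_diameter_from_coccolith(L, list(alpha = 0.5, beta = 1.5))
  expect_true(all(diff(d) >= 0))
  expect_error(cell_diameter_from_coccolith(1, list(alpha = -5, beta = 2)),
               "non-positive")
})

test_that("cellular PIC/POC follows the quota chain", {
  q <- cellular_pic_poc(1.5, 15, 5)
  # independent log-space evaluation of the same chain
  V <- pi / 6 * 5^3
  poc_log <- exp(log(0.216) + 0.939 * log(V))
  expect_equal(q$poc_pg_c, poc_log, tolerance = 1e-12)
  expect_equal(q$pic_pg_c, 1.5 * 15 * (12.011 / 100.087), tolerance = 1e-12)
  expect_equal(q$pic_pg_c, 2.70, tolerance = 0.005)
  expect_equal(q$poc_pg_c, 10.95, tolerance = 0.005)
  expect_equal(q$pic_poc, 0.247, tolerance = 0.005)
  # linearity in mean mass
  q2 <- cellular_pic_poc(3.0, 15, 5)
  expect_equal(q2$pic_pg_c, 2 * q$pic_pg_c)
  expect_equal(q2$pic_poc, 2 * q$pic_poc)
  expect_error(cellular_pic_poc(1.5, 0, 5), "positive")
})

test_that("per-sample indices flag thin cells and are magnification invariant", {
  tr <- make_transect(seed = 9, n_measure = 12)
  mi <- morphometric_indices(tr$morpho)
  expect_false(any(mi$indices$flag_insufficient))
  expect_true(all(mi$indices$n == 12))
  # uniform magnification: L,W -> sL,sW, A -> s^2 A, m -> s^3 m leaves kse
  # and SN thickness unchanged up to the refit reference
  s <- 1.7
  mag <- tr$morpho
  mag$length <- s * mag$length; mag$width <- s * mag$width
  mag$area <- s^2 * mag$area; mag$mass <- s^3 * mag$mass
  mi2 <- morphometric_indices(mag)
  expect_equal(mi2$indices$kse, mi$indices$kse, tolerance = 1e-10)
  # insufficient cells are flagged missing, with a beta = 1 fallback fit
  small <- tr$morpho[tr$morpho$sample_id == "S01", ]
  small <- small[c(1:12, 13:17), ]  # second taxon has only 5 records
  mi3 <- morphometric_indices(small)
  thin <- mi3$indices[mi3$indices$n == 5, ]
  expect_true(thin$flag_insufficient)
  expect_true(is.na(thin$sn_thickness))
  expect_equal(mi3$fits[[thin$taxon]]$beta, 1)
})
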