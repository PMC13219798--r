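test_that("niche weight is a Gaussian-thermal Monod-nutrient product", {
  expect_equal(niche_weight(20, 1e9, 20, 5, 0.1), 1.0, tolerance = 1e-9)
  expect_equal(niche_weight(20, 0.1, 20, 5, 0.1), 0.5)
  expect_equal(niche_weight(25, 0.1, 20, 5, 0.1), exp(-0.5) * 0.5,
               tolerance = 1e-12)
  sst <- seq(0, 30, by = 0.5)
  w <- niche_weight(sst, 0.5, 18, 6, 0.2)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(sst[which.max(w)], 18)
  expect_error(niche_weight(NaN, 0.5, 18, 6, 0.2), "finite")
})

test_that("generator configuration enforces its invariants", {
  expect_error(transect_config(n_samples = 2), "n_samples")
  expect_error(transect_config(total_count = 200), "total_count")
  taxa <- default_taxon_params()
  taxa$gamma[1] <- -0.5  # a low PIC/POC taxon must couple positively
  expect_error(transect_config(taxa = taxa), "gamma")
  taxa <- default_taxon_params()
  taxa$gamma[5] <- 0.5   # a high PIC/POC taxon must couple negatively
  expect_error(transect_config(taxa = taxa), "gamma")
})

test_that("the same seed reproduces byte-identical tables", {
  t1 <- generate_transect(transect_config(seed = 42))
  t2 <- generate_transect(transect_config(seed = 42))
  expect_identical(t1, t2)
  d1 <- file.path(tempdir(), "tr1"); d2 <- file.path(tempdir(), "tr2")
  write_tables(t1, d1); write_tables(t2, d2)
  for (f in c("census.csv", "morpho.csv", "env.csv", "samples.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  t3 <- generate_transect(transect_config(seed = 43))
  expect_false(identical(t1$census$count, t3$census$count))
})

test_that("counts close to the configured effort and truth shares to one", {
  tr <- make_transect(seed = 8)
  totals <- tapply(tr$census$count, tr$census$sample_id, sum)
  expect_true(all(totals == 320))
  shares <- tapply(tr$truth$table$rel_abundance_true,
                   tr$truth$table$sample_id, sum)
  expect_true(all(abs(shares - 1) < 1e-12))
  expect_true(all(tr$truth$table$mu_true > 0))
  expect_true(all(tr$morpho$width <= tr$morpho$length))
})

test_that("count-based abundance estimates sit inside binomial 99% CIs of truth", {
  tr <- make_transect(seed = 10)
  ab <- census_abundances(tr$census)
  j <- merge(ab, tr$truth$table, by = c("sample_id", "taxon"))
  ci <- t(mapply(function(k, p) {
    stats::qbinom(c(0.005, 0.995), 320, p) / 320
  }, j$count, j$rel_abundance_true))
  inside <- j$rel_abundance >= ci[, 1] & j$rel_abundance <= ci[, 2]
  # a handful of 1% misses over ~95 cells is expected
  expect_gt(mean(inside), 0.95)
})

test_that("thickness coupling has opposite signs in the two functional groups", {
  tr <- make_transect(seed = 12)
  mi <- morphometric_indices(tr$morpho)
  j <- merge(mi$indices, tr$truth$table, by = c("sample_id", "taxon"))
  for (tx in unique(j$taxon)) {
    d <- j[j$taxon == tx, ]
    res <- tx_pearson(d$sn_thickness, d$mu_true)
    grp <- d$pic_poc_group[1]
    if (grp == "low") expect_gt(res$r, 0) else expect_lt(res$r, 0)
    expect_lte(res$p, 0.05)
  }
})

test_that("a degenerate niche still emits a sample on the abundance floor", {
  taxa <- default_taxon_params()
  taxa$sst_opt <- rep(60, 5)  # nothing lives anywhere on the transect
  taxa$gamma <- c(0.5, 0.5, -0.5, -0.5, -0.5)
  cfg <- transect_config(seed = 1, taxa = taxa)
  expect_warning(tr <- generate_transect(cfg), "degenerate niche")
  totals <- tapply(tr$census$count, tr$census$sample_id, sum)
  expect_true(all(totals == 320))
})
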