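test_that("generation is bit-identical under a fixed seed", {
  cfg <- scenario_config(n_sites = 10, n_species = 10, n_empty_sites = 1)
  g1 <- generate_scenario(cfg, seed = 7)
  g2 <- generate_scenario(cfg, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_scenario(cfg, seed = 8)
  expect_false(identical(g1$occurrence, g3$occurrence))
})

test_that("scenario_config validates its fields", {
  expect_error(scenario_config(n_sites = 2), class = "streambeta_invalid_config")
  expect_error(scenario_config(occupancy_noise = 0.6),
               class = "streambeta_invalid_config")
  expect_error(scenario_config(elevation_range = c(2000, 1000)),
               class = "streambeta_invalid_config")
  expect_error(scenario_config(n_empty_sites = 18),
               class = "streambeta_invalid_config")
  # nested regime needs enough distinguishable range extents
  expect_error(scenario_config(regime = "nested", n_sites = 6, n_species = 10),
               class = "streambeta_invalid_config")
})

test_that("noise-free nested regime yields pure nestedness (ratio exactly 1)", {
  cfg <- scenario_config(regime = "nested", n_sites = 12, n_species = 12,
                         occupancy_noise = 0, n_empty_sites = 0)
  gen <- generate_scenario(cfg, seed = 1)
  bm <- beta_matrices(gen$occurrence)
  expect_true(all(bm$sim == 0))
  sm <- beta_summary(bm)
  expect_identical(sm$mean_ratio, 1)
  expect_equal(sm$dominant_component, "nestedness")
  # every pair is a subset pair
  m <- incidence_matrix(gen$occurrence)
  for (i in 1:11) for (j in (i + 1):12) {
    inter <- sum(m[i, ] & m[j, ])
    expect_true(inter == sum(m[i, ]) || inter == sum(m[j, ]))
  }
})

test_that("noise-free equal-richness turnover regime has zero nestedness", {
  cfg <- scenario_config(regime = "turnover", n_sites = 15, n_species = 15,
                         occupancy_noise = 0, n_empty_sites = 0,
                         niche_breadth = 250)
  gen <- generate_scenario(cfg, seed = 2)
  m <- incidence_matrix(gen$occurrence)
  expect_equal(length(unique(rowSums(m))), 1)  # equal richness
  bm <- beta_matrices(gen$occurrence)
  expect_true(all(bm$sne == 0))
  sm <- suppressWarnings(beta_summary(bm))
  expect_identical(sm$mean_ratio, 0)
  expect_equal(sm$dominant_component, "turnover")
})

test_that("the 0.5 rule classifies noisy regimes correctly in almost all runs", {
  classify <- function(regime, seed) {
    cfg <- scenario_config(regime = regime, n_sites = 12, n_species = 12,
                           occupancy_noise = 0.05, n_empty_sites = 0,
                           niche_breadth = 250)
    gen <- generate_scenario(cfg, seed = seed)
    occ <- drop_empty_sites(gen$occurrence)$occurrence
    suppressWarnings(beta_summary(beta_matrices(occ))$dominant_component)
  }
  seeds <- 1:50
  nested_ok <- vapply(seeds, function(s) classify("nested", s) == "nestedness",
                      logical(1))
  turn_ok <- vapply(seeds, function(s) classify("turnover", s) == "turnover",
                    logical(1))
  expect_gte(mean(nested_ok), 0.98)
  expect_gte(mean(turn_ok), 0.98)
})

test_that("empty transects are planted and flagged in truth", {
  gen <- generate_scenario(scenario_config(), seed = 101)
  expect_equal(sum(rowSums(incidence_matrix(gen$occurrence)) == 0), 3)
  dropped <- drop_empty_sites(gen$occurrence)
  expect_equal(nrow(dropped$occurrence), 15)
  expect_setequal(dropped$removed, gen$truth$empty_sites)
})

test_that("temperature calibration hits the requested rank correlation", {
  elev <- seq(485, 2865, length.out = 18)
  exact <- calibrate_env_correlation(elev, 1)
  expect_equal(cor(elev, exact, method = "spearman"), 1)

  cal <- calibrate_env_correlation(elev, 0.81, seed = 3)
  rho <- cor(elev, as.numeric(cal), method = "spearman")
  expect_gt(rho, 0.76); expect_lt(rho, 0.86)
  expect_equal(attr(cal, "rho"), rho)

  weak <- vapply(1:40, function(s) {
    cor(elev, as.numeric(calibrate_env_correlation(elev, 0.1, seed = s)),
        method = "spearman")
  }, numeric(1))
  expect_gte(mean(abs(weak) < 0.3), 0.9)

  expect_error(calibrate_env_correlation(elev, 1.5),
               class = "streambeta_invalid_config")
})

test_that("gradient scenarios produce a positive elevational signal on total dissimilarity", {
  hits <- vapply(1:30, function(s) {
    cfg <- scenario_config(regime = "turnover", n_sites = 14, n_species = 14,
                           occupancy_noise = 0.05, n_empty_sites = 0,
                           niche_breadth = 250)
    gen <- generate_scenario(cfg, seed = s)
    occ <- drop_empty_sites(gen$occurrence)$occurrence
    meta <- gen$meta[match(occ$site_id, gen$meta$site_id), ]
    res <- mantel(beta_matrices(occ)$sor, elevational_distance(meta),
                  n_perm = 199, seed = s)
    res$r > 0 && res$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("neutral scenarios give approximately uniform Mantel p-values", {
  ps <- vapply(1:100, function(s) {
    cfg <- scenario_config(regime = "neutral", n_sites = 10, n_species = 15,
                           occupancy_noise = 0, n_empty_sites = 0)
    gen <- generate_scenario(cfg, seed = s)
    occ <- drop_empty_sites(gen$occurrence)$occurrence
    meta <- gen$meta[match(occ$site_id, gen$meta$site_id), ]
    mantel(beta_matrices(occ)$sor, elevational_distance(meta),
           n_perm = 99, seed = s)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the YAML scenario config round-trips through the bundled default", {
  path <- system.file("extdata", "montane_scenario.yaml", package = "streambeta")
  cfg <- read_scenario_config(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$n_sites, 18L)
  expect_equal(cfg$n_species, 19L)
  expect_equal(cfg$elevation_range, c(485, 2865))
  expect_equal(cfg$n_empty_sites, 3L)
  expect_equal(cfg$env_elev_rho, 0.81)
})
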