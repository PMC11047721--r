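test_that("pair_counts matches set arithmetic", {
  expect_equal(pair_counts(c(1, 1, 1, 1), c(1, 1, 0, 0)),
               list(a = 2, b = 2, c = 0))
  expect_equal(pair_counts(c(1, 0, 1), c(1, 0, 1)), list(a = 2, b = 0, c = 0))
  expect_error(pair_counts(c(0, 0), c(1, 0)), class = "streambeta_empty_site")

  withr::with_seed(11, {
    for (k in 1:200) {
      x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.5)
      if (sum(x) == 0 || sum(y) == 0) next
      pc <- pair_counts(x, y)
      sx <- which(x == 1); sy <- which(y == 1)
      expect_identical(pc$a, length(intersect(sx, sy)))
      expect_identical(pc$b, length(setdiff(sx, sy)))
      expect_identical(pc$c, length(setdiff(sy, sx)))
    }
  })
})

test_that("beta_pair reproduces hand-evaluated partitions", {
  nested <- beta_pair(list(a = 2, b = 2, c = 0))
  expect_equal(nested$beta_sor, 1 / 3)
  expect_equal(nested$beta_sim, 0)
  expect_equal(nested$beta_sne, 1 / 3)

  disjoint <- beta_pair(list(a = 0, b = 2, c = 1))
  expect_equal(unlist(disjoint), c(beta_sor = 1, beta_sim = 1, beta_sne = 0))

  mixed <- beta_pair(list(a = 1, b = 2, c = 1))
  expect_equal(unlist(mixed), c(beta_sor = 0.6, beta_sim = 0.5, beta_sne = 0.1))
  # direct product form of the nestedness component for the same counts
  expect_equal(abs(2 - 1) / (2 * 1 + 2 + 1) * 1 / (1 + min(2, 1)), 0.1)

  expect_error(beta_pair(list(a = 0, b = 2, c = 0)),
               class = "streambeta_empty_site")
})

test_that("partition identity and bounds hold over random pairs", {
  withr::with_seed(23, {
    for (k in 1:300) {
      a <- sample(0:8, 1); b <- sample(0:8, 1); cc <- sample(0:8, 1)
      if (a + b < 1 || a + cc < 1 || (a == 0 && min(b, cc) == 0)) next
      bp <- beta_pair(list(a = a, b = b, c = cc))
      expect_lt(abs(bp$beta_sor - bp$beta_sim - bp$beta_sne), 1e-12)
      expect_true(bp$beta_sim >= 0 && bp$beta_sim <= bp$beta_sor)
      expect_true(bp$beta_sor <= 1)
    }
  })
})

test_that("beta_matrices agrees entry-for-entry with a set-operation loop", {
  occ <- random_occurrence(15, 19, seed = 4)
  bm <- beta_matrices(occ)
  oracle <- beta_oracle(occ)
  expect_equal(unname(bm$sor), unname(oracle$sor), tolerance = 1e-12)
  expect_equal(unname(bm$sim), unname(oracle$sim), tolerance = 1e-12)
  expect_equal(unname(bm$sne), unname(oracle$sne), tolerance = 1e-12)
  expect_lt(max(abs(bm$sor - bm$sim - bm$sne)), 1e-12)
})

test_that("beta_matrices agrees with vegan's independent implementation", {
  skip_if_not_installed("vegan")
  occ <- random_occurrence(12, 15, seed = 8)
  m <- incidence_matrix(occ)
  bm <- beta_matrices(occ)
  expect_equal(unname(bm$sor), unname(as.matrix(vegan::betadiver(m, "w"))),
               tolerance = 1e-12)
  expect_equal(unname(bm$sim), unname(as.matrix(vegan::betadiver(m, "sim"))),
               tolerance = 1e-12)
})

test_that("species-column permutation leaves matrices unchanged; site permutation is consistent", {
  occ <- random_occurrence(8, 12, seed = 3)
  bm <- beta_matrices(occ)
  perm_sp <- occ[, c(1, 1 + sample(12))]
  expect_equal(beta_matrices(perm_sp), bm)
  ord <- sample(8)
  bm_perm <- beta_matrices(occ[ord, ])
  expect_equal(bm_perm$sor, bm$sor[ord, ord])
})

test_that("adding a shared species strictly decreases total dissimilarity", {
  withr::with_seed(5, {
    for (k in 1:50) {
      a <- sample(0:5, 1); b <- sample(0:5, 1); cc <- sample(0:5, 1)
      if (a + b < 1 || a + cc < 1 || b + cc == 0 || (a == 0 && min(b, cc) == 0)) next
      s0 <- beta_pair(list(a = a, b = b, c = cc))$beta_sor
      s1 <- beta_pair(list(a = a + 1, b = b, c = cc))$beta_sor
      expect_lt(s1, s0)
    }
  })
})

test_that("beta_summary averages pairs and applies the 0.5 dominance rule", {
  # two pairs: (1,2,1) -> (0.6, 0.5, 0.1) and (0,2,1) -> (1, 1, 0)
  occ <- tibble::tibble(site_id = c("x", "y", "z"),
                        s1 = c(1L, 1L, 0L), s2 = c(1L, 0L, 1L),
                        s3 = c(1L, 0L, 0L), s4 = c(0L, 1L, 0L))
  bm <- beta_matrices(occ)
  pr <- beta_pair(pair_counts(c(1, 1, 1, 0), c(1, 0, 0, 1)))
  expect_equal(bm$sor["y", "x"], pr$beta_sor)

  sm <- beta_summary(bm)
  v <- unfold(bm$sor)
  expect_equal(sm$sd_sor, sd(v))
  expect_equal(sm$n_pairs, 3)
  # hand arithmetic: pairs are (0.6, 0.5, 0.1), (0.5, 0, 0.5), (1, 1, 0)
  expect_equal(sm$mean_sor, (0.6 + 0.5 + 1) / 3)
  expect_equal(sm$mean_ratio, (0.1 / 0.6 + 1 + 0) / 3)
  expect_equal(sm$dominant_component, "turnover")
})

test_that("nested chains and disjoint communities hit the ratio extremes", {
  chain <- tibble::tibble(site_id = c("a", "b", "c", "d"),
                          s1 = c(1L, 1L, 1L, 1L), s2 = c(1L, 1L, 1L, 0L),
                          s3 = c(1L, 1L, 0L, 0L), s4 = c(1L, 0L, 0L, 0L))
  bm <- beta_matrices(chain)
  expect_true(all(bm$sim == 0))
  sm <- beta_summary(bm)
  expect_equal(sm$mean_ratio, 1)
  expect_equal(sm$dominant_component, "nestedness")

  disjoint <- tibble::tibble(site_id = c("a", "b", "c"),
                             s1 = c(1L, 0L, 0L), s2 = c(0L, 1L, 0L),
                             s3 = c(0L, 0L, 1L))
  smd <- beta_summary(beta_matrices(disjoint))
  expect_equal(smd$mean_sor, 1)
  expect_equal(smd$mean_ratio, 0)
  expect_equal(smd$dominant_component, "turnover")
})

test_that("identical pairs are excluded from ratio statistics with a warning", {
  occ <- tibble::tibble(site_id = c("a", "b", "c"),
                        s1 = c(1L, 1L, 0L), s2 = c(0L, 0L, 1L))
  bm <- beta_matrices(occ)   # a and b identical
  expect_warning(sm <- beta_summary(bm), class = "streambeta_zero_sor")
  expect_equal(sm$n_zero_sor, 1)
  expect_equal(sm$n_pairs, 3)

  same <- tibble::tibble(site_id = c("a", "b"), s1 = c(1L, 1L))
  expect_error(beta_summary(beta_matrices(same)), class = "streambeta_degenerate")
})

test_that("ratio-of-means variant is reported when requested", {
  occ <- random_occurrence(8, 10, seed = 6)
  bm <- beta_matrices(occ)
  sm <- beta_summary(bm, ratio_method = "of_means")
  expect_equal(sm$mean_ratio, mean(unfold(bm$sne)) / mean(unfold(bm$sor)))
  expect_true(is.na(sm$sd_ratio))
})

test_that("tidy and glance return the summary as tibbles", {
  sm <- beta_summary(beta_matrices(random_occurrence(6, 8, seed = 2)))
  td <- tidy(sm)
  expect_equal(td$index, c("sor", "sim", "sne", "ratio"))
  expect_equal(td$mean[1], sm$mean_sor)
  expect_equal(glance(sm)$dominant_component, sm$dominant_component)
})
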