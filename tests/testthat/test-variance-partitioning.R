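test_that("standardize_matrix z-scores the unfolded entries and is idempotent", {
  d <- random_dist(7, seed = 1)
  s <- standardize_matrix(d)
  v <- s[lower.tri(s)]
  expect_lt(abs(mean(v)), 1e-12)
  expect_lt(abs(sd(v) - 1), 1e-12)
  expect_equal(unname(diag(s)), rep(0, 7))
  expect_equal(standardize_matrix(s), s, tolerance = 1e-12)
  # affine invariance
  expect_equal(standardize_matrix(3 + 2 * d - diag(3, 7)), s, tolerance = 1e-12)
  const <- refold(rep(2, 21), rownames(d))
  expect_error(standardize_matrix(const), class = "streambeta_constant_matrix")
})

test_that("mrm coefficients and R-squared match the normal-equation oracle", {
  dy <- random_dist(8, seed = 11)
  preds <- list(p1 = random_dist(8, seed = 12), p2 = random_dist(8, seed = 13),
                p3 = random_dist(8, seed = 14))
  fit <- mrm(dy, preds, n_perm = 49, seed = 1)
  X <- vapply(preds, function(d) {
    z <- standardize_matrix(d); z[lower.tri(z)]
  }, numeric(28))
  oracle <- ols_oracle(unfold(dy), X)
  expect_equal(fit$intercept, unname(oracle$coef[1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate, unname(oracle$coef[-1]), tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_equal(glance(fit)$r_squared, fit$r_squared)
})

test_that("mrm recovers a planted single driver", {
  driver <- random_dist(12, seed = 21)
  noise1 <- random_dist(12, seed = 22)
  noise2 <- random_dist(12, seed = 23)
  dy <- standardize_matrix(driver)
  dy <- dy - min(dy)          # shift to a valid non-negative distance matrix
  diag(dy) <- 0
  fit <- mrm(dy, list(driver = driver, n1 = noise1, n2 = noise2),
             n_perm = 199, seed = 2)
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "driver"] - 1), 0.05)
  expect_gt(fit$r_squared, 0.95)
  expect_lte(est$p[est$term == "driver"], 0.05)
})

test_that("mrm with one predictor reproduces distance_decay exactly", {
  dy <- random_dist(9, seed = 31)
  dx <- random_dist(9, seed = 32)
  fit_m <- mrm(dy, list(x = dx), n_perm = 9, seed = 1, standardize = FALSE)
  fit_d <- distance_decay(dy, dx)
  expect_equal(fit_m$coefficients$estimate, fit_d$slope, tolerance = 1e-12)
  expect_equal(fit_m$r_squared, fit_d$r_squared, tolerance = 1e-12)
})

test_that("mrm errors on rank deficiency, site mismatch and tiny designs", {
  dy <- random_dist(8, seed = 41)
  dx <- random_dist(8, seed = 42)
  expect_error(mrm(dy, list(a = dx, b = dx), n_perm = 9),
               class = "streambeta_rank_deficient")
  small <- random_dist(4, seed = 43)
  many <- setNames(lapply(44:49, function(s) random_dist(4, seed = s)),
                   letters[1:6])
  expect_error(mrm(small, many, n_perm = 9), class = "streambeta_too_few_pairs")
  swapped <- dx
  rownames(swapped) <- colnames(swapped) <- rev(rownames(dx))
  expect_error(mrm(dy, list(x = swapped), n_perm = 9),
               class = "streambeta_site_mismatch")
})

test_that("mrm p-values are seed-reproducible and invariant to predictor order", {
  dy <- random_dist(9, seed = 51)
  preds <- list(a = random_dist(9, seed = 52), b = random_dist(9, seed = 53))
  f1 <- mrm(dy, preds, n_perm = 99, seed = 6)
  f2 <- mrm(dy, preds, n_perm = 99, seed = 6)
  expect_equal(f1$p_model, f2$p_model)
  expect_equal(f1$coefficients, f2$coefficients)
  f3 <- mrm(dy, rev(preds), n_perm = 99, seed = 6)
  expect_equal(f3$p_model, f1$p_model)
  expect_equal(dplyr::arrange(f3$coefficients, term),
               dplyr::arrange(f1$coefficients, term))
})

test_that("hier_part degenerates correctly for k = 1 and orthogonal predictors", {
  dy <- random_dist(8, seed = 61)
  dx <- random_dist(8, seed = 62)
  hp1 <- hier_part(dy, list(x = dx))
  uni <- distance_decay(dy, dx)$r_squared
  expect_equal(hp1$contributions$independent, uni, tolerance = 1e-10)
  expect_equal(hp1$contributions$joint, 0, tolerance = 1e-10)

  # construct two orthogonal predictors over the unfolded space
  n <- 8; m <- n * (n - 1) / 2
  v1 <- withr::with_seed(63, rnorm(m))
  v2 <- withr::with_seed(64, rnorm(m))
  v1 <- v1 - mean(v1)
  v2 <- v2 - mean(v2) - v1 * sum(v1 * (v2 - mean(v2))) / sum(v1^2)
  ids <- sprintf("s%02d", 1:n)
  p1 <- refold(v1, ids); p2 <- refold(v2, ids)
  diag(p1) <- diag(p2) <- 0
  hp2 <- hier_part(dy, list(a = p1, b = p2), standardize = FALSE)
  r2a <- summary(lm(unfold(dy) ~ v1))$r.squared
  r2b <- summary(lm(unfold(dy) ~ v2))$r.squared
  expect_equal(hp2$contributions$independent, c(r2a, r2b), tolerance = 1e-8)
  expect_lt(max(abs(hp2$contributions$joint)), 1e-8)
})

test_that("subset-weight contributions equal the all-orderings brute force", {
  dy <- random_dist(9, seed = 71)
  preds <- setNames(lapply(72:75, function(s) random_dist(9, seed = s)),
                    paste0("p", 1:4))
  hp <- hier_part(dy, preds)
  X <- vapply(preds, function(d) {
    z <- standardize_matrix(d); z[lower.tri(z)]
  }, numeric(36))
  oracle <- hier_part_oracle(unfold(dy), X)
  expect_equal(hp$contributions$independent, oracle, tolerance = 1e-10)
  expect_equal(sum(hp$contributions$independent), hp$r_squared, tolerance = 1e-8)
  uni <- vapply(seq_along(preds), function(j) {
    summary(lm(unfold(dy) ~ X[, j]))$r.squared
  }, numeric(1))
  expect_equal(hp$contributions$independent + hp$contributions$joint, uni,
               tolerance = 1e-8)
  expect_equal(sum(hp$contributions$independent_pct), 100, tolerance = 1e-8)
})

test_that("partition_table combines MRM and partitioning per component", {
  occ <- random_occurrence(9, 12, seed = 81)
  bm <- beta_matrices(occ)
  beta3 <- list(total = bm$sor, turnover = bm$sim, nestedness = bm$sne)
  preds <- list(geography = random_dist(9, seed = 82),
                elevation = random_dist(9, seed = 83),
                ph = random_dist(9, seed = 84))
  pt <- partition_table(beta3, preds, n_perm = 49, seed = 3)
  td <- tidy(pt)
  expect_equal(nrow(td), 9)
  expect_setequal(unique(td$predictor), c("Geo", "Ele", "pH"))
  expect_equal(unique(td$component), c("total", "turnover", "nestedness"))
  gl <- glance(pt)
  expect_equal(gl$r_squared[gl$component == "total"],
               mrm(bm$sor, preds, n_perm = 9, seed = 1)$r_squared)

  # identical responses give identical columns
  same <- partition_table(list(a = bm$sor, b = bm$sor), preds,
                          n_perm = 49, seed = 3)
  ts <- tidy(same)
  expect_equal(ts$independent[ts$component == "a"],
               ts$independent[ts$component == "b"])

  # serialization round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(td, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(td))
})

test_that("thirteen predictors are supported", {
  dy <- random_dist(10, seed = 91)
  preds <- setNames(lapply(1:13, function(s) random_dist(10, seed = 900 + s)),
                    paste0("p", 1:13))
  hp <- hier_part(dy, preds)
  expect_equal(nrow(hp$gof_cache), 2^13)
  expect_equal(sum(hp$contributions$independent), hp$r_squared, tolerance = 1e-8)
  too_many <- setNames(lapply(1:17, function(s) random_dist(10, seed = 950 + s)),
                       paste0("q", 1:17))
  expect_error(hier_part(dy, too_many), class = "streambeta_too_many_predictors")
})
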