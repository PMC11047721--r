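# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (set operations, explicit loops, normal equations,
# full ordering enumeration) so they share no code with the implementation.

random_occurrence <- function(n_sites, n_species, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_sites * n_species, 1L, p), n_sites, n_species)
    # guarantee no empty rows
    for (i in which(rowSums(m) == 0L)) m[i, sample(n_species, 1L)] <- 1L
    dplyr::bind_cols(
      tibble::tibble(site_id = sprintf("s%02d", seq_len(n_sites))),
      tibble::as_tibble(matrix(m, n_sites, n_species,
                               dimnames = list(NULL, sprintf("sp%02d", seq_len(n_species)))))
    )
  })
}

random_dist <- function(n, seed = 1, dim = 3) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n * dim), n)
    m <- as.matrix(dist(pts))
    dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    m
  })
}

# Set-operation oracle for the pairwise partition: explicit species-name
# intersections/differences, scalar formulas per pair.
beta_oracle <- function(occ) {
  m <- as.matrix(occ[, -1]) > 0
  n <- nrow(m)
  sp <- colnames(occ)[-1]
  sor <- sim <- sne <- matrix(0, n, n, dimnames = list(occ$site_id, occ$site_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    si <- sp[m[i, ]]; sj <- sp[m[j, ]]
    a <- length(intersect(si, sj))
    b <- length(setdiff(si, sj))
    cc <- length(setdiff(sj, si))
    sor[i, j] <- (b + cc) / (2 * a + b + cc)
    sim[i, j] <- min(b, cc) / (a + min(b, cc))
    sne[i, j] <- sor[i, j] - sim[i, j]
  }
  list(sor = sor, sim = sim, sne = sne)
}

# Normal-equation OLS oracle on plain vectors.
ols_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(coef = drop(beta), r_squared = r2)
}

# Brute-force hierarchical partitioning: average incremental R^2 of each
# predictor over all k! orderings, with subset R^2 from the OLS oracle.
hier_part_oracle <- function(y, X) {
  k <- ncol(X)
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    ols_oracle(y, X[, cols, drop = FALSE])$r_squared
  }
  perms <- gtools_permutations(k)
  indep <- numeric(k)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    for (pos in seq_along(ord)) {
      before <- ord[seq_len(pos - 1)]
      indep[ord[pos]] <- indep[ord[pos]] +
        r2_of(c(before, ord[pos])) - r2_of(before)
    }
  }
  indep / nrow(perms)
}

# Minimal permutation enumerator (recursive) for oracle use.
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= k - 1) sub[, pos:(k - 1), drop = FALSE]
             else sub[, 0, drop = FALSE]
    cbind(left, k, right)
  }))
}

small_env <- function(n = 10, seed = 7) {
  withr::with_seed(seed, tibble::tibble(
    site_id = sprintf("s%02d", 1:n),
    ph = rnorm(n, 7.5, 0.3),
    conductivity = rnorm(n, 120, 20),
    water_depth = rnorm(n, 25, 6)
  ))
}

small_meta <- function(n = 10, seed = 7) {
  withr::with_seed(seed, tibble::tibble(
    site_id = sprintf("s%02d", 1:n),
    latitude = 29.3 + cumsum(runif(n, 0, 0.02)),
    longitude = 103.3 + cumsum(runif(n, 0, 0.02)),
    elevation = sort(runif(n, 485, 2865))
  ))
}
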