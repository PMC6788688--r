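test_that("LD computation handles duplicates, monomorphic variants and PSD repair", {
  set.seed(6)
  G <- matrix(rbinom(300, 2, 0.4), 100, 3)
  G <- cbind(G, G[, 1])           # duplicated column
  G <- cbind(G, 1L)               # monomorphic
  R <- compute_ld(G)
  expect_equal(ncol(R), 4)
  expect_equal(attr(R, "dropped"), 5L)
  expect_equal(diag(R), rep(1, 4))
  expect_equal(R[1, 4], 1)
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_error(compute_ld(G[1, , drop = FALSE]), "2 individuals")
  # independent variants have small correlations
  set.seed(7)
  G2 <- matrix(rbinom(1000 * 20, 2, 0.5), 1000, 20)
  R2 <- compute_ld(G2)
  off <- abs(R2[upper.tri(R2)])
  expect_gte(mean(off < 0.1), 0.9)
})

test_that("single-variant and symmetric posteriors behave as expected", {
  r1 <- caviar_posteriors(6, matrix(1, 1, 1), k = 1)
  expect_gt(r1$pip, 0.99)
  r2 <- caviar_posteriors(c(4, 4), diag(2), k = 2)
  expect_lt(abs(r2$pip[1] - r2$pip[2]), 1e-12)
  expect_equal(sum(r2$config_post), 1, tolerance = 1e-10)
})

test_that("configuration posteriors equal the exhaustive 2^m oracle", {
  set.seed(9)
  for (m in c(4, 8)) {
    A <- matrix(rnorm(m * m), m)
    S <- cov2cor(crossprod(A) + diag(m))
    z <- rnorm(m, 0, 2)
    z[2] <- 5
    got <- caviar_posteriors(z, S, k = m, gamma = 0.05, sigma = 5.2)
    want <- oracle_caviar(z, S, gamma = 0.05, sigma = 5.2)
    expect_lt(max(abs(got$pip - want$pip)), 1e-10)
    expect_equal(sum(got$config_post), 1, tolerance = 1e-10)
  }
})

test_that("PIP grows with |Z| when everything else is fixed", {
  S <- cov2cor(matrix(c(1, .3, .2, .3, 1, .4, .2, .4, 1), 3))
  pips <- sapply(c(2, 4, 6), function(zz)
    caviar_posteriors(c(zz, 1, 1), S, k = 2)$pip[1])
  expect_true(all(diff(pips) > 0))
})

test_that("credible sets are the smallest PIP-ordered sets carrying the mass", {
  # constructed posteriors: one dominant variant
  res <- structure(list(pip = c(0.995, 0.004, 0.001),
                        configs = list(integer(0), 1L, 2L, 3L),
                        config_post = c(0.0, 0.995, 0.004, 0.001),
                        positions = 1:3),
                   class = "finemap_result")
  expect_equal(as.integer(credible_set(res, 0.99)), 1L)
  # uniform posteriors over m singletons -> ceiling(rho * m) variants
  m <- 10
  resu <- structure(list(pip = rep(1 / m, m),
                         configs = c(list(integer(0)), as.list(1:m)),
                         config_post = c(0, rep(1 / m, m)),
                         positions = 1:m),
                    class = "finemap_result")
  for (rho in c(0.5, 0.8, 0.99))
    expect_length(credible_set(resu, rho), ceiling(rho * m))
  # rho = 0 edge returns the top variant, invalid rho errors
  expect_equal(as.integer(credible_set(res, 0)), 1L)
  expect_error(credible_set(res, 1), "rho")
})

test_that("CLPP is the PIP product, bounded by both margins", {
  mk <- function(pip) structure(list(pip = pip, positions = seq_along(pip)),
                                class = "finemap_result")
  out <- clpp(mk(c(1, 0, 0.8)), mk(c(1, 0.9, 0.5)))
  expect_equal(out$clpp, c(1, 0, 0.4))
  expect_true(all(out$clpp <= pmin(out$pip1, out$pip2) + 1e-12))
  expect_true(out$colocalized[1] && !out$colocalized[3])
  expect_error(clpp(mk(c(1, 0)), mk(c(1, 0, 0))), "mismatch")
})

test_that("a pleiotropic causal variant carries the maximum CLPP in most regions", {
  set.seed(23)
  n <- 600
  m <- 50
  top <- logical(20)
  for (r in 1:20) {
    Z0 <- matrix(rnorm(n * m), n, m)
    for (j in 2:m) Z0[, j] <- 0.8 * Z0[, j - 1] + sqrt(1 - 0.8^2) * Z0[, j]
    G <- (Z0 > -0.2) + (matrix(rnorm(n * m), n, m) + 0.8 * Z0 > -0.2)
    ld <- compute_ld(G)
    if (length(attr(ld, "dropped"))) next
    causal <- sample(m, 1)
    g <- G[, causal]
    b <- 6 / (sd(g) * sqrt(n))
    y1 <- b * g + rnorm(n)
    y2 <- b * g + rnorm(n)
    zs <- function(y) sapply(1:m, function(j) {
      fit <- summary(lm(y ~ G[, j]))$coefficients
      fit[2, 1] / fit[2, 2]
    })
    r1 <- caviar_posteriors(zs(y1), ld, k = 2)
    r2 <- caviar_posteriors(zs(y2), ld, k = 2)
    top[r] <- which.max(clpp(r1, r2)$clpp) == causal
  }
  expect_gte(mean(top), 0.9)
})

test_that("fine-mapping the simulated cross region ranks the planted variant first", {
  map <- build_genetic_map(1, 31, 4, seed = 61)
  cfg <- cross_config(n_f2 = 800, n_f1 = 30, seed = 62)
  cr <- simulate_cross(cfg, map)
  ph <- simulate_phenotypes(cr)
  X <- covariate_design(cr$pedigree[cr$f2_rows, ])
  A <- kinship_from_pedigree(cr$pedigree)[cr$f2_rows, cr$f2_rows]
  Ae <- eigen(A, symmetric = TRUE)
  G <- genotype_matrix(cr)
  R <- compute_ld(G)
  fp1 <- fit_polygenic(ph$trait1, X, A, A_eig = Ae)
  fp2 <- fit_polygenic(ph$trait2, X, A, A_eig = Ae)
  z1 <- assoc_zscores(grammar_scan(fp1$residuals, G))
  z2 <- assoc_zscores(grammar_scan(fp2$residuals, G))
  r1 <- caviar_posteriors(z1, R, k = 2, positions = cr$map$bp)
  r2 <- caviar_posteriors(z2, R, k = 2, positions = cr$map$bp)
  ci <- cr$qtl$marker
  expect_equal(which.max(r1$pip), ci)
  expect_true(ci %in% credible_set(r1, 0.99))
  expect_equal(which.max(clpp(r1, r2)$clpp), ci)
})
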