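test_that("genetic map construction is monotone, even-spaced and deterministic", {
  m1 <- build_genetic_map(1, 2, 10, seed = 1)
  expect_equal(nrow(m1), 2)
  expect_equal(diff(m1$cM), 10)

  m2 <- build_genetic_map(18, 50, 2, seed = 7)
  expect_equal(nrow(m2), 900)
  for (cc in unique(m2$chrom)) {
    sub <- m2[m2$chrom == cc, ]
    expect_true(all(diff(sub$cM) > 0))
    expect_true(all(diff(sub$bp) > 0))
  }
  expect_identical(m2, build_genetic_map(18, 50, 2, seed = 7))

  expect_error(build_genetic_map(0, 5, 1), "counts")
  expect_error(build_genetic_map(1, 5, -1), "spacing")
})

test_that("Kosambi map function matches its closed form and limits", {
  expect_equal(kosambi_recombination(0), 0)
  expect_equal(kosambi_recombination(10), 0.5 * tanh(0.2), tolerance = 1e-12)
  expect_equal(kosambi_recombination(10), 0.09869, tolerance = 1e-4)
  expect_equal(kosambi_recombination(1000), 0.5, tolerance = 1e-9)
  expect_error(kosambi_recombination(-1), "distance")
  r <- kosambi_recombination(seq(0, 100, 5))
  expect_true(all(diff(r) > 0) && all(r < 0.5))
})

test_that("simulated crosses are Mendelian-consistent with correct F1 genotypes", {
  fx <- small_cross()
  cr <- fx$cross
  # Q fixed in breed B -> all F1 heterozygous Q/q
  f1 <- cr$pedigree$generation == 1L
  expect_true(all(cr$qtl$q_count[f1] == 1L))
  G <- (cr$H1 == 2L) + (cr$H2 == 2L)
  md <- check_mendelian(G, cr$pedigree)
  expect_equal(sum(md$errors), 0)
  # truth QTL genotype consistent with transmitted haplotypes
  expect_identical(cr$qtl$q_count,
                   (cr$H1[, cr$qtl$marker] == 2L) + (cr$H2[, cr$qtl$marker] == 2L))
})

test_that("same seed reproduces the cross bit-identically", {
  fx <- small_cross()
  cr2 <- simulate_cross(fx$cfg, fx$map)
  expect_identical(fx$cross$H1, cr2$H1)
  expect_identical(fx$cross$O2, cr2$O2)
  expect_identical(fx$cross$pedigree, cr2$pedigree)
})

test_that("F2 QTL genotypes segregate 1:2:1", {
  fx <- small_cross()
  q <- fx$cross$qtl$q_count[fx$cross$f2_rows]
  n <- length(q)
  # each genotype within 3 binomial SEs of its expectation
  for (g in 0:2) {
    p0 <- c(0.25, 0.5, 0.25)[g + 1]
    expect_lt(abs(mean(q == g) - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  expect_gt(chisq.test(tabulate(q + 1, 3), p = c(1, 2, 1) / 4)$p.value, 0.001)
})

test_that("a near-zero-length map gives unrecombined parental gametes", {
  map <- build_genetic_map(1, 5, 1e-7, seed = 2)
  cfg <- cross_config(n_f2 = 50, n_f1 = 10, seed = 5)
  cr <- simulate_cross(cfg, map)
  ped <- cr$pedigree
  ok <- vapply(cr$f2_rows, function(i) {
    s <- ped$sire[i]
    pat <- cr$H1[i, ]
    identical(pat, cr$H1[s, ]) || identical(pat, cr$H2[s, ])
  }, TRUE)
  expect_true(all(ok))
})

test_that("phenotype model reproduces configured variances, additivity and correlation", {
  map <- build_genetic_map(1, 10, 5, seed = 4)
  # pure noise: trait variance ~ sigma_e2
  cfg <- cross_config(n_f2 = 1000, n_f1 = 20, a = c(0, 0), d = c(0, 0),
                      sigma_g2 = c(0, 0), sigma_e2 = c(1, 1), res_cor = 0.5,
                      sex_effect = c(0, 0), batch_sd = 0, cw_slope = c(0, 0),
                      seed = 6)
  cr <- simulate_cross(cfg, map)
  ph <- simulate_phenotypes(cr)
  expect_lt(abs(var(ph$trait1) - 1), 0.1)
  expect_lt(abs(cor(ph$trait1, ph$trait2) - 0.5), 0.1)

  # additive QTL: heterozygote mean at the homozygote midpoint
  cfg2 <- cross_config(n_f2 = 1000, n_f1 = 20, a = c(1, 1), d = c(0, 0),
                       sigma_g2 = c(0, 0), sigma_e2 = c(0.5, 0.5),
                       sex_effect = c(0, 0), batch_sd = 0, cw_slope = c(0, 0),
                       seed = 7)
  cr2 <- simulate_cross(cfg2, map)
  ph2 <- simulate_phenotypes(cr2)
  q <- cr2$qtl$q_count[cr2$f2_rows]
  mid <- (mean(ph2$trait1[q == 2]) + mean(ph2$trait1[q == 0])) / 2
  se <- sqrt(var(ph2$trait1[q == 1]) / sum(q == 1) +
               var(ph2$trait1[q == 2]) / (4 * sum(q == 2)) +
               var(ph2$trait1[q == 0]) / (4 * sum(q == 0)))
  expect_lt(abs(mean(ph2$trait1[q == 1]) - mid), 3 * se)
})

test_that("variant panel holds the planted causal variant and respects edge cases", {
  fx <- small_cross()
  vp <- simulate_variant_panel(fx$cross, seed = 5)
  pan <- vp$panel
  expect_equal(nrow(pan$variants), 200)
  expect_true(pan$causal_pos %in% pan$variants$pos)
  expect_equal(pan$causal_pos, fx$cross$qtl$bp)
  # causal variant genotypes mirror truth QTL genotypes
  ci <- which(pan$variants$pos == pan$causal_pos)
  qc <- fx$cross$qtl$q_count[pan$sample_rows]
  expect_identical(unname(pan$gt[ci, ]), c("0/0", "0/1", "1/1")[qc + 1])
  # deterministic
  vp2 <- simulate_variant_panel(fx$cross, seed = 5)
  expect_identical(pan$variants, vp2$panel$variants)
  expect_identical(pan$gt, vp2$panel$gt)
  # empty panel
  vp0 <- simulate_variant_panel(fx$cross, n_variants = 0, seed = 1)
  expect_equal(nrow(vp0$panel$variants), 0)
  # region too small
  expect_error(simulate_variant_panel(fx$cross,
                                      region = c(fx$cross$qtl$bp,
                                                 fx$cross$qtl$bp + 10),
                                      n_variants = 50, seed = 1),
               "region too small")
})

test_that("sire QTL genotypes can be conditioned for MASA designs", {
  fx <- masa_cross()
  truth <- fx$cross$qtl$sire_truth
  expect_equal(sum(truth == "het"), 8)
  expect_equal(sum(truth == "hom"), 4)
  G <- (fx$cross$H1 == 2L) + (fx$cross$H2 == 2L)
  expect_equal(sum(check_mendelian(G, fx$cross$pedigree)$errors), 0)
})
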