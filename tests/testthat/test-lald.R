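make_toy_cross <- function(H1, H2, cM = NULL) {
  M <- ncol(H1)
  map <- data.frame(chrom = "1", name = paste0("m", 1:M),
                    cM = cM %||% seq(0, by = 1, length.out = M),
                    bp = seq(1e6, by = 1e6, length.out = M),
                    stringsAsFactors = FALSE)
  list(map = map, H1 = H1, H2 = H2, f2_rows = seq_len(nrow(H1)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window-identity clustering separates breeds and is deterministic", {
  # all haplotypes identical -> one cluster
  H <- matrix(1L, 10, 7)
  cr <- make_toy_cross(H, H)
  a <- assign_haplotype_clusters(cr, "1", 3, window_markers = 5, K = 20)
  expect_equal(a$K_eff, 1)
  # two fixed breeds -> exactly two clusters separating them
  H1 <- matrix(1L, 10, 7)
  H2 <- matrix(2L, 10, 7)
  cr2 <- make_toy_cross(H1, H2)
  a2 <- assign_haplotype_clusters(cr2, "1", 3, window_markers = 5, K = 20)
  expect_equal(a2$K_eff, 2)
  expect_true(all(a2$cluster[, 1] != a2$cluster[, 2]))
  # deterministic on real data, and capped at K
  fx <- small_cross()
  b1 <- assign_haplotype_clusters(fx$cross, "1", 20, K = 6)
  b2 <- assign_haplotype_clusters(fx$cross, "1", 20, K = 6)
  expect_identical(b1, b2)
  expect_lte(b1$K_eff, 6)
  expect_error(assign_haplotype_clusters(fx$cross, "1", 1e6), "outside")
})

test_that("LOD-drop intervals match hand-computed geometry", {
  prof <- data.frame(bp = 1:11 * 1000,
                     lod = c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0))
  iv <- lod_drop_interval(prof, drop = 2, chrom = "1")
  expect_equal(iv$start, 4000)  # outermost positions with LOD >= 3
  expect_equal(iv$end, 8000)
  # single spike
  sp <- data.frame(bp = 1:5 * 1000, lod = c(0, 0, 10, 0, 0))
  iv2 <- lod_drop_interval(sp, drop = 2)
  expect_equal(c(iv2$start, iv2$end), c(3000, 3000))
  # flat profile spans the region and is flagged
  fl <- data.frame(bp = 1:5 * 1000, lod = rep(1, 5))
  iv3 <- lod_drop_interval(fl, drop = 2)
  expect_equal(c(iv3$start, iv3$end), c(1000, 5000))
  expect_true(attr(iv3, "flat"))
  expect_error(lod_drop_interval(prof, drop = 0), "drop")
})

test_that("interval intersection reproduces the printed critical-region arithmetic", {
  lk <- genomic_interval("12", 54842795, 55561243)
  dk <- genomic_interval("12", 55073130, 55931714)
  expect_equal(interval_length_kb(lk), 718.4)
  expect_equal(interval_length_kb(dk), 858.6)
  shared <- intersect_intervals(lk, dk)
  expect_equal(shared$interval$start, 55073130)
  expect_equal(shared$interval$end, 55561243)
  expect_equal(shared$length_kb, 488.1)
  # identity and disjoint edges
  self <- intersect_intervals(lk, lk)
  expect_equal(self$length_kb, interval_length_kb(lk))
  far <- intersect_intervals(lk, genomic_interval("12", 60000000, 60001000))
  expect_equal(far$length_kb, 0)
  expect_true(is.na(far$interval$start))
  expect_error(intersect_intervals(lk, genomic_interval("1", 1, 2)),
               "different chromosomes")
})

test_that("the mixed-model scan localizes the QTL and a cofactor removes it", {
  fx <- small_cross()
  sc <- lald_scan(fx$cross, fx$pheno$trait1, covariates = fx$X,
                  A_eig = fx$A_eig)
  expect_gt(sc$max_lod, 3)
  expect_lt(abs(sc$argmax_cM - fx$cross$map$cM[fx$cross$qtl$marker]), 10)
  # LOD >= 0 everywhere and the interval contains the argmax
  expect_true(all(sc$profile$lod >= 0))
  iv <- lod_drop_interval(sc, drop = 2, chrom = "1")
  expect_true(iv$start <= sc$argmax_bp && sc$argmax_bp <= iv$end)
  # widening the drop never shrinks the interval
  iv3 <- lod_drop_interval(sc, drop = 3, chrom = "1")
  expect_true(iv3$start <= iv$start && iv3$end >= iv$end)
  # conditioning on the detected QTL removes the signal
  cof <- lald_scan(fx$cross, fx$pheno$trait1, covariates = fx$X,
                   A_eig = fx$A_eig, cofactor_position = sc$argmax_cM)
  expect_lt(cof$max_lod, 3)
})

test_that("LOD at the QTL grows with the simulated effect size", {
  map <- build_genetic_map(1, 30, 3, seed = 13)
  lods <- sapply(c(0.3, 0.8, 1.6), function(aa) {
    cfg <- cross_config(n_f2 = 250, n_f1 = 16, a = c(aa, aa), seed = 17)
    cr <- simulate_cross(cfg, map)
    ph <- simulate_phenotypes(cr)
    lald_scan(cr, ph$trait1)$max_lod
  })
  expect_true(all(diff(lods) > 0))
})

test_that("haplotype-effect bimodality verdicts match construction", {
  set.seed(2)
  bi <- haplotype_effect_bimodality(c(rnorm(10, -1, 0.1), rnorm(10, 1, 0.1)))
  expect_true(bi$bimodal)
  expect_lt(abs(diff(sort(bi$means)) - 2), 0.3)
  expect_false(haplotype_effect_bimodality(rep(3, 10))$bimodal)
  expect_error(haplotype_effect_bimodality(c(1, 2, 3)), "at least 4")
  # specificity: a single Gaussian is rarely called bimodal
  set.seed(31)
  calls <- replicate(100, haplotype_effect_bimodality(rnorm(20))$bimodal)
  expect_gte(mean(!calls), 0.9)
})

test_that("cluster effects straddle the planted allele contrast", {
  fx <- small_cross()
  sc <- lald_scan(fx$cross, fx$pheno$trait1, covariates = fx$X,
                  A_eig = fx$A_eig)
  # fitted effects split into two groups on opposite sides of zero
  # (Q-bearing vs q-bearing clusters); BLUP shrinkage compresses the
  # separation, so the fixed 2-SD rule is used rather than the calibrated one
  bi <- haplotype_effect_bimodality(sc$effects, threshold = 2)
  expect_true(bi$bimodal)
  expect_true(prod(sign(bi$means)) < 0)
})
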