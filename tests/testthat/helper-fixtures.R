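# Shared simulated fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

# small two-chromosome cross with a strong QTL, used across module tests
small_cross <- function() {
  if (is.null(.fix$small)) {
    map <- build_genetic_map(2, 40, 2, seed = 11)
    cfg <- cross_config(n_f2 = 300, n_f1 = 24, seed = 3)
    cr <- simulate_cross(cfg, map)
    ph <- simulate_phenotypes(cr)
    A <- kinship_from_pedigree(cr$pedigree)[cr$f2_rows, cr$f2_rows]
    .fix$small <- list(map = map, cfg = cfg, cross = cr, pheno = ph,
                       A = A, A_eig = eigen(A, symmetric = TRUE),
                       X = covariate_design(cr$pedigree[cr$f2_rows, ]))
  }
  .fix$small
}

# 12-sire family cross (8 heterozygous, 4 homozygous) for MASA tests
masa_cross <- function(seed = 21, n_per_family = 80) {
  key <- sprintf("masa_%d_%d", seed, n_per_family)
  if (is.null(.fix[[key]])) {
    map <- build_genetic_map(1, 40, 2, seed = 31)
    cfg <- cross_config(n_f2 = 12 * n_per_family, n_f1 = 24,
                        sire_qtl = c(rep("het", 8), rep("hom", 4)),
                        seed = seed)
    cr <- simulate_cross(cfg, map)
    ph <- simulate_phenotypes(cr)
    .fix[[key]] <- list(map = map, cfg = cfg, cross = cr, pheno = ph)
  }
  .fix[[key]]
}
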