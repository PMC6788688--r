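# Shared configuration for the analysis drivers.
#
# Two synthetic intercrosses emulate the study design: a large cross
# between a Western commercial breed and a native breed ("LK-like") and a
# smaller replication cross ("DK-like"), genotyped on a shared chip map,
# with one pleiotropic QTL planted on chromosome 1 and mirrored as a 6-bp
# promoter deletion in the sequence-variant panels.  Sizes are scaled to
# desk hardware; the statistical structure (two divergent crosses, mixed
# het/hom F1 sires, ~25% QTL variance) follows the study design.

library(crossfsv)

RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

study_map <- function() build_genetic_map(2, 70, 1, seed = 1001)
masa_map <- function() build_genetic_map(1, 40, 2, seed = 1002)

lk_config <- function() cross_config(
  n_f2 = 1000, n_f1 = 40, n_f0_sires = 17, n_f0_dams = 19, seed = 2001)

dk_config <- function() cross_config(
  n_f2 = 380, n_f1 = 20, n_f0_sires = 9, n_f0_dams = 10, seed = 2002)

# crosses with a fixed 8-het / 4-hom and 4-het / 2-hom sire composition,
# used for MASA and the variant-filter cascade
lk_masa_config <- function() cross_config(
  n_f2 = 960, n_f1 = 24, sire_qtl = c(rep("het", 8), rep("hom", 4)),
  seed = 2003)
dk_masa_config <- function() cross_config(
  n_f2 = 400, n_f1 = 12, n_f0_sires = 9, n_f0_dams = 14,
  sire_qtl = c(rep("het", 4), rep("hom", 2)), seed = 2004)

build_study <- function(cfg, map = study_map()) {
  cr <- simulate_cross(cfg, map)
  ph <- simulate_phenotypes(cr)
  A <- kinship_from_pedigree(cr$pedigree)[cr$f2_rows, cr$f2_rows]
  list(cross = cr, pheno = ph, A = A,
       A_eig = eigen(A, symmetric = TRUE),
       X = covariate_design(cr$pedigree[cr$f2_rows, ]))
}
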