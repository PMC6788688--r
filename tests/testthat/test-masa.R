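toy_panel <- function(pos, ref, alt, gt, samples, chrom = "1") {
  structure(list(region = list(chrom = chrom, start = min(pos) - 10,
                               end = max(pos) + 10),
                 variants = data.frame(pos = pos, ref = ref, alt = alt,
                                       biallelic = !grepl(",", alt),
                                       stringsAsFactors = FALSE),
                 gt = matrix(gt, nrow = length(pos), byrow = TRUE,
                             dimnames = list(NULL, samples)),
                 samples = samples, causal_pos = NA_integer_,
                 cross_id = NA_character_),
            class = "variant_panel")
}

test_that("sire calls follow the log10 likelihood-ratio thresholds", {
  expect_equal(masa_call(3), "heterozygous")
  expect_equal(masa_call(0), "undetermined")
  expect_equal(masa_call(-3), "homozygous")
  expect_equal(masa_call(c(2, -2)), c("undetermined", "undetermined"))
  expect_equal(masa_call(2.001), "heterozygous")
})

test_that("MASA separates segregating from nonsegregating sires without wrong calls", {
  fx <- masa_cross()
  cr <- fx$cross
  qcM <- cr$map$cM[cr$qtl$marker]
  # allele substitution effect ~ a = 1 at the QTL
  calls <- masa_genotype_sires(cr, fx$pheno$trait1, qcM, effect_estimate = 1)
  truth <- cr$qtl$sire_truth[as.character(calls$sire)]
  wrong <- (calls$call == "heterozygous" & truth == "hom") |
    (calls$call == "homozygous" & truth == "het")
  expect_equal(sum(wrong), 0)
  # most sires correctly called or left undetermined, never miscalled
  correct_or_und <- (calls$call == "heterozygous" & truth == "het") |
    (calls$call == "homozygous" & truth == "hom") |
    calls$call == "undetermined"
  expect_gte(sum(correct_or_und), 10)
  expect_gte(sum(calls$call == "heterozygous" & truth == "het"), 6)
  expect_error(masa_genotype_sires(cr, fx$pheno$trait1, qcM, 1,
                                   min_offspring = 1000), "smaller")
})

test_that("the biallelic filter keeps exactly the two-allele variants", {
  smp <- c("F0_1", "S1", "S2")
  pan <- toy_panel(pos = c(10, 20, 30),
                   ref = c("A", "C", "G"), alt = c("T", "A,T", "C"),
                   gt = c("0/0", "0/1", "1/1",
                          "0/1", "1/2", "0/2",
                          "0/0", "0/0", "0/0"),   # monomorphic: one allele
                   samples = smp)
  st <- filter_biallelic(pan)
  expect_equal(st$variants$pos, 10)
  expect_equal(unname(st$stage_counts), c(3, 1))
})

test_that("the segregation-pattern filter enforces sire genotype classes", {
  smp <- c("S1", "S2", "S3", "S4")
  calls <- data.frame(sire = 1:4,
                      log10_lr = c(3, 4, -3, 0),
                      call = c("heterozygous", "heterozygous",
                               "homozygous", "undetermined"))
  pan <- toy_panel(pos = c(10, 20, 30, 40),
                   ref = "A", alt = "T",
                   gt = c("0/1", "0/1", "0/0", "1/1",  # match (S4 free)
                          "0/0", "0/1", "0/0", "0/1",  # hom in het sire
                          "0/1", "0/1", "0/1", "0/0",  # het in hom sire
                          "0/1", "0/1", NA, "0/0"),    # missing genotype
                   samples = smp)
  st <- filter_segregation_pattern(filter_biallelic(pan), calls)
  expect_equal(st$variants$pos, 10)
  expect_error(filter_segregation_pattern(filter_biallelic(pan),
                                          calls[calls$call == "undetermined", ]),
               "no called sires")
})

test_that("cross intersection matches by position and alleles", {
  smp <- "S1"
  a <- toy_panel(c(10, 20, 30), ref = "A", alt = "T",
                 gt = rep("0/1", 3), samples = smp)
  b <- toy_panel(c(20, 30, 40), ref = "A", alt = "T",
                 gt = rep("0/1", 3), samples = smp)
  sa <- filter_biallelic(a)
  sb <- filter_biallelic(b)
  shared <- intersect_crosses(sa, sb)
  expect_equal(shared$variants$pos, c(20, 30))
  # A subset of B returns A
  expect_equal(intersect_crosses(shared, sb)$variants$pos, c(20, 30))
  # disjoint sets are empty
  c2 <- toy_panel(c(100, 200), ref = "A", alt = "T", gt = rep("0/1", 2),
                  samples = smp)
  expect_equal(nrow(intersect_crosses(sa, filter_biallelic(c2))$variants), 0)
})

test_that("motif overlap respects BED conventions and deletion spans", {
  smp <- "S1"
  motifs <- data.frame(chrom = "1", start = 99, end = 200, label = "m")
  pan <- toy_panel(pos = c(150, 100, 99, 95, 201),
                   ref = c("A", "C", "G", "GACCTG", "T"),
                   alt = c("T", "A", "A", "G", "A"),
                   gt = rep("0/1", 5), samples = smp)
  st <- filter_motif_overlap(filter_biallelic(pan), motifs)
  # 150 inside; 100 at the BED start (0-based 99 = 1-based 100); 99 outside;
  # deletion at 95 spans 96-100 so it touches the motif; 201 outside
  expect_setequal(st$variants$pos, c(150, 100, 95))
  empty <- filter_motif_overlap(filter_biallelic(pan), motifs[0, ])
  expect_equal(nrow(empty$variants), 0)
})

test_that("stage counts are monotone and the first two stages commute", {
  fx <- small_cross()
  vp <- simulate_variant_panel(fx$cross, seed = 8, n_pattern_consistent = 10)
  calls <- data.frame(sire = fx$cross$f1_males,
                      log10_lr = 3,
                      call = "heterozygous", stringsAsFactors = FALSE)
  s1 <- filter_segregation_pattern(filter_biallelic(vp$panel), calls)
  expect_true(all(diff(unname(s1$stage_counts)) <= 0))
  # commuting the filters yields the same final variant set
  cand0 <- structure(c(vp$panel, list(stage_counts = c(input = 200))),
                     class = "fsv_candidate_set")
  s2 <- filter_biallelic(filter_segregation_pattern(cand0, calls))
  expect_setequal(s1$variants$pos, s2$variants$pos)
})

test_that("the full cascade returns exactly the planted causal variant", {
  fxA <- masa_cross()
  fxB <- masa_cross(seed = 22)
  qA <- fxA$cross$map$cM[fxA$cross$qtl$marker]
  vpA <- simulate_variant_panel(fxA$cross, seed = 41)
  vpB <- simulate_variant_panel(fxB$cross, seed = 42, motifs = vpA$motifs)
  callsA <- masa_genotype_sires(fxA$cross, fxA$pheno$trait1, qA, 1)
  callsB <- masa_genotype_sires(fxB$cross, fxB$pheno$trait1, qA, 1)
  cas <- fsv_cascade(vpA$panel, vpB$panel, callsA, callsB, vpA$motifs)
  expect_equal(cas$positions, vpA$panel$causal_pos)
  expect_true(all(diff(unname(cas$counts)) <= 0))
})
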