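#!/usr/bin/env Rscript
# Simulate the two intercrosses and export them in the standard formats
# (PED/MAP genotypes, TSV phenotypes and truth, VCF sequence-variant
# panels, BED motif track).

source("analysis/00_config.R")

map <- study_map()
lk <- build_study(lk_config(), map)
dk <- build_study(dk_config(), map)

outdir <- file.path(RESULTS, "data")
write_cross(lk$cross, lk$pheno, outdir, prefix = "lk")
write_cross(dk$cross, dk$pheno, outdir, prefix = "dk")

vp_lk <- simulate_variant_panel(lk$cross, seed = 3001)
vp_dk <- simulate_variant_panel(dk$cross, seed = 3002, motifs = vp_lk$motifs)
write_vcf_minimal(vp_lk$panel, file.path(outdir, "lk_region.vcf"))
write_vcf_minimal(vp_dk$panel, file.path(outdir, "dk_region.vcf"))
write_bed(vp_lk$motifs, file.path(outdir, "motifs.bed"))

cat(sprintf("LK cross: %d F2, QTL at chr%s:%d (marker %d), Q fixed in breed B\n",
            length(lk$cross$f2_rows), lk$cross$qtl$chrom, lk$cross$qtl$bp,
            lk$cross$qtl$marker))
cat(sprintf("DK cross: %d F2, same QTL position\n", length(dk$cross$f2_rows)))
cat(sprintf("variant panels: %d variants each, causal deletion at %d %s\n",
            nrow(vp_lk$panel$variants), vp_lk$panel$causal_pos,
            "(inside an MRF-binding-style motif)"))

# sanity: simulated genotypes are Mendelian-consistent
G <- (lk$cross$H1 == 2L) + (lk$cross$H2 == 2L)
md <- check_mendelian(G, lk$cross$pedigree)
cat(sprintf("Mendelian errors in LK cross: %d\n", sum(md$errors)))
qc <- qc_filter_markers(genotype_matrix(lk$cross))
cat(sprintf("marker QC on F2 genotypes: %d/%d retained\n",
            sum(qc$keep), length(qc$keep)))
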