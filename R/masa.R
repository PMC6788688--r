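# Marker-assisted segregation analysis (MASA): QTL-genotype calls for F1
# sires from their half-sib families, and the four-stage candidate-variant
# filter cascade (biallelic -> sire segregation pattern -> cross
# intersection -> motif overlap).

#' Call an F1 sire's QTL genotype from its log10 likelihood ratio
#'
#' Heterozygous if the score exceeds 2, homozygous if it is below -2,
#' undetermined in between.
#'
#' @param log10_lr log10 likelihood ratio score(s).
#' @param threshold decision threshold (default 2).
#' @return character: "heterozygous", "homozygous" or "undetermined".
#' @export
masa_call <- function(log10_lr, threshold = 2) {
  ifelse(log10_lr > threshold, "heterozygous",
         ifelse(log10_lr < -threshold, "homozygous", "undetermined"))
}

#' MASA: QTL-genotype likelihood-ratio calls for all F1 sires
#'
#' For each sire family the covariate-adjusted trait is modelled against
#' the paternal transmission probability at the tested position.  The
#' log10 likelihood ratio compares a fixed paternal-allele substitution
#' effect (`effect_estimate`, taken from the across-family analysis at the
#' same position; the sign is free because the phase of the sire's
#' haplotypes is arbitrary) against a zero effect.  The maternal
#' transmission probability is fitted as a nuisance covariate so the
#' dam-transmitted allele does not inflate the family residual.
#'
#' @param cross a `cross_data`.
#' @param trait numeric F2 trait vector.
#' @param pos_cM tested position (cM) on `chrom`.
#' @param effect_estimate allele-substitution effect from the
#'   across-family analysis.
#' @param covariates optional design matrix for all F2.
#' @param chrom chromosome (default the QTL chromosome).
#' @param min_offspring minimum family size; smaller families error.
#' @param threshold call threshold on the log10 LR.
#' @return data.frame: sire, n_offspring, log10_lr, call.
#' @export
masa_genotype_sires <- function(cross, trait, pos_cM, effect_estimate,
                                covariates = NULL,
                                chrom = cross$qtl$chrom,
                                min_offspring = 10, threshold = 2) {
  rows <- cross$f2_rows
  y <- as.numeric(trait)
  X <- if (is.null(covariates))
    covariate_design(cross$pedigree[rows, ]) else as.matrix(covariates)
  e <- stats::lm.fit(X, y)$residuals
  sel <- cross$map$chrom == chrom
  map_sub <- cross$map[sel, ]
  out <- lapply(cross$f1_males, function(s) {
    fam <- which(cross$pedigree$sire[rows] == s)
    if (length(fam) < min_offspring)
      stop("sire ", s, " family smaller than ", min_offspring)
    tA <- 1 - .origin_prob_B(cross$O1[rows[fam], sel, drop = FALSE],
                             map_sub, pos_cM)
    # maternal transmission probability absorbs the dam-allele contribution
    tM <- 1 - .origin_prob_B(cross$O2[rows[fam], sel, drop = FALSE],
                             map_sub, pos_cM)
    ef <- e[fam]
    nf <- length(fam)
    Xn <- cbind(1, tM)
    rss <- function(v) sum(stats::lm.fit(Xn, v)$residuals^2)
    rss0 <- rss(ef)
    rssb <- min(rss(ef - effect_estimate * tA),
                rss(ef + effect_estimate * tA))
    lr <- (nf / 2) * log10(rss0 / rssb)
    data.frame(sire = s, n_offspring = nf, log10_lr = lr,
               call = masa_call(lr, threshold), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- filter cascade ---------------------------------------------------

# observed allele indices at one variant from "a/b" genotype strings
.observed_alleles <- function(g) {
  g <- g[!is.na(g)]
  unique(unlist(strsplit(g, "/", fixed = TRUE)))
}

.new_candidate_set <- function(panel, keep = rep(TRUE, nrow(panel$variants)),
                               counts = c(input = nrow(panel$variants))) {
  structure(list(region = panel$region,
                 variants = panel$variants[keep, , drop = FALSE],
                 gt = panel$gt[keep, , drop = FALSE],
                 samples = panel$samples,
                 causal_pos = panel$causal_pos,
                 cross_id = panel$cross_id,
                 stage_counts = counts),
            class = "fsv_candidate_set")
}

#' Filter cascade stage 1: biallelic variants
#'
#' Retains variants with exactly two observed alleles across the founders
#' and F1 sires (a biallelic causal variant is implied by a bimodal
#' founder-haplotype effect distribution).
#'
#' @param panel a `variant_panel` or `fsv_candidate_set`.
#' @return `fsv_candidate_set` with updated `stage_counts`.
#' @export
filter_biallelic <- function(panel) {
  set <- if (inherits(panel, "fsv_candidate_set")) panel else
    .new_candidate_set(panel)
  v <- set$variants
  keep <- vapply(seq_len(nrow(v)), function(i)
    length(.observed_alleles(set$gt[i, ])) == 2, TRUE)
  counts <- c(set$stage_counts, biallelic = sum(keep))
  out <- .new_candidate_set(set, keep, counts)
  out
}

#' Filter cascade stage 2: sire segregation pattern
#'
#' Retains variants heterozygous in every heterozygous-called sire and
#' homozygous in every homozygous-called sire; undetermined sires impose
#' no constraint; a missing sire genotype fails the variant.
#'
#' @param candidates an `fsv_candidate_set`.
#' @param sire_calls data.frame from [masa_genotype_sires()].
#' @param sire_samples named character vector mapping sire id to panel
#'   sample name (default `S<id>` as written by the simulator).
#' @return filtered `fsv_candidate_set`.
#' @export
filter_segregation_pattern <- function(candidates, sire_calls,
                                       sire_samples = NULL) {
  called <- sire_calls[sire_calls$call != "undetermined", , drop = FALSE]
  if (!nrow(called)) stop("no called sires")
  if (is.null(sire_samples))
    sire_samples <- stats::setNames(sprintf("S%s", called$sire), called$sire)
  cols <- match(sire_samples[as.character(called$sire)], candidates$samples)
  if (any(is.na(cols))) stop("sire sample missing from panel")
  want_het <- called$call == "heterozygous"
  keep <- vapply(seq_len(nrow(candidates$variants)), function(i) {
    g <- candidates$gt[i, cols]
    if (any(is.na(g))) return(FALSE)
    al <- strsplit(g, "/", fixed = TRUE)
    het <- vapply(al, function(x) x[1] != x[2], TRUE)
    all(het == want_het)
  }, TRUE)
  counts <- c(candidates$stage_counts, pattern = sum(keep))
  .new_candidate_set(candidates, keep, counts)
}

#' Filter cascade stage 3: intersection of the two crosses
#'
#' Retains variants present (by position, REF and ALT) in both candidate
#' sets.
#'
#' @param setA,setB `fsv_candidate_set`s over the same reference region.
#' @return `fsv_candidate_set` based on `setA`.
#' @export
intersect_crosses <- function(setA, setB) {
  if (!identical(setA$region$chrom, setB$region$chrom))
    stop("candidate sets are on different reference regions")
  keyA <- with(setA$variants, paste(pos, ref, alt))
  keyB <- with(setB$variants, paste(pos, ref, alt))
  keep <- keyA %in% keyB
  counts <- c(setA$stage_counts, intersected = sum(keep))
  .new_candidate_set(setA, keep, counts)
}

#' Filter cascade stage 4: regulatory-motif overlap
#'
#' Retains variants whose affected span overlaps a motif interval.  SNPs
#' occupy their POS; for VCF-style deletions (REF longer than ALT) the
#' affected span is the deleted bases POS+1 .. POS+len(REF)-1.  Motifs are
#' BED convention (0-based half-open) and converted internally.
#'
#' @param candidates an `fsv_candidate_set`.
#' @param motifs motif track data.frame (chrom, start, end, BED
#'   convention).  An empty track yields an empty result.
#' @return filtered `fsv_candidate_set`.
#' @export
filter_motif_overlap <- function(candidates, motifs) {
  v <- candidates$variants
  if (!nrow(motifs)) {
    keep <- rep(FALSE, nrow(v))
  } else {
    m1 <- bed_to_1based(motifs$start, motifs$end)
    span_lo <- ifelse(nchar(v$ref) > 1, v$pos + 1, v$pos)
    span_hi <- v$pos + pmax(nchar(v$ref) - 1, 0)
    keep <- vapply(seq_len(nrow(v)), function(i)
      any(span_lo[i] <= m1$end & span_hi[i] >= m1$start), TRUE)
  }
  counts <- c(candidates$stage_counts, motif = sum(keep))
  .new_candidate_set(candidates, keep, counts)
}

#' Run the full four-stage FSV filter cascade on two crosses
#'
#' @param panelA,panelB `variant_panel`s for the two crosses.
#' @param callsA,callsB sire-call tables from [masa_genotype_sires()].
#' @param motifs motif track (BED convention).
#' @return list: `final` (`fsv_candidate_set` surviving all stages),
#'   `counts_A`, `counts_B` (per-stage counts up to the pattern stage for
#'   each cross), `positions` of the survivors.
#' @export
fsv_cascade <- function(panelA, panelB, callsA, callsB, motifs) {
  sA <- filter_segregation_pattern(filter_biallelic(panelA), callsA)
  sB <- filter_segregation_pattern(filter_biallelic(panelB), callsB)
  shared <- intersect_crosses(sA, sB)
  final <- filter_motif_overlap(shared, motifs)
  list(final = final, counts_A = sA$stage_counts, counts_B = sB$stage_counts,
       counts = final$stage_counts, positions = final$variants$pos)
}
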