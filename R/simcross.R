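# Synthetic two-cross F2 intercross generator.
#
# The generator emulates the data-generating process assumed by every
# downstream analysis: two divergent founder breeds crossed to F1, F1 x F1
# matings to a large F2 cohort, a dense SNP map, one biallelic QTL with a
# mostly additive, pleiotropic effect on two correlated traits, polygenic
# background from pedigree kinship, and a sequence-variant panel in the
# focal region containing a planted causal regulatory variant.

#' Build a synthetic genetic map
#'
#' Markers are evenly spaced in genetic distance (`mean_spacing_cM`) within
#' each chromosome; physical positions are proportional to genetic positions
#' at roughly 1 Mb/cM with multiplicative jitter, so the map is strictly
#' monotone in both scales.
#'
#' @param n_chromosomes number of chromosomes (autosomes).
#' @param markers_per_chromosome markers on each chromosome.
#' @param mean_spacing_cM genetic spacing between adjacent markers, in cM.
#' @param seed integer seed; the map is deterministic given the seed.
#' @return data.frame with columns `chrom`, `name`, `cM`, `bp`, one row per
#'   marker, ordered by chromosome then position.
#' @export
build_genetic_map <- function(n_chromosomes, markers_per_chromosome,
                              mean_spacing_cM, seed = 1L) {
  if (n_chromosomes < 1 || markers_per_chromosome < 1)
    stop("counts must be >= 1")
  if (mean_spacing_cM <= 0) stop("spacing must be > 0")
  set.seed(as.integer(seed))
  maps <- lapply(seq_len(n_chromosomes), function(cc) {
    m <- markers_per_chromosome
    cm <- (seq_len(m) - 1) * mean_spacing_cM
    gaps_bp <- round(c(0, diff(cm)) * 1e6 * stats::runif(m, 0.9, 1.1))
    gaps_bp[-1] <- pmax(gaps_bp[-1], 1)
    bp <- 100000 + cumsum(gaps_bp)
    data.frame(chrom = as.character(cc),
               name  = sprintf("chr%d_m%d", cc, seq_len(m)),
               cM = cm, bp = bp, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  map
}

#' Kosambi map function
#'
#' Converts genetic distance to recombination fraction allowing for
#' interference: r = tanh(2m)/2 with m the distance in Morgans.
#'
#' @param distance_cM genetic distance(s) in centiMorgans, >= 0.
#' @return recombination fraction(s) in [0, 0.5).
#' @export
kosambi_recombination <- function(distance_cM) {
  if (any(distance_cM < 0)) stop("distance must be >= 0")
  0.5 * tanh(2 * distance_cM / 100)
}

#' Configuration for a simulated F2 intercross
#'
#' Defaults emulate a Landrace x Korean-native-pig style cross: divergent
#' founder allele frequencies on a 60K-chip-like map, a biallelic QTL whose
#' high allele Q is absent in the Western breed and segregates at
#' intermediate frequency (0.65) in the native breed, mostly additive
#' pleiotropic effects on two correlated traits (redness-like and IMF-like),
#' polygenic variance from pedigree kinship, and fixed effects of sex,
#' batch and carcass weight.
#'
#' @param n_f0_sires,n_f0_dams founder counts for breed A (sires) and
#'   breed B (dams).
#' @param n_f1 F1 individuals (sexes alternate male/female).
#' @param n_f2 F2 individuals.
#' @param qtl_chrom,qtl_bp QTL location; the QTL is snapped to the nearest
#'   mapped marker (`qtl_bp = NULL` uses the middle marker of the
#'   chromosome).
#' @param a,d per-trait additive and dominance effects of the Q allele.
#' @param sigma_g2,sigma_e2 per-trait polygenic and residual variances.
#' @param res_cor residual correlation between the two traits.
#' @param mu per-trait intercepts.
#' @param sex_effect per-trait additive effect of male sex.
#' @param n_batches,batch_sd number of (cyclically assigned) batches and the
#'   SD of their random effects.
#' @param cw_slope per-trait slope on (centred) carcass weight.
#' @param cw_mean,cw_sd distribution of the carcass-weight covariate (kg).
#' @param freq_divergence mean absolute allele-frequency difference between
#'   founder breeds at chip markers.
#' @param qtl_freq_Q length-2 vector: frequency of Q in breed A and breed B.
#' @param sire_qtl optional character vector ("het"/"hom") forcing the QTL
#'   genotype of each F1 male by conditioning its founder dam's genotype;
#'   used to reproduce a fixed segregating/nonsegregating sire composition.
#' @param seed integer seed.
#' @return list of class `cross_config`.
#' @export
cross_config <- function(n_f0_sires = 17, n_f0_dams = 19,
                         n_f1 = 40, n_f2 = 1000,
                         qtl_chrom = "1", qtl_bp = NULL,
                         a = c(1, 1), d = c(0.2, 0.2),
                         sigma_g2 = c(0.6, 0.6), sigma_e2 = c(0.93, 0.93),
                         res_cor = 0.35, mu = c(0, 0),
                         sex_effect = c(0.3, 0.2),
                         n_batches = 4, batch_sd = 0.3,
                         cw_slope = c(0.01, 0.01), cw_mean = 85, cw_sd = 8,
                         freq_divergence = 0.6,
                         qtl_freq_Q = c(0.0, 1.0),
                         sire_qtl = NULL, seed = 1L) {
  stopifnot(all(sigma_g2 >= 0), all(sigma_e2 > 0), abs(res_cor) < 1,
            n_f0_sires >= 1, n_f0_dams >= 1, n_f1 >= 2, n_f2 >= 1)
  cfg <- list(n_f0_sires = n_f0_sires, n_f0_dams = n_f0_dams,
              n_f1 = n_f1, n_f2 = n_f2,
              qtl_chrom = as.character(qtl_chrom), qtl_bp = qtl_bp,
              a = a, d = d, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
              res_cor = res_cor, mu = mu, sex_effect = sex_effect,
              n_batches = n_batches, batch_sd = batch_sd,
              cw_slope = cw_slope, cw_mean = cw_mean, cw_sd = cw_sd,
              freq_divergence = freq_divergence, qtl_freq_Q = qtl_freq_Q,
              sire_qtl = sire_qtl, seed = as.integer(seed))
  class(cfg) <- "cross_config"
  cfg
}

# One meiosis over the whole map: interference-free, per-interval
# recombination from the Kosambi distance, 0.5 at chromosome boundaries
# (independent strand restart).  Returns gamete allele and origin vectors.
.meiosis <- function(h1, h2, o1, o2, r_between) {
  switch_ <- stats::runif(length(r_between)) < r_between
  strand <- 1L + cumsum(switch_) %% 2L
  s1 <- strand == 1L
  list(h = ifelse(s1, h1, h2), o = ifelse(s1, o1, o2))
}

# Inter-marker recombination vector for a map (first element per chromosome
# is 0.5 so each chromosome starts on a random strand).
.map_recomb <- function(map) {
  d <- c(0, diff(map$cM))
  newchrom <- c(TRUE, map$chrom[-1] != map$chrom[-nrow(map)])
  d[newchrom] <- 0
  r <- kosambi_recombination(d)
  r[newchrom] <- 0.5
  r
}

#' Simulate one F2 intercross
#'
#' Founder haplotypes are drawn from breed-specific allele frequencies,
#' gametes are formed by interference-free meiosis with per-interval
#' Kosambi recombination fractions, and founder-breed origin labels are
#' carried along as truth.  Fixed-effect covariates (sex, batch, carcass
#' weight) are attached to the pedigree; phenotypes are added by
#' [simulate_phenotypes()].
#'
#' @param config a [cross_config()].
#' @param map a genetic map from [build_genetic_map()].
#' @return list of class `cross_data` with elements `map`, `pedigree`
#'   (id, sire, dam, generation, sex, batch, carcass_weight, breed),
#'   phased haplotype matrices `H1`/`H2` (alleles 1/2; row per individual,
#'   column per marker; H1 = paternal gamete) with origin matrices
#'   `O1`/`O2` (1 = breed A, 2 = breed B), `f2_rows`, and `qtl` truth
#'   (marker index, position, per-individual Q count, per-F1-male call).
#' @export
simulate_cross <- function(config, map) {
  stopifnot(inherits(config, "cross_config"))
  .validate_map(map)
  set.seed(config$seed)
  M <- nrow(map)
  on_chr <- which(map$chrom == config$qtl_chrom)
  if (!length(on_chr)) stop("QTL chromosome not on map")
  qm <- if (is.null(config$qtl_bp)) on_chr[ceiling(length(on_chr) / 2)] else
    on_chr[which.min(abs(map$bp[on_chr] - config$qtl_bp))]
  qtl_bp <- map$bp[qm]

  # breed allele frequencies (allele 2 = alternative; at the QTL, allele 2 = Q)
  p0 <- stats::runif(M, 0.1, 0.9)
  half <- config$freq_divergence / 2
  sgn <- sample(c(-1, 1), M, replace = TRUE)
  fA <- pmin(pmax(p0 - sgn * half, 0), 1)
  fB <- pmin(pmax(p0 + sgn * half, 0), 1)
  fA[qm] <- config$qtl_freq_Q[1]
  fB[qm] <- config$qtl_freq_Q[2]

  n0 <- config$n_f0_sires + config$n_f0_dams
  n1 <- config$n_f1
  n2 <- config$n_f2
  n <- n0 + n1 + n2
  H1 <- H2 <- O1 <- O2 <- matrix(0L, n, M)

  idxA <- seq_len(config$n_f0_sires)
  idxB <- config$n_f0_sires + seq_len(config$n_f0_dams)
  for (i in idxA) {
    H1[i, ] <- 1L + (stats::runif(M) < fA)
    H2[i, ] <- 1L + (stats::runif(M) < fA)
    O1[i, ] <- O2[i, ] <- 1L
  }
  for (i in idxB) {
    H1[i, ] <- 1L + (stats::runif(M) < fB)
    H2[i, ] <- 1L + (stats::runif(M) < fB)
    O1[i, ] <- O2[i, ] <- 2L
  }

  # F1: breed-A sires x breed-B dams, sexes alternating male first
  f1_idx <- n0 + seq_len(n1)
  f1_sex <- rep_len(c(1L, 2L), n1)
  f1_males <- f1_idx[f1_sex == 1L]
  f1_sire <- rep_len(idxA, n1)
  f1_dam <- rep_len(idxB, n1)
  if (!is.null(config$sire_qtl)) {
    calls <- rep_len(config$sire_qtl, length(f1_males))
    if (length(f1_males) > length(idxB))
      stop("sire_qtl conditioning needs one founder dam per F1 male")
    # give each F1 male its own founder dam and fix QTL genotypes so the
    # male's QTL genotype is determined (breed A fixed q/q)
    for (i in idxA) H1[i, qm] <- H2[i, qm] <- 1L
    f1_dam[f1_sex == 1L] <- idxB[seq_along(f1_males)]
    for (k in seq_along(f1_males)) {
      dk <- f1_dam[f1_sex == 1L][k]
      al <- if (calls[k] == "het") 2L else 1L
      H1[dk, qm] <- H2[dk, qm] <- al
    }
  }
  r_between <- .map_recomb(map)
  for (k in seq_len(n1)) {
    i <- f1_idx[k]; s <- f1_sire[k]; dd <- f1_dam[k]
    g <- .meiosis(H1[s, ], H2[s, ], O1[s, ], O2[s, ], r_between)
    H1[i, ] <- g$h; O1[i, ] <- g$o
    g <- .meiosis(H1[dd, ], H2[dd, ], O1[dd, ], O2[dd, ], r_between)
    H2[i, ] <- g$h; O2[i, ] <- g$o
  }

  # F2: F1 males x F1 females; contiguous, near-equal sire families
  f1_females <- f1_idx[f1_sex == 2L]
  if (!length(f1_males) || !length(f1_females))
    stop("need at least one F1 male and one F1 female")
  f2_idx <- n0 + n1 + seq_len(n2)
  f2_sire <- sort(rep_len(f1_males, n2))
  f2_dam <- sample(rep_len(f1_females, n2))
  for (k in seq_len(n2)) {
    i <- f2_idx[k]; s <- f2_sire[k]; dd <- f2_dam[k]
    g <- .meiosis(H1[s, ], H2[s, ], O1[s, ], O2[s, ], r_between)
    H1[i, ] <- g$h; O1[i, ] <- g$o
    g <- .meiosis(H1[dd, ], H2[dd, ], O1[dd, ], O2[dd, ], r_between)
    H2[i, ] <- g$h; O2[i, ] <- g$o
  }

  pedigree <- data.frame(
    id = seq_len(n),
    sire = c(rep(0L, n0), f1_sire, f2_sire),
    dam = c(rep(0L, n0), f1_dam, f2_dam),
    generation = rep(c(0L, 1L, 2L), c(n0, n1, n2)),
    sex = c(rep(1L, config$n_f0_sires), rep(2L, config$n_f0_dams),
            f1_sex, rep_len(c(1L, 2L), n2)),
    batch = c(rep(1L, n0 + n1),
              ((seq_len(n2) - 1L) %/% 2L) %% config$n_batches + 1L),
    carcass_weight = c(rep(NA_real_, n0 + n1),
                       stats::rnorm(n2, config$cw_mean, config$cw_sd)),
    stringsAsFactors = FALSE)
  pedigree$breed <- c(rep(c("A", "B"), c(config$n_f0_sires, config$n_f0_dams)),
                      rep(NA_character_, n1 + n2))

  q_count <- (H1[, qm] == 2L) + (H2[, qm] == 2L)
  sire_truth <- ifelse(q_count[f1_males] == 1L, "het", "hom")
  names(sire_truth) <- f1_males

  structure(list(map = map, pedigree = pedigree,
                 H1 = H1, H2 = H2, O1 = O1, O2 = O2,
                 f2_rows = f2_idx, f1_males = f1_males,
                 qtl = list(marker = qm, chrom = config$qtl_chrom,
                            bp = qtl_bp, q_count = q_count,
                            sire_truth = sire_truth),
                 config = config),
            class = "cross_data")
}

.validate_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("chrom", "name", "cM", "bp") %in% names(map)))
  for (cc in unique(map$chrom)) {
    sub <- map[map$chrom == cc, ]
    if (any(diff(sub$cM) <= 0) || any(diff(sub$bp) <= 0))
      stop("map positions must be strictly increasing within a chromosome")
    if (any(sub$cM < 0)) stop("genetic positions must be >= 0")
  }
  invisible(TRUE)
}

#' Genotype matrix (additive coding) for a cross
#'
#' @param cross a `cross_data`.
#' @param rows individual rows (default F2 only).
#' @return integer matrix of counts of allele 2, individuals x markers.
#' @export
genotype_matrix <- function(cross, rows = cross$f2_rows) {
  g <- (cross$H1[rows, , drop = FALSE] == 2L) +
       (cross$H2[rows, , drop = FALSE] == 2L)
  colnames(g) <- cross$map$name
  rownames(g) <- cross$pedigree$id[rows]
  g
}

#' Simulate phenotypes for the F2 cohort
#'
#' Trait model: y = mu + sex + batch + beta * carcass_weight
#' + a * x_add + d * x_dom + u + e, with x_add in {-1, 0, 1} the centred Q
#' count, x_dom the heterozygosity indicator, u multivariate normal with
#' covariance A * sigma_g2 (A the pedigree relationship matrix) and e
#' bivariate normal with the configured cross-trait correlation.
#'
#' @param cross a `cross_data`.
#' @param config the [cross_config()] used to build it.
#' @param seed seed for the phenotype draw (defaults to `config$seed + 1`).
#' @return data.frame: id, sire, dam, sex, batch, carcass_weight, trait1,
#'   trait2 for each F2, with the truth genotype codes attached as
#'   attributes `x_add` and `x_dom`.
#' @export
simulate_phenotypes <- function(cross, config = cross$config,
                                seed = config$seed + 1L) {
  if (is.null(cross$qtl$q_count)) stop("missing truth QTL genotypes")
  set.seed(as.integer(seed))
  ped <- cross$pedigree
  A <- kinship_from_pedigree(ped[, c("id", "sire", "dam")])
  L <- chol(A + diag(1e-8, nrow(A)))
  n <- nrow(ped)
  U <- cbind(sqrt(config$sigma_g2[1]) * crossprod(L, stats::rnorm(n)),
             sqrt(config$sigma_g2[2]) * crossprod(L, stats::rnorm(n)))

  f2 <- cross$f2_rows
  n2 <- length(f2)
  Se <- diag(sqrt(config$sigma_e2)) %*%
    matrix(c(1, config$res_cor, config$res_cor, 1), 2) %*%
    diag(sqrt(config$sigma_e2))
  E <- matrix(stats::rnorm(n2 * 2), n2, 2) %*% chol(Se)
  batch_eff <- stats::rnorm(config$n_batches, 0, config$batch_sd)

  q <- cross$qtl$q_count[f2]
  x_add <- q - 1L
  x_dom <- as.integer(q == 1L)
  cw <- ped$carcass_weight[f2]
  cwc <- cw - mean(cw)
  y <- sapply(1:2, function(t) {
    config$mu[t] + config$sex_effect[t] * (ped$sex[f2] == 1L) +
      batch_eff[ped$batch[f2]] + config$cw_slope[t] * cwc +
      config$a[t] * x_add + config$d[t] * x_dom + U[f2, t] + E[, t]
  })
  out <- data.frame(id = ped$id[f2], sire = ped$sire[f2], dam = ped$dam[f2],
                    sex = ped$sex[f2], batch = ped$batch[f2],
                    carcass_weight = cw,
                    trait1 = y[, 1], trait2 = y[, 2])
  attr(out, "x_add") <- x_add
  attr(out, "x_dom") <- x_dom
  out
}

#' Simulate a sequence-variant panel and motif track for the focal region
#'
#' The panel holds genotypes of the founders and F1 sires over a region
#' around the QTL: multi-allelic decoys, biallelic variants with random
#' genotype patterns (resampled if they accidentally match the sire
#' segregation pattern), exactly `n_pattern_consistent` decoys whose F1-sire
#' genotypes match the truth QTL genotypes, and one planted causal variant
#' (a 6-bp deletion, VCF-style representation) at the QTL position.  The
#' motif track (BED convention, 0-based half-open) contains decoy motifs
#' and, if `causal_in_motif`, one motif covering the deleted span.
#'
#' @param cross a `cross_data`.
#' @param region `c(start, end)` in bp (1-based inclusive) on the QTL
#'   chromosome; default a ~488-kb window centred on the QTL.
#' @param n_variants total variants, planted causal included.
#' @param n_pattern_consistent decoys matching the sire segregation pattern.
#' @param causal_in_motif place the causal variant inside a motif?
#' @param seed integer seed.
#' @param prop_multiallelic fraction of variants given a second ALT allele.
#' @param motifs optional motif track to reuse (shared across crosses).
#' @param n_motifs decoy motif count when generating the track.
#' @return list with elements `panel` (a `variant_panel`: `region`,
#'   `variants` data.frame (pos, ref, alt, biallelic), `gt` character matrix
#'   variants x samples, `samples`, `sample_rows`, `causal_pos`, `cross_id`)
#'   and `motifs` (data.frame chrom, start, end, label).
#' @export
simulate_variant_panel <- function(cross, region = NULL, n_variants = 200,
                                   n_pattern_consistent = 25,
                                   causal_in_motif = TRUE, seed = 1L,
                                   prop_multiallelic = 0.1,
                                   motifs = NULL, n_motifs = 8) {
  set.seed(as.integer(seed))
  qtl_bp <- cross$qtl$bp
  chrom <- cross$qtl$chrom
  if (is.null(region))
    region <- c(max(1, qtl_bp - 244057), qtl_bp + 244056)
  if (n_variants > 0 && diff(region) + 1 < n_variants * 2)
    stop("region too small for n_variants")
  if (n_variants > 0 && n_pattern_consistent > n_variants - 1)
    stop("n_pattern_consistent must be <= n_variants - 1")

  ped <- cross$pedigree
  founder_rows <- which(ped$generation == 0L)
  sire_rows <- cross$f1_males
  rows <- c(founder_rows, sire_rows)
  samples <- c(sprintf("F0_%d", founder_rows), sprintf("S%d", sire_rows))
  ns <- length(rows)
  sire_is_het <- cross$qtl$sire_truth == "het"

  panel_empty <- function() {
    list(region = list(chrom = chrom, start = region[1], end = region[2]),
         variants = data.frame(pos = integer(), ref = character(),
                               alt = character(), biallelic = logical(),
                               stringsAsFactors = FALSE),
         gt = matrix(character(), 0, ns, dimnames = list(NULL, samples)),
         samples = samples, sample_rows = rows,
         causal_pos = NA_integer_, cross_id = NA_character_)
  }
  if (n_variants == 0) {
    pan <- panel_empty()
    class(pan) <- "variant_panel"
    return(list(panel = pan, motifs = motifs))
  }

  # causal variant: 6-bp deletion at the QTL position, ALT (short) allele = Q
  causal_pos <- qtl_bp
  causal_ref <- "GACCTGC"
  causal_alt <- "G"
  qc <- cross$qtl$q_count[rows]
  gt_from_count <- c("0/0", "0/1", "1/1")
  causal_gt <- gt_from_count[qc + 1L]

  nm1 <- n_variants - 1L
  pool <- setdiff(seq.int(region[1], region[2]), causal_pos)
  pos <- sort(sample(pool, nm1))
  n_multi <- round(prop_multiallelic * n_variants)
  kind <- rep("random", nm1)
  if (n_multi > 0) kind[seq_len(n_multi)] <- "multi"
  if (n_pattern_consistent > 0)
    kind[n_multi + seq_len(n_pattern_consistent)] <- "pattern"
  kind <- sample(kind)

  bases <- c("A", "C", "G", "T")
  sire_cols <- length(founder_rows) + seq_along(sire_rows)
  matches_pattern <- function(g) {
    sg <- g[sire_cols]
    het <- sg == "0/1"
    all(het[sire_is_het]) && all(!het[!sire_is_het] & !is.na(sg))
  }
  random_gt <- function() {
    p <- stats::runif(1, 0.1, 0.9)
    gt_from_count[stats::rbinom(ns, 2, p) + 1L]
  }

  variants <- vector("list", nm1)
  gts <- vector("list", nm1)
  for (v in seq_len(nm1)) {
    ref <- sample(bases, 1)
    if (kind[v] == "multi") {
      alts <- sample(setdiff(bases, ref), 2)
      # genotypes over three alleles so >2 alleles are observed
      g <- sprintf("%d/%d", sample(0:2, ns, TRUE), sample(0:2, ns, TRUE))
      g <- vapply(strsplit(g, "/"), function(x)
        paste(sort(as.integer(x)), collapse = "/"), "")
      alt <- paste(alts, collapse = ",")
    } else if (kind[v] == "pattern") {
      alt <- sample(setdiff(bases, ref), 1)
      g <- character(ns)
      g[seq_along(founder_rows)] <-
        ifelse(ped$breed[founder_rows] == "A", "0/0",
               gt_from_count[stats::rbinom(length(founder_rows), 2, 0.6) + 1L][
                 seq_along(founder_rows)])
      g[sire_cols] <- ifelse(sire_is_het, "0/1",
                             sample(c("0/0", "1/1"), length(sire_rows), TRUE))
    } else {
      alt <- sample(setdiff(bases, ref), 1)
      g <- random_gt()
      while (matches_pattern(g)) g <- random_gt()
    }
    variants[[v]] <- data.frame(pos = pos[v], ref = ref, alt = alt,
                                biallelic = kind[v] != "multi",
                                stringsAsFactors = FALSE)
    gts[[v]] <- g
  }
  vdf <- do.call(rbind, c(variants, list(
    data.frame(pos = causal_pos, ref = causal_ref, alt = causal_alt,
               biallelic = TRUE, stringsAsFactors = FALSE))))
  gt <- do.call(rbind, c(gts, list(causal_gt)))
  ord <- order(vdf$pos)
  vdf <- vdf[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(vdf) <- NULL
  colnames(gt) <- samples

  if (is.null(motifs)) {
    w <- 15L
    starts0 <- sample(seq.int(region[1], region[2] - w), n_motifs)
    motifs <- data.frame(chrom = chrom, start = starts0,
                         end = starts0 + w,
                         label = sprintf("motif_%d", seq_len(n_motifs)),
                         stringsAsFactors = FALSE)
    if (causal_in_motif) {
      # cover the deleted span pos+1 .. pos+6 (BED 0-based half-open)
      motifs <- rbind(motifs,
                      data.frame(chrom = chrom, start = causal_pos,
                                 end = causal_pos + 10L, label = "motif_mrf",
                                 stringsAsFactors = FALSE))
    }
    motifs <- motifs[order(motifs$start), ]
    rownames(motifs) <- NULL
  }

  pan <- list(region = list(chrom = chrom, start = region[1], end = region[2]),
              variants = vdf, gt = gt, samples = samples, sample_rows = rows,
              causal_pos = causal_pos, cross_id = NA_character_)
  class(pan) <- "variant_panel"
  list(panel = pan, motifs = motifs)
}
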