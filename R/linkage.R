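# Line-cross and half-sib interval mapping by Haley-Knott regression on
# line-origin probabilities, permutation thresholds, and variance explained
# by the QTL.
#
# Line-origin probabilities are computed per phased haplotype by Markov
# interpolation between the flanking markers whose founder-breed origin is
# known, with inter-marker transition probabilities equal to the Kosambi
# recombination fractions (two-marker conditioning, not full multipoint).

# P(origin == breed B at pos_cM) for each row of an origin matrix.
# O: individuals x markers origin labels (1 = A, 2 = B, NA = unknown),
# columns restricted to one chromosome and matching map_sub.
.origin_prob_B <- function(O, map_sub, pos_cM) {
  cm <- map_sub$cM
  if (pos_cM < cm[1] - 1e-9 || pos_cM > cm[length(cm)] + 1e-9)
    stop("position outside map")
  jL <- max(which(cm <= pos_cM + 1e-9))
  jR <- min(which(cm >= pos_cM - 1e-9))
  rL <- kosambi_recombination(pos_cM - cm[jL])
  rR <- kosambi_recombination(cm[jR] - pos_cM)
  oL <- O[, jL]
  oR <- O[, jR]
  tLB <- ifelse(is.na(oL), 0.5, ifelse(oL == 2L, 1 - rL, rL))
  tLA <- ifelse(is.na(oL), 0.5, ifelse(oL == 1L, 1 - rL, rL))
  tRB <- ifelse(is.na(oR), 0.5, ifelse(oR == 2L, 1 - rR, rR))
  tRA <- ifelse(is.na(oR), 0.5, ifelse(oR == 1L, 1 - rR, rR))
  wB <- tLB * tRB
  wA <- tLA * tRA
  wB / (wA + wB)
}

#' Line-origin QTL genotype probabilities for the F2
#'
#' Conditional probabilities that an F2 individual carries 2, 1 or 0
#' copies of the breed-B-origin (Q-line) allele at a position, given the
#' origins of the flanking markers on each phased haplotype and the
#' Kosambi map distances.
#'
#' @param cross a `cross_data`.
#' @param chrom chromosome id.
#' @param pos_cM position in cM on that chromosome.
#' @param rows individual rows (default F2).
#' @return data.frame p_QQ, p_Qq, p_qq (rows sum to 1).
#' @export
line_cross_probabilities <- function(cross, chrom, pos_cM,
                                     rows = cross$f2_rows) {
  sel <- cross$map$chrom == chrom
  if (!any(sel)) stop("chromosome not on map")
  map_sub <- cross$map[sel, ]
  pB1 <- .origin_prob_B(cross$O1[rows, sel, drop = FALSE], map_sub, pos_cM)
  pB2 <- .origin_prob_B(cross$O2[rows, sel, drop = FALSE], map_sub, pos_cM)
  data.frame(p_QQ = pB1 * pB2,
             p_Qq = pB1 * (1 - pB2) + (1 - pB1) * pB2,
             p_qq = (1 - pB1) * (1 - pB2))
}

# interpolate bp for cM positions on one chromosome
.cm_to_bp <- function(map_sub, pos_cM) {
  round(stats::approx(map_sub$cM, map_sub$bp, xout = pos_cM, rule = 2)$y)
}

#' Line-cross Haley-Knott scan
#'
#' At each position the trait is regressed on the covariates plus an
#' additive coefficient (p_QQ - p_qq) and a dominance coefficient (p_Qq);
#' the F statistic compares this model with the covariates-only model.
#'
#' @param cross a `cross_data`.
#' @param trait numeric trait vector for the F2 (aligned with
#'   `cross$f2_rows`).
#' @param covariates design matrix including the intercept (default from
#'   the pedigree covariates).
#' @param step_cM scan step.
#' @param chrom chromosome to scan (default the QTL chromosome).
#' @param positions optional explicit cM positions (overrides `step_cM`).
#' @return list of class `f_profile`: `profile` data.frame (cM, bp, F, p,
#'   rss_full, rss_reduced, df1, df2), `max_F`, `argmax_cM`, `argmax_bp`,
#'   `pct_var_qtl` at the maximum.
#' @export
line_cross_scan <- function(cross, trait, covariates = NULL, step_cM = 1,
                            chrom = cross$qtl$chrom, positions = NULL) {
  rows <- cross$f2_rows
  y <- as.numeric(trait)
  stopifnot(length(y) == length(rows))
  X <- if (is.null(covariates))
    covariate_design(cross$pedigree[rows, ]) else as.matrix(covariates)
  if (qr(X)$rank < ncol(X)) stop("collinear covariates")
  sel <- cross$map$chrom == chrom
  map_sub <- cross$map[sel, ]
  if (is.null(positions))
    positions <- seq(map_sub$cM[1], map_sub$cM[nrow(map_sub)], by = step_cM)
  fit0 <- stats::lm.fit(X, y)
  rss0 <- sum(fit0$residuals^2)
  n <- length(y)
  degenerate <- rss0 <= 1e-12 * (1 + sum(y^2))
  out <- lapply(positions, function(pp) {
    pr <- line_cross_probabilities(cross, chrom, pp, rows)
    xa <- pr$p_QQ - pr$p_qq
    xd <- pr$p_Qq
    Xf <- cbind(X, xa = xa, xd = xd)
    qrf <- qr(Xf)
    rss1 <- sum(qr.resid(qrf, y)^2)
    df1 <- qrf$rank - qr(X)$rank
    df2 <- n - qrf$rank
    Fv <- if (!degenerate && df1 > 0 && rss1 > 1e-300)
      max(((rss0 - rss1) / df1) / (rss1 / df2), 0) else 0
    c(F = Fv, p = stats::pf(Fv, max(df1, 1), df2, lower.tail = FALSE),
      rss_full = rss1, rss_reduced = rss0, df1 = df1, df2 = df2)
  })
  prof <- as.data.frame(do.call(rbind, out))
  prof <- cbind(data.frame(cM = positions,
                           bp = .cm_to_bp(map_sub, positions)), prof)
  i <- which.max(prof$F)
  res <- list(profile = prof, max_F = prof$F[i], argmax_cM = prof$cM[i],
              argmax_bp = prof$bp[i],
              pct_var_qtl = pct_var_qtl(prof$rss_reduced[i], prof$rss_full[i]))
  class(res) <- "f_profile"
  res
}

#' Percentage of variance explained by the fitted QTL
#'
#' 100 * (RSS_reduced - RSS_full) / RSS_reduced, from the residual sums of
#' squares of the linkage models without and with the QTL term.
#'
#' @param rss_reduced,rss_full residual sums of squares (> 0,
#'   rss_full <= rss_reduced).
#' @export
pct_var_qtl <- function(rss_reduced, rss_full) {
  if (any(rss_reduced <= 0) || any(rss_full <= 0))
    stop("residual sums of squares must be > 0")
  if (any(rss_full > rss_reduced + 1e-9))
    stop("rss_full must be <= rss_reduced")
  100 * (rss_reduced - rss_full) / rss_reduced
}

#' Permutation thresholds for the line-cross scan
#'
#' Covariate-adjusted residuals of the trait are permuted across the F2;
#' for each permutation the maximum scan statistic over positions is
#' recorded and empirical quantiles returned.  The scan statistic here is
#' the F for the covariate-residualised QTL coefficients, so the observed
#' maximum (also returned) is computed on the same scale.
#'
#' @param cross,trait,covariates,step_cM,chrom,positions as in
#'   [line_cross_scan()].
#' @param n_perm number of permutations (>= 100).
#' @param alphas significance levels.
#' @param seed integer seed; thresholds are deterministic given the seed.
#' @return list: `thresholds` (named by alpha), `observed_max`, `perm_max`.
#' @export
permutation_thresholds <- function(cross, trait, covariates = NULL,
                                   step_cM = 2, chrom = cross$qtl$chrom,
                                   positions = NULL, n_perm = 1000,
                                   alphas = c(0.05, 0.01), seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (any(n_perm * alphas < 5))
    warning("n_perm too small for the smallest alpha")
  rows <- cross$f2_rows
  y <- as.numeric(trait)
  X <- if (is.null(covariates))
    covariate_design(cross$pedigree[rows, ]) else as.matrix(covariates)
  sel <- cross$map$chrom == chrom
  map_sub <- cross$map[sel, ]
  if (is.null(positions))
    positions <- seq(map_sub$cM[1], map_sub$cM[nrow(map_sub)], by = step_cM)
  n <- length(y)
  p <- qr(X)$rank
  e <- stats::lm.fit(X, y)$residuals
  # orthonormal bases of the covariate-adjusted QTL coefficients
  Qs <- lapply(positions, function(pp) {
    pr <- line_cross_probabilities(cross, chrom, pp, rows)
    D <- cbind(pr$p_QQ - pr$p_qq, pr$p_Qq)
    D <- D - X %*% stats::lm.fit(X, D)$coefficients
    qr.Q(qr(D))[, seq_len(qr(D)$rank), drop = FALSE]
  })
  fstat_max <- function(ev) {
    tot <- sum(ev^2)
    best <- 0
    for (Q in Qs) {
      df1 <- ncol(Q)
      ss <- sum(crossprod(Q, ev)^2)
      f <- (ss / df1) / ((tot - ss) / (n - p - df1))
      if (f > best) best <- f
    }
    best
  }
  set.seed(as.integer(seed))
  perm_max <- vapply(seq_len(n_perm), function(b) fstat_max(sample(e)), 0)
  thr <- stats::quantile(perm_max, 1 - alphas, type = 1, names = FALSE)
  names(thr) <- paste0("alpha_", alphas)
  list(thresholds = thr, observed_max = fstat_max(e), perm_max = perm_max)
}

#' Half-sib QTL scan within one F1 sire family
#'
#' Within the family, the trait is regressed on the probability that the
#' offspring inherited the sire's breed-A-origin haplotype at each
#' position (paternal transmission probability from the flanking markers);
#' the profile reports -log10 p of that coefficient.
#'
#' @param cross a `cross_data`.
#' @param sire_id pedigree id of an F1 male.
#' @param trait numeric trait vector for all F2 (aligned with
#'   `cross$f2_rows`).
#' @param covariates optional design matrix for all F2.
#' @param step_cM scan step.
#' @param chrom chromosome to scan.
#' @param min_offspring minimum family size.
#' @return list: `profile` (cM, bp, minus_log10_p, effect), `max`,
#'   `argmax_cM`, `n_offspring`.
#' @export
halfsib_family_scan <- function(cross, sire_id, trait, covariates = NULL,
                                step_cM = 2, chrom = cross$qtl$chrom,
                                min_offspring = 10) {
  rows <- cross$f2_rows
  fam <- which(cross$pedigree$sire[rows] == sire_id)
  if (length(fam) == 0) stop("sire has no offspring")
  if (length(fam) < min_offspring)
    stop("sire family smaller than ", min_offspring)
  y <- as.numeric(trait)[fam]
  X <- if (is.null(covariates))
    covariate_design(cross$pedigree[rows, ]) else as.matrix(covariates)
  X <- X[fam, , drop = FALSE]
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  sel <- cross$map$chrom == chrom
  map_sub <- cross$map[sel, ]
  positions <- seq(map_sub$cM[1], map_sub$cM[nrow(map_sub)], by = step_cM)
  O1 <- cross$O1[rows[fam], sel, drop = FALSE]
  n <- length(y)
  out <- lapply(positions, function(pp) {
    tA <- 1 - .origin_prob_B(O1, map_sub, pp)
    if (stats::sd(tA) < 1e-12)
      return(c(minus_log10_p = 0, effect = 0))
    Xf <- cbind(X, tA = tA)
    qrf <- qr(Xf)
    r1 <- sum(qr.resid(qrf, y)^2)
    r0 <- sum(qr.resid(qr(X), y)^2)
    df2 <- n - qrf$rank
    Fv <- max(0, (r0 - r1) / (r1 / df2))
    pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
    c(minus_log10_p = -log10(pv),
      effect = qr.coef(qrf, y)[["tA"]])
  })
  prof <- cbind(data.frame(cM = positions, bp = .cm_to_bp(map_sub, positions)),
                as.data.frame(do.call(rbind, out)))
  i <- which.max(prof$minus_log10_p)
  list(profile = prof, max = prof$minus_log10_p[i], argmax_cM = prof$cM[i],
       n_offspring = n)
}
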