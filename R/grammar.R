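# Two-stage mixed-model association (GRAMMAR): a pedigree-kinship polygenic
# model absorbs family structure and fixed effects, then each marker is
# tested by simple regression of the polygenic residuals on the additive
# genotype code.

#' Additive relationship matrix from a pedigree (tabular method)
#'
#' Founders are taken as unrelated and non-inbred.  Unknown parents are
#' coded 0.  The pedigree is topologically sorted internally if needed.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`.
#' @return symmetric numeric matrix with dimnames = ids.
#' @export
kinship_from_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree)[, c("id", "sire", "dam")]
  n <- nrow(ped)
  idx <- match(ped$id, ped$id)
  si <- match(ped$sire, ped$id, nomatch = 0L)
  di <- match(ped$dam, ped$id, nomatch = 0L)
  # topological order: parents before offspring
  ord <- integer(0)
  placed <- logical(n)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ok <- vapply(remaining, function(i)
      (si[i] == 0L || placed[si[i]]) && (di[i] == 0L || placed[di[i]]),
      TRUE)
    ready <- remaining[ok]
    if (!length(ready)) stop("pedigree cycle detected")
    placed[ready] <- TRUE
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    s <- si[i]; d <- di[i]
    done <- ord[seq_len(match(i, ord) - 1L)]
    if (length(done)) {
      row <- numeric(length(done))
      if (s > 0L) row <- row + 0.5 * A[s, done]
      if (d > 0L) row <- row + 0.5 * A[d, done]
      A[i, done] <- row
      A[done, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Fit the polygenic mixed model and return GRAMMAR residuals
#'
#' Model: y = Xb + u + e with u ~ N(0, A sigma_g2), e ~ N(0, I sigma_e2).
#' REML estimation by eigendecomposition of A and a one-dimensional profile
#' over the heritability ratio (golden-section on h2, tolerance 1e-8), as
#' in eigendecomposition-based mixed-model solvers.  The GRAMMAR residuals
#' are y - X b_hat - u_hat with u_hat the BLUP of the polygenic effects.
#'
#' @param y numeric response (no NAs).
#' @param X fixed-effect design matrix (full column rank), including the
#'   intercept.
#' @param A additive relationship matrix for the same individuals.
#' @param A_eig optional precomputed `eigen(A, symmetric = TRUE)` to reuse
#'   across traits.
#' @return list: `sigma_g2`, `sigma_e2`, `h2`, `loglik` (REML at optimum),
#'   `beta`, `u` (BLUP), `residuals` (GRAMMAR residuals).
#' @export
fit_polygenic <- function(y, X, A, A_eig = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is singular")
  if (is.null(A_eig)) A_eig <- eigen(A, symmetric = TRUE)
  d <- A_eig$values
  if (min(d) < -1e-6) stop("relationship matrix is not positive semi-definite")
  d <- pmax(d, 0)
  U <- A_eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  reml_ll <- function(h2) {
    delta <- h2 / (1 - h2)
    lam <- delta * d + 1
    w <- 1 / lam
    XtW <- Xt * w
    XX <- crossprod(Xt, XtW)
    b <- solve(XX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    s2 <- sum(w * r^2) / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(lam)) +
              determinant(XX, logarithm = TRUE)$modulus[1] +
              (n - p) * (1 + log(2 * pi)))
  }
  grid <- seq(0.01, 0.99, by = 0.02)
  ll <- vapply(grid, reml_ll, 0)
  # smallest h2 within numerical ties of the grid maximum (flat likelihoods,
  # e.g. identity kinship, collapse to the OLS solution)
  g0 <- grid[min(which(ll > max(ll) - 1e-7))]
  opt <- stats::optimize(reml_ll, c(max(1e-6, g0 - 0.02), min(1 - 1e-6, g0 + 0.02)),
                         maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  # prefer the boundary h2 -> 0 when it is not beaten by the interior optimum
  if (reml_ll(1e-9) >= opt$objective - 1e-7) {
    h2 <- 1e-9
    opt <- list(maximum = h2, objective = reml_ll(h2))
  }
  delta <- h2 / (1 - h2)
  lam <- delta * d + 1
  w <- 1 / lam
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  b <- solve(XX, crossprod(XtW, yt))
  rmarg <- y - X %*% b
  rt <- crossprod(U, rmarg)
  s2e <- sum(w * rt^2) / (n - p)
  u_hat <- U %*% (delta * d * w * rt)
  resid <- U %*% (w * rt)
  list(sigma_g2 = delta * s2e, sigma_e2 = s2e, h2 = h2,
       loglik = opt$objective, beta = drop(b), u = drop(u_hat),
       residuals = drop(resid))
}

#' Per-marker regression scan of GRAMMAR residuals
#'
#' Simple linear regression of the residuals on the additive genotype code
#' (count of the minor allele, 0/1/2), one marker at a time; two-sided
#' p-values from the t distribution; missing genotypes dropped per marker.
#' Monomorphic markers are flagged and given effect 0, p = 1.
#'
#' @param residuals GRAMMAR residual vector.
#' @param genotypes individuals x markers matrix of allele counts (0/1/2,
#'   NA = missing), aligned with `residuals`.
#' @param sigma_g2 additive genetic variance used for %Var_SNP (optional).
#' @param map optional map data.frame (chrom, name, bp) for annotation.
#' @return list of class `assoc_result`: `table` (per-marker maf, effect,
#'   se, p, pct_var, monomorphic), `lambda` (genomic inflation), and
#'   `thresholds` from [significance_thresholds()].
#' @export
grammar_scan <- function(residuals, genotypes, sigma_g2 = NULL, map = NULL) {
  G <- as.matrix(genotypes)
  y <- as.numeric(residuals)
  stopifnot(nrow(G) == length(y))
  obs <- !is.na(G)
  G0 <- ifelse(obs, G, 0)
  # flip to minor-allele counts
  nobs <- colSums(obs)
  p_alt <- colSums(G0) / (2 * pmax(nobs, 1))
  flip <- p_alt > 0.5
  G0[, flip] <- ifelse(obs[, flip, drop = FALSE],
                       2 - G[, flip, drop = FALSE], 0)
  maf <- ifelse(flip, 1 - p_alt, p_alt)

  Sx <- colSums(G0)
  Sxx <- colSums(G0^2)
  Sy <- drop(crossprod(obs, y))
  Syy <- drop(crossprod(obs, y^2))
  Sxy <- drop(crossprod(G0, y))
  nn <- nobs
  den <- nn * Sxx - Sx^2
  mono <- den <= 0 | nn < 3
  den[mono] <- 1
  beta <- (nn * Sxy - Sx * Sy) / den
  rss <- Syy - Sy^2 / pmax(nn, 1) - beta^2 * den / pmax(nn, 1)
  rss <- pmax(rss, 0)
  s2 <- rss / pmax(nn - 2, 1)
  se <- sqrt(s2 * nn / den)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = pmax(nn - 2, 1), lower.tail = FALSE)
  beta[mono] <- 0
  se[mono] <- NA_real_
  pval[mono] <- 1

  tab <- data.frame(marker = colnames(G) %||% seq_len(ncol(G)),
                    n = nn, maf = maf, effect = beta, se = se, p = pval,
                    p_bonferroni = pmin(pval * sum(!mono), 1),
                    monomorphic = mono, stringsAsFactors = FALSE)
  if (!is.null(map)) tab <- cbind(map[, intersect(c("chrom", "bp"), names(map)),
                                      drop = FALSE], tab)
  if (!is.null(sigma_g2))
    tab$pct_var <- ifelse(mono, 0, pct_var_snp(pmax(maf, 1e-12), beta, sigma_g2))
  res <- list(table = tab,
              lambda = genomic_inflation(pval[!mono]),
              thresholds = significance_thresholds(sum(!mono)))
  class(res) <- "assoc_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mixed-model (GLS) effect of a single marker
#'
#' Measured-genotype estimate: the marker enters the polygenic mixed model
#' as a fixed covariate and its effect is estimated by generalized least
#' squares at the variance ratio of a previous [fit_polygenic()].  Used to
#' report unbiased allele effects at top markers (the GRAMMAR residual
#' regression deflates effects).
#'
#' @param y trait vector.
#' @param X covariate design (with intercept).
#' @param genotype marker allele counts (0/1/2; NA dropped is not
#'   supported here - supply complete genotypes).
#' @param fit result of [fit_polygenic()] on (y, X, A).
#' @param A_eig eigendecomposition of A (as used in the fit).
#' @return list: `effect`, `se`.
#' @export
gls_marker_effect <- function(y, X, genotype, fit, A_eig) {
  W <- cbind(X, g = as.numeric(genotype))
  n <- length(y)
  delta <- fit$h2 / (1 - fit$h2)
  lam <- delta * pmax(A_eig$values, 0) + 1
  Wt <- crossprod(A_eig$vectors, W)
  yt <- crossprod(A_eig$vectors, y)
  w <- 1 / lam
  WW <- crossprod(Wt, Wt * w)
  Wy <- crossprod(Wt * w, yt)
  b <- solve(WW, Wy)
  r <- yt - Wt %*% b
  s2 <- sum(w * r^2) / (n - ncol(W))
  covb <- solve(WW) * s2
  k <- ncol(W)
  list(effect = b[k], se = sqrt(covb[k, k]))
}

#' Genome-wide significance thresholds
#'
#' Bonferroni-adjusted significant threshold alpha / n_markers, suggestive
#' threshold 1 / n_markers (one false positive per scan), and the
#' -log10 of the significant threshold.
#'
#' @param n_markers number of tested markers (>= 1).
#' @param alpha genome-wide type-I error rate.
#' @return list: `bonferroni_p`, `suggestive_p`, `threshold_minus_log10`.
#' @export
significance_thresholds <- function(n_markers, alpha = 0.05) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  bp <- alpha / n_markers
  list(bonferroni_p = bp, suggestive_p = 1 / n_markers,
       threshold_minus_log10 = -log10(bp))
}

#' Percentage of variance explained by a SNP
#'
#' 100 * 2 p (1 - p) a^2 / sigma_g2, with p the minor allele frequency and
#' a the estimated allelic effect; the denominator is the additive genetic
#' variance of the trait.
#'
#' @param p minor allele frequency in (0, 0.5].
#' @param a allelic effect (trait units per allele).
#' @param sigma_g2 additive genetic variance (> 0).
#' @return percentage(s).
#' @export
pct_var_snp <- function(p, a, sigma_g2) {
  if (any(sigma_g2 <= 0)) stop("sigma_g2 must be > 0")
  if (any(p <= 0 | p > 0.5)) stop("p must be in (0, 0.5]")
  100 * 2 * p * (1 - p) * a^2 / sigma_g2
}

#' Genomic inflation factor
#'
#' lambda = median of the 1-df chi-square association statistics divided by
#' the null median 0.4549364.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Fixed-effect design matrix for the standard covariates
#'
#' Intercept, male indicator, batch dummies (first batch as reference) and
#' centred carcass weight, built from a phenotype/covariate table.
#'
#' @param pheno data.frame with `sex`, `batch`, `carcass_weight`.
#' @return numeric design matrix.
#' @export
covariate_design <- function(pheno) {
  batches <- sort(unique(pheno$batch))
  Xb <- if (length(batches) > 1)
    sapply(batches[-1], function(b) as.numeric(pheno$batch == b)) else NULL
  X <- cbind(intercept = 1, male = as.numeric(pheno$sex == 1),
             Xb, cw = pheno$carcass_weight - mean(pheno$carcass_weight))
  colnames(X) <- c("intercept", "male",
                   if (!is.null(Xb)) paste0("batch", batches[-1]), "cw")
  X
}
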