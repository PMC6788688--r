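# Bayesian fine-mapping from summary statistics and LD: per-variant
# posterior inclusion probabilities by exhaustive enumeration of causal
# configurations, credible sets, and colocalization of two traits by the
# product of posterior inclusion probabilities (CLPP).

#' Pairwise LD matrix from genotypes
#'
#' Pearson correlation of additive genotype codes, pairwise-complete;
#' monomorphic variants are dropped (logged as an attribute); the matrix
#' is regularized by adding eps to the diagonal when not positive
#' semi-definite.
#'
#' @param genotypes individuals x variants matrix of allele counts.
#' @param eps ridge added if the correlation matrix is not PSD.
#' @return correlation matrix with attribute `dropped` (indices of
#'   monomorphic variants).
#' @export
compute_ld <- function(genotypes, eps = 1e-4) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2) stop("need at least 2 individuals")
  sds <- apply(G, 2, stats::sd, na.rm = TRUE)
  dropped <- which(is.na(sds) | sds == 0)
  if (length(dropped)) G <- G[, -dropped, drop = FALSE]
  R <- stats::cor(G, use = "pairwise.complete.obs")
  R[is.na(R)] <- 0
  diag(R) <- 1
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 0)
    R <- (R + diag(eps, nrow(R))) / (1 + eps)
  attr(R, "dropped") <- dropped
  R
}

# log multivariate normal density at z, mean 0, covariance S (via chol)
.ldmvnorm0 <- function(z, S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(S + diag(1e-8, nrow(S)))
  v <- backsolve(ch, z, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(v^2)
}

#' Posterior causal-configuration probabilities (CAVIAR model)
#'
#' Association Z-scores are modelled as multivariate normal with
#' covariance Sigma + sigma^2 Sigma I_c Sigma, where Sigma is the LD
#' matrix and I_c selects the causal configuration c; configurations of
#' size up to `k` (the null configuration included) carry the prior
#' gamma^|c| (1-gamma)^(m-|c|).  Posterior inclusion probabilities are
#' marginal sums over configurations.  Likelihoods accumulate in log
#' space with max-subtraction.
#'
#' @param z numeric Z-score vector.
#' @param ld LD matrix matching `z`.
#' @param k maximum number of causal variants per configuration.
#' @param gamma per-variant prior inclusion probability.
#' @param sigma prior non-centrality scale.
#' @param positions optional variant positions (used for tie-breaking in
#'   credible sets).
#' @param max_configs safety cap on the number of configurations.
#' @return list of class `finemap_result`: `pip`, `configs` (list of
#'   integer vectors), `config_post`, `prior`, `positions`.
#' @export
caviar_posteriors <- function(z, ld, k = 2, gamma = 0.01, sigma = 5.2,
                              positions = seq_along(z),
                              max_configs = 1e6) {
  m <- length(z)
  stopifnot(k >= 1, nrow(ld) == m, ncol(ld) == m)
  Sigma <- as.matrix(ld)
  n_cfg <- sum(vapply(0:min(k, m), function(s) choose(m, s), 0))
  if (n_cfg > max_configs) stop("too many configurations; lower k")
  configs <- list(integer(0))
  for (s in seq_len(min(k, m)))
    configs <- c(configs, utils::combn(m, s, simplify = FALSE))
  loglik <- vapply(configs, function(cc) {
    S <- Sigma
    if (length(cc)) {
      Sc <- Sigma[, cc, drop = FALSE]
      S <- S + sigma^2 * tcrossprod(Sc)
    }
    .ldmvnorm0(z, S)
  }, 0)
  logprior <- vapply(configs, function(cc)
    length(cc) * log(gamma) + (m - length(cc)) * log(1 - gamma), 0)
  lp <- loglik + logprior
  w <- exp(lp - max(lp))
  post <- w / sum(w)
  pip <- vapply(seq_len(m), function(i)
    sum(post[vapply(configs, function(cc) i %in% cc, TRUE)]), 0)
  res <- list(pip = pip, configs = configs, config_post = post,
              prior = list(k = k, gamma = gamma, sigma = sigma),
              positions = positions)
  class(res) <- "finemap_result"
  res
}

#' Credible set of candidate causal variants
#'
#' Smallest variant set (greedy by PIP, ties broken by position) whose
#' contained-configuration posterior mass reaches `rho`; the mass of a set
#' is the summed posterior of configurations fully inside it (the null
#' configuration counts toward every set).
#'
#' @param result a `finemap_result`.
#' @param rho credible level in [0, 1); `rho = 0` returns the top variant.
#' @return integer vector of variant indices (sorted), with attribute
#'   `mass`.
#' @export
credible_set <- function(result, rho = 0.99) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  m <- length(result$pip)
  ord <- order(-result$pip, result$positions)
  sizes <- vapply(result$configs, length, 0L)
  set_mass <- function(sel) {
    inside <- vapply(result$configs, function(cc) all(cc %in% sel), TRUE)
    sum(result$config_post[inside])
  }
  for (j in seq_len(m)) {
    sel <- ord[seq_len(j)]
    mm <- set_mass(sel)
    if (mm >= rho) break
  }
  out <- sort(sel)
  attr(out, "mass") <- mm
  out
}

#' Colocalization posterior (CLPP) of two traits
#'
#' CLPP_i = PIP_i(trait 1) * PIP_i(trait 2); a variant is flagged
#' colocalized when its CLPP exceeds the threshold.
#'
#' @param result1,result2 `finemap_result`s over the same variants, in
#'   the same order.
#' @param threshold CLPP needed to flag colocalization.
#' @return data.frame: position, pip1, pip2, clpp, colocalized.
#' @export
clpp <- function(result1, result2, threshold = 0.99) {
  if (length(result1$pip) != length(result2$pip) ||
      !identical(result1$positions, result2$positions))
    stop("mismatched variant sets")
  cl <- result1$pip * result2$pip
  data.frame(position = result1$positions, pip1 = result1$pip,
             pip2 = result2$pip, clpp = cl, colocalized = cl > threshold)
}

#' Z-scores from an association scan
#'
#' @param assoc an `assoc_result` (or its `table`).
#' @return numeric vector effect / SE (0 for monomorphic markers).
#' @export
assoc_zscores <- function(assoc) {
  tab <- if (inherits(assoc, "assoc_result")) assoc$table else assoc
  z <- tab$effect / tab$se
  z[!is.finite(z)] <- 0
  z
}
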