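# Independent oracle implementations.  These deliberately use different
# code paths (direct enumeration, all-pairs loops, textbook formulas) from
# the package routines they validate.

# Exact HWE by full enumeration of genotype tables with the observed
# allele counts; probabilities written with choose()/factorial().
oracle_hwe_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  nA <- 2 * n_hom1 + n_het
  hets <- 0:min(nA, 2 * n - nA)
  hets <- hets[(nA - hets) %% 2 == 0]
  pr <- sapply(hets, function(h) {
    hom1 <- (nA - h) / 2
    hom2 <- n - h - hom1
    if (hom1 < 0 || hom2 < 0) return(0)
    factorial(n) / (factorial(hom1) * factorial(h) * factorial(hom2)) *
      2^h / choose(2 * n, nA)
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# log MVN(0, S) density by direct solve()/det()
oracle_ldmvnorm0 <- function(z, S) {
  k <- length(z)
  -0.5 * (k * log(2 * pi) + log(det(S)) +
            drop(t(z) %*% solve(S) %*% z))
}

# Brute-force posterior over ALL 2^m causal configurations
oracle_caviar <- function(z, ld, gamma, sigma) {
  m <- length(z)
  masks <- 0:(2^m - 1)
  lp <- sapply(masks, function(msk) {
    cc <- which(bitwAnd(msk, 2^(0:(m - 1))) > 0)
    S <- ld
    if (length(cc))
      S <- ld + sigma^2 * (ld[, cc, drop = FALSE] %*% ld[cc, , drop = FALSE])
    oracle_ldmvnorm0(z, S) +
      length(cc) * log(gamma) + (m - length(cc)) * log(1 - gamma)
  })
  w <- exp(lp - max(lp))
  post <- w / sum(w)
  pip <- sapply(1:m, function(i)
    sum(post[bitwAnd(masks, 2^(i - 1)) > 0]))
  list(pip = pip, post = post)
}

# Average pairwise difference per bp over complete haplotypes
oracle_pi_pairwise <- function(H, L) {
  n <- nrow(H)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(H[i, ] != H[j, ])
  tot / choose(n, 2) / L
}

# Textbook Tajima's D on complete data, pi from all-pairs differences
oracle_tajima <- function(H) {
  n <- nrow(H)
  cnt <- colSums(H)
  S <- sum(cnt > 0 & cnt < n)
  pi_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pi_tot <- pi_tot + sum(H[i, ] != H[j, ])
  pi_tot <- pi_tot / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Site-independent sample with a neutral (1/i) frequency spectrum
neutral_sample <- function(n, S) {
  probs <- (1 / (1:(n - 1)))
  probs <- probs / sum(probs)
  H <- matrix(0L, n, S)
  counts <- sample(1:(n - 1), S, replace = TRUE, prob = probs)
  for (s in seq_len(S)) H[sample(n, counts[s]), s] <- 1L
  H
}
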