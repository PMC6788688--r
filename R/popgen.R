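# Population-genetic diagnostics for the focal region: per-population
# allele frequencies of the candidate variant, nucleotide diversity and
# Tajima's D with missing data handled by per-site effective sample sizes.

#' Per-population allele frequency of a focal variant
#'
#' @param genotypes_by_pop named list; each element a vector of Q-allele
#'   counts (0/1/2, NA = missing) for one population.
#' @return data.frame: population, n_called (alleles), freq_Q (NA and
#'   flagged when a population has zero calls).
#' @export
allele_frequency_table <- function(genotypes_by_pop) {
  stopifnot(length(genotypes_by_pop) >= 1)
  out <- lapply(names(genotypes_by_pop), function(pop) {
    g <- genotypes_by_pop[[pop]]
    called <- sum(!is.na(g)) * 2
    data.frame(population = pop, n_called = called,
               freq_Q = if (called > 0) sum(g, na.rm = TRUE) / called else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$flagged <- res$n_called == 0
  res
}

#' Nucleotide diversity per base pair with missing data
#'
#' pi = sum over sites of [n_i / (n_i - 1)] * 2 p_i (1 - p_i) divided by
#' the callable length, with n_i the number of called alleles at site i;
#' sites with fewer than two calls are skipped.  With complete data this
#' equals the average pairwise difference per bp.
#'
#' @param haplotypes haplotype x site matrix of 0/1 alleles (NA =
#'   missing); sites are SNPs only.
#' @param L_callable callable length in bp (> 0).
#' @return pi per bp.
#' @export
nucleotide_diversity <- function(haplotypes, L_callable) {
  if (L_callable <= 0) stop("callable length must be > 0")
  H <- as.matrix(haplotypes)
  n_i <- colSums(!is.na(H))
  use <- n_i >= 2
  if (!any(use)) return(0)
  p <- colMeans(H, na.rm = TRUE)[use]
  ni <- n_i[use]
  sum(ni / (ni - 1) * 2 * p * (1 - p)) / L_callable
}

#' Tajima's D with missing data
#'
#' Classic Tajima's D computed from the segregating-site count S and the
#' (total, not per-bp) heterozygosity-based diversity; the constants a1,
#' a2, e1, e2 are evaluated at the effective sample size n* = rounded
#' mean of the per-site called allele counts.
#'
#' @param haplotypes haplotype x site matrix of 0/1 alleles (NA =
#'   missing).
#' @return list: `D`, `n_star`, `S`, `pi_total`.
#' @export
tajimas_d <- function(haplotypes) {
  H <- as.matrix(haplotypes)
  n_i <- colSums(!is.na(H))
  use <- n_i >= 2
  H <- H[, use, drop = FALSE]
  n_i <- n_i[use]
  cnt <- colSums(H, na.rm = TRUE)
  seg <- cnt > 0 & cnt < n_i
  S <- sum(seg)
  if (S == 0) stop("no segregating sites: Tajima's D undefined")
  n_star <- round(mean(n_i))
  if (n_star < 4) stop("need at least 4 sampled alleles")
  p <- (cnt / n_i)[seg]
  ni <- n_i[seg]
  pi_total <- sum(ni / (ni - 1) * 2 * p * (1 - p))
  n <- n_star
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, n_star = n_star, S = S, pi_total = pi_total)
}
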