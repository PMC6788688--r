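# Readers/writers for the standard formats (PED/MAP, minimal VCF, BED,
# TSV), marker QC and Mendelian checks.  Internal coordinate convention is
# 1-based inclusive; BED input is converted on read.

#' 1-based inclusive genomic interval
#' @param chrom chromosome id.
#' @param start,end base-pair positions, 1-based inclusive, start <= end.
#' @export
genomic_interval <- function(chrom, start, end) {
  if (length(start) && length(end) && start > end)
    stop("start must be <= end")
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)), class = "genomic_interval")
}

#' Interval length in kb, rounded to 0.1
#'
#' length_kb = (end - start + 1) / 1000, reported to one decimal.
#' @param interval a [genomic_interval()] (or anything with start/end).
#' @export
interval_length_kb <- function(interval) {
  if (!length(interval$start) || is.na(interval$start)) return(0)
  round((interval$end - interval$start + 1) / 100) / 10
}

#' Convert BED (0-based half-open) coordinates to 1-based inclusive
#' @param start0,end0 BED start and end.
#' @return list with `start`, `end` (1-based inclusive).
#' @export
bed_to_1based <- function(start0, end0) {
  if (any(start0 < 0) || any(end0 <= start0))
    stop("BED requires 0 <= start < end")
  list(start = start0 + 1, end = end0)
}

#' Read a BED motif track
#'
#' Columns: chrom, start (0-based), end (half-open), optional name.
#' @param path BED file path.
#' @return data.frame chrom, start, end, label (BED convention retained).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!is.numeric(x[[2]]) || !is.numeric(x[[3]]))
    stop("non-numeric BED coordinates")
  out <- data.frame(chrom = as.character(x[[1]]), start = x[[2]], end = x[[3]],
                    label = if (ncol(x) >= 4) as.character(x[[4]]) else
                      sprintf("motif_%d", seq_len(nrow(x))),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$end <= out$start))
    stop("invalid BED interval")
  out
}

#' Write a motif track as BED
#' @param motifs data.frame chrom, start, end, label (BED convention).
#' @param path output path.
#' @export
write_bed <- function(motifs, path) {
  utils::write.table(motifs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal (GT-only) VCF into a variant panel
#'
#' POS is 1-based; ALT with a comma marks a multi-allelic record
#' (`biallelic = FALSE`).  Only the GT field is used.
#'
#' @param path VCF path (plain text).
#' @return a `variant_panel` (see [simulate_variant_panel()]); `region` is
#'   the span of the records read.
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (!length(hdr_i)) stop("missing #CHROM header line")
  hdr <- strsplit(sub("^#", "", lines[hdr_i[1]]), "\t")[[1]]
  samples <- if (length(hdr) > 9) hdr[-(1:9)] else character()
  body <- lines[-seq_len(hdr_i[1])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    pan <- list(region = list(chrom = NA_character_, start = NA, end = NA),
                variants = data.frame(pos = integer(), ref = character(),
                                      alt = character(), biallelic = logical(),
                                      stringsAsFactors = FALSE),
                gt = matrix(character(), 0, length(samples),
                            dimnames = list(NULL, samples)),
                samples = samples, causal_pos = NA_integer_,
                cross_id = NA_character_)
    class(pan) <- "variant_panel"
    return(pan)
  }
  f <- strsplit(body, "\t")
  pos <- suppressWarnings(as.integer(vapply(f, `[`, "", 2)))
  if (any(is.na(pos))) stop("non-numeric POS in VCF")
  ref <- vapply(f, `[`, "", 4)
  alt <- vapply(f, `[`, "", 5)
  gt <- t(vapply(f, function(x)
    sub(":.*$", "", x[-(1:9)]), character(length(samples))))
  if (length(samples) == 1) gt <- matrix(gt, ncol = 1)
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  colnames(gt) <- samples
  pan <- list(region = list(chrom = vapply(f, `[`, "", 1)[1],
                            start = min(pos), end = max(pos)),
              variants = data.frame(pos = pos, ref = ref, alt = alt,
                                    biallelic = !grepl(",", alt),
                                    stringsAsFactors = FALSE),
              gt = gt, samples = samples, causal_pos = NA_integer_,
              cross_id = NA_character_)
  class(pan) <- "variant_panel"
  pan
}

#' Write a variant panel as a minimal VCF
#' @param panel a `variant_panel`.
#' @param path output path.
#' @export
write_vcf_minimal <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")), con)
  v <- panel$variants
  if (nrow(v)) {
    gt <- panel$gt
    gt[is.na(gt)] <- "./."
    rows <- vapply(seq_len(nrow(v)), function(i)
      paste(c(panel$region$chrom, v$pos[i], ".", v$ref[i], v$alt[i], ".",
              "PASS", ".", "GT", gt[i, ]), collapse = "\t"), "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write genotypes as PLINK-style PED/MAP
#'
#' @param fam data.frame: fid, iid, pat, mat, sex, pheno.
#' @param a1,a2 character allele matrices (individuals x markers), "0" for
#'   missing.
#' @param map data.frame chrom, name, cM, bp.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(fam, a1, a2, map, ped_path, map_path) {
  stopifnot(nrow(a1) == nrow(fam), ncol(a1) == nrow(map),
            dim(a1)[1] == dim(a2)[1], dim(a1)[2] == dim(a2)[2])
  M <- ncol(a1)
  inter <- matrix("", nrow(a1), 2 * M)
  inter[, seq(1, 2 * M, 2)] <- a1
  inter[, seq(2, 2 * M, 2)] <- a2
  ped <- cbind(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex, fam$pheno, inter)
  data.table::fwrite(as.data.frame(ped), ped_path, sep = " ",
                     col.names = FALSE, quote = FALSE)
  data.table::fwrite(map[, c("chrom", "name", "cM", "bp")], map_path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(ped_path)
}

#' Read PLINK-style PED/MAP
#'
#' @param ped_path,map_path input paths.
#' @return list: `fam` (fid, iid, pat, mat, sex, pheno), allele matrices
#'   `a1`, `a2` ("0" = missing), `map` (chrom, name, cM, bp; must be sorted
#'   within chromosomes), and `geno` (counts of the marker's second allele,
#'   NA where missing).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- as.data.frame(data.table::fread(map_path, header = FALSE,
                                         colClasses = list(character = 1:2)))
  names(map) <- c("chrom", "name", "cM", "bp")
  .validate_map(map)
  ped <- as.data.frame(data.table::fread(ped_path, header = FALSE,
                                         colClasses = "character"))
  M <- nrow(map)
  if (ncol(ped) != 6 + 2 * M)
    stop("PED column count does not match MAP marker count")
  fam <- data.frame(fid = ped[[1]], iid = ped[[2]], pat = ped[[3]],
                    mat = ped[[4]], sex = as.integer(ped[[5]]),
                    pheno = ped[[6]], stringsAsFactors = FALSE)
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, 2 * M, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * M, 2), drop = FALSE]
  dimnames(a1) <- dimnames(a2) <- list(fam$iid, map$name)
  miss <- a1 == "0" | a2 == "0"
  geno <- matrix(NA_integer_, nrow(a1), ncol(a1), dimnames = dimnames(a1))
  for (j in seq_len(M)) {
    als <- sort(unique(c(a1[!miss[, j], j], a2[!miss[, j], j])))
    if (length(als) > 2) stop("more than two alleles at marker ", map$name[j])
    second <- if (length(als) == 2) als[2] else als[1]
    if (length(als))
      geno[!miss[, j], j] <- (a1[!miss[, j], j] == second) +
        (a2[!miss[, j], j] == second)
  }
  list(fam = fam, a1 = a1, a2 = a2, map = map, geno = geno)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: the p-value is the total probability, under the
#' conditional distribution of heterozygote counts given allele counts, of
#' all tables at most as probable as the observed one.
#'
#' @param n_het,n_hom1,n_hom2 genotype counts.
#' @return p-value.
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het = h | allele counts), up to a constant
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Marker quality-control rules
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum genotype call rate.
#' @param hwe_p_min markers with exact HWE p <= this are removed.
#' @param mendel_error_max maximum tolerated Mendelian error rate.
#' @export
marker_qc_rules <- function(maf_min = 0.05, call_rate_min = 0.90,
                            hwe_p_min = 1e-6, mendel_error_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0,
            call_rate_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1)
  list(maf_min = maf_min, call_rate_min = call_rate_min,
       hwe_p_min = hwe_p_min, mendel_error_max = mendel_error_max)
}

#' Filter markers by MAF, call rate and exact HWE
#'
#' The HWE test is computed on the supplied matrix, which should contain
#' the F2 individuals only.  Markers failing any rule are removed.
#'
#' @param genotypes individuals x markers matrix of allele counts
#'   (0/1/2/NA).
#' @param rules a [marker_qc_rules()].
#' @param mendel_rates optional per-marker Mendelian error rates from
#'   [check_mendelian()], filtered against `mendel_error_max`.
#' @return list: `keep` (logical per marker), `report` (per-rule removal
#'   counts), `stats` (per-marker maf, call_rate, hwe_p).
#' @export
qc_filter_markers <- function(genotypes, rules = marker_qc_rules(),
                              mendel_rates = NULL) {
  G <- as.matrix(genotypes)
  if (!length(G)) stop("empty genotype matrix")
  obs <- !is.na(G)
  nobs <- colSums(obs)
  call_rate <- nobs / nrow(G)
  p <- colSums(G, na.rm = TRUE) / (2 * pmax(nobs, 1))
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[obs[, j], j]
    hwe_exact_p(sum(g == 1), sum(g == 0), sum(g == 2))
  }, 0)
  fail_maf <- maf < rules$maf_min
  fail_cr <- call_rate < rules$call_rate_min
  fail_hwe <- hwe_p <= rules$hwe_p_min
  fail_mendel <- if (is.null(mendel_rates)) rep(FALSE, ncol(G)) else
    mendel_rates > rules$mendel_error_max
  keep <- !(fail_maf | fail_cr | fail_hwe | fail_mendel)
  list(keep = keep,
       report = data.frame(rule = c("maf", "call_rate", "hwe", "mendel", "kept"),
                           n = c(sum(fail_maf), sum(fail_cr), sum(fail_hwe),
                                 sum(fail_mendel), sum(keep))),
       stats = data.frame(maf = maf, call_rate = call_rate, hwe_p = hwe_p))
}

#' Per-marker Mendelian error rate
#'
#' An error is an offspring genotype impossible given the available
#' parental genotypes (e.g. parents 0 x 0 with offspring 1).  Trios with a
#' parent absent from the matrix use the remaining parent; the rate is
#' errors / informative offspring-parent checks.
#'
#' @param genotypes individuals x markers allele-count matrix (0/1/2/NA),
#'   rows aligned with `pedigree$id`.
#' @param pedigree data.frame id, sire, dam (0 = unknown).
#' @return list: `rate` per marker, `errors`, `informative`.
#' @export
check_mendelian <- function(genotypes, pedigree) {
  G <- as.matrix(genotypes)
  ids <- pedigree$id
  si <- match(pedigree$sire, ids, nomatch = 0L)
  di <- match(pedigree$dam, ids, nomatch = 0L)
  off <- which(si > 0L | di > 0L)
  M <- ncol(G)
  err <- info <- integer(M)
  for (i in off) {
    gc <- G[i, ]
    gs <- if (si[i] > 0L) G[si[i], ] else rep(NA_integer_, M)
    gd <- if (di[i] > 0L) G[di[i], ] else rep(NA_integer_, M)
    usable <- !is.na(gc) & (!is.na(gs) | !is.na(gd))
    e <- rep(FALSE, M)
    both <- usable & !is.na(gs) & !is.na(gd)
    e[both] <- (gc[both] == 0 & (gs[both] == 2 | gd[both] == 2)) |
      (gc[both] == 2 & (gs[both] == 0 | gd[both] == 0)) |
      (gc[both] == 1 & ((gs[both] == 0 & gd[both] == 0) |
                          (gs[both] == 2 & gd[both] == 2)))
    one <- usable & xor(is.na(gs), is.na(gd))
    gp <- ifelse(is.na(gs), gd, gs)
    e[one] <- (gc[one] == 0 & gp[one] == 2) | (gc[one] == 2 & gp[one] == 0)
    err <- err + e
    info <- info + usable
  }
  list(rate = ifelse(info > 0, err / pmax(info, 1), NA_real_),
       errors = err, informative = info)
}

#' Export a cross as PED/MAP + phenotype TSV (+ truth TSV)
#'
#' Convenience writer used by the analysis drivers.
#' @param cross a `cross_data`.
#' @param pheno phenotype table from [simulate_phenotypes()].
#' @param dir output directory.
#' @param prefix file prefix.
#' @export
write_cross <- function(cross, pheno, dir, prefix = "cross") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- cross$pedigree
  fam <- data.frame(fid = 1L, iid = ped$id, pat = ped$sire, mat = ped$dam,
                    sex = ped$sex, pheno = -9)
  a1 <- matrix(as.character(cross$H1), nrow(cross$H1))
  a2 <- matrix(as.character(cross$H2), nrow(cross$H2))
  write_ped_map(fam, a1, a2, cross$map,
                file.path(dir, paste0(prefix, ".ped")),
                file.path(dir, paste0(prefix, ".map")))
  data.table::fwrite(pheno, file.path(dir, paste0(prefix, "_pheno.tsv")),
                     sep = "\t")
  truth <- data.frame(id = ped$id, q_count = cross$qtl$q_count)
  data.table::fwrite(truth, file.path(dir, paste0(prefix, "_truth.tsv")),
                     sep = "\t")
  invisible(dir)
}
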