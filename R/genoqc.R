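# Post-genotyping validation: call rates, Axiom-style conversion categories,
# the exact conditional Hardy-Weinberg test, QC filtering with a two-way
# removal ledger, and MAF spectra.

#' Per-SNP and per-sample call rates
#'
#' @param m dosage matrix, samples x SNPs, entries 0/1/2/NA.
#' @return list with `snp` and `sample` call-rate vectors in [0,1].
#' @export
call_rates <- function(m) {
  stopifnot(length(m) > 0)
  list(snp = colMeans(!is.na(m)), sample = rowMeans(!is.na(m)))
}

#' Classify SNPs into conversion categories
#'
#' Genotype-level approximation of array cluster QC: a SNP whose call rate is
#' below `snp_cr_min` is `Failed`; otherwise it is `MonoHighResolution` when
#' only one allele is observed, `NoMinorHom` when it is polymorphic but the
#' minor-allele homozygote class is absent, and `PolyHighResolution` when the
#' minor-allele homozygote is present. The four categories partition the
#' SNPs.
#'
#' @param m dosage matrix, samples x SNPs.
#' @param snp_cr_min call-rate threshold for `Failed` (default 0.97).
#' @return a `conversion_report`: list with per-SNP `category` (factor) and
#'   per-category `fractions` summing to 1.
#' @export
classify_conversion <- function(m, snp_cr_min = 0.97) {
  cr <- colMeans(!is.na(m))
  nh0 <- colSums(m == 0, na.rm = TRUE)
  nh1 <- colSums(m == 1, na.rm = TRUE)
  nh2 <- colSums(m == 2, na.rm = TRUE)
  n_ref <- 2 * nh0 + nh1
  n_alt <- 2 * nh2 + nh1
  minor_hom <- ifelse(n_alt <= n_ref, nh2, nh0)
  poly <- n_ref > 0 & n_alt > 0
  cat <- ifelse(cr < snp_cr_min, "Failed",
                ifelse(!poly, "MonoHighResolution",
                       ifelse(minor_hom > 0, "PolyHighResolution", "NoMinorHom")))
  lev <- c("PolyHighResolution", "MonoHighResolution", "NoMinorHom", "Failed")
  category <- factor(cat, levels = lev)
  structure(list(category = stats::setNames(category, colnames(m)),
                 fractions = as.numeric(table(category)) / length(category)),
            class = "conversion_report")
}

# log of the conditional probability of n_Aa heterozygotes given n genotypes
# and n_A copies of allele A (standard exact-HWE conditional distribution)
.hwe_logprob <- function(n_Aa, n, n_A) {
  n_a <- 2 * n - n_A
  n_AA <- (n_A - n_Aa) / 2
  n_aa <- (n_a - n_Aa) / 2
  lgamma(n + 1) - lgamma(n_AA + 1) - lgamma(n_Aa + 1) - lgamma(n_aa + 1) +
    n_Aa * log(2) + lgamma(n_A + 1) + lgamma(n_a + 1) - lgamma(2 * n + 1)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the total probability of all attainable heterozygote counts (same parity
#' as the observed one) whose conditional probability does not exceed the
#' observed count's probability (ties included; no mid-p correction).
#' Monomorphic sites have a single attainable configuration and p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  n_A <- 2 * n_AA + n_Aa
  n_minor <- min(n_A, 2 * n - n_A)
  if (n_minor == 0) return(1)
  hets <- seq(n_Aa %% 2, n_minor, by = 2)
  lp <- .hwe_logprob(hets, n, n_A)
  lp_obs <- .hwe_logprob(n_Aa, n, n_A)
  p <- sum(exp(lp[lp <= lp_obs + 1e-9]))
  min(1, p)
}

#' Vectorised exact HWE p-values for a dosage matrix
#' @param m dosage matrix, samples x SNPs.
#' @return numeric vector of p-values (one per SNP). Distributions are
#'   memoised over (n, allele count), so large SNP panels are cheap.
#' @export
hwe_pvalues <- function(m) {
  nh0 <- colSums(m == 0, na.rm = TRUE)
  nh1 <- colSums(m == 1, na.rm = TRUE)
  nh2 <- colSums(m == 2, na.rm = TRUE)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  vapply(seq_len(ncol(m)), function(j) {
    keyname <- paste(nh0[j] + nh1[j] + nh2[j], 2 * nh0[j] + nh1[j], nh1[j], sep = "_")
    got <- cache[[keyname]]
    if (!is.null(got)) return(got)
    p <- hwe_exact_test(nh0[j], nh1[j], nh2[j])
    cache[[keyname]] <- p
    p
  }, numeric(1))
}

#' QC filter with a two-way removal ledger
#'
#' SNPs are removed when the call rate is below `cr_min` or the exact HWE
#' p-value is below `hwe_alpha`; a SNP failing both is counted once, under
#' the call-rate reason (removal precedence keeps the ledger disjoint).
#' Polymorphic SNPs among the kept ones are reported with the
#' `MAF > poly_maf` convention.
#'
#' @param m dosage matrix, samples x SNPs (one population).
#' @param cr_min SNP call-rate threshold (default 0.95).
#' @param hwe_alpha HWE p-value threshold (default 1e-7).
#' @param poly_maf MAF above which a kept SNP counts as polymorphic
#'   (default 0.001).
#' @return list: `kept` (SNP keys), `ledger` (removed_callrate, removed_hwe,
#'   kept, total), `n_polymorphic`.
#' @export
qc_filter <- function(m, cr_min = 0.95, hwe_alpha = 1e-7, poly_maf = 0.001) {
  cr <- colMeans(!is.na(m))
  fail_cr <- cr < cr_min
  pv <- hwe_pvalues(m)
  fail_hwe <- !fail_cr & pv < hwe_alpha
  kept <- !fail_cr & !fail_hwe
  keys <- colnames(m) %||% as.character(seq_len(ncol(m)))
  p <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  list(kept = keys[kept],
       ledger = c(removed_callrate = sum(fail_cr), removed_hwe = sum(fail_hwe),
                  kept = sum(kept), total = ncol(m)),
       n_polymorphic = sum(kept & !is.na(maf) & maf > poly_maf))
}

#' MAF spectrum histogram
#'
#' Bins are half-open `[lo, hi)`; the last bin is closed at 0.5 so the total
#' is conserved.
#'
#' @param freqs minor allele frequencies in [0, 0.5].
#' @param bin_edges increasing edge vector covering [0, 0.5].
#' @return data.frame `lo`, `hi`, `count`, `fraction`.
#' @export
maf_spectrum <- function(freqs, bin_edges = c(0, 0.05, 0.15, 0.25, 0.35, 0.5)) {
  if (length(freqs) && (min(freqs) < 0 || max(freqs) > 0.5))
    stop("frequencies outside [0, 0.5]")
  k <- length(bin_edges) - 1L
  idx <- findInterval(freqs, bin_edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = k)
  data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
             count = counts,
             fraction = if (length(freqs)) counts / length(freqs) else rep(0, k))
}
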