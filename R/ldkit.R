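# Relatedness pruning and binned linkage-disequilibrium decay.

#' Genomic relationship matrix
#'
#' Allele-frequency-standardised dosage GRM: entry (j,k) is the mean over
#' SNPs of (x_j - 2p)(x_k - 2p) / (2p(1-p)), computed pairwise-complete over
#' non-missing genotypes. SNPs are pre-filtered to MAF >= `maf_min`;
#' monomorphic SNPs are skipped.
#'
#' @param m dosage matrix, samples x SNPs.
#' @param maf_min MAF floor (default 0.05).
#' @return symmetric samples x samples matrix.
#' @export
genomic_relatedness <- function(m, maf_min = 0.05) {
  stopifnot(nrow(m) >= 2)
  p <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  use <- !is.na(maf) & maf >= maf_min & p > 0 & p < 1
  if (!any(use)) stop("no SNPs pass the MAF floor")
  x <- m[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(x, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(z)
  z0 <- z; z0[!obs] <- 0
  num <- tcrossprod(z0)
  den <- tcrossprod(obs * 1)
  if (any(den == 0)) stop("a sample pair has zero overlapping called SNPs")
  g <- num / den
  dimnames(g) <- list(rownames(m), rownames(m))
  g
}

#' Greedy relatedness pruning
#'
#' While any retained pair exceeds `cutoff`, the sample participating in the
#' most above-cutoff pairs is removed (ties broken by removing the
#' lexicographically larger id), so exactly one member of each violating
#' pair goes and no retained pair exceeds the cutoff.
#'
#' @param g symmetric relatedness matrix with sample dimnames.
#' @param cutoff relatedness threshold (default 0.12).
#' @return character vector of retained sample ids.
#' @export
prune_related <- function(g, cutoff = 0.12) {
  ids <- rownames(g) %||% as.character(seq_len(nrow(g)))
  dimnames(g) <- list(ids, ids)
  keep <- ids
  repeat {
    sub <- g[keep, keep, drop = FALSE]
    viol <- sub > cutoff
    diag(viol) <- FALSE
    n_viol <- rowSums(viol)
    if (all(n_viol == 0)) break
    worst <- which(n_viol == max(n_viol))
    drop_id <- max(names(n_viol)[worst]) # lexicographically larger id
    keep <- setdiff(keep, drop_id)
  }
  keep
}

#' Pairwise r-squared within a distance window
#'
#' r2 is the squared Pearson correlation of alternate-allele dosages over
#' pairwise-complete samples, for SNP pairs on the same chromosome at
#' distance <= `max_dist` with at most `max_pairs_window` intervening SNPs.
#' SNPs are pre-filtered to MAF >= `maf_min`; pairs involving a
#' zero-variance dosage vector are skipped (counted in the `skipped`
#' attribute).
#'
#' @param m dosage matrix, samples x SNPs (column names = variant keys).
#' @param chrom,pos SNP coordinates, parallel to the columns of `m`.
#' @param max_dist maximum pair distance in bp (default 1,001,000).
#' @param max_pairs_window maximum SNP-count window (default 50,000).
#' @param maf_min MAF floor (default 0.05).
#' @return data.frame: snpA, snpB, dist, r2 (all r2 in [0,1]).
#' @export
pairwise_r2 <- function(m, chrom, pos, max_dist = 1001000,
                        max_pairs_window = 50000, maf_min = 0.05) {
  p <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  use <- !is.na(maf) & maf >= maf_min
  m <- m[, use, drop = FALSE]
  chrom <- chrom[use]; pos <- pos[use]
  keys <- colnames(m) %||% as.character(seq_len(ncol(m)))
  out <- list(); skipped <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(pos[idx])]
    if (length(idx) < 2) next
    x <- m[, idx, drop = FALSE]
    cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- pos[idx][pr[, 2]] - pos[idx][pr[, 1]]
    span <- pr[, 2] - pr[, 1]
    okd <- d <= max_dist & d >= 1 & span <= max_pairs_window
    pr <- pr[okd, , drop = FALSE]; d <- d[okd]
    r <- cc[cbind(pr[, 1], pr[, 2])]
    nz <- !is.na(r)
    skipped <- skipped + sum(!nz)
    out[[length(out) + 1]] <- data.frame(
      snpA = keys[idx][pr[nz, 1]], snpB = keys[idx][pr[nz, 2]],
      dist = d[nz], r2 = r[nz]^2, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snpA = character(0), snpB = character(0),
               dist = numeric(0), r2 = numeric(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Bin r-squared values by distance
#'
#' A pair at distance d lands in bin `ceiling(d / bin_width)`: bins are
#' closed on the right, (0, 2000], (2000, 4000], ... for the default 2 kb
#' width. Pair counts are conserved.
#'
#' @param pairs data.frame from [pairwise_r2()] (needs `dist`, `r2`).
#' @param bin_width bin width in bp (default 2000).
#' @return data.frame: lo, hi, n_pairs, mean_r2.
#' @export
bin_ld <- function(pairs, bin_width = 2000) {
  stopifnot(all(pairs$dist >= 1))
  b <- ceiling(pairs$dist / bin_width)
  agg <- tapply(pairs$r2, b, mean)
  cnt <- tapply(pairs$r2, b, length)
  idx <- as.integer(names(agg))
  out <- data.frame(lo = (idx - 1) * bin_width, hi = idx * bin_width,
                    n_pairs = as.integer(cnt), mean_r2 = as.numeric(agg))
  out[order(out$lo), , drop = FALSE]
}

#' Mean r-squared at named distances
#'
#' Looks up the bin containing each query distance (bins closed on the
#' right), e.g. the decay value "at 50 kb" is the mean of the bin whose
#' interval contains 50,000 bp.
#'
#' @param bins data.frame from [bin_ld()].
#' @param query_distances distances in bp.
#' @return named numeric vector of bin means.
#' @export
ld_decay_summary <- function(bins, query_distances) {
  stopifnot(nrow(bins) > 0)
  vapply(query_distances, function(d) {
    hit <- which(bins$lo < d & d <= bins$hi)
    if (length(hit) == 0) stop("query distance ", d, " beyond covered bins")
    bins$mean_r2[hit]
  }, numeric(1), USE.NAMES = FALSE) -> v
  names(v) <- paste0(query_distances, "bp")
  v
}
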