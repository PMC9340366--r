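# Population-genetic site filters: MAF cleaning, chromosome allow-lists,
# replicate concordance, doubled-haploid heterozygosity, full genotyping.

#' Minor allele frequency per site
#'
#' MAF = min(p, 1-p) with p = alternate-allele count over called alleles in
#' the chosen samples; missing genotypes are excluded from the denominator.
#' Sites with zero called alleles return NA (undefined, distinct from 0).
#'
#' @param cs a bi-allelic CallSet.
#' @param samples sample ids to count over (default: all).
#' @return numeric vector of MAF in [0, 0.5] (NA where undefined).
#' @export
compute_maf <- function(cs, samples = NULL) {
  am <- gt_allele_mats(cs)
  a1 <- am$a1; a2 <- am$a2
  if (!is.null(samples)) {
    a1 <- a1[, samples, drop = FALSE]
    a2 <- a2[, samples, drop = FALSE]
  }
  called <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  altc <- rowSums(a1 == 1L, na.rm = TRUE) + rowSums(a2 == 1L, na.rm = TRUE)
  p <- ifelse(called > 0, altc / called, NA_real_)
  pmin(p, 1 - p)
}

#' Bi-allelic single-base SNP mask
#' @param cs a CallSet.
#' @return logical vector: TRUE where the record is a bi-allelic A/C/G/T SNP.
#' @export
is_biallelic_snp <- function(cs) {
  r <- cs$records
  nchar(r$ref) == 1L & !grepl(",", r$alt, fixed = TRUE) & nchar(r$alt) == 1L &
    r$ref %in% c("A", "C", "G", "T") & r$alt %in% c("A", "C", "G", "T")
}

#' Database cleaning: bi-allelic SNPs on allowed chromosomes above a MAF floor
#'
#' Reproduces the catalogue-cleaning rule: keep bi-allelic SNPs located on an
#' allowed chromosome (e.g. the karyotype chromosomes plus the mitochondrial
#' chromosome) whose MAF in the named population is at least `maf_min`
#' (`MAF >= maf_min`; the single boundary convention used throughout).
#' Records tagged `REF_CONFLICT` by merging are also dropped here.
#'
#' @param cs a CallSet.
#' @param population population label present in the roster.
#' @param maf_min MAF floor (default 0.01).
#' @param chroms non-empty chromosome allow-list.
#' @return the filtered `CallSet` with attrition logged per rule.
#' @export
clean_database <- function(cs, population, maf_min = 0.01, chroms) {
  stopifnot(length(chroms) > 0)
  if (!population %in% cs$roster$population)
    stop("population not in roster: ", population)
  out <- subset_callset(cs, cs$records$filter != "REF_CONFLICT", step = "ref_conflict")
  out <- subset_callset(out, is_biallelic_snp(out), step = "biallelic_snp")
  out <- subset_callset(out, out$records$chrom %in% chroms, step = "chromosome_allowlist")
  samp <- cs$roster$sample_id[cs$roster$population == population]
  maf <- compute_maf(out, samples = samp)
  subset_callset(out, !is.na(maf) & maf >= maf_min,
                 step = sprintf("maf>=%g[%s]", maf_min, population))
}

# genotype comparability helpers for replicate concordance
.called <- function(g) g != "./." & !grepl(".", g, fixed = TRUE)

#' Replicate concordance filter and replicate deduplication
#'
#' A doubled-haploid line is discordant at a site when two of its replicate
#' samples carry different called genotypes (a missing genotype is not
#' evidence of discordance). Sites where more than `max_discordant_lines`
#' lines are discordant are removed; afterwards only the deepest sample of
#' each replicated line is retained in the call set.
#'
#' @param cs a CallSet whose roster has replicate groups.
#' @param max_discordant_lines tolerated discordant lines per site (default 1).
#' @return filtered, deduplicated `CallSet`.
#' @export
replicate_concordance_filter <- function(cs, max_discordant_lines = 1) {
  ros <- cs$roster
  groups <- unique(ros$replicate_group[!is.na(ros$replicate_group)])
  if (length(groups) == 0) stop("roster has no replicate groups")
  n <- n_sites(cs)
  n_disc <- integer(n)
  for (grp in groups) {
    ids <- ros$sample_id[!is.na(ros$replicate_group) & ros$replicate_group == grp]
    g <- cs$gt[, ids, drop = FALSE]
    ok <- matrix(.called(g), nrow = n)
    disc <- vapply(seq_len(n), function(i) {
      gi <- g[i, ok[i, ]]
      length(unique(gi)) > 1L
    }, logical(1))
    n_disc <- n_disc + disc
  }
  out <- subset_callset(cs, n_disc <= max_discordant_lines,
                        step = sprintf("replicate_discordance>%d", max_discordant_lines))
  # keep one sample per line: the deepest
  keep_samples <- unlist(lapply(split(ros, ros$line_id), function(df) {
    df$sample_id[which.max(df$depth_rank)]
  }))
  keep_samples <- c(keep_samples, ros$sample_id[is.na(ros$line_id)])
  keep <- ros$sample_id %in% keep_samples
  out$gt <- out$gt[, ros$sample_id[keep], drop = FALSE]
  out$roster <- ros[keep, , drop = FALSE]
  rownames(out$roster) <- NULL
  out
}

#' Doubled-haploid heterozygosity (PSV) filter
#'
#' Doubled-haploid lines are expected fully homozygous, so heterozygous calls
#' flag paralogous sequence variants. Sites where the number of heterozygous
#' doubled-haploid samples exceeds `max_het` are removed.
#'
#' @param cs a CallSet whose roster contains doubled-haploid samples.
#' @param max_het maximum tolerated heterozygous DH samples (e.g. 1 for the
#'   strict PSV screen, 4 for the relaxed preselection rule).
#' @return filtered `CallSet`.
#' @export
dh_heterozygosity_filter <- function(cs, max_het = 1) {
  dh <- cs$roster$sample_id[cs$roster$role == "doubled_haploid"]
  if (length(dh) == 0) stop("no doubled-haploid samples in roster")
  n_het <- rowSums(is_het_matrix(cs, samples = dh))
  subset_callset(cs, n_het <= max_het, step = sprintf("dh_het>%d", max_het))
}

#' Keep only fully genotyped sites
#'
#' @param cs a CallSet.
#' @param samples non-empty sample subset that must be fully called.
#' @return filtered `CallSet`.
#' @export
fully_genotyped_filter <- function(cs, samples = NULL) {
  samples <- samples %||% colnames(cs$gt)
  stopifnot(length(samples) > 0)
  g <- cs$gt[, samples, drop = FALSE]
  any_missing <- apply(matrix(!.called(g), nrow = n_sites(cs)), 1, any)
  subset_callset(cs, !any_missing, step = "fully_genotyped")
}
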