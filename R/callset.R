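# CallSet: the in-memory model of a multi-sample variant call set.
#
# records: data.frame, one row per site, sorted by (chrom, pos):
#   chrom, pos (1-based), id, ref, alt (comma-separated alternates), qual,
#   filter, and the INFO keys used by the hard filters as numeric columns
#   (DP, MQ, QD, FS, SOR, MQRankSum, ReadPosRankSum, AN; NA when absent).
# gt: character matrix sites x samples; genotypes normalised to "a/b" with
#   sorted allele indices, "." for a missing allele ("./." fully missing).
# roster: data.frame sample_id, population, role ("doubled_haploid" or
#   "diploid"), line_id, replicate_group, depth_rank.

INFO_KEYS <- c("DP", "MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum", "AN")

#' Construct a CallSet
#'
#' @param records data.frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   optional `id`, `qual`, `filter` and numeric INFO columns
#'   (`DP`, `MQ`, `QD`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`, `AN`).
#' @param gt character matrix (sites x samples) of genotypes such as
#'   `"0/0"`, `"0/1"`, `"./."`; column names are sample ids.
#' @param roster sample roster; see [make_roster()]. If NULL, a default
#'   all-diploid roster named after `colnames(gt)` is built.
#' @return an object of class `CallSet`.
#' @export
callset <- function(records, gt = NULL, roster = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(records)))
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  n_rec <- nrow(records)
  if (is.null(records$id)) records$id <- rep_len(".", n_rec)
  if (is.null(records$qual)) records$qual <- rep_len(NA_real_, n_rec)
  if (is.null(records$filter)) records$filter <- rep_len("PASS", n_rec)
  for (k in INFO_KEYS) {
    records[[k]] <- if (is.null(records[[k]])) rep_len(NA_real_, n_rec)
      else as.numeric(records[[k]])
  }
  records <- records[, c("chrom", "pos", "id", "ref", "alt", "qual", "filter", INFO_KEYS)]
  if (is.null(gt)) {
    gt <- matrix(character(0), nrow = nrow(records), ncol = 0)
  }
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(records)) stop("gt must have one row per record")
  if (ncol(gt) > 0) gt[] <- normalize_gt(gt)
  if (is.null(roster)) roster <- make_roster(colnames(gt) %||% character(0))
  if (ncol(gt) > 0 && !identical(colnames(gt), roster$sample_id)) {
    roster <- roster[match(colnames(gt), roster$sample_id), , drop = FALSE]
    if (anyNA(roster$sample_id)) stop("roster is missing some gt samples")
  }
  cs <- structure(list(records = records, gt = gt, roster = roster),
                  class = "CallSet")
  validate_callset(cs)
  cs
}

#' Build a sample roster
#'
#' @param sample_id character vector of unique sample names.
#' @param population population label per sample.
#' @param role `"diploid"` or `"doubled_haploid"`.
#' @param line_id doubled-haploid line identifier (NA for diploids).
#' @param replicate_group replicate-group label (NA when not replicated).
#' @param depth_rank numeric sequencing-depth rank used to keep the deepest
#'   sample of a replicated line (larger = deeper).
#' @return a roster data.frame.
#' @export
make_roster <- function(sample_id, population = "pop1", role = "diploid",
                        line_id = NA_character_, replicate_group = NA_character_,
                        depth_rank = 1) {
  n <- length(sample_id)
  df <- data.frame(sample_id = as.character(sample_id),
                   population = rep_len(as.character(population), n),
                   role = rep_len(as.character(role), n),
                   line_id = rep_len(as.character(line_id), n),
                   replicate_group = rep_len(as.character(replicate_group), n),
                   depth_rank = rep_len(as.numeric(depth_rank), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in roster")
  bad <- !is.na(df$replicate_group) & is.na(df$line_id)
  if (any(bad)) stop("replicate_group requires a line_id")
  df
}

validate_callset <- function(cs) {
  r <- cs$records
  if (nrow(r) == 0) return(invisible(cs))
  if (any(r$pos < 1L)) stop("positions must be >= 1")
  ord <- order(match(r$chrom, unique(r$chrom)), r$pos)
  if (!identical(ord, seq_len(nrow(r)))) {
    first <- which(ord != seq_len(nrow(r)))[1]
    stop(sprintf("records not sorted by (chrom, pos); first violation at row %d (%s:%d)",
                 first, r$chrom[first], r$pos[first]))
  }
  key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) records")
  invisible(cs)
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet: %d sites x %d samples (%s)\n",
              nrow(x$records), ncol(x$gt),
              paste(unique(x$roster$population), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a CallSet
#' @param cs a CallSet.
#' @return integer count.
#' @export
n_sites <- function(cs) nrow(cs$records)

#' Variant keys "chrom:pos:ref:alt"
#' @param cs a CallSet or a candidate/panel data.frame with the key columns.
#' @return character vector.
#' @export
variant_keys <- function(cs) {
  r <- if (inherits(cs, "CallSet")) cs$records else cs
  paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
}

#' Subset the sites of a CallSet
#'
#' @param cs a CallSet.
#' @param keep logical mask or integer row indices of records to retain.
#' @param step optional label; when given, the removal is logged into the
#'   [attrition()] ledger.
#' @return the subsetted `CallSet`.
#' @export
subset_callset <- function(cs, keep, step = NULL) {
  if (is.logical(keep)) keep <- which(keep)
  out <- structure(list(records = cs$records[keep, , drop = FALSE],
                        gt = cs$gt[keep, , drop = FALSE],
                        roster = cs$roster),
                   class = "CallSet")
  rownames(out$records) <- NULL
  if (!is.null(step)) {
    out <- append_attrition(out, cs, step, n_sites(cs), length(keep))
  } else {
    attr(out, "attrition") <- attr(cs, "attrition")
  }
  out
}

# Normalise genotype strings: keep only the GT field, "|" -> "/", allele
# order sorted (unphased semantics), missing allele as ".".
normalize_gt <- function(gt) {
  g <- sub(":.*$", "", as.character(gt))
  g <- gsub("|", "/", g, fixed = TRUE)
  g[is.na(g) | g == "." | g == "./." | g == ""] <- "./."
  parts <- strsplit(g, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) p <- c(p, ".")
    p[p == "" | is.na(p)] <- "."
    suppressWarnings(idx <- as.integer(p))
    if (anyNA(idx)) return(paste(p[order(is.na(idx))], collapse = "/"))
    paste(sort(idx), collapse = "/")
  }, character(1))
}

# Allele-index matrices (n_sites*n_samples rows handled as two integer
# matrices); NA for missing alleles.
gt_allele_mats <- function(cs) {
  g <- cs$gt
  a1 <- suppressWarnings(matrix(as.integer(sub("/.*$", "", g)), nrow = nrow(g),
                                dimnames = dimnames(g)))
  a2 <- suppressWarnings(matrix(as.integer(sub("^.*/", "", g)), nrow = nrow(g),
                                dimnames = dimnames(g)))
  # half-missing counted fully missing (conservative)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

# Heterozygous = two distinct called alleles. Missing / half-missing -> FALSE.
is_het_matrix <- function(cs, samples = NULL) {
  am <- gt_allele_mats(cs)
  het <- !is.na(am$a1) & !is.na(am$a2) & am$a1 != am$a2
  if (!is.null(samples)) het <- het[, samples, drop = FALSE]
  het
}

#' Dosage matrix (samples x SNPs)
#'
#' Converts a bi-allelic CallSet to alternate-allele dosages 0/1/2 with NA for
#' missing (half-missing genotypes count as missing). Sites with more than one
#' alternate allele are refused.
#'
#' @param cs a CallSet.
#' @param samples optional character vector of sample ids to keep.
#' @return integer matrix, rows = samples, columns = SNP keys.
#' @export
dosage_matrix <- function(cs, samples = NULL) {
  if (any(grepl(",", cs$records$alt, fixed = TRUE)))
    stop("dosage_matrix requires bi-allelic records")
  am <- gt_allele_mats(cs)
  d <- am$a1 + am$a2
  dimnames(d) <- list(variant_keys(cs), colnames(cs$gt))
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  t(d)
}
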