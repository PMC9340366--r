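# VCF and roster I/O. Reading goes through vcfR; writing is a plain-text
# VCF v4.2 emitter so synthetic call sets stay uncompressed and round-trips
# are byte-stable.

#' Read a VCF file into a CallSet
#'
#' Parses a VCF v4.2 file (plain or bgzipped) keeping CHROM/POS/ID/REF/ALT/
#' QUAL/FILTER, the INFO keys used by the hard filters, and the GT field.
#' Input must be coordinate-sorted; the first violating record is reported.
#'
#' @param path VCF file path.
#' @param roster optional roster (see [make_roster()]) or path to a sample
#'   metadata TSV written by [write_roster()].
#' @return a `CallSet`.
#' @export
read_vcf <- function(path, roster = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n > 0) {
    chrom <- as.character(fix[, "CHROM"])
    pos <- as.integer(fix[, "POS"])
    grp <- match(chrom, unique(chrom))
    bad <- which(diff(grp) < 0 | (diff(grp) == 0 & diff(pos) < 0))
    if (length(bad) > 0) {
      i <- bad[1] + 1L
      stop(sprintf("unsorted VCF: record %d (%s:%d) out of order", i, chrom[i], pos[i]))
    }
  }
  rec <- data.frame(
    chrom = if (n) as.character(fix[, "CHROM"]) else character(0),
    pos = if (n) as.integer(fix[, "POS"]) else integer(0),
    id = if (n) ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]) else character(0),
    ref = if (n) as.character(fix[, "REF"]) else character(0),
    alt = if (n) as.character(fix[, "ALT"]) else character(0),
    qual = if (n) suppressWarnings(as.numeric(fix[, "QUAL"])) else numeric(0),
    filter = if (n) ifelse(is.na(fix[, "FILTER"]) | fix[, "FILTER"] == ".",
                           "PASS", fix[, "FILTER"]) else character(0),
    stringsAsFactors = FALSE)
  if (n > 0) {
    for (k in INFO_KEYS) {
      rec[[k]] <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = k)))
    }
  }
  gt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) > 1 && n > 0) {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n, dimnames = list(NULL, colnames(v@gt)[-1]))
  } else if (!is.null(v@gt) && ncol(v@gt) > 1) {
    gt <- matrix(character(0), nrow = 0, ncol = ncol(v@gt) - 1,
                 dimnames = list(NULL, colnames(v@gt)[-1]))
  }
  if (is.character(roster) && length(roster) == 1L) roster <- read_roster(roster)
  callset(rec, gt = gt, roster = roster)
}

#' Write a CallSet as plain-text VCF v4.2
#'
#' @param cs a CallSet.
#' @param path output path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  r <- cs$records
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", INFO_KEYS, INFO_KEYS),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- ncol(cs$gt) > 0
  if (has_gt) cols <- c(cols, "FORMAT", colnames(cs$gt))
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(r) > 0) {
    info <- vapply(seq_len(nrow(r)), function(i) {
      vals <- unlist(r[i, INFO_KEYS])
      keep <- !is.na(vals)
      if (!any(keep)) return(".")
      paste(sprintf("%s=%s", INFO_KEYS[keep],
                    sub("\\.?0+$", "", sprintf("%.6f", vals[keep]))), collapse = ";")
    }, character(1))
    qual <- ifelse(is.na(r$qual), ".", sub("\\.?0+$", "", sprintf("%.4f", r$qual)))
    body <- paste(r$chrom, r$pos, r$id, r$ref, r$alt, qual, r$filter, info, sep = "\t")
    if (has_gt) {
      gtcol <- apply(cs$gt, 1, paste, collapse = "\t")
      body <- paste(body, "GT", gtcol, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the sample-metadata sidecar TSV
#'
#' @param roster a roster data.frame ([make_roster()]).
#' @param path TSV path.
#' @return `path` (write) or the roster (read).
#' @export
write_roster <- function(roster, path) {
  utils::write.table(roster, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(sample_id = "character",
                                         population = "character",
                                         role = "character",
                                         line_id = "character",
                                         replicate_group = "character",
                                         depth_rank = "numeric"),
                          stringsAsFactors = FALSE)
  make_roster(df$sample_id, df$population, df$role, df$line_id,
              df$replicate_group, df$depth_rank)
}
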