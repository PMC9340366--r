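# Call-set algebra: merge with allele reconciliation, multi-caller
# intersection, and hard filtering on INFO/QUAL thresholds.

split_alts <- function(alt) strsplit(alt, ",", fixed = TRUE)

#' Merge two call sets (union of sites and samples)
#'
#' Site union keyed on (chrom, pos, ref). At shared sites with different
#' alternate alleles the alternate lists are concatenated (deduplicated,
#' first call set's order first) and genotype allele indices are remapped by
#' allele string, so such sites become multi-allelic. Samples absent from a
#' call set get missing genotypes at its private sites. Two records at the
#' same position with conflicting reference alleles are both kept, tagged
#' `FILTER=REF_CONFLICT`, and a warning is raised; downstream preselection
#' excludes them.
#'
#' @param a,b CallSets on the same reference coordinate system, with disjoint
#'   sample ids.
#' @return the merged `CallSet`.
#' @export
merge_callsets <- function(a, b) {
  if (length(intersect(colnames(a$gt), colnames(b$gt))) > 0)
    stop("sample ids overlap between call sets")
  key_a <- paste(a$records$chrom, a$records$pos, a$records$ref, sep = "\r")
  key_b <- paste(b$records$chrom, b$records$pos, b$records$ref, sep = "\r")
  pos_a <- paste(a$records$chrom, a$records$pos, sep = "\r")
  pos_b <- paste(b$records$chrom, b$records$pos, sep = "\r")
  conflict <- (pos_a %in% pos_b) & !(key_a %in% key_b)
  conflict_b <- (pos_b %in% pos_a) & !(key_b %in% key_a)
  if (any(conflict) || any(conflict_b))
    warning(sprintf("%d position(s) with conflicting REF alleles tagged REF_CONFLICT",
                    length(unique(c(pos_a[conflict], pos_b[conflict_b])))))
  b_only <- !(key_b %in% key_a)
  shared_b <- match(key_a, key_b) # index into b for each a record (NA if private)

  n_a <- nrow(a$records); n_out <- n_a + sum(b_only)
  rec <- rbind(a$records, b$records[b_only, , drop = FALSE])
  rec$filter[c(conflict, conflict_b[b_only])] <- "REF_CONFLICT"
  samp_a <- colnames(a$gt); samp_b <- colnames(b$gt)
  gt <- matrix("./.", nrow = n_out, ncol = length(samp_a) + length(samp_b),
               dimnames = list(NULL, c(samp_a, samp_b)))
  if (length(samp_a)) gt[seq_len(n_a), samp_a] <- a$gt
  if (length(samp_b)) gt[n_a + seq_len(sum(b_only)), samp_b] <- b$gt[b_only, , drop = FALSE]

  # reconcile alternate alleles at shared (chrom,pos,ref) sites
  shared_idx <- which(!is.na(shared_b))
  for (i in shared_idx) {
    j <- shared_b[i]
    alts_a <- split_alts(a$records$alt[i])[[1]]
    alts_b <- split_alts(b$records$alt[j])[[1]]
    alts <- unique(c(alts_a, alts_b))
    rec$alt[i] <- paste(alts, collapse = ",")
    if (length(samp_b)) {
      g <- b$gt[j, ]
      if (!identical(alts_b, alts)) {
        # remap b's allele indices by allele string (0 = ref unchanged)
        map <- c(0L, match(alts_b, alts))
        g <- vapply(strsplit(g, "/", fixed = TRUE), function(p) {
          idx <- suppressWarnings(as.integer(p))
          p[!is.na(idx)] <- map[idx[!is.na(idx)] + 1L]
          paste(p, collapse = "/")
        }, character(1))
      }
      gt[i, samp_b] <- g
    }
  }
  roster <- rbind(a$roster, b$roster)
  ord <- order(match(rec$chrom, unique(rec$chrom)), rec$pos)
  callset(rec[ord, , drop = FALSE], gt = gt[ord, , drop = FALSE], roster = roster)
}

#' Intersect call sets from multiple callers
#'
#' Keeps only sites present (same chrom, pos, ref and alternate-allele set)
#' in every input; genotypes and annotations come from
#' `callsets[[primary_index]]`.
#'
#' @param callsets list of >= 2 CallSets.
#' @param primary_index which call set supplies the retained records.
#' @return a `CallSet`.
#' @export
intersect_callsets <- function(callsets, primary_index = 1) {
  stopifnot(length(callsets) >= 2)
  if (primary_index < 1 || primary_index > length(callsets))
    stop("primary_index out of range")
  keyf <- function(cs) {
    alts <- vapply(split_alts(cs$records$alt),
                   function(x) paste(sort(x), collapse = ","), character(1))
    paste(cs$records$chrom, cs$records$pos, cs$records$ref, alts, sep = "\r")
  }
  keys <- lapply(callsets, keyf)
  shared <- Reduce(intersect, keys)
  prim <- callsets[[primary_index]]
  subset_callset(prim, keys[[primary_index]] %in% shared, step = "caller_intersection")
}

# Parse a disjunctive hard-filter expression such as
# "QD < 2.0 || MQ < 40.0 || FS > 60.0" or "DP < 120; MQ < 30.0; QUAL < 600".
parse_filter_rule <- function(rule) {
  atoms <- trimws(strsplit(rule, "\\|\\||;")[[1]])
  atoms <- atoms[atoms != ""]
  out <- lapply(atoms, function(a) {
    m <- regmatches(a, regexec("^([A-Za-z]+)\\s*(<=|>=|<|>)\\s*(-?[0-9.eE+]+)$", a))[[1]]
    if (length(m) == 0) stop("cannot parse predicate: ", a)
    key <- m[2]
    if (!(key %in% c(INFO_KEYS, "QUAL"))) stop("unknown filter key: ", key)
    list(key = key, op = m[3], value = as.numeric(m[4]))
  })
  out
}

#' Remove records matching INFO/QUAL hard-filter predicates
#'
#' `rule` is a disjunction of atomic comparisons (separated by `||` or `;`)
#' on QUAL or the INFO keys DP, MQ, QD, FS, SOR, MQRankSum, ReadPosRankSum,
#' AN, e.g. the GATK-style
#' `"QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0 || MQRankSum < -12.5 || ReadPosRankSum < -8.0"`.
#' A record matching any predicate is removed. Records lacking a referenced
#' key are retained for that predicate (the convention of the tool these
#' expressions come from).
#'
#' @param cs a CallSet.
#' @param rule filter expression string.
#' @return the filtered `CallSet` (removal logged in [attrition()]).
#' @export
filter_info_thresholds <- function(cs, rule) {
  preds <- parse_filter_rule(rule)
  n <- n_sites(cs)
  hit <- rep(FALSE, n)
  for (p in preds) {
    v <- if (p$key == "QUAL") cs$records$qual else cs$records[[p$key]]
    cmp <- switch(p$op,
                  "<" = v < p$value, ">" = v > p$value,
                  "<=" = v <= p$value, ">=" = v >= p$value,
                  stop("unknown comparison operator: ", p$op))
    cmp[is.na(cmp)] <- FALSE # missing key: predicate does not fire
    hit <- hit | cmp
  }
  subset_callset(cs, !hit, step = paste0("info_filter[", rule, "]"))
}
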