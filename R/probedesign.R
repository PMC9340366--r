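# Array-candidate selection: inter-marker spacing, flank extraction and
# trimming, probe uniqueness, ambiguity, window density balancing, two-round
# preselection and panel assembly.

#' Inter-marker spacing filter
#'
#' A site survives iff its distance to the nearest site of the FULL input
#' catalogue (not the surviving set) is at least `min_distance` bp; distance
#' is measured within chromosome. "At least" is inclusive: two sites exactly
#' `min_distance` apart both survive.
#'
#' @param cs a sorted CallSet (the full catalogue).
#' @param min_distance minimum distance to the nearest catalogued SNP (bp).
#' @return filtered `CallSet`.
#' @export
spacing_filter <- function(cs, min_distance = 50) {
  r <- cs$records
  keep <- rep(TRUE, nrow(r))
  for (ch in unique(r$chrom)) {
    idx <- which(r$chrom == ch)
    p <- r$pos[idx]
    if (length(p) > 1) {
      gaps <- diff(p)
      near <- pmin(c(Inf, gaps), c(gaps, Inf)) # nearest-neighbour distance
      keep[idx] <- near >= min_distance
    }
  }
  subset_callset(cs, keep, step = sprintf("spacing>=%dbp", as.integer(min_distance)))
}

#' Extract probe flanking sequences
#'
#' Left flank = reference bases `[pos-flank_len, pos)`, right flank =
#' `(pos, pos+flank_len]` (1-based; the variant base itself is excluded).
#' Flanks are truncated at chromosome ends.
#'
#' @param reference a named [Biostrings::DNAStringSet].
#' @param chrom,pos vectors locating the variants.
#' @param flank_len maximum flank length (default 50).
#' @return data.frame with `left_flank`, `right_flank`.
#' @export
extract_flanks <- function(reference, chrom, pos, flank_len = 50) {
  lens <- Biostrings::width(reference)[match(chrom, names(reference))]
  if (anyNA(lens)) stop("variant chromosome absent from reference")
  if (any(pos < 1 | pos > lens)) stop("variant position beyond chromosome end")
  left <- character(length(pos)); right <- character(length(pos))
  for (ch in unique(chrom)) {
    s <- as.character(reference[[ch]])
    i <- which(chrom == ch)
    left[i] <- substring(s, pmax(1, pos[i] - flank_len), pos[i] - 1)
    right[i] <- substring(s, pos[i] + 1, pmin(nchar(s), pos[i] + flank_len))
  }
  data.frame(left_flank = left, right_flank = right, stringsAsFactors = FALSE)
}

# trim one flank at N-runs; `side` = "left" keeps the variant-proximal suffix,
# "right" the prefix.
trim_one_flank <- function(seq, side, max_run = 3) {
  m <- gregexpr(sprintf("N{%d,}", max_run + 1L), seq)[[1]]
  if (m[1] == -1) return(seq)
  if (side == "left") {
    # variant sits at the right end: cut after the run closest to the variant
    last_end <- max(m + attr(m, "match.length") - 1L)
    substring(seq, last_end + 1L, nchar(seq))
  } else {
    substring(seq, 1L, min(m) - 1L)
  }
}

#' Trim flanks at runs of N and decide probe viability
#'
#' A flank containing a run of more than `max_run` N bases is truncated at
#' the run boundary nearest the variant (the variant-proximal segment is
#' kept). The candidate is kept iff the shorter trimmed flank still has at
#' least `min_short` bp and the longer one has the full `full_len` bp.
#'
#' @param left,right character vectors of flanks (each <= `full_len` bp).
#' @param max_run longest tolerated N run (default 3).
#' @param min_short minimum length of the shorter flank (default 20).
#' @param full_len required length of the longer flank (default 50).
#' @return data.frame `left_trimmed`, `right_trimmed`, `keep`.
#' @export
trim_flank_n_runs <- function(left, right, max_run = 3, min_short = 20, full_len = 50) {
  lt <- vapply(left, trim_one_flank, character(1), side = "left",
               max_run = max_run, USE.NAMES = FALSE)
  rt <- vapply(right, trim_one_flank, character(1), side = "right",
               max_run = max_run, USE.NAMES = FALSE)
  ll <- nchar(lt); rl <- nchar(rt)
  keep <- pmin(ll, rl) >= min_short & pmax(ll, rl) == full_len
  data.frame(left_trimmed = lt, right_trimmed = rt, keep = keep,
             stringsAsFactors = FALSE)
}

#' Strand-ambiguous allele pair?
#'
#' A SNP is ambiguous iff its unordered allele pair is {A,T} or {C,G}: a
#' strand flip maps the pair onto itself, so genotyping such a SNP needs four
#' probes instead of two.
#'
#' @param ref,alt single-base allele vectors.
#' @return logical vector.
#' @export
classify_ambiguity <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("non-ACGT allele")
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

# integer encoding of a chromosome for the ungapped scan aligner
.seq_ints <- function(s) utf8ToInt(toupper(s))

# mismatch counts of `pattern` at every offset of `subject` (both strings)
mismatch_profile <- function(subject, pattern) {
  si <- .seq_ints(subject); pi <- .seq_ints(pattern)
  L <- length(si); m <- length(pi)
  if (L < m) return(integer(0))
  n_off <- L - m + 1L
  mism <- integer(n_off)
  for (k in seq_len(m)) mism <- mism + (si[k:(k + n_off - 1L)] != pi[k])
  mism
}

revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# all best-scoring (match +1 / mismatch -1, ungapped) hits of a probe across
# a genome, both strands; returns data.frame(chrom, start, strand, score)
scan_hits <- function(genome_chars, probe, min_score = -Inf) {
  hits <- list()
  for (ch in names(genome_chars)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") probe else revcomp(probe)
      mm <- mismatch_profile(genome_chars[[ch]], pat)
      if (length(mm) == 0) next
      sc <- nchar(probe) - 2L * mm
      at <- which(sc >= min_score)
      if (length(at)) {
        hits[[length(hits) + 1]] <- data.frame(
          chrom = ch, start = at, strand = strand, score = sc[at],
          mismatches = mm[at], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(0), start = integer(0), strand = character(0),
               score = integer(0), mismatches = integer(0))
}

#' Probe flanking-sequence uniqueness
#'
#' Checks whether, for at least one side of the variant, the variant-proximal
#' `probe_len`-mer has a unique best placement in the reference (no
#' co-optimal hit on either strand) located at the expected locus on the
#' variant's chromosome. `mode = "exact"` counts exact occurrences of the
#' k-mer and its reverse complement; `mode = "scored"` runs an ungapped scan
#' (match +1, mismatch -1) and requires the best score to beat all other
#' placements (co-optimal margin 0).
#'
#' @param reference a named [Biostrings::DNAStringSet].
#' @param chrom,pos variant coordinates (vectors).
#' @param left,right (possibly trimmed) flank sequences.
#' @param probe_len probe length (default 35).
#' @param mode `"exact"` (default) or `"scored"`.
#' @return logical vector: TRUE iff at least one side is unique. Candidates
#'   with both flanks shorter than `probe_len` are FALSE, with reason
#'   attribute `"reason"` set to `"flanks_too_short"` at those entries.
#' @export
flank_uniqueness <- function(reference, chrom, pos, left, right,
                             probe_len = 35, mode = c("exact", "scored")) {
  mode <- match.arg(mode)
  n <- length(pos)
  out <- logical(n)
  reason <- rep(NA_character_, n)
  genome_chars <- NULL
  if (mode == "scored") {
    genome_chars <- stats::setNames(
      lapply(seq_along(reference), function(i) as.character(reference[[i]])),
      names(reference))
  }
  for (i in seq_len(n)) {
    sides <- list()
    if (nchar(left[i]) >= probe_len) {
      kmer <- substring(left[i], nchar(left[i]) - probe_len + 1L, nchar(left[i]))
      sides[[length(sides) + 1]] <- list(kmer = kmer, exp_start = pos[i] - probe_len)
    }
    if (nchar(right[i]) >= probe_len) {
      sides[[length(sides) + 1]] <- list(kmer = substring(right[i], 1L, probe_len),
                                         exp_start = pos[i] + 1L)
    }
    if (length(sides) == 0) { reason[i] <- "flanks_too_short"; next }
    uniq <- FALSE
    for (sd in sides) {
      if (mode == "exact") {
        fwd <- Biostrings::vmatchPattern(sd$kmer, reference)
        rev <- Biostrings::vcountPattern(revcomp(sd$kmer), reference)
        n_fwd <- sum(S4Vectors::elementNROWS(fwd))
        if (n_fwd + sum(rev) != 1L || n_fwd != 1L) next
        hit_chr <- names(reference)[which(S4Vectors::elementNROWS(fwd) == 1L)]
        hit_start <- IRanges::start(fwd[[which(S4Vectors::elementNROWS(fwd) == 1L)]])
        if (hit_chr == chrom[i] && hit_start == sd$exp_start) uniq <- TRUE
      } else {
        hits <- scan_hits(genome_chars, sd$kmer)
        best <- max(hits$score)
        top <- hits[hits$score == best, , drop = FALSE]
        if (nrow(top) == 1L && top$chrom == chrom[i] && top$strand == "+" &&
            top$start == sd$exp_start) uniq <- TRUE
      }
      if (uniq) break
    }
    out[i] <- uniq
  }
  attr(out, "reason") <- reason
  out
}

#' Build a probe-candidate table from a call set
#'
#' Extracts and trims flanks, flags strand-ambiguous allele pairs, counts
#' heterozygous doubled-haploid lines, and attaches per-population MAF
#' columns (`maf_<population>`) computed over the roster's populations.
#'
#' @param cs a bi-allelic CallSet.
#' @param reference a named [Biostrings::DNAStringSet].
#' @param flank_len flank length (default 50).
#' @param maf_callsets optional named list of CallSets from which to compute
#'   per-population MAF (matched by variant key); defaults to `cs` itself,
#'   split by roster population.
#' @return a candidate data.frame.
#' @export
probe_candidates <- function(cs, reference, flank_len = 50, maf_callsets = NULL) {
  stopifnot(all(is_biallelic_snp(cs)))
  r <- cs$records
  fl <- extract_flanks(reference, r$chrom, r$pos, flank_len)
  tr <- trim_flank_n_runs(fl$left_flank, fl$right_flank, full_len = flank_len)
  cand <- data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
                     left_flank = fl$left_flank, right_flank = fl$right_flank,
                     left_trimmed = tr$left_trimmed, right_trimmed = tr$right_trimmed,
                     trim_keep = tr$keep,
                     ambiguous = classify_ambiguity(r$ref, r$alt),
                     stringsAsFactors = FALSE)
  dh <- cs$roster$sample_id[cs$roster$role == "doubled_haploid"]
  cand$n_het_dh <- if (length(dh)) rowSums(is_het_matrix(cs, samples = dh)) else 0L
  if (is.null(maf_callsets)) {
    for (popn in unique(cs$roster$population)) {
      samp <- cs$roster$sample_id[cs$roster$population == popn]
      cand[[paste0("maf_", popn)]] <- compute_maf(cs, samples = samp)
    }
  } else {
    keys <- variant_keys(cs)
    for (popn in names(maf_callsets)) {
      src <- maf_callsets[[popn]]
      m <- compute_maf(src)
      cand[[paste0("maf_", popn)]] <- m[match(keys, variant_keys(src))]
    }
  }
  cand$legacy <- FALSE
  cand
}

#' Add a `flank_unique` column to a candidate table
#' @param cand candidate data.frame from [probe_candidates()].
#' @param reference reference genome.
#' @param probe_len,mode see [flank_uniqueness()].
#' @return `cand` with a logical `flank_unique` column.
#' @export
add_flank_uniqueness <- function(cand, reference, probe_len = 35, mode = "exact") {
  cand$flank_unique <- as.logical(flank_uniqueness(
    reference, cand$chrom, cand$pos, cand$left_trimmed, cand$right_trimmed,
    probe_len = probe_len, mode = mode))
  cand
}

maf_columns <- function(cand) grep("^maf_", names(cand), value = TRUE)

#' Window-density balancing
#'
#' Chromosomes are tiled with non-overlapping windows starting at coordinate
#' 0. In windows that received more than `max_per_window` candidates, only
#' candidates whose maximum MAF over populations is at least `maf_floor`
#' survive ("more than" is strict: a window with exactly `max_per_window`
#' candidates is untouched). No further cap is applied.
#'
#' @param cand candidate data.frame with `maf_*` columns.
#' @param window window width in bp (default 100 kb).
#' @param max_per_window count above which the MAF floor kicks in (default 30).
#' @param maf_floor MAF threshold in dense windows (default 0.15).
#' @return the thinned candidate data.frame.
#' @export
density_adjust <- function(cand, window = 100000, max_per_window = 30, maf_floor = 0.15) {
  if (window <= 0) stop("window must be > 0")
  if (nrow(cand) == 0) return(cand)
  win <- floor((cand$pos - 1) / window)
  keycol <- paste(cand$chrom, win, sep = "\r")
  counts <- table(keycol)
  dense <- keycol %in% names(counts)[counts > max_per_window]
  mafs <- as.matrix(cand[, maf_columns(cand), drop = FALSE])
  maxmaf <- do.call(pmax, c(as.data.frame(mafs), list(na.rm = TRUE)))
  keep <- !dense | (!is.na(maxmaf) & maxmaf >= maf_floor)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  append_attrition(out, cand, sprintf("density>%d/%gkb", max_per_window, window / 1000),
                   nrow(cand), nrow(out))
}

#' Preselection round
#'
#' Applies, in order: bi-allelic check (candidates are bi-allelic by
#' construction, kept for the attrition record), the MAF rule (`quantifier =
#' "all"`: MAF >= floor in every named population; `"any"`: in at least one),
#' the doubled-haploid heterozygosity cap, flank trimming viability and
#' flank uniqueness. Per-predicate attrition is recorded.
#'
#' @param cand candidate data.frame (with `flank_unique` already computed).
#' @param populations population names whose `maf_<pop>` columns are tested.
#' @param maf_floor MAF floor (default 0.10).
#' @param quantifier `"all"` or `"any"`.
#' @param max_het_dh maximum heterozygous DH lines (default 4).
#' @return the preselected subset with an attrition ledger.
#' @export
preselect <- function(cand, populations, maf_floor = 0.10,
                      quantifier = c("all", "any"), max_het_dh = 4) {
  quantifier <- match.arg(quantifier)
  cols <- paste0("maf_", populations)
  missing_cols <- setdiff(cols, names(cand))
  if (length(missing_cols)) stop("unknown population in spec: ",
                                 paste(sub("^maf_", "", missing_cols), collapse = ", "))
  step <- function(x, keep, label) {
    out <- x[keep, , drop = FALSE]
    rownames(out) <- NULL
    append_attrition(out, x, label, nrow(x), nrow(out))
  }
  out <- step(cand, rep(TRUE, nrow(cand)), "biallelic")
  m <- as.matrix(out[, cols, drop = FALSE])
  pass <- if (quantifier == "all") {
    rowSums(!is.na(m) & m >= maf_floor) == length(cols)
  } else {
    rowSums(!is.na(m) & m >= maf_floor) >= 1
  }
  out <- step(out, pass, sprintf("maf>=%g[%s:%s]", maf_floor, quantifier,
                                 paste(populations, collapse = "+")))
  out <- step(out, out$n_het_dh <= max_het_dh, sprintf("dh_het<=%d", max_het_dh))
  out <- step(out, out$trim_keep, "flank_trim")
  if (is.null(out$flank_unique)) stop("run add_flank_uniqueness() first")
  step(out, out$flank_unique, "flank_unicity")
}

#' Assemble the final panel
#'
#' Union of the preselected candidates and the legacy (prior-array) markers,
#' minus candidates annotated `not_recommended` by the external designability
#' score. Strand-ambiguous candidates are excluded from the selected set but
#' legacy markers are exempt. Duplicate variant keys collapse to one entry
#' with the legacy flag preserved; a position shared by a selected candidate
#' and a legacy marker with different alleles is an error.
#'
#' @param selected preselected candidate data.frame.
#' @param legacy data.frame of legacy markers (chrom, pos, ref, alt, plus
#'   optional flank columns), or NULL.
#' @param designability data.frame (key, designable) with `designable` in
#'   recommended / neutral / not_recommended; unknown keys are `unknown`.
#' @return the panel data.frame (columns of `selected` plus `legacy` and
#'   `designable`).
#' @export
assemble_panel <- function(selected, legacy = NULL, designability = NULL) {
  sel <- selected[!selected$ambiguous, , drop = FALSE]
  sel$legacy <- FALSE
  if (!is.null(legacy) && nrow(legacy) > 0) {
    leg <- legacy
    for (col in setdiff(names(sel), names(leg))) leg[[col]] <- NA
    leg <- leg[, names(sel), drop = FALSE]
    leg$legacy <- TRUE
    pos_key_sel <- paste(sel$chrom, sel$pos, sep = "\r")
    pos_key_leg <- paste(leg$chrom, leg$pos, sep = "\r")
    full_sel <- variant_keys(sel); full_leg <- variant_keys(leg)
    clash <- pos_key_leg %in% pos_key_sel & !(full_leg %in% full_sel)
    if (any(clash)) stop("key collision with conflicting alleles at ",
                         paste(utils::head(full_leg[clash], 3), collapse = ", "))
    panel <- rbind(sel, leg)
  } else {
    panel <- sel
  }
  key <- variant_keys(panel)
  legacy_by_key <- tapply(panel$legacy, key, any)
  panel <- panel[!duplicated(key), , drop = FALSE]
  panel$legacy <- as.logical(legacy_by_key[variant_keys(panel)])
  panel$designable <- "unknown"
  if (!is.null(designability)) {
    m <- match(variant_keys(panel), designability$key)
    panel$designable[!is.na(m)] <- designability$designable[m[!is.na(m)]]
  }
  panel <- panel[panel$designable != "not_recommended", , drop = FALSE]
  ord <- order(match(panel$chrom, unique(panel$chrom)), panel$pos)
  panel <- panel[ord, , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Write panel as TSV and probe FASTA
#'
#' The FASTA encodes each probe as left flank, the alleles as `[ref/alt]`,
#' and the right flank (array-submission style), one record per marker keyed
#' `chrom:pos:ref:alt`.
#'
#' @param panel panel data.frame from [assemble_panel()].
#' @param tsv,fasta output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(panel, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    defl <- sprintf(">%s", variant_keys(panel))
    seqs <- sprintf("%s[%s/%s]%s", panel$left_trimmed, panel$ref, panel$alt,
                    panel$right_trimmed)
    writeLines(as.vector(rbind(defl, seqs)), fasta)
  }
  invisible(c(tsv = tsv, fasta = fasta))
}
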