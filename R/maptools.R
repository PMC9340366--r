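# Probe remapping to a second assembly and marker density / gap statistics.

#' Map probes to a target reference with best-hit uniqueness
#'
#' Exhaustive ungapped scan (match +1, mismatch -1) of each probe and its
#' reverse complement over the target; hits below `identity_min` are
#' discarded. A probe is uniquely placed iff its best hit's score beats every
#' other hit's score by more than the `score_edge` fraction (best-hit-edge
#' semantics: a runner-up with score >= best*(1 - score_edge) voids
#' uniqueness). Probes with no surviving hit are `unplaced`; probes with a
#' non-unique best are `rejected`; the two are reported separately.
#'
#' An external aligner's tabular hits can be used instead via
#' [placements_from_hits()].
#'
#' @param probes named character vector of probe sequences (>= 20 bp).
#' @param target a named [Biostrings::DNAStringSet] (non-empty).
#' @param identity_min minimum identity fraction of a hit (default 0.95).
#' @param score_edge best-hit score-edge fraction (default 0.1).
#' @return data.frame: probe, status (`unique` / `rejected` / `unplaced`),
#'   chrom, start (1-based), strand, score, identity.
#' @export
map_probes <- function(probes, target, identity_min = 0.95, score_edge = 0.1) {
  if (length(target) == 0) stop("empty target reference")
  if (any(nchar(probes) < 20)) stop("probes must be >= 20 bp")
  nm <- names(probes) %||% as.character(seq_along(probes))
  genome_chars <- stats::setNames(
    lapply(seq_along(target), function(i) as.character(target[[i]])), names(target))
  rows <- lapply(seq_along(probes), function(i) {
    m <- nchar(probes[i])
    max_mm <- floor((1 - identity_min) * m)
    hits <- scan_hits(genome_chars, probes[i], min_score = m - 2L * max_mm)
    if (nrow(hits) == 0) {
      return(data.frame(probe = nm[i], status = "unplaced", chrom = NA_character_,
                        start = NA_integer_, strand = NA_character_,
                        score = NA_real_, identity = NA_real_,
                        stringsAsFactors = FALSE))
    }
    best <- max(hits$score)
    runner <- sort(hits$score, decreasing = TRUE)[2]
    unique_best <- sum(hits$score == best) == 1L &&
      (is.na(runner) || runner < best * (1 - score_edge))
    top <- hits[which.max(hits$score), , drop = FALSE]
    data.frame(probe = nm[i], status = if (unique_best) "unique" else "rejected",
               chrom = top$chrom, start = top$start, strand = top$strand,
               score = top$score, identity = 1 - top$mismatches / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Derive placements from external tabular alignment hits
#'
#' Accepts outfmt-6-style hits (columns: probe, chrom, identity, start,
#' score, strand) and applies the same identity floor and best-hit
#' score-edge uniqueness rule as [map_probes()].
#'
#' @param hits data.frame of candidate hits.
#' @param identity_min,score_edge as in [map_probes()].
#' @return placements data.frame in the [map_probes()] format.
#' @export
placements_from_hits <- function(hits, identity_min = 0.95, score_edge = 0.1) {
  hits <- hits[hits$identity >= identity_min, , drop = FALSE]
  rows <- lapply(split(hits, hits$probe), function(h) {
    best <- max(h$score)
    runner <- sort(h$score, decreasing = TRUE)[2]
    unique_best <- sum(h$score == best) == 1L &&
      (is.na(runner) || runner < best * (1 - score_edge))
    top <- h[which.max(h$score), , drop = FALSE]
    data.frame(probe = top$probe, status = if (unique_best) "unique" else "rejected",
               chrom = top$chrom, start = top$start,
               strand = top$strand %||% "+", score = top$score,
               identity = top$identity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-marker distance statistics
#'
#' Gaps are successive position differences within each chromosome. When
#' `chrom_sizes` is supplied, the trailing gap from the last marker to the
#' chromosome end is included (chromosome-end gaps are real coverage holes).
#'
#' @param positions_by_chrom named list of sorted marker positions.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param gap_threshold report the fraction of gaps above this (default 10 kb).
#' @param top_k number of largest gaps to report with coordinates.
#' @return list: `gaps` (data.frame chrom, start, end, gap), `median`,
#'   `mean`, `frac_above`, `largest` (top-k rows).
#' @export
intermarker_stats <- function(positions_by_chrom, chrom_sizes = NULL,
                              gap_threshold = 10000, top_k = 3) {
  gap_list <- lapply(names(positions_by_chrom), function(ch) {
    p <- positions_by_chrom[[ch]]
    if (is.unsorted(p)) stop("positions must be sorted (chromosome ", ch, ")")
    g <- if (length(p) > 1) {
      data.frame(chrom = ch, start = p[-length(p)], end = p[-1], gap = diff(p))
    } else {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 gap = numeric(0))
    }
    if (!is.null(chrom_sizes) && length(p) > 0 && ch %in% names(chrom_sizes)) {
      endgap <- chrom_sizes[[ch]] - p[length(p)]
      if (endgap > 0) {
        g <- rbind(g, data.frame(chrom = ch, start = p[length(p)],
                                 end = chrom_sizes[[ch]], gap = endgap))
      }
    }
    g
  })
  gaps <- do.call(rbind, gap_list)
  rownames(gaps) <- NULL
  if (nrow(gaps) == 0) {
    return(list(gaps = gaps, median = NA_real_, mean = NA_real_,
                frac_above = NA_real_, largest = gaps))
  }
  list(gaps = gaps,
       median = stats::median(gaps$gap),
       mean = mean(gaps$gap),
       frac_above = mean(gaps$gap > gap_threshold),
       largest = gaps[order(-gaps$gap), ][seq_len(min(top_k, nrow(gaps))), ])
}

#' Marker counts in tiled windows
#'
#' Windows tile each chromosome from coordinate 0; counts conserve the total
#' marker number.
#'
#' @param positions_by_chrom named list of marker positions.
#' @param window window width in bp (default 1 Mb).
#' @param chrom_sizes optional named vector; when given, trailing empty
#'   windows up to the chromosome end are included in the track.
#' @return list: `track` (data.frame chrom, start, count) and `summary`
#'   (mean, median, min, max over windows).
#' @export
density_per_window <- function(positions_by_chrom, window = 1e6, chrom_sizes = NULL) {
  if (window <= 0) stop("window must be > 0")
  tr <- lapply(names(positions_by_chrom), function(ch) {
    p <- positions_by_chrom[[ch]]
    size <- if (!is.null(chrom_sizes) && ch %in% names(chrom_sizes))
      chrom_sizes[[ch]] else if (length(p)) max(p) else 0
    n_win <- max(1L, ceiling(size / window))
    counts <- tabulate(floor((p - 1) / window) + 1L, nbins = n_win)
    data.frame(chrom = ch, start = (seq_len(n_win) - 1) * window, count = counts)
  })
  track <- do.call(rbind, tr)
  rownames(track) <- NULL
  list(track = track,
       summary = c(mean = mean(track$count), median = stats::median(track$count),
                   min = min(track$count), max = max(track$count)))
}
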