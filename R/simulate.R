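# Synthetic-data generators: reference genomes with duplicated segments,
# Wright-Fisher haplotypes with recombination, doubled-haploid call sets with
# PSV-style heterozygous artifacts, and diploid call sets.
#
# All operations draw from named substreams of `config$seed`, so identical
# (config, seed) pairs give byte-identical outputs and adding one operation
# to a pipeline does not perturb the others.

#' Simulation configuration
#'
#' Parameters of the synthetic study system: a small salmonid-like genome with
#' partially duplicated (pseudo-tetraploid) segments, a finite random-mating
#' population shaped by drift, recombination and recurrent mutation, and
#' genotyping imperfections.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param mutation_density expected density of mutable sites per bp; the
#'   segregating output density is somewhat lower (see the methods vignette).
#' @param duplicated_fraction fraction of each chromosome lying in duplicated
#'   segments (must be < 0.5 so donor and copy fit side by side).
#' @param psv_het_rate probability that a duplicated-segment site shows a
#'   spurious heterozygous call in a doubled-haploid line (PSV artifact).
#' @param Ne effective population size (diploid individuals; 2*Ne haplotypes).
#' @param recomb_rate recombination rate c, Morgans per bp.
#' @param genotype_error_rate per-genotype error probability.
#' @param missing_rate per-genotype missing probability for diploid samples.
#' @param seed master seed; every operation derives a named substream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2, chrom_length_bp = 100000,
                       mutation_density = 0.005, duplicated_fraction = 0.1,
                       psv_het_rate = 0.8, Ne = 50, recomb_rate = 1e-8,
                       genotype_error_rate = 0.001, missing_rate = 0.01,
                       seed = 1) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_length_bp = as.integer(chrom_length_bp),
              mutation_density = mutation_density,
              duplicated_fraction = duplicated_fraction,
              psv_het_rate = psv_het_rate,
              Ne = as.integer(Ne),
              recomb_rate = recomb_rate,
              genotype_error_rate = genotype_error_rate,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  probs <- c(duplicated_fraction = cfg$duplicated_fraction,
             psv_het_rate = cfg$psv_het_rate,
             genotype_error_rate = cfg$genotype_error_rate,
             missing_rate = cfg$missing_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities/fractions outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (cfg$Ne < 2) stop("Ne must be >= 2")
  if (cfg$n_chrom < 1 || cfg$chrom_length_bp < 1) stop("lengths must be positive")
  if (cfg$mutation_density < 0) stop("mutation_density must be >= 0")
  if (cfg$recomb_rate < 0) stop("recomb_rate must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference genome with duplicated segments
#'
#' Each chromosome is random DNA; a `duplicated_fraction` share of it is made
#' of segments copied from donor segments in the first half of the same
#' chromosome, emulating the residually tetraploid regions where
#' paralog-collapsed mapping creates PSVs. Copies are exact by default
#' (`copy_divergence = 0`), so probes inside them are provably non-unique;
#' set a small divergence to emulate older, partially diverged duplications.
#' The annotation covers the copy segments (where DH heterozygous artifacts
#' will be simulated).
#'
#' @param config a [sim_config()].
#' @param segment_bp target size of one duplicated segment.
#' @param copy_divergence per-base substitution rate applied to each copy.
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `segments`
#'   (BED-style data.frame: chrom, start, end, donor_start; 0-based
#'   half-open).
#' @export
simulate_reference <- function(config, segment_bp = 5000, copy_divergence = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duplicated_fraction >= 0.5)
    stop("duplicated_fraction >= 0.5: donor/copy layout impossible")
  L <- config$chrom_length_bp
  with_substream(config$seed, "reference", {
    seqs <- character(config$n_chrom)
    seg_list <- list()
    for (ci in seq_len(config$n_chrom)) {
      chrom <- sprintf("chr%d", ci)
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      dup_total <- round(config$duplicated_fraction * L)
      if (dup_total > 0) {
        seg_bp <- min(segment_bp, dup_total)
        n_seg <- max(1L, round(dup_total / seg_bp))
        seg_len <- rep(floor(dup_total / n_seg), n_seg)
        rem <- dup_total - sum(seg_len)
        if (rem > 0) seg_len[seq_len(rem)] <- seg_len[seq_len(rem)] + 1L
        half <- floor(L / 2)
        # copies tile the second half; donors drawn from the first half
        copy_starts <- cumsum(c(half, seg_len[-n_seg] + 100))
        if (copy_starts[n_seg] + seg_len[n_seg] > L)
          stop("duplicated segments do not fit; lower duplicated_fraction")
        for (si in seq_len(n_seg)) {
          don0 <- sample.int(half - seg_len[si], 1) # 0-based donor start
          cp0 <- copy_starts[si]
          seg <- base[(don0 + 1):(don0 + seg_len[si])]
          nmut <- rbinom(1, seg_len[si], copy_divergence)
          if (nmut > 0) {
            at <- sample.int(seg_len[si], nmut)
            seg[at] <- vapply(seg[at], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
          }
          base[(cp0 + 1):(cp0 + seg_len[si])] <- seg
          seg_list[[length(seg_list) + 1]] <- data.frame(
            chrom = chrom, start = cp0, end = cp0 + seg_len[si],
            donor_start = don0, stringsAsFactors = FALSE)
        }
      }
      seqs[ci] <- paste(base, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("chr%d", seq_len(config$n_chrom))
    segments <- if (length(seg_list)) do.call(rbind, seg_list) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 donor_start = integer(0))
    list(genome = genome, segments = segments)
  })
}

#' Write the duplicated-segment annotation as BED
#' @param segments the `segments` element of [simulate_reference()].
#' @param path output path (0-based half-open BED3).
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  utils::write.table(segments[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Forward Wright-Fisher simulation of haplotypes
#'
#' Evolves 2*Ne haplotypes per chromosome for `burnin_gens` generations
#' (default 4*Ne) under random mating, Poisson crossovers at `recomb_rate`
#' Morgans/bp and recurrent symmetric mutation at mutable sites placed at
#' `mutation_density` per bp, then returns the segregating sites. At
#' equilibrium the expected r-squared between sites declines with distance as
#' a function of 4*Ne*c*d.
#'
#' @param config a [sim_config()].
#' @param reference optional result of [simulate_reference()]; when given,
#'   reference alleles are the genome bases at the site positions.
#' @param burnin_gens generations to evolve (default 4*Ne).
#' @param theta scaled per-site mutation rate 4*Ne*mu (default 0.02, small
#'   enough that recurrent mutation does not mask the distance-dependence of
#'   LD created by recombination).
#' @return a `HaplotypeSet`: list with `sites` (chrom, pos, ref, alt) and
#'   `haplotypes` (2*Ne x n_sites 0/1 matrix).
#' @export
simulate_haplotypes <- function(config, reference = NULL, burnin_gens = NULL,
                                theta = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  if (config$mutation_density <= 0)
    stop("mutation_density must be > 0 to obtain segregating sites")
  n_hap <- 2L * config$Ne
  gens <- burnin_gens %||% (4L * config$Ne)
  mu <- theta / (4 * config$Ne)
  L <- config$chrom_length_bp
  with_substream(config$seed, "haplotypes", {
    site_list <- list(); hap_list <- list()
    for (ci in seq_len(config$n_chrom)) {
      chrom <- sprintf("chr%d", ci)
      n_cand <- max(2L, round(config$mutation_density * L))
      pos <- sort(sample.int(L, n_cand))
      H <- matrix(rbinom(n_hap * n_cand, 1, 0.5), nrow = n_hap)
      H <- wf_generations(H, pos, L, config$Ne, config$recomb_rate * L, mu, gens)
      freq <- colMeans(H)
      seg_sites <- which(freq > 0 & freq < 1)
      if (length(seg_sites) == 0) next
      pos <- pos[seg_sites]
      H <- H[, seg_sites, drop = FALSE]
      ref <- if (is.null(reference)) {
        sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      } else {
        substring(as.character(reference$genome[[chrom]]), pos, pos)
      }
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1), USE.NAMES = FALSE)
      site_list[[ci]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                                    stringsAsFactors = FALSE)
      hap_list[[ci]] <- H
    }
    if (length(site_list) == 0)
      stop("zero segregating sites after burn-in; increase mutation_density")
    sites <- do.call(rbind, site_list)
    rownames(sites) <- NULL
    haps <- do.call(cbind, hap_list)
    structure(list(sites = sites, haplotypes = haps, config = config),
              class = "HaplotypeSet")
  })
}

#' Build a HaplotypeSet directly from an allele-frequency spectrum
#'
#' Sites are independent; haplotype alleles are Bernoulli draws at the given
#' frequencies. This is the generator for populations with a specified
#' frequency spectrum (e.g. linkage-free random-mating null populations for
#' Hardy-Weinberg calibration).
#'
#' @param config a [sim_config()] (supplies `Ne` and the seed).
#' @param freqs allele-1 frequencies, one per site, strictly in (0,1).
#' @param chrom chromosome label(s) recycled over sites.
#' @param spacing_bp distance between successive site positions.
#' @return a `HaplotypeSet`.
#' @export
haplotypes_from_spectrum <- function(config, freqs, chrom = "chr1", spacing_bp = 100) {
  stopifnot(inherits(config, "sim_config"), all(freqs > 0 & freqs < 1))
  n_hap <- 2L * config$Ne
  S <- length(freqs)
  with_substream(config$seed, "spectrum", {
    H <- matrix(rbinom(n_hap * S, 1, rep(freqs, each = n_hap)), nrow = n_hap)
    ref <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    sites <- data.frame(chrom = rep_len(chrom, S),
                        pos = seq_len(S) * as.integer(spacing_bp),
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
    structure(list(sites = sites, haplotypes = H, config = config),
              class = "HaplotypeSet")
  })
}

# one chromosome's Wright-Fisher update: `gens` generations of random mating
# with Poisson crossovers (expectation exp_co per meiosis) and symmetric
# per-site mutation at rate mu. H is the 2*Ne x n_sites 0/1 matrix.
wf_generations <- function(H, pos, L, Ne, exp_co, mu, gens) {
  n_hap <- nrow(H)
  n_site <- ncol(H)
  for (g in seq_len(gens)) {
    parents <- sample.int(Ne, n_hap, replace = TRUE)
    n_co <- rpois(n_hap, exp_co)
    Hn <- H
    for (i in seq_len(n_hap)) {
      h1 <- 2L * parents[i] - 1L; h2 <- 2L * parents[i]
      if (runif(1) < 0.5) { tmp <- h1; h1 <- h2; h2 <- tmp }
      if (n_co[i] == 0L) {
        Hn[i, ] <- H[h1, ]
      } else {
        bp <- sort(runif(n_co[i], 0, L))
        seg <- findInterval(pos, bp)
        from1 <- seg %% 2L == 0L
        Hn[i, from1] <- H[h1, from1]
        Hn[i, !from1] <- H[h2, !from1]
      }
    }
    H <- Hn
    n_mut <- rbinom(1, n_hap * n_site, mu)
    if (n_mut > 0) {
      at <- sample.int(n_hap * n_site, n_mut)
      H[at] <- 1L - H[at]
    }
  }
  H
}

#' Evolve a haplotype set onward as a diverged sister population
#'
#' Continues the Wright-Fisher process from the current haplotypes for
#' `generations` further generations (same mating, recombination and mutation
#' model as [simulate_haplotypes()]), yielding a daughter population that has
#' drifted away from the source. Sites are kept as-is: markers ascertained in
#' the source population may be monomorphic in the daughter, exactly like
#' array markers genotyped in a distinct commercial line.
#'
#' @param haps a `HaplotypeSet`.
#' @param config a [sim_config()] (Ne, recombination rate and seed for the
#'   daughter population).
#' @param generations number of generations of divergence.
#' @param theta scaled per-site mutation rate (default 0.02).
#' @return a `HaplotypeSet` with the same `sites` table.
#' @export
evolve_haplotypes <- function(haps, config, generations, theta = 0.02) {
  stopifnot(inherits(haps, "HaplotypeSet"))
  if (nrow(haps$haplotypes) != 2L * config$Ne)
    stop("config$Ne must match the haplotype count (2*Ne haplotypes)")
  mu <- theta / (4 * config$Ne)
  L <- config$chrom_length_bp
  with_substream(config$seed, "evolve", {
    H <- haps$haplotypes
    for (ch in unique(haps$sites$chrom)) {
      idx <- which(haps$sites$chrom == ch)
      H[, idx] <- wf_generations(H[, idx, drop = FALSE], haps$sites$pos[idx],
                                 L, config$Ne, config$recomb_rate * L, mu,
                                 generations)
    }
    out <- haps
    out$haplotypes <- H
    out$config <- config
    out
  })
}

# sites (pos) falling in duplicated copy segments (0-based half-open BED)
sites_in_segments <- function(sites, segments) {
  if (is.null(segments) || nrow(segments) == 0) return(rep(FALSE, nrow(sites)))
  inseg <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(segments))) {
    inseg <- inseg | (sites$chrom == segments$chrom[i] &
                        sites$pos > segments$start[i] &
                        sites$pos <= segments$end[i])
  }
  inseg
}

#' Sample doubled-haploid call sets with PSV artifacts
#'
#' Each line doubles one haplotype, so true genotypes are homozygous
#' everywhere. Sites inside duplicated segments become heterozygous with
#' probability `psv_het_rate` per line (paralog-collapsed calling), and every
#' sample independently suffers random genotype errors at
#' `genotype_error_rate`. Replicated lines share the line genotype and differ
#' only by those independent errors.
#'
#' @param haps a `HaplotypeSet`.
#' @param segments duplicated-segment annotation from [simulate_reference()]
#'   (NULL for none).
#' @param n_lines number of doubled-haploid lines (<= haplotype count).
#' @param replicate_lines integer vector of line indices sequenced twice.
#' @param config a [sim_config()].
#' @param population population label for the roster.
#' @return a `CallSet` with a doubled-haploid roster (replicates named
#'   `<line>_r2` with lower depth rank).
#' @export
sample_doubled_haploids <- function(haps, segments, n_lines,
                                    replicate_lines = integer(0), config,
                                    population = "INRAE") {
  stopifnot(inherits(haps, "HaplotypeSet"))
  n_hap <- nrow(haps$haplotypes)
  if (n_lines > n_hap) stop("n_lines exceeds available haplotypes")
  if (length(replicate_lines) &&
      (any(replicate_lines < 1) || any(replicate_lines > n_lines)))
    stop("replicate_lines references unknown line")
  S <- nrow(haps$sites)
  with_substream(config$seed, "doubled_haploids", {
    hap_idx <- sample.int(n_hap, n_lines)
    dup <- sites_in_segments(haps$sites, segments)
    line_gt <- matrix(NA_character_, nrow = S, ncol = n_lines)
    for (li in seq_len(n_lines)) {
      a <- haps$haplotypes[hap_idx[li], ]
      g <- ifelse(a == 1L, "1/1", "0/0")
      if (any(dup) && config$psv_het_rate > 0) {
        psv <- dup & (runif(S) < config$psv_het_rate)
        g[psv] <- "0/1"
      }
      line_gt[, li] <- g
    }
    sample_ids <- sprintf("DH%02d", seq_len(n_lines))
    cols <- list(); ids <- character(0)
    line_of <- character(0); repgrp <- character(0); depth <- numeric(0)
    for (li in seq_len(n_lines)) {
      reps <- if (li %in% replicate_lines) 2L else 1L
      for (ri in seq_len(reps)) {
        g <- line_gt[, li]
        if (config$genotype_error_rate > 0) {
          err <- runif(S) < config$genotype_error_rate
          if (any(err)) {
            g[err] <- vapply(g[err], function(cur)
              sample(setdiff(c("0/0", "0/1", "1/1"), cur), 1), character(1))
          }
        }
        cols[[length(cols) + 1]] <- g
        ids <- c(ids, if (ri == 1) sample_ids[li] else paste0(sample_ids[li], "_r2"))
        line_of <- c(line_of, sample_ids[li])
        repgrp <- c(repgrp, if (reps > 1) sample_ids[li] else NA_character_)
        depth <- c(depth, if (ri == 1) 2 else 1)
      }
    }
    gt <- do.call(cbind, cols)
    colnames(gt) <- ids
    roster <- make_roster(ids, population = population, role = "doubled_haploid",
                          line_id = line_of, replicate_group = repgrp,
                          depth_rank = depth)
    rec <- haps$sites
    rec$AN <- 2 * length(ids)
    callset(rec, gt = gt, roster = roster)
  })
}

#' Sample a diploid population call set
#'
#' Individuals are formed by pairing haplotypes at random without replacement
#' (so the two haplotypes of an individual are always distinct draws), then
#' genotypes are masked missing at `missing_rate`.
#'
#' @param haps a `HaplotypeSet`.
#' @param n_ind number of diploid individuals (2*n_ind <= haplotype count).
#' @param config a [sim_config()].
#' @param population population label.
#' @return a `CallSet` of diploid samples.
#' @export
sample_diploids <- function(haps, n_ind, config, population = "pop1") {
  stopifnot(inherits(haps, "HaplotypeSet"))
  n_hap <- nrow(haps$haplotypes)
  if (2 * n_ind > n_hap) stop("2*n_ind exceeds available haplotypes")
  S <- nrow(haps$sites)
  with_substream(config$seed, "diploids", {
    perm <- sample.int(n_hap, 2L * n_ind)
    a1 <- haps$haplotypes[perm[seq_len(n_ind) * 2L - 1L], , drop = FALSE]
    a2 <- haps$haplotypes[perm[seq_len(n_ind) * 2L], , drop = FALSE]
    g <- matrix(paste0(pmin(t(a1), t(a2)), "/", pmax(t(a1), t(a2))),
                nrow = S, ncol = n_ind)
    if (config$missing_rate > 0) {
      miss <- matrix(runif(S * n_ind) < config$missing_rate, nrow = S)
      g[miss] <- "./."
    }
    ids <- sprintf("%s_ind%03d", population, seq_len(n_ind))
    colnames(g) <- ids
    roster <- make_roster(ids, population = population, role = "diploid")
    rec <- haps$sites
    rec$AN <- 2 * n_ind
    callset(rec, gt = g, roster = roster)
  })
}
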