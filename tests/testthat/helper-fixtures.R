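# Shared in-code fixtures: tiny call sets built by hand and a small simulated
# study system reused across test files.

# call set from a compact spec: list of rows chrom,pos,ref,alt + genotype rows
mini_callset <- function(pos, gt_rows, chrom = "chr1", ref = "A", alt = "T",
                         samples = NULL, roster = NULL, ...) {
  n <- length(pos)
  rec <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                    ref = rep_len(ref, n), alt = rep_len(alt, n),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (k in names(extra)) rec[[k]] <- extra[[k]]
  gt <- NULL
  if (!is.null(gt_rows)) {
    gt <- do.call(rbind, gt_rows)
    colnames(gt) <- samples %||% sprintf("s%d", seq_len(ncol(gt)))
  }
  callset(rec, gt = gt, roster = roster)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent enumeration oracle for the exact HWE test: direct factorial
# formula over every attainable heterozygote count
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa; n_a <- 2 * n - n_A
  if (min(n_A, n_a) == 0) return(1)
  probs <- c()
  hets <- c()
  for (h in 0:min(n_A, n_a)) {
    if ((n_A - h) %% 2 != 0) next
    aa <- (n_A - h) / 2; bb <- (n_a - h) / 2
    if (aa < 0 || bb < 0) next
    pr <- exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
                h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n))
    probs <- c(probs, pr); hets <- c(hets, h)
  }
  p_obs <- probs[hets == n_Aa]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# one shared simulated system (reference with duplications, WF haplotypes)
sim_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chrom = 2, chrom_length_bp = 50000,
                        mutation_density = 0.004, duplicated_fraction = 0.2,
                        psv_het_rate = 0.8, Ne = 30, recomb_rate = 1e-8,
                        genotype_error_rate = 0, missing_rate = 0, seed = 42)
      ref <- simulate_reference(cfg)
      haps <- simulate_haplotypes(cfg, ref, burnin_gens = 60)
      cache <<- list(cfg = cfg, ref = ref, haps = haps)
    }
    cache
  }
})
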