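test_that("MAF counts alleles over called genotypes only", {
  cs <- mini_callset(100, list(c("0/0", "0/1", "1/1", "0/0")))
  expect_equal(compute_maf(cs), 0.375)  # p = 3/8
  cs0 <- mini_callset(100, list(c("0/0", "0/0")))
  expect_equal(compute_maf(cs0), 0)
  csNA <- mini_callset(100, list(c("./.", "./.")))
  expect_true(is.na(compute_maf(csNA)))  # undefined, distinct from 0
})

test_that("MAF equals the brute-force allele tally on random genotype vectors", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 50
    gts <- sample(c("0/0", "0/1", "1/1", "./."), n, replace = TRUE)
    cs <- mini_callset(100, list(gts))
    alleles <- unlist(strsplit(gts[gts != "./."], "/"))
    p <- mean(alleles == "1")
    expect_equal(compute_maf(cs), if (length(alleles)) min(p, 1 - p) else NA_real_)
  }
})

test_that("database cleaning removes non-bi-allelic, off-chromosome and rare SNPs", {
  samples <- sprintf("s%d", 1:4)
  rec <- data.frame(chrom = c("chr1", "chr1", "chr1", "scaffold_12"),
                    pos = c(100, 200, 300, 50),
                    ref = c("A", "A", "A", "A"),
                    alt = c("T", "T,G", "G", "T"), stringsAsFactors = FALSE)
  gt <- rbind(c("0/1", "0/0", "0/0", "0/0"),   # MAF 1/8
              c("0/1", "0/2", "0/0", "0/0"),   # tri-allelic
              c("0/0", "0/0", "0/0", "0/0"),   # MAF 0
              c("0/1", "0/1", "0/1", "0/1"))   # scaffold
  colnames(gt) <- samples
  cs <- callset(rec[order(match(rec$chrom, unique(rec$chrom)), rec$pos), ],
                gt = gt, roster = make_roster(samples, population = "USDA"))
  out <- clean_database(cs, "USDA", maf_min = 0.01, chroms = paste0("chr", 1:29))
  expect_equal(out$records$pos, 100L)
  led <- attrition(out)
  expect_equal(led$input, led$removed + led$kept)
  expect_equal(led$input[-1], led$kept[-length(led$kept)])
  # boundary: MAF exactly at the floor is kept
  out2 <- clean_database(cs, "USDA", maf_min = 0.125, chroms = "chr1")
  expect_equal(out2$records$pos, 100L)
  out3 <- clean_database(cs, "USDA", maf_min = 0.126, chroms = "chr1")
  expect_equal(n_sites(out3), 0L)
  expect_error(clean_database(cs, "nosuch", chroms = "chr1"), "population")
  # idempotence
  expect_equal(variant_keys(clean_database(out, "USDA", chroms = paste0("chr", 1:29))),
               variant_keys(out))
})

dh_roster <- function(lines, reps = character(0)) {
  ids <- c(lines, paste0(reps, "_r2"))
  make_roster(ids, population = "INRAE", role = "doubled_haploid",
              line_id = c(lines, reps),
              replicate_group = c(ifelse(lines %in% reps, lines, NA), reps),
              depth_rank = c(rep(2, length(lines)), rep(1, length(reps))))
}

test_that("replicate concordance filter removes sites and deduplicates samples", {
  ros <- dh_roster(c("L1", "L2"), reps = c("L1", "L2"))
  gt <- rbind(c("0/0", "1/1", "0/0", "1/1"),  # both lines concordant
              c("0/0", "1/1", "1/1", "1/1"),  # L1 discordant
              c("0/0", "1/1", "1/1", "0/0"),  # both discordant
              c("0/0", "1/1", "./.", "0/0"))  # L1 missing rep: not discordant; L2 discordant
  colnames(gt) <- c("L1", "L2", "L1_r2", "L2_r2")
  cs <- mini_callset(c(10, 20, 30, 40), NULL)
  cs <- callset(cs$records, gt = gt, roster = ros)
  out <- replicate_concordance_filter(cs, max_discordant_lines = 1)
  expect_equal(out$records$pos, c(10L, 20L, 40L))  # only the 2-line discordant site goes
  expect_setequal(colnames(out$gt), c("L1", "L2"))  # deepest sample kept
  expect_error(replicate_concordance_filter(
    mini_callset(10, list("0/0"), roster = make_roster("s1"))), "replicate")
})

test_that("replicate filter equals the brute-force per-line comparison", {
  set.seed(5)
  n <- 500
  lines <- c("L1", "L2", "L3")
  ros <- dh_roster(lines, reps = lines)
  gpool <- c("0/0", "0/1", "1/1", "./.")
  gt <- matrix(sample(gpool, n * 6, replace = TRUE, prob = c(.4, .1, .4, .1)),
               nrow = n, dimnames = list(NULL, c(lines, paste0(lines, "_r2"))))
  cs <- callset(data.frame(chrom = "chr1", pos = seq_len(n) * 10, ref = "A",
                           alt = "T"), gt = gt, roster = ros)
  out <- replicate_concordance_filter(cs, max_discordant_lines = 1)
  disc_count <- sapply(seq_len(n), function(i) {
    sum(sapply(lines, function(l) {
      g <- gt[i, c(l, paste0(l, "_r2"))]
      g <- g[g != "./."]
      length(unique(g)) > 1
    }))
  })
  expect_equal(out$records$pos, (seq_len(n) * 10L)[disc_count <= 1])
})

test_that("DH heterozygosity filter enforces the max_het cap", {
  ros <- make_roster(sprintf("DH%02d", 1:12), role = "doubled_haploid",
                     line_id = sprintf("DH%02d", 1:12))
  mkgt <- function(n_het) {
    g <- rep("0/0", 12); if (n_het > 0) g[seq_len(n_het)] <- "0/1"; g
  }
  gt <- rbind(mkgt(2), mkgt(4), mkgt(0), mkgt(5))
  colnames(gt) <- ros$sample_id
  cs <- callset(data.frame(chrom = "chr1", pos = c(10, 20, 30, 40), ref = "A",
                           alt = "T"), gt = gt, roster = ros)
  expect_equal(dh_heterozygosity_filter(cs, max_het = 1)$records$pos, 30L)
  expect_equal(dh_heterozygosity_filter(cs, max_het = 4)$records$pos,
               c(10L, 20L, 30L))
  ros2 <- make_roster("s1")
  cs2 <- mini_callset(10, list("0/1"), roster = ros2)
  expect_error(dh_heterozygosity_filter(cs2), "doubled-haploid")
})

test_that("PSV-free DH data suffers no false removals", {
  sys <- sim_system()
  cfg0 <- sys$cfg; cfg0$psv_het_rate <- 0; cfg0$genotype_error_rate <- 0
  dh <- sample_doubled_haploids(sys$haps, sys$ref$segments, n_lines = 10,
                                config = cfg0)
  out <- dh_heterozygosity_filter(dh, max_het = 1)
  expect_equal(n_sites(out), n_sites(dh))
})

test_that("fully-genotyped filter matches the closed-form retention rate", {
  set.seed(9)
  n <- 10000; k <- 29; pmiss <- 0.1
  gt <- matrix(ifelse(runif(n * k) < pmiss, "./.", "0/1"), nrow = n,
               dimnames = list(NULL, sprintf("s%d", 1:k)))
  cs <- callset(data.frame(chrom = "chr1", pos = seq_len(n) * 100, ref = "A",
                           alt = "T"), gt = gt)
  out <- fully_genotyped_filter(cs)
  expected <- (1 - pmiss)^k
  sd3 <- 3 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(n_sites(out) / n - expected), sd3)
  cs1 <- mini_callset(10, list(c("0/0", "./.")))
  expect_equal(n_sites(fully_genotyped_filter(cs1)), 0L)
})
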