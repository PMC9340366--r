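test_that("spacing filter keeps sites >= min_distance from the nearest catalogued SNP", {
  cs <- mini_callset(c(100, 140, 300), NULL, alt = c("T", "G", "C"))
  out <- spacing_filter(cs, 50)
  expect_equal(out$records$pos, 300L)  # 100 & 140 are 40 apart: both removed
  single <- mini_callset(100, NULL)
  expect_equal(n_sites(spacing_filter(single, 50)), 1L)  # no neighbour
  boundary <- mini_callset(c(100, 150), NULL, alt = c("T", "G"))
  expect_equal(n_sites(spacing_filter(boundary, 50)), 2L)  # exactly 50: kept
})

test_that("spacing filter equals the all-pairs nearest-neighbour oracle", {
  set.seed(17)
  pos <- sort(sample(100000, 5000))
  pos <- pos[!duplicated(pos)]
  cs <- mini_callset(pos, NULL, alt = "T")
  out <- spacing_filter(cs, 50)
  nn <- vapply(seq_along(pos), function(i)
    min(abs(pos[i] - pos[-i])), numeric(1))  # O(n^2)-ish oracle
  expect_equal(out$records$pos, pos[nn >= 50])
})

test_that("flank extraction matches string slicing, truncating at chromosome ends", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 50), collapse = "")))
  fl <- extract_flanks(ref, "chr1", 51, flank_len = 50)
  s <- as.character(ref[[1]])
  expect_equal(fl$left_flank, substring(s, 1, 50))
  expect_equal(nchar(fl$left_flank), 50L)
  fl2 <- extract_flanks(ref, "chr1", 10, flank_len = 50)
  expect_equal(nchar(fl2$left_flank), 9L)
  expect_equal(fl2$left_flank, substring(s, 1, 9))
  set.seed(23)
  pos <- sample(200, 20)
  fl3 <- extract_flanks(ref, rep("chr1", 20), pos, flank_len = 7)
  expect_equal(fl3$left_flank, substring(s, pmax(1, pos - 7), pos - 1))
  expect_equal(fl3$right_flank, substring(s, pos + 1, pmin(200, pos + 7)))
  expect_error(extract_flanks(ref, "chr1", 201), "beyond chromosome end")
})

test_that("N-run trimming keeps the variant-proximal segment and applies the keep rule", {
  right50 <- strrep("A", 50)
  # left flank: 16 bases, NNNN, then 30 bases next to the variant
  left <- paste0(strrep("C", 16), "NNNN", strrep("G", 30))
  tr <- trim_flank_n_runs(left, right50)
  expect_equal(tr$left_trimmed, strrep("G", 30))
  expect_true(tr$keep)  # 30 >= 20 and the other side has the full 50
  # both sides trimmed below full length -> rejected
  both <- trim_flank_n_runs(left, paste0(strrep("T", 30), "NNNN", strrep("A", 16)))
  expect_equal(both$right_trimmed, strrep("T", 30))
  expect_false(both$keep)
  # runs of exactly max_run N are tolerated
  ok <- trim_flank_n_runs(paste0(strrep("C", 20), "NNN", strrep("G", 27)), right50)
  expect_equal(nchar(ok$left_trimmed), 50L)
  expect_true(ok$keep)
  # shorter side below min_short -> rejected
  short <- trim_flank_n_runs(paste0(strrep("C", 30), "NNNN", strrep("G", 16)), right50)
  expect_false(short$keep)
})

test_that("ambiguity classification: exactly the strand-symmetric pairs", {
  expect_true(classify_ambiguity("A", "T"))
  expect_false(classify_ambiguity("A", "G"))
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  amb <- classify_ambiguity(pairs$ref, pairs$alt)
  expect_equal(sum(amb), 4L)  # A/T, T/A, C/G, G/C of the 12 ordered pairs
  expect_error(classify_ambiguity("A", "N"), "non-ACGT")
})

test_that("flank uniqueness: unique 35-mers pass, duplicated-segment copies fail", {
  sys <- sim_system()
  cand <- probe_candidates(
    sample_diploids(sys$haps, n_ind = 10, config = sys$cfg), sys$ref$genome)
  cand <- add_flank_uniqueness(cand, sys$ref$genome)
  dup <- panelforge:::sites_in_segments(cand, sys$ref$segments)
  # sites deep inside exact duplicated copies can never have a unique probe
  seg <- sys$ref$segments
  deep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(seg))) {
    deep <- deep | (cand$chrom == seg$chrom[i] & cand$pos > seg$start[i] + 36 &
                      cand$pos <= seg$end[i] - 36)
  }
  if (any(deep)) expect_false(any(cand$flank_unique[deep]))
  expect_true(any(cand$flank_unique[!dup]))
  # both flanks shorter than the probe -> FALSE with a reason code
  ref <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 10)))
  u <- flank_uniqueness(ref, "chr1", 20, strrep("A", 10), strrep("C", 10))
  expect_false(as.logical(u))
  expect_equal(attr(u, "reason"), "flanks_too_short")
})

test_that("scored uniqueness flags near-duplicates that exact search misses", {
  set.seed(29)
  core <- paste(sample(c("A", "C", "G", "T"), 35, replace = TRUE), collapse = "")
  chars <- strsplit(core, "")[[1]]
  decoy <- chars
  at <- c(5, 20)
  for (i in at) decoy[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  decoy <- paste(decoy, collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  seqs <- paste0(pad(100), core, pad(100), decoy, pad(100))
  ref <- Biostrings::DNAStringSet(c(chr1 = seqs))
  pos <- 100 + 36  # variant right after the core 35-mer
  exact <- flank_uniqueness(ref, "chr1", pos, core, "", probe_len = 35,
                            mode = "exact")
  scored <- flank_uniqueness(ref, "chr1", pos, core, "", probe_len = 35,
                             mode = "scored")
  expect_true(as.logical(exact))   # 2-mismatch copy invisible to exact search
  expect_true(as.logical(scored))  # margin 0: 2 mismatches still distinct
  # an exact second copy defeats both modes
  ref2 <- Biostrings::DNAStringSet(c(chr1 = paste0(pad(50), core, pad(50), core,
                                                   pad(50))))
  expect_false(as.logical(flank_uniqueness(ref2, "chr1", 50 + 36, core, "",
                                           mode = "exact")))
  expect_false(as.logical(flank_uniqueness(ref2, "chr1", 50 + 36, core, "",
                                           mode = "scored")))
})

test_that("density balancing thins only windows above the cap and is idempotent", {
  set.seed(31)
  n <- 31
  cand <- data.frame(chrom = "chr1", pos = sort(sample(99999, n)), ref = "A",
                     alt = "G", maf_USDA = c(rep(0.2, 10), rep(0.05, n - 10)),
                     maf_INRAE = 0.05, stringsAsFactors = FALSE)
  out <- density_adjust(cand, window = 100000, max_per_window = 30,
                        maf_floor = 0.15)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$maf_USDA >= 0.15))
  # exactly 30 in a window: untouched ("more than 30" is strict)
  out30 <- density_adjust(cand[1:30, ], window = 100000)
  expect_equal(nrow(out30), 30L)
  # idempotent, and equals the brute-force window scan
  expect_equal(density_adjust(out, window = 100000), out,
               ignore_attr = "attrition")
  expect_equal(nrow(density_adjust(cand[0, , drop = FALSE])), 0L)
})

test_that("density balancing matches a group-by oracle on random candidates", {
  set.seed(37)
  n <- 2000
  cand <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                     pos = sample(500000, n), ref = "A", alt = "G",
                     maf_USDA = round(runif(n, 0, 0.5), 3),
                     maf_INRAE = round(runif(n, 0, 0.5), 3),
                     stringsAsFactors = FALSE)
  cand <- cand[!duplicated(cand[c("chrom", "pos")]), ]
  out <- density_adjust(cand, window = 100000, max_per_window = 30,
                        maf_floor = 0.15)
  win <- paste(cand$chrom, floor((cand$pos - 1) / 100000))
  keep <- unlist(lapply(split(seq_len(nrow(cand)), win), function(i) {
    if (length(i) > 30) i[pmax(cand$maf_USDA[i], cand$maf_INRAE[i]) >= 0.15] else i
  }))
  expect_setequal(paste(out$chrom, out$pos), paste(cand$chrom, cand$pos)[sort(keep)])
  # never increases a window above max(incoming, cap)
  win_out <- paste(out$chrom, floor((out$pos - 1) / 100000))
  expect_true(all(table(win_out)[names(table(win))] <= table(win), na.rm = TRUE))
})

test_that("preselection applies the round's predicates in order with a ledger", {
  cand <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400), ref = "A",
                     alt = "G", trim_keep = c(TRUE, TRUE, TRUE, FALSE),
                     flank_unique = c(TRUE, TRUE, FALSE, TRUE),
                     n_het_dh = c(0, 5, 0, 0),
                     maf_USDA = c(0.12, 0.30, 0.30, 0.30),
                     maf_INRAE = c(0.08, 0.30, 0.30, 0.30),
                     ambiguous = FALSE, stringsAsFactors = FALSE)
  # round 1: MAF >= 0.10 in both databases
  r1 <- preselect(cand, c("USDA", "INRAE"), maf_floor = 0.10, quantifier = "all")
  expect_equal(nrow(r1), 0L)  # each candidate fails some predicate
  led <- attrition(r1)
  expect_equal(led$input, led$removed + led$kept)
  expect_equal(led$kept[length(led$kept)], 0L)
  # round 2: INRAE only; candidate 1 still fails (0.08), candidate 2 the het cap
  r2 <- preselect(cand, "INRAE", maf_floor = 0.10)
  expect_equal(nrow(r2), 0L)
  cand$maf_INRAE[1] <- 0.12
  r3 <- preselect(cand, "INRAE", maf_floor = 0.10)
  expect_equal(r3$pos, 100)
  expect_error(preselect(cand, "NOPE"), "unknown population")
  expect_equal(nrow(preselect(cand[0, ], "INRAE")), 0L)
})

test_that("panel assembly follows the set algebra with legacy exemptions", {
  set.seed(41)
  n <- 100
  sel <- data.frame(chrom = "chr1", pos = seq_len(n) * 100, ref = "A", alt = "G",
                    left_trimmed = strrep("A", 50), right_trimmed = strrep("C", 50),
                    ambiguous = rep(c(FALSE, TRUE), c(90, 10)),
                    stringsAsFactors = FALSE)
  legacy <- data.frame(chrom = "chr1", pos = c(seq_len(10) * 100, 20005, 20015),
                       ref = "A", alt = c(rep("G", 10), "T", "T"),
                       stringsAsFactors = FALSE)
  desig <- data.frame(key = variant_keys(sel)[11:20],
                      designable = "not_recommended", stringsAsFactors = FALSE)
  panel <- assemble_panel(sel, legacy, desig)
  # oracle: 90 non-ambiguous selected - 10 not_recommended + 2 legacy-only
  # (10 legacy overlap selected and collapse)
  expect_equal(nrow(panel), 90 - 10 + 2)
  expect_equal(sum(panel$legacy), 12L)
  expect_true(all(panel$designable != "not_recommended"))
  # conflicting alleles at a shared position -> error
  bad_leg <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "C")
  expect_error(assemble_panel(sel, bad_leg), "collision")
  # ambiguous legacy markers are exempt from the ambiguity exclusion
  amb_leg <- data.frame(chrom = "chr1", pos = 99999, ref = "A", alt = "T")
  p2 <- assemble_panel(sel, amb_leg)
  expect_true(any(p2$pos == 99999))
})

test_that("panel TSV and probe FASTA are written in submission style", {
  panel <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                      left_trimmed = "ACGT", right_trimmed = "TTTT",
                      legacy = FALSE, designable = "unknown",
                      stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_panel(panel, tsv = tsv, fasta = fa)
  expect_equal(readLines(fa), c(">chr1:100:A:G", "ACGT[A/G]TTTT"))
  expect_equal(nrow(utils::read.table(tsv, header = TRUE)), 1L)
})
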