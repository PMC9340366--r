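---
title: "Methods: SNP array panel design, validation and LD analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP array panel design, validation and LD analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Salmonid genomes carry the residue of an ancestral whole-genome duplication:
large chromosome segments still exist in two near-identical copies. Short
reads from both copies collapse onto one locus during mapping, and the fixed
differences between the copies then masquerade as SNPs — paralogous sequence
variants (PSVs). A genotyping array built on PSVs wastes probes on markers
that can never cluster cleanly. panelforge implements the full cascade that
turns multi-population variant call sets into a spaced, probe-compatible,
density-balanced marker panel, and the validation analyses used after
genotyping: call rates, conversion categories, exact Hardy-Weinberg tests,
MAF spectra, probe remapping to a second assembly, and binned
linkage-disequilibrium (LD) decay.

The central trick for PSV removal is biological, not computational: doubled
haploid (DH) lines, produced by gynogenesis or androgenesis, carry two
identical chromosome sets and are therefore homozygous at every true locus.
A heterozygous call in a DH line is an artifact. Sites where more than
`max_het` DH lines are heterozygous are discarded
(`dh_heterozygosity_filter()`; `max_het = 1` for the strict screen on 12 DH
samples, `max_het = 4` for the relaxed preselection rule applied after
database merging can re-introduce sites).

# The pipeline and its parameters

## Call-set algebra

* `merge_callsets()` unions sites and samples keyed on (chrom, pos, ref).
  When two databases disagree on the alternate allele, the alternate lists
  are concatenated (first argument's order first) and the second call set's
  genotype indices are remapped *by allele string*, never positionally. A
  position with two different reference alleles is genuinely pathological;
  both records are kept, tagged `FILTER=REF_CONFLICT`, warned about, and
  excluded later by `clean_database()` — conservative and auditable.
* `intersect_callsets()` implements multi-caller consensus: only sites with
  identical (chrom, pos, ref, alt-set) in every caller's output survive, and
  genotypes are taken from a designated primary caller.
* `filter_info_thresholds()` applies GATK-style hard-filter disjunctions
  such as `"QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0 ||
  MQRankSum < -12.5 || ReadPosRankSum < -8.0"`. A record lacking an
  annotation is retained for that predicate, matching the convention of the
  tool those expressions are written for.

## Site filters

* MAF is counted over called alleles only; sites with no called allele are
  NA, deliberately distinct from MAF 0. The boundary convention is a single
  one everywhere: **keep iff MAF >= floor** (floors: 1% for database
  cleaning, 10% for preselection, 15% inside dense windows, 5% before LD).
* `replicate_concordance_filter()`: a line is discordant at a site when its
  two sequencing replicates carry different *called* genotypes — a missing
  genotype is not evidence of inconsistency. Sites with more than one
  discordant line are removed, after which only the deepest sample per line
  is retained.
* Half-missing genotypes (`./1`) are counted as missing (conservative).
* Every filter appends to an attrition ledger (`attrition()`), and
  `input = removed + kept` holds row-wise at every stage — pipeline
  accounting is asserted in the tests, not assumed.

## Probe design

* `spacing_filter()` (default 50 bp) measures the distance to the nearest
  SNP of the **full input catalogue**, not of the surviving set: a marker 40
  bp from a discarded SNP still risks probe-site polymorphism, so both
  members of a close pair are removed.
* Flanks are the up-to-50 bp on each side of the variant, excluding the
  variant base, truncated at chromosome ends. A flank containing a run of
  more than 3 N bases is truncated at the run boundary nearest the variant —
  probes anchor at the variant, so the variant-proximal segment is the one
  that matters. A candidate survives trimming iff its shorter flank keeps at
  least 20 bp and its longer flank the full 50 bp.
* `flank_uniqueness()` checks that for at least one side the
  variant-proximal 35-mer has a unique best placement (forward or reverse
  complement) at the expected locus. The default mode is an exact-match scan
  — deterministic and reproducible on any machine; a scored mode (ungapped,
  match +1 / mismatch -1, co-optimal margin 0) additionally resolves
  near-duplicate copies. We deliberately do not pin an external aligner
  version: its defaults drift, an exact scan does not.
* Ambiguity: an unordered allele pair {A,T} or {C,G} maps onto itself under
  a strand flip and needs four probes instead of two; such candidates are
  excluded from the selected set, with legacy markers exempt.
* `density_adjust()` tiles each chromosome with 100-kb windows from
  coordinate 0 (tiled, not sliding — deterministic and matching the per-100
  kb phrasing of the rule). In windows that received **more than** 30
  candidates, only candidates with MAF >= 15% in at least one database
  survive. No quota is enforced beyond the MAF floor: the rule is a filter,
  not a cap, so the operation is idempotent.
* `preselect()` chains the round predicates in declared order (bi-allelism,
  MAF floor with an all/any quantifier over databases, DH heterozygote cap,
  trim viability, flank unicity) and logs per-predicate attrition. Round 1
  demands MAF >= 10% in both databases; round 2 relaxes to the primary
  database only.
* `assemble_panel()` forms (selected ∪ legacy) minus `not_recommended`
  external-designability annotations, collapsing duplicate keys with the
  legacy flag preserved. Designability is modelled as an external annotation
  joined by variant key (`recommended` / `neutral` / `not_recommended` /
  `unknown`); reproducing the vendor's score is out of scope.

## Post-genotyping validation

* Conversion categories are a genotype-level approximation of array
  cluster QC, since cluster geometry is not available: `Failed` = SNP call
  rate < 97%; `MonoHighResolution` = only one allele observed;
  `NoMinorHom` = polymorphic but no minor-allele homozygote;
  `PolyHighResolution` = minor-allele homozygote present. Defining
  PolyHighResolution by the presence of the minor homozygote (rather than
  "all three genotype classes") makes the four categories a partition even
  for the rare two-homozygote-classes-no-het configuration; the tests
  assert exhaustiveness on arbitrary matrices.
* `hwe_exact_test()` is the conditional exact test: given the allele
  counts, sum the probabilities of all attainable heterozygote counts whose
  conditional probability does not exceed that of the observed count.
  Ties are included; mid-p is **not** used (standard exact-test
  convention). Probabilities come from log-gamma arithmetic; the test suite
  checks every genotype triple with n <= 50 against an independent
  factorial-formula enumeration at 1e-12.
* `qc_filter()` removes SNPs with call rate < 95% or HWE p < 1e-7, counting
  a SNP failing both once, under call rate — precedence keeps the two-way
  removal ledger disjoint. "Polymorphic" for reporting means MAF > 0.001.
* `maf_spectrum()` bins are half-open `[lo, hi)` with the last bin closed
  at 0.5 so totals are conserved.

## Remapping and density

`map_probes()` uses the same exhaustive ungapped scan, with best-hit-edge
uniqueness: a placement is unique iff every other hit scores below
`best * (1 - score_edge)` (default edge 0.1, identity floor 0.95). Unplaced
probes and probes with a non-unique best hit are reported separately, since
they mean different things for a panel (missing sequence vs duplication).
External tabular hits can be substituted via `placements_from_hits()`.
`intermarker_stats()` includes the trailing chromosome-end gap only when
chromosome sizes are supplied — end gaps are real coverage holes, but only
measurable when the end is known.

## LD

r² is the squared Pearson correlation of unphased alternate-allele dosages
over pairwise-complete samples — exactly what the standard command-line
tools compute on diploid data, and fully specified without phasing. Pairs
are restricted to the same chromosome, distance <= 1,001 kb and at most
50,000 intervening SNPs, after a MAF >= 5% filter. Distance bins are closed
on the right ((0, 2 kb], (2 kb, 4 kb], ...): a pair at exactly 2,000 bp
belongs to the first bin. The 1/(2n) sample-size inflation of r² is
subtracted only inside the simulator-recovery tests, never from reported
values. Relatedness pruning is greedy and deterministic: repeatedly remove
the sample with the most above-cutoff pairs, breaking ties toward the
lexicographically larger id, until no retained pair exceeds the cutoff
(0.12 by default) — determinism was preferred over bug-compatibility with
any particular tool's internal ordering.

# The synthetic study system

`sim_config()` + `simulate_reference()` + `simulate_haplotypes()` generate
a small genome and population with the statistical structure the pipeline
assumes:

* **Reference**: random DNA per chromosome; a `duplicated_fraction` share
  consists of segments copied (exactly, by default) from donors in the
  first half of the chromosome. Exact copies make probes inside them
  provably non-unique, which the uniqueness tests exploit;
  `copy_divergence` can add divergence to emulate older duplications.
  Segment-level placement is a free parameter of the model; the tiled
  second-half layout was chosen for determinism.
* **Population**: forward Wright-Fisher simulation — 2·Ne haplotypes,
  random mating, Poisson crossovers at c Morgans/bp, recurrent symmetric
  mutation — run for 4·Ne burn-in generations so the equilibrium
  E[r²] ≈ f(4·Ne·c·d) relationship holds. A forward simulation was chosen
  over a coalescent for transparency: the whole model is ~40 lines of
  plain R. `mutation_density` is the density of *mutable* sites per bp; the
  segregating output density is somewhat lower (about 10–25% of candidates
  segregate at a snapshot under the default scaled mutation rate).
* **theta = 0.02** (per-site 4·Ne·mu) by default: recurrent mutation must
  be rare relative to recombination across the distances of interest, or it
  flattens the LD decay the simulator exists to produce; 0.02 keeps the
  mutation "distance" (4·Ne·2mu = 0.04) far below the recombination scale
  at 50 kb–1 Mb while still maintaining hundreds of segregating sites per
  Mb. With Ne = 50 and c = 1e-8/bp, 4·Ne·c·d reaches ~2 only near 1 Mb, so
  the LD-recovery tests simulate 2-Mb chromosomes and read the far bins
  near 1 Mb; the short-range contrast is read at 0–2 kb vs 48–50 kb.
* **Doubled haploids**: each line doubles one haplotype (homozygous
  everywhere); sites inside duplicated segments become heterozygous with
  probability `psv_het_rate` per line — PSV artifacts are modelled at
  genotype level because genotypes are all the pipeline ever sees.
  Replicates share the line genotype and differ only through independent
  genotyping errors (a replicated line at error rate e disagrees at
  ≈ 2·e·(1−e) of sites, which the tests verify against the closed form).
* **Diploids**: random pairing of haplotypes without replacement (no
  individual can receive the same haplotype copy twice), missing genotypes
  at `missing_rate`. `evolve_haplotypes()` continues the Wright-Fisher
  process to create drifted sister populations — markers ascertained in the
  source deme can be monomorphic in the daughter, which is what populates
  the monomorphic conversion class during validation.
  `haplotypes_from_spectrum()` builds linkage-free populations at a
  specified frequency spectrum, used for Hardy-Weinberg calibration and
  relatedness nulls.
* **Determinism**: every operation draws from a named substream of the
  master seed, so identical (config, seed) give byte-identical outputs and
  adding one operation to a pipeline does not perturb the others.

What the generator does **not** emulate: read-level errors and mapping
(PSVs appear directly as genotype artifacts), array cluster geometry and
the vendor's designability scoring (modelled as an external annotation),
site-frequency spectra of real salmonid populations (the recurrent-mutation
equilibrium spectrum is flatter), and linked selection. Passing tests
therefore demonstrate that the *rules* are implemented correctly and behave
as theory predicts on a neutral model — not that the package reproduces any
particular empirical genome's numbers.

# Numerical choices and degenerate inputs

* Exact HWE ties are compared on log-probabilities with a 1e-9 absolute
  slack; monomorphic sites return p = 1 (single attainable configuration).
* Zero called alleles give MAF = NA, never 0; zero-variance dosage vectors
  make r² undefined and the pair is skipped with a count, never silently
  dropped.
* VCF coordinates are 1-based inclusive externally; all interval work (BED
  segments, density windows) is 0-based half-open, with windows tiling from
  coordinate 0.
* Genotypes are normalised on input to unphased sorted form (`1|0` → `0/1`),
  so comparisons are strand- and phase-order-free.

# Problem sizes

The test-suite simulations use 50 kb–2 Mb genomes, Ne = 30–100, hundreds to
a few thousand segregating sites, 20 Wright-Fisher replicates for the LD
shape checks, 100,000 SNPs for Hardy-Weinberg type-I calibration, and the
exhaustive HWE oracle sweep covers all ~23,000 genotype triples with
n <= 50. These sizes give stable averages for every property tested while
keeping a full run of suite plus acceptance script in the tens of minutes
on one core.

# Known limitations

* The exhaustive scan aligner is desk-scale (O(genome x probe)); for real
  genomes, feed external aligner hits through `placements_from_hits()`.
* Conversion categories cannot see cluster-shape failures; "Failed"
  collapses everything that is not a call-rate pass.
* The Wright-Fisher simulator is unsuitable for Ne much above a few
  hundred (burn-in is 4·Ne generations of explicit matings).
* `merge_callsets()` requires disjoint sample ids; merging the same cohort
  called twice is the job of `intersect_callsets()`, not merge.
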