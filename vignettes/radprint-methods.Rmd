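---
title: "Methods: de novo RAD genotyping and chromosome-print mapping"
author: "radprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo RAD genotyping and chromosome-print mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical and algorithmic choices behind
`radprint`: the genetic model, each stage's procedure and parameters,
what the simulator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## Genetic model and assumptions

The pipeline targets a backcross in a taxon whose females undergo
achiasmatic meiosis (no crossing over), as in Lepidoptera. Two
consequences carry the whole design:

* every progeny inherits one *intact* maternal homolog per chromosome,
  so a maternal-specific allele's presence/absence vector over progeny
  (its *segregation pattern*) takes exactly one of two values per
  chromosome, and those two values are bitwise complements — a
  *chromosome print*;
* crossing over in the father is informative, so paternal-specific
  alleles support a conventional two-point linkage map within each
  chromosome.

Assumptions: dominant (presence/absence) scoring of alleles; a single
mother and father; progeny sexes known if the W/Z pair is to be
identified; mother WZ so the W print equals the female indicator
vector. Sequencing is 51-base paired-end with a 5-base inline MID and a
6-base SbfI footprint; 40 tag bases identify the allele.

## Stage-by-stage procedure and tunable parameters

**Demultiplexing** (`demultiplex`). MID matching is exact — the
published MIDs are not error-correcting codes, and a one-mismatch
rescue would risk assigning reads to the wrong individual, which is far
more damaging here than losing a read. The footprint check is exact;
reads whose tag contains an N are discarded and counted (the clustering
distance has no N semantics). Qualities are decoded at Phred+33 (a
`phred_offset = 64` switch covers older encodings) and capped at 41.

**Unique collapsing** (`collapse_uniques`). Identical tags merge into
uniques with per-position *median* qualities; singletons (1 read) are
removed, since nothing downstream can corroborate them.

**Locus clustering** (`cluster_uniques`, `locus_threshold = 7`). The
distance between uniques sums, over mismatching positions, the product
of the two correct-call probabilities $(1-10^{-q_1/10})(1-10^{-q_2/10})$
computed from the median qualities. The threshold of 7 bases (out of
40) is deliberately liberal: over-clustering is recoverable downstream,
under-clustering is not. Clustering is single linkage; the candidate
pair screen by Hamming distance is exact because the weighted distance
never exceeds the Hamming distance and each mismatch contributes at
least $(1-10^{-q_{\min}/10})^2$.

**Allele calling** (`call_alleles`, `qual_threshold = 20`,
`max_error_frac = 0.1`). Within a locus, a base observed in exactly one
unique is masked as a likely sequencing error *only when that unique
holds less than 10% of the locus read count*. The qualifier matters: in
a clean heterozygous locus represented by exactly two well-supported
uniques, every SNP base is private to one unique, and an unconditional
single-unique rule would collapse all such loci into one allele. In
noisy data the unconditional rule survives only because error-derived
uniques corroborate true SNP bases; conditioning on relative support
makes the intent — "rare, private, therefore error" — explicit.
Positions whose mean quality falls below Q20 are ignored during
comparison. Uniques identical after masking merge; the representative
sequence is the highest-read-count member (ties broken
lexicographically), and a masked unique matching no allele stays as its
own allele so the frequency filters decide its fate.

**Fragment counting** (`count_fragments`). PCR duplicates of a sheared
fragment yield identical paired-end mates, so distinct mates estimate
independent DNA fragments. Fragment counts, not read counts, feed all
thresholds.

**Locus merging across individuals** (`merge_loci`,
`allele_mismatches = 3`). Two haplotypes are *allelic* (same locus)
when they differ at ≤ 3 of the 40 bases; per-individual loci union by
single linkage over allelic pairs. Allele *identity* across
individuals, by contrast, is exact sequence equality: after error
correction the same haplotype reads out as the same string, and
tolerating mismatches in identity would fuse the distinct haplotypes of
heterozygous loci. The mismatch parameter is exposed (0–6) because the
appropriate value depends on within-locus diversity of the organism.

**Normalization** (`estimate_scale_factor`, `normalize_and_filter`,
`min_fragments = 3`, `min_individuals = 2`). Fragment-count histograms
have a large error peak at 1–2 fragments, a trough, a main peak near
the per-allele depth, and a long repeat tail. The scale factor
$SF_i = (\min_m/\min_i + \max_m/\max_i)/2$ uses the trough and
main-peak x-positions, with the mother as reference ($SF_m = 1$).
Trough/peak reading is automated: y-values over the histogram's support
are smoothed with a centred window-3 moving average; the trough is the
first local minimum at $x \ge 2$ that lies strictly below the start of
the curve with nothing before it above that start (both guards are
structural: a dip that fails them separates two interior modes — e.g.
one-copy vs two-copy alleles — rather than the error peak from the main
peak); the peak is the global maximum beyond the trough, which also
ignores the repeat tail. When no valid trough exists (clean data
without an error peak, as in noise-free simulations) the estimator
falls back to the ratio of median fragment counts with a warning —
this preserves $SF_m = 1$ and the inverse-depth behaviour — and manual
per-individual overrides take precedence over both. Normalization
happens *before* thresholds; presence requires ≥ 3 normalized
fragments, and "present in a single individual" is judged after that
threshold.

**Chromosome prints** (`group_patterns`, `pair_complements`).
Candidates are grouped by exact pattern; all-ones patterns are set
aside as homozygous-maternal (not assignable). Complementary pairs are
ranked by total supporting alleles (ties by lexicographic pattern) and
numbered from 1; with `expected_chromosomes` set, surplus pairs join
the residuals. Any binary progeny label (sex, phenotype) can be matched
against prints with `match_label`; a chance pattern collision between
chromosomes is possible in principle (probability < 0.1% at 20 progeny
and 31 chromosomes) and would surface as a missing print pair.

**Paternal map** (`assign_by_allelism`, `propagate_patterns`,
`collapse_markers`, `build_groups`). Assignment requires all allelic
matches on one chromosome; propagation runs three passes — identical
pattern, exact complement, Hamming-1 — each re-anchored on everything
assigned so far, and a pattern claimed by two chromosomes is a logged
conflict that assigns nothing. Markers need ≥ 3 supporting alleles; a
pattern and its complement are one marker in opposite phase. The
backcross two-point LOD is implemented in closed form (the original
analysis delegated grouping to closed-source software; the
likelihood-ratio form here is standard and is verified in the tests
against a brute-force grid). Markers link when LOD > `lod_group` (2)
*and* recombinant count ≤ `max_link_diffs` (5 of 20); ordering is
exhaustive for ≤ 8 markers and greedy double-ended nearest-neighbour
with 2-opt refinement above that; adjacent distances use the
count-based `100/N` cM-per-crossover convention (5 cM at N = 20)
rather than a mapping function — Haldane/Kosambi corrections are
deliberately out of scope at these marker densities. Markers that link
to nothing are kept as singleton groups of length 0, so the map is a
partition, not a selection.

## The simulator: what it emulates, what it does not

`sim_config()` defaults describe the motivating experimental design: 31
chromosomes, Poisson(100) RAD loci per chromosome, 20 backcross
progeny, maternal and paternal heterozygosity 0.4, 20% shared parental
polymorphism, ~30 independent fragments per allele copy read ~1.4 times
each, log-normal depth variation (sdlog 0.35, unit mean) spanning the
order-of-magnitude spread seen across a multiplexed lane, per-base
substitution error 0.001 with consistent Q30 qualities, and a minimum
of 49 informative maternal alleles per chromosome (the smallest
per-chromosome count in the motivating study; heterozygosity is topped
up per chromosome to reach it). `male_crossovers = 0.42` per chromosome
per meiosis makes the expected total map $31 \times 0.42 \times 100
\approx 1300$ cM under the 100/N convention, matching the order of
published lepidopteran maps. Chromosome 1 is sex-linked: daughters are
exactly the progeny receiving the mother's homolog 2 (the W). Locus tag
sequences are random 40-mers kept ≥ 10 mismatches apart so true loci
never merge spuriously; within a locus, variants differ from the
ancestral sequence at single distinct positions, keeping all haplotype
pairs within the allelism threshold.

Not modelled: indels, paralogues and repeat families (the long
fragment-count tail of real libraries), restriction-site polymorphism
(allele dropout), base-composition-dependent error, quality decay along
the read, and crossover interference (crossovers are Poisson). Passing
tests on simulated data therefore demonstrate correctness of the
*inference machinery* under the stated generative model, not robustness
to repeat-rich genomes — on real data the liberal clustering threshold
and the fragment/individual filters are the main defences, and they are
parameters, not constants.

Two conventions fix the test conditions. The *clean* condition means
`per_base_error = 0` **and** uniform depth multipliers: with the
default log-normal depth spread, Poisson fragment sampling alone
produces ~10⁻⁴ presence dropout, enough to add an occasional
one-off residual pattern, and depth variation is a noise source in its
own right (it is exercised, together with sequencing error, by the
noisy-recovery tests at per-base error 0.001 across five seeds on a
6-chromosome genome — the noise parameters are fixed by the study
conditions, the genome size by tractability). Under the clean condition
the full 31-chromosome pipeline recovers exactly 62 non-constant
patterns pairing into 31 prints with every allele on its true
chromosome.

## Numerical choices and degenerate inputs

* Median of an even number of qualities is the mean of the central
  pair; base qualities are capped at 41.
* Representative-sequence ties (equal read counts) break
  lexicographically; print ranking ties break on lexicographic pattern;
  marker-phase ties take the lexicographically smaller pattern.
* `two_point_stats` handles $r = 0$ as $N \log_{10} 2$ and returns LOD
  0 at $r = 0.5$; patterns must be non-empty and of equal length.
* Empty inputs return empty outputs (collapsing, grouping); a
  zero-chromosome simulation writes valid empty files; an empty
  manifest, duplicate MIDs, or a missing parent are hard errors.
* `run_config` rejects unknown keys so a misspelled parameter cannot
  silently revert to its default.
* Read-count means in reports round half to even, matching the printed
  accounting conventions of the field.
* Sub-seeds for the read-emission stage derive from the main seed below
  $2^{31}$; a fixed seed reproduces simulated FASTQ byte-for-byte.

## Problem sizes used by the tests

The suite runs the full-design clean recovery once (31 chromosomes,
~3,100 loci, 22 individuals, ~6M read pairs, a few minutes), five noisy
replicates at 6 chromosomes × ~50 loci, and toy-scale property checks
everywhere else; oracle comparisons (exhaustive clustering components,
LOD grids, exhaustive marker orders) are capped at the sizes where the
oracles are exact by construction (≤ 12 uniques, ≤ 8 markers). These
sizes are the package's own trade-off between coverage and turnaround
for a routine test run.

## Known limitations

* Scale-factor estimation presumes the error-peak/trough/main-peak
  histogram shape; libraries without a visible error peak fall back to
  median ratios, and pathological histograms require manual overrides.
* Pattern propagation trusts anchored patterns; at very small progeny
  counts distinct chromosomes can share patterns by chance and the
  conflict logic then refuses to assign rather than guessing.
* The count-based cM convention underestimates distance where double
  crossovers occur between adjacent markers; at ≤ 30 markers per
  chromosome and 20 progeny this bias is far below sampling noise.
* Marker components separated by > 5 recombinants are reported as
  separate linkage groups on the same chromosome rather than joined,
  so total map length is a lower bound at low marker density.
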