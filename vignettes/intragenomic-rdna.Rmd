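---
title: "Quantifying intragenomic rDNA polymorphism: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intragenomic rDNA polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Arbuscular mycorrhizal fungi (Glomeromycota) are unusual among fungi in
carrying only a small number — on the order of 6 to 11 — of *divergent*
copies of the nuclear rDNA operon, spread over several chromosomes, rather
than a large homogenized tandem array. Consequently a single spore yields a
cloud of rDNA sequences: the conserved SSU copies differ by fractions of a
percent, while ITS1/ITS2 copies within one genome can differ by ten percent
or more. Any analysis that treats an rDNA sequence as a proxy for an
organism — OTU clustering at a fixed radius, barcode-based species
assignment, phylogenetics of single copies — inherits this intragenomic
variance as a confounder.

`rdnapoly` packages the computational side of studying this phenomenon:
simulating multi-copy communities and HiFi amplicon sequencing over them,
recovering the individual copies from reads, quantifying per-locus
intragenomic distances, sweeping OTU thresholds, profiling SNP density
along the operon, and evaluating barcode gaps on companion protein-coding
genes. Everything downstream is exercised against the generator's known
truth, which is what the test suite and `scripts/acceptance.R` verify.

## The synthetic community model

`community_spec()` describes a hierarchy root → species → strain → copies:

* A random root operon is drawn with locus lengths SSU 1700, ITS1 250,
  5.8S 160, ITS2 250, LSU 800 bp (3160 bp total) — round figures matching
  the loci of a fungal rDNA repeat unit at the scale targeted by long
  amplicons.
* Species ancestors derive from the root by independent per-site
  substitutions at `species_divergence` (default 0.05), strains from their
  species at `strain_divergence` (default 0.01). These two defaults are
  free choices at realistic scales: congeneric AMF species differ by a few
  percent at conserved loci, conspecific strains by about an order of
  magnitude less. No indels are applied above the copy level so locus
  coordinates remain commensurable across strains.
* Copies are **star-shaped** descendants of their strain ancestor — no
  within-strain tree. This is deliberate: in real genomes the copies do not
  cluster by strain or chromosome, and a star is the simplest process
  producing such unstructured variation. Per-locus substitution rates
  default to SSU 0.001, 5.8S 0.01, LSU 0.02, ITS1 = ITS2 = 0.05, encoding
  the empirical ordering SSU < 5.8S < LSU < ITS. A per-site 1-bp indel
  probability (default 0.002) applies to copies only; an optional
  `long_insert` mode places one 100–300 bp block into a random copy's ITS1
  to emulate the length polymorphism seen in some lineages (off by
  default).
* Chromosome assignment is a label drawn uniformly over 4–6 chromosomes,
  for report parity only; no genomic context is simulated.
* Copy abundance weights are lognormal with `sdlog = 0.5`, normalized to
  mean 1. True abundance skew among copies is not well characterized
  empirically; this choice gives mild, realistic unevenness (roughly
  3-fold between extreme copies) and is exposed in the spec.
* Three companion protein-coding genes (900/1100/1000 bp) mutate without
  indels at intraspecific 0.004 and interspecific 0.04 — a 10-fold
  separation, comfortably above the 3-fold regime where a universal barcode
  gap is expected, and in line with the percent-level conspecific
  thresholds reported for AMF protein-coding markers.

Read simulation (`read_sim_spec()`) emulates HiFi consensus amplicons:
every copy template is flanked by a fixed synthetic 20-mer primer pair,
read counts are Poisson(depth × weight), per-base substitution errors
default to 0.002 and 1-bp indel errors to 0.0005 (high-accuracy consensus
reads), 5% of reads are two-parent PCR chimeras with a uniform breakpoint,
2% are contaminants drawn from a pool of 3 unrelated random templates, and
orientation is randomized. Qualities are a constant Phred 40, which is how
consensus-read FASTQ typically looks after CCS. All stochastic stages
consume explicit seeds; a master seed derives sub-seeds deterministically,
so identical specs reproduce byte-identical FASTQ.

What the generator does **not** model: realistic per-pass PacBio error
profiles, homopolymer-biased indels, chimera breakpoint hot-spots, primer
mismatch biases across taxa, and concerted evolution. Passing tests
therefore demonstrate correctness of the algorithms under a clean,
controlled error model — not field performance on real spore extracts.

## Distances

`eachgap_distance()` implements the each-gap convention: within the
compared span every column with a base mismatch *or* a gap in exactly one
sequence counts as one difference; columns where both sequences are gapped
are skipped. With `count_ends = FALSE` (the default) the span runs from the
later of the two first non-gap columns to the earlier of the two last
non-gap columns, so terminal gaps arising from unequal sequence lengths are
never penalized. Columns containing N in either sequence are excluded from
both numerator and denominator — the conservative treatment of ambiguity,
recorded in the matrix `convention` attribute. A pair with zero comparable
columns gets distance 0 plus a warning flag rather than an error, so
matrix construction never aborts; flagged pairs are listed in the
`zero_overlap` attribute.

Percentages in reports are rounded half-away-from-zero to one decimal
(`percent()`), and raw fractions are always retained alongside; the
rounding convention only affects display.

When no external multiple alignment is available,
`pairwise_distance_matrix()` aligns each pair globally (affine gaps,
deterministic tie-breaking: diagonal before gaps, then gap in the first
sequence) and applies the each-gap distance to the aligned pair. Pairwise
mode and MSA mode agree exactly on indel-free data; with indels they can
differ by the usual aligner ambiguities, which is below the reporting
precision at the divergences involved here.

## Locus windows

Locus boundaries come from annotated references, not from HMM scans: the
generator tracks each copy's boundaries through its indels, and
`project_locus_map()` transfers reference coordinates onto alignment
columns through the reference row's gap structure (monotone by
construction). The Krüger barcode window is the last 280 bp of the SSU
(clipped at the SSU start) through the first 800 bp of the LSU (clipped at
the LSU end); the 280 bp tail is configurable since the fragment is only
nominally "circa 280 bp" of SSU.

## OTU clustering

`cluster_at_threshold()` is a deliberately naive agglomerative
implementation: at each step every inter-cluster linkage (minimum, mean,
or maximum pairwise distance) is recomputed from the original matrix, the
smallest is merged if it does not exceed the threshold, and ties are broken
by the lexicographically smallest pair of cluster ids (a cluster is
identified by its smallest member id). Distance matrices from real
alignments are full of exact ties (equal fractions), and tie order is
where library implementations diverge across platforms, so determinism is
worth the O(n³) cost at the tens-of-copies scale this package targets.
`stats::hclust` is used in the test suite as an independent cross-check on
tie-free random matrices. Which linkage produced published OTU-count
heatmaps is generally unstated, so reports print all three; `average` is
the default.

## Copy recovery

The pipeline order is fixed: primer trim → length/N filter → dereplicate →
chimera removal → swarm → reference filter → abundance gate. Design
choices that deserve justification:

* **Primer trimming** is anchored with substitutions only (≤ 2 per primer
  by default), trying both orientations. Reads whose primer carries an
  indel error are lost (about 2% at the default error rates), which mirrors
  how strict primer trimming behaves in practice. Default insert length
  window 2300–3300 bp with zero N.
* **Chimera detection** re-states reference-free two-parent detection as a
  testable rule: a candidate is aligned to every pair of already-accepted
  amplicons at ≥ 2× its abundance; across all crossover positions the best
  prefix+suffix match profile defines the chimeric model; the candidate is
  chimeric if the model explains it better than the best single parent by
  ≥ 0.02 identity and reaches ≥ 0.99 model identity. Identities are
  expressed per candidate base so single-parent and crossover scores share
  a denominator. On constructed 50/50 chimeras with parents ≥ 5% divergent
  this rule is exact (recall 1.0 in the acceptance battery) and it does
  not flag 1%-divergent clean variants.
* **Swarm clustering** links any unassigned amplicon within edit distance
  `d` of a cluster member, seeding clusters from the highest-abundance
  amplicon — agglomeration without a global radius. `d = 1` (the classic
  default) is appropriate when most reads are error-free. At 30× depth on
  a 3.2 kb amplicon with 0.002 + 0.0005 per-base errors, a read carries ~7
  errors on average and P(error-free read) ≈ e⁻⁷ < 0.1%, so `d = 1` leaves
  almost every read a singleton. For that regime the radius must absorb
  the distance between two reads of the same copy, about twice the
  expected per-read error count (~14), while staying far below the ~90
  edit distance between distinct copies; `d = 16` — the upper bound of the
  supported range — satisfies both with margin, and is what the analysis
  scripts and acceptance battery use. This was fixed from the error model
  above, not fitted to outcomes.
* **Representative sequence**: the cluster seed (modal amplicon) is the
  maximum-likelihood copy sequence when error-free reads dominate, and is
  the default. In the error-dominated regime the seed itself carries ~7
  errors, so `representative = "consensus"` replaces it with the
  abundance-weighted column consensus of the members projected onto the
  seed; junction insertions supported by a majority of members repair seed
  deletion errors. With ≥ 5 members the consensus is almost surely exact.
* **Reference filter**: cluster seeds must reach 0.8 global-alignment
  identity to the best panel sequence. A bounded-edit screen
  (identity ≥ 1 − d/maxlen) decides clear cases cheaply; borderline seeds
  fall back to an exact banded alignment. Genuine copies sit near 0.92
  identity to a strain-ancestor panel, random contaminants near 0.5, so
  the threshold has a wide safety margin.
* **Abundance gate**: 1-D 2-means on log₁₀ cluster abundance, centers
  initialized at the extremes, keeping the higher group — with one guard:
  if the two centers end up closer than one log₁₀ unit (no 10-fold
  abundance gap), the data contain no noise mode and every cluster is
  retained. Without the guard, noise-free runs (e.g. error-free reads)
  would lose their lowest-abundance genuine copy to an arbitrary split.
  A `fixed_min` mode is available as the plain alternative.

Two identical genomic copies collapse into one recovered sequence — they
are indistinguishable by amplicon sequencing, and the recovered copy count
is compared against *distinct* true sequences throughout.

## SNP density

`map_reads()` aligns each read (both orientations) to a single reference
copy with free terminal gaps and a diagonal band (default half-width 100,
far above the indel drift of these data), discards reads under 0.8 core
identity, and accumulates per-position A/C/G/T/deletion counts.
`call_snps()` uses min depth 20, min alternate fraction 0.05, min
alternate count 3 — chosen so that sequencing errors (expected per-site
alternate fraction ≈ 0.002) stay well below the calling floor while a
single divergent copy among eight (alternate fraction ≈ 0.125) is called
reliably; the thresholds are configurable and recorded on the output.
Density uses 100 bp windows at 10 bp steps: sliding-window defaults in
karyotype-scale tools target megabases and are meaningless on a 3 kb
amplicon. Deletions are counted in depth but never called as SNPs.

## Barcode gap

`gap_table()` reports, per species, the maximum conspecific pairwise
distance and the minimum distance from any member to its nearest
non-conspecific sequence; the gap verdict is `min_inter > max_intra`.
Singleton species have no defined `max_intra` (and no verdict) but still
serve as nearest-neighbour targets for other species. The indicative
conspecific threshold is interpreted as an order-statistic quantile: the
smallest distance d such that at least a fraction q (default 0.95) of all
conspecific pairs lie at ≤ d, with no interpolation. A statement like
"95% of conspecific sequences fall within X" is ambiguous between pairs
and sequences; the pairwise reading is implemented because it is the
natural statistic over a distance matrix, and q is exposed so the stricter
per-sequence variant can be computed from `partition_distances()` if
needed.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open; all human-facing tables are
  1-based inclusive (SNP positions) or percentages.
* Alphabet is strict A/C/G/T/N plus the gap; IUPAC ambiguity codes are
  rejected at ingest, because the distance semantics above are undefined
  for partial matches.
* Alignment scores default to match 2, mismatch −3, gap open −5, gap
  extend −2 (a standard amplicon-comparison scheme); a gap of length L
  costs open + L·extend. Traceback ties prefer diagonal, then a gap in the
  first sequence, making alignments platform-deterministic.
* Banded alignment requires the band to exceed the indel drift; bands are
  chosen automatically for pairwise distance work (full matrix below
  1500 bp, 20% of the length plus the length difference above) and exposed
  as parameters everywhere else. A band that cannot reach the end of both
  sequences raises an error rather than returning a truncated alignment.
* Zero-overlap pairs, singleton groups, all-equal abundance gates, empty
  pipeline stages: all return flagged results rather than errors, so batch
  analyses never abort mid-run.

## Problem sizes in the shipped analyses

The numbered scripts and the acceptance battery use a 3-species ×
2-strain community (≈ 50 copies, ≈ 1800 reads) for community-level
analyses, 20 seeded single-strain runs at 30× depth for copy-recovery
performance, 20 trials × 6 parents for chimera detection, and 1000/200/100
randomized cases for the distance/clustering/swarm oracle comparisons.
These sizes give stable rates (binomial standard errors of a few percent
at worst) while keeping a full run in minutes on one core; all of them are
parameters, not limits.

## Known limitations

* The chimera rule tests candidates only against accepted amplicons at
  ≥ 2× abundance; chimeras of equal-abundance parents (rare in
  dereplicated amplicon data, where true copies dominate) pass through and
  must be caught later by the abundance gate.
* The swarm radius is a single global `d`; the fastidious grafting phase
  of the original algorithm is not implemented, as desk-scale datasets do
  not need it.
* Pairwise-mode distances depend mildly on aligner parameters where indels
  are involved; external MSAs can be supplied via `aligned_set()` +
  `distance_matrix()` when column-exact reproducibility against other
  tools matters.
* The read simulator's uniform error model understates structured HiFi
  artifacts; recovery rates on real data will be somewhat lower than the
  simulated ones, particularly for copies at low amplification efficiency.
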