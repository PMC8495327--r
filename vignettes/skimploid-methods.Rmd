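---
title: "Methods and design of skimploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of skimploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures, the parameters that matter (with defaults and why), what the
synthetic data generator does and does not emulate, the numerical choices,
and the known limitations.

## The problem

An allopolyploid carries two complete nuclear subgenomes from two diploid
progenitor species; its organelles (plastome, mitogenome) descend from the
maternal parent only. Genome skimming — shotgun sequencing at a small
fraction of nuclear coverage — oversamples everything high-copy: organelle
genomes (often 20–100× the nuclear depth), ribosomal DNA arrays, tandem
satellite DNA and dispersed repeats. `skimploid` exploits this: different
genomic compartments carry different genealogical signals, and comparing
per-compartment phylogenies of an allopolyploid against candidate diploid
clades separates the maternal lineage (organelle signal) from the full set
of genome donors (nuclear repeat signal).

## The alignment-free distance

All read-level phylogenetics uses canonical k-mers: a window of length *k*
(odd, so a k-mer never equals its own reverse complement) is identified
with the lexicographic minimum of itself and its reverse complement;
windows containing non-ACGT symbols are skipped. A **profile** is the set
of distinct canonical k-mers seen at least `min_count` times; for read data
`min_count = 2` prunes most singleton sequencing-error k-mers, for
assembled sequences `min_count = 1` is exact.

The pairwise distance between profiles A and B is

d = −(1/k) · ln( n_s / min(n_A, n_B) ),

with n_s the number of shared distinct k-mers. Under Jukes–Cantor
divergence the probability that a k-window is substitution-free is
(1 − p)^k with p = (3/4)(1 − e^(−4d/3)), so −(1/k)·ln of the shared
fraction recovers −ln(1 − p) ≈ d for small d; at d = 0.05 the estimator is
within 1 % of truth on 50 kb sequences. The `min` denominator makes the
estimate robust to unequal genome size and coverage (the smaller profile
bounds what can possibly be shared). Disjoint profiles get a configurable
cap `d_cap = 1.0`. The original published AAF tool additionally applies
coverage- and error-dependent tip corrections; these are described only
qualitatively in the literature and are deliberately not reproduced — our
estimator is declared, not claimed identical.

Numeric k-mer codes are exact for k ≤ 26 (2k bits must fit a double's
52-bit mantissa); `canonical_kmers()` accepts k up to 31 via a string
fallback. Defaults: k = 21 for profiles and mapping, k = 17 for read
clustering (more sensitive), k = 15 for pipeline compartment
classification (see below).

Trees come from classical neighbor joining (Q criterion, negative branch
estimates clamped to zero, ties broken by input order — verified against an
independent implementation and exact on additive matrices). Bootstrap
support resamples each profile's distinct k-mers with replacement to the
original count; the resampling unit is the k-mer, a deterministic contract
independent of read length (this differs from the AAF tool's internal
scheme and is documented as such). Robinson–Foulds distances count
non-trivial bipartitions present in exactly one tree and are tested against
exhaustive enumeration for all trees on ≤ 6 taxa.

## The synthetic world

The generator is first-class, tested code, and its defaults are the
package's stated world:

* **Species tree** — user Newick with branch lengths in substitutions/site;
  the default pipeline world has six diploids in two clades (branch lengths
  0.008–0.025) and two allotetraploids whose maternal parents sit in clade
  I. Root age defaults to 12.4 Mya (a secondary-calibration age typical of
  the legume systems this emulates), used only by `scale_tree_ages()`.
* **Genomes** — desk-scale blueprint: 200 kb nuclear (monoploid), 20 kb
  circular plastome, 35 kb circular mitogenome, organelle copy boost 50
  (organelle read depth = 50× nuclear coverage, the regime that makes
  seed-free organelle assembly work), rDNA unit 1 kb × 6 tandem copies,
  satellite families of 110–180 bp monomers at 1.5–2.5 % genomic
  abundance with clade-specific gain edges and lognormal abundance drift
  (σ = 0.1/branch), plus dispersed TE families. Real plastome sizes
  (~156 kb) are configurable but unnecessary for the properties tested.
* **Substitution model** — Jukes–Cantor throughout, by design: it gives
  closed-form recoverable distances for testing (the real study's Bayesian
  GTR machinery is out of scope). A site on a branch of length d
  substitutes with probability (3/4)(1 − e^(−4d/3)).
* **Satellite arrays** — contiguous head-to-tail tandems at fixed loci,
  rebuilt at each leaf from the leaf's evolved monomer at the leaf's
  realized abundance; each copy receives i.i.d. substitutions at
  `intra_array_div = 0.02` to model copy heterogeneity. Concerted-evolution
  homogenization is *not* modelled; inter-species monomer variants arise
  from branch substitutions only. A consequence worth knowing: most
  *distinct* k-mers of an array are private per-copy variants, so satellite
  profiles are dominated by within-species variant k-mers — exactly what
  makes the paternal-array truncation visible to the set-based distance.
* **Allopolyploids** — nuclear union of the two parents (two annotated
  subgenomes), organelles byte-identical to the maternal parent at
  formation (no post-formation evolution is modelled), satellite family set
  the strict union. Reflecting the commonly reported attrition of
  paternal-subgenome repeats in allopolyploids, each paternal satellite
  array is truncated to `paternal_sat_retention = 0.5` of its length —
  family presence is preserved, abundance is halved. Empirically the
  pipeline's compartment-congruence behavior is insensitive to this value
  over 0.1–1.0; it is kept as a documented biological feature, not a
  tuning knob.
* **Reads** — 2×150 bp pairs, insert ~ Normal(350, 30) truncated below at
  the read length, fragment starts uniform (circular templates wrap),
  strand random, i.i.d. substitution errors (default 1 %), constant
  quality 'I'. Pair counts are deterministic:
  round(coverage × multiplier × L / (2·150)). Both mates carry the
  compartment/family of the fragment midpoint as truth (so a read spanning
  an array boundary is labelled by its fragment's midpoint — a ≤ 75 bp
  blur, irrelevant at the ≥ 90 % thresholds tested). Default desk coverage
  is 5–10×; the real study's per-sample yield (~3 Gb) is intentionally not
  matched.

What a green test does **not** establish: behavior under indels and
structural variation, GC/coverage bias, PCR duplicates, quality-dependent
errors, heterozygosity, concerted evolution, or real-scale genome
complexity. None of these are simulated.

## Organelle assembly

Reads are decomposed into k-mers (k = 25) on both strands; k-mers with
count below a depth threshold are discarded and the rest form de Bruijn
graph edges over (k−1)-mer nodes. `"auto"` thresholding locates the
dominant coverage mode as the *mass-weighted 75th percentile* of the k-mer
count histogram — robust whenever the boosted compartment holds ≥ 25 % of
k-mer mass — and takes the middle of the argmin plateau of the histogram
below that mode (the valley between nuclear and organelle depth).
Contigs are walked along unique successors from the deepest unused edge; a
walk that returns to its start edge is circular. Circular contigs are
reported as the lexicographically minimal rotation of min(seq, revcomp),
making assembly rotation-invariant and string-comparable to references.

Branching above threshold (an internal repeat ≥ k) stops the walk and
yields partial contigs plus a diagnostic. Paired-insert repeat resolution
is not implemented: with 350 bp inserts, repeats long enough to survive the
depth threshold (> 500 bp in the mitogenome-repeat regime this emulates)
cannot be spanned by pairs anyway — mirroring why some real mitogenomes
assemble as linear contigs. Long-repeat detection (`find_long_repeats`)
seeds exact 21-mer anchors, chains them per diagonal (gap ≤ 100 bp),
extends gaplessly with an X-drop of 15 (match +1, mismatch −3) requiring a
run of ≥ 4 matches before the end advances (so isolated chance matches do
not inflate a repeat across its true edge), and reports pairs strictly
longer than 500 bp and strictly above 95 % identity, direct and inverted.
Synteny blocks chain unique shared 21-mers into collinear same-orientation
runs with gaps ≤ 1 kb; coordinates are 0-based half-open.

## Repeat discovery and the satellitome

Repeat discovery mimics graph-based clustering pipelines: reads are sampled
per species proportional to monoploid genome size × ploidy/2 relative to
the first-listed diploid, then clustered by connected components of the
"≥ 5 shared canonical 17-mers" graph (components, not community detection:
deterministic and testable). **Sampling must stay well below 1× nuclear
coverage** — at higher coverage overlapping single-copy reads chain into
one giant component and the method degenerates; the pipeline default of
600 reads/species is ~0.45× of the default 200 kb genome and the stage
caps the request automatically. This is why the desk default is far below
the "million reads" scale of real runs: the *ratio* logic is identical, the
absolute number follows the coverage constraint.

Organelle-matching reads are removed before sampling (at a permissive
threshold, 0.2), since organelles dominate raw skim read pools and repeat
discovery concerns the nuclear fraction.

Cluster consensus building anchors member reads to a growing consensus by
exact shared k-mers on both strands (offset = anchor-vote mode) and takes
per-column majorities (ties lexicographic), iterating while the consensus
grows. For a tandem array the consensus converges to roughly one monomer
plus a read-length of wrap, so `detect_tandem()` searches shifts up to
(length − 30) for the smallest period with ≤ 20 % mismatch over the
overlap; when no internal shift fits but member reads anchor across the
end–start junction of the doubled consensus, the cluster is tandem with the
consensus length as its period (the typical outcome for units near or
above the consensus length, e.g. rDNA). Alternating diverged monomer
variants yield the smallest acceptable period with the better-fitting
higher-order period recorded as `secondary_period`.

Satellite abundance across samples uses a strict unique-mapping rule:
each read goes to the single consensus with the greatest shared
k-mer fraction ≥ `min_frac`, equal-best ties are discarded, and
A[s, f] = 100 × assigned/total reads of the sample (the denominator is all
reads, organelles included, so the organelle boost deflates nuclear
percentages consistently — read counts, not base counts, by documented
choice). `min_frac = 0.35` tolerates the ~3 % combined divergence (copy
heterogeneity + sequencing error) between a read and its own consensus at
k = 21. The presence rule retains a consensus iff any sample reaches
τ = 0.01 %; retained rows keep sub-threshold cells. Families group by
single-linkage at 60 % rotation/strand-aware identity (one monomer is
doubled and the other aligned globally-in-pattern/locally-in-subject, so
any rotation can match; identity = matches/alignment length, indels count
against); variants split at 95 %. The 60 % family cutoff is a declared
default: monomer pairs at ~70 % identity — the classic variant-I/variant-II
situation — must fall inside one family, and do.

Parental signatures: a satellite is clade-diagnostic if present in ≥ 1
clade member and absent in every other diploid; a clade is a contributor
iff ≥ 1 of its diagnostics is present in the polyploid; no diagnostics at
all → "inconclusive", not an error.

## Pipeline design notes

* **Stage order** is simulate → assemble → repeats → classify →
  satellitome → phylo → report: classification needs references that only
  assembly and repeat discovery can derive from the data (user-supplied
  references short-circuit this). Each stage writes its outputs (text
  artifacts plus a checkpoint) before the next begins; one master seed
  fans out to per-stage seeds by fixed offsets, and an identical
  config + seed reproduces the report byte-for-byte.
* **Second-pass comparative annotation.** A cluster that fails tandem
  detection in its own sample (too few sampled reads) but matches another
  sample's satellite consensus (score ≥ 0.25 at k = 13) is reclassified as
  satellite before references are built. Without this, such a cluster's
  consensus captures its sample's satellite reads into the dispersed-repeat
  bin at shared-fraction 1.0, the sample's satellite k-mer profile shares
  nothing with any other sample (capped distance rows), and NJ placement of
  hybrids destabilizes. This mirrors the custom-library re-annotation pass
  of real comparative repeat workflows and was the decisive robustness fix
  for per-compartment congruence.
* **Classification k = 15 in the pipeline** (the exported `classify_reads`
  keeps k = 21, threshold 0.5, ties → unassigned): cross-species reads of a
  shared satellite family at ~7–10 % total divergence retain about a third
  of their 15-mers against another species' consensus but almost none of
  their 21-mers. Compartment purity still dominates recall — ties go to
  `unassigned`, mates are classified independently and disagreements are
  recorded, not reconciled.
* **Total-read profiles use a coverage-scaled count filter**
  (`min_count_total = "auto"` = 3 × coverage). In real skimming data the
  total-read AAF signal is carried by the high-copy fraction because
  single-copy k-mers fall below the count filter; at desk-scale coverage a
  fixed `min_count = 2` would let single-copy k-mers swamp that signal and
  the characteristic "total reads follow the maternal/organelle topology"
  phenomenon would vanish. Compartment profiles keep `min_count = 2`.
* **Maternal calls** take the organelle-compartment distance argmin over
  diploids, reporting all diploids within 10 % of the minimum as a tie set
  (two very close candidate parents are reported as such rather than
  resolved arbitrarily).
* **Polyploid placement labels** come from bipartitions: the smallest
  split side containing the polyploid and ≥ 1 clade member; exactly one
  clade represented → that clade's label, ties or mixtures → "unresolved"
  (so a polyploid attached between both clades, or two sister polyploids
  without nearby diploids, resolve sensibly).
* **Dating** midpoint-roots the tree, averages node-to-leaf path lengths
  into UPGMA-style heights (parents clamped to be at least their
  children's), and scales so the root sits exactly at the calibration age;
  leaves are age 0.

## Numerical and degenerate-input choices

Ties in classification and unique mapping are discarded rather than broken
arbitrarily; NJ ties break on input order; majority-vote ties break
lexicographically (A < C < G < T); negative branch estimates clamp to 0;
empty profiles are errors for distances but empty read sets give empty
profiles; `k > nchar(seq)` yields an empty k-mer set, not an error; a
pipeline config with no satellite families completes with an empty
satellitome section.

## Known limitations

No indels or rearrangements anywhere (alignment identity tests use them
only as inputs); no 5S-specific rDNA handling; no BAM/SAM emission; the
assembler resolves no repeats; bootstrap is k-mer-level only; NJ placement
of hybrids is intrinsically fragile when distance matrices are strongly
non-additive — the pipeline mitigates the degenerate-row causes (see
above) but a hybrid exactly equidistant from two well-sampled clades is
reported as whatever NJ yields, with "unresolved" available from the
labelling rule. Desk-scale acceptance checks scale every simulation down
(genome sizes, coverage, sample counts are stated in the tests) and say so.
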