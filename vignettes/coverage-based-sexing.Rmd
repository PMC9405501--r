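---
title: "Coverage-based molecular sexing: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based molecular sexing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexratio)
```

## The problem and the model

In species with chromosomal sex determination, the two sexes differ in sex
chromosome dosage: XX females carry two copies of the X, XY males one. Shotgun
sequencing reads sample the genome roughly in proportion to copy number, so
the ratio of mean read depth over X-linked sequence to mean depth over
autosomal sequence (the X:A ratio) has expectation ~1 in females and ~0.5 in
males. This signal survives at extremely low sequencing effort — down to a
few thousand mapped reads — which makes it usable for degraded museum,
subfossil, environmental and low-yield screening samples where PCR-based
sexing fails and only a single individual is available.

`sexratio` implements this estimator for the common hard case: the species of
interest has a reference assembly (possibly from a relative) with *unknown*
sex-linked scaffolds. The pipeline is:

1. **Partition** the reference assembly (`partition_assembly()`): find
   scaffold regions syntenic to donor X and Y chromosome assemblies from any
   sufficiently close species, mask coordinates claimed by both X and Y
   (pseudoautosomal homology), and call everything with no sex-linked hit
   autosomal.
2. **Filter** the individual's mapped reads (`filter_alignments()`,
   `mark_duplicates()`): mapping quality at least 30, duplicates removed, and
   optionally downsample to an exact mapped-read count
   (`downsample_alignments()`).
3. **Estimate** the X:A ratio (`identify_sex()`): per-base depth with base
   and mapping quality thresholds of 25, then 10 replicates each drawing 10
   million random sites from the X-linked and autosomal compartments
   independently; the call is made from the mean of the replicate ratios.
   A mean ratio at or above 0.8 is called female, at or below 0.7 male, and
   the band in between undetermined — undetermined is reported rather than
   guessed because a wrong sex is more damaging to downstream inference than
   a missing one.

## The synteny mapper

Published pipelines of this kind delegate the synteny step to a whole-genome
aligner. Here that step is a self-contained canonical k-mer anchor mapper
with collinear chaining, which is all the downstream logic needs: *which
coordinates of which scaffolds look like the donor X (or Y)*.

* k-mers of size `k = 21` are strand-canonicalized (a k-mer and its reverse
  complement share a key) and indexed over the concatenated donor X and Y;
  k-mers occurring more than `max_occ = 4` times are dropped as repeats.
* Scaffold k-mers are looked up and hits grouped by donor sequence, label and
  strand; within a group, anchors sorted by scaffold offset are greedily
  chained while consecutive anchors are within `chain_gap = 5000` bp on both
  sequences and reference offsets stay monotone (increasing on the forward
  strand, decreasing on the reverse).
* Chains with at least `min_chain_anchors = 5` anchors become labeled
  scaffold intervals.

With 21-mers, the probability that a random anchor chain of five collinear
anchors arises by chance is negligible (the keyspace is $4^{21} \approx 4
\times 10^{12}$), so autosomal scaffolds essentially never acquire spurious
sex-linked intervals; conversely, at divergence $d$ the anchor density is
$(1-d)^{21}$ per position — about 22% at $d = 0.07$ and 2% at $d = 0.17$ —
still far denser than one anchor per `chain_gap`, so true synteny chains
survive well past the divergences at which such donors are used in practice.
The mapper does not attempt whole-genome-alignment fidelity (inversions
within a chain gap, duplications, translocation phasing); it only has to
recover compartment membership.

**Pseudoautosomal masking.** The X and Y share homologous pseudoautosomal
regions; reads from them map at double (male) dosage relative to truly
X-specific sequence. Coordinates claimed by both labels are therefore
removed from both interval sets (BED-style subtraction). Two granularities
are deliberately mixed, matching standard practice: X depth is computed over
the syntenic *intervals*, while the autosomal complement is defined at whole
*scaffold* level (any scaffold owning a pre-mask sex-linked interval is
excluded from the autosomes). A scaffold whose every sex-linked interval is
masked away — one lying wholly inside the pseudoautosomal region — is
conservatively excluded from both compartments.

## The estimator

Depth is computed per base with `samtools depth` semantics: a read
contributes to a site only if its mapping quality is ≥ 25 and its base
quality at that site is ≥ 25. **Zero-coverage sites count.** At 1,000 mapped
reads on a megabase-scale genome almost every position has depth 0; the X:A
ratio is a ratio of mean coverage over *all sampled positions*, not over
covered positions (which would collapse both means toward 1 and destroy the
signal). This is exposed but not recommended to change
(`include-zero-sites` behaviour is the default and the tested path).

Replicates draw sites uniformly *without replacement* (10 million distinct
positions is the natural reading of sampling "sites"), with per-replicate
seeds `seed + i` so runs are reproducible yet replicates independent. The
mean of the 10 replicate ratios — mean-of-ratios, not a pooled ratio — is
classified. On compartments smaller than `n_sites` (every desk-scale
simulation, where compartments are under a few megabases) the draw is
exhaustive, a warning is recorded, and all replicates coincide; the
replicate machinery is then exercised but adds no variance, which is the
correct degenerate behaviour of the estimator, and the mean is the
exhaustive compartment ratio.

## The simulator and what it does (not) emulate

`build_truth_genome()` / `derive_reference()` / `simulate_mapped_reads()`
exist so every stage above is testable with no external data, with truth
known by construction:

* A diploid genome of uniform-random sequence: by default 3 autosomes of
  1 Mb, a 0.5 Mb X and a 0.1 Mb Y whose first 2% of the X's length is a
  shared pseudoautosomal prefix. These sizes keep compartments large enough
  for stable depth means at 1,000–100,000 reads while a full factorial
  experiment runs in minutes on one CPU.
* Reference assemblies derived by i.i.d. substitutions (no indels, keeping
  truth coordinates exact) at divergences spanning 0–0.17, mirroring
  conspecific to family-level donors, and fragmentation to a target N50 with
  lognormal piece lengths (accepted when the realized N50 is within 25%).
  Contiguity regimes of interest: a contiguous reference (N50 = chromosome
  scale) versus a fragmented one (N50 tens of kb).
* Reads are placed uniformly with chromosome dosage weights (XX: autosomes
  2, X 2, Y 0; XY: autosomes 2, X 1, Y 1) and emitted directly as alignments
  on the reference scaffolds via the truth coordinate map — "perfect
  mapping". This isolates the partition and ratio logic from mapper
  behaviour; a `mismap_frac` knob relocates reads uniformly to stress-test
  robustness, and `low_mapq_frac` plants low-MAPQ reads to exercise filters.
  Base-call errors are applied at `base_error_rate` to read bases (which
  depth never inspects); base qualities are a constant Phred 37 by default,
  so quality filters are exercised by explicitly constructed fixtures rather
  than by a quality-profile model.

Not emulated, by design: indels and structural variation, ancient-DNA damage
patterns, realistic quality profiles, paired-end reads, and real mapper
behaviour (multi-mapping, soft clipping, reference bias). Passing tests
therefore demonstrate the *estimator's* correctness under its dosage model
and the partitioner's recovery under substitution-style divergence — not
robustness to mapping artefacts of real degraded libraries, which the MAPQ
and duplicate filters only approximate.

## Numerical and procedural choices

* **Coordinates** are 0-based half-open (BED) everywhere; interval
  arithmetic is delegated to `GenomicRanges` behind tibble surfaces.
* **Duplicates** use a single-end 5′-position + length key; the survivor is
  the highest summed base quality, ties broken by smallest read id —
  deterministic without optical-duplicate logic.
* **Downsampling** is uniform without replacement to an *exact* count, with
  an explicit "insufficient reads" error carrying the deficit, since
  low-yield samples routinely cannot reach a requested read count.
* **Determinism**: every stochastic operation takes a seed and restores the
  RNG state (`withr::with_seed`); derived seeds are simple offsets.
  Partitioning is fully deterministic.
* **Accounting**: cohort accuracy is reported both strictly (undetermined
  counts as wrong) and leniently (undetermined excluded), printed as
  integer percentages in `"strict/lenient"` cells when the two differ —
  e.g. 8 correct / 1 undetermined / 1 wrong in 10 is `80/89`.
* **Degenerate inputs**: empty compartments, all-zero autosomal depth,
  unsorted duplicate-marking input, malformed BED rows and donor assemblies
  sharing no anchors each fail with a classed, stage-named error rather
  than propagating NaNs.

## Problem sizes used in the test suite

The packaged tests run two scales, chosen so the whole suite and the
reproduction script complete comfortably on a single CPU: unit fixtures use
a ~0.53 Mb genome, and the end-to-end study conditions use the ~3.6 Mb
genome above with cohorts of 5–20 individuals per sex at 1,000–50,000
mapped reads. At these scales the binomial sampling noise of read placement
dominates the estimator's spread: per-individual mean X:A ratios have a
standard deviation of roughly 0.03 at 10,000 reads and 0.09 at 1,000 reads,
so female/male cohorts separate cleanly at the 0.7/0.8 thresholds with
ample margin at 10,000+ reads, while at 1,000 reads occasional undetermined
calls are expected behaviour, not failures of the method.

## Known limitations

* Neo-sex chromosomes or donor/target rearrangements of sex-linked material
  are invisible to a synteny partition against a single donor pair.
* A ZW system is handled only by relabeling (the estimator is symmetric in
  homogametic/heterogametic); no lineage-specific logic is included.
* The depth model treats `aligned_length` as the reference span (no CIGAR
  indel awareness); real BAMs with heavy indel alignments will be
  approximated.
* Interval-level X depth versus whole-scaffold X depth is a genuine open
  choice; interval-level is implemented as primary because it is the least
  contaminated by non-syntenic sequence on X-bearing scaffolds.
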