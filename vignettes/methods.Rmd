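---
title: "Detecting mutagen-induced mutational signatures in subclones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutagen-induced mutational signatures in subclones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscreen)
```

## The experimental design this package models

In a controlled mutagenesis screen, cultures of a stable diploid cell line
are exposed to candidate mutagens (or solvent-only controls), single cells
are expanded into daughter subclones, and each subclone is whole-genome
sequenced. Mutations private to a subclone arose after the single-cell
bottleneck, so each subclone catalog is a direct readout of the mutational
processes active during the experiment: a ubiquitous *background* process
from cell culture plus, in treated arms, any *mutagen-associated* process.

`sigscreen` implements the downstream statistics of such a screen. It does
not call variants; it consumes per-subclone somatic mutation catalogs (TSV
or VCF), a reference genome (FASTA or in-memory), and annotation tracks
(gene footprints with strand, replication-timing deciles, CpG intervals).
Two post-calling filters are applied first: a variant-allele-fraction
filter (VAF >= 0.2, keeping clonal mutations that were present in the
founding cell) and removal of mutations shared between subclones of one
parental culture (pre-existing, not de novo).

## Mutation classification

Three channel schemes are implemented, each with an exhaustively tested
enumeration:

* **SBS96** — single-base substitutions, pyrimidine-collapsed (6 classes)
  crossed with the 5' and 3' flanking base (96 channels). A mutation whose
  reference base is a purine is represented by the reverse complement of its
  reference triplet.
* **DBS78** — tandem double substitutions (both bases of a dinucleotide
  changed). The 16 x 9 = 144 raw types collapse under reverse complement to
  78 classes; 12 types are their own reverse complement. Canonical
  representatives follow the COSMIC convention (reference dinucleotide in
  {AC, AT, CC, CG, CT, GC, TA, TC, TG, TT}; palindromic references take the
  lexicographically smaller alt).
* **ID29** — indels, classified by class (deletion/insertion), motif
  (1-bp C or T after pyrimidine collapse; multi-bp by motif length 2, 3,
  >= 4), the repeat tract at the site, and one microhomology-mediated
  deletion category (deletions only). 16 + 12 + 1 = 29 channels.

Two ID29 conventions deserve note, since published figure panels leave the
grid underdetermined and we had to fix one:

* *Tract length* counts the total copies of the motif in the reference
  tract — for a deletion the deleted copy is included (deleting one C of
  `CCCCC` is a deletion at a tract of 5), for an insertion only existing
  copies count. This is the convention standard in indel signature
  classification; a consequence is that the deletion tract-0 channels are
  structurally empty (a deleted base always sits in a tract of >= 1). Bins
  are 0, 1–2, 3–4, >= 5. The schema is a data table
  (`id29_channels()`), so an alternative grid can be swapped in without
  code changes.
* *Microhomology* is scored only for multi-bp deletions with no flanking
  full copy of the motif (tract of exactly 1): the length of the longest
  flanking prefix/suffix match is computed and any match >= 1 routes the
  deletion to the MH channel.

Indels are left-aligned against the reference before classification, so the
channel is invariant to the calling dialect. Runs of three or more adjacent
substitutions are excluded from both the SBS and DBS catalogs and counted
separately — only pairs are defined as double substitutions.

## The burden test

Each treatment has 2–4 subclones; 35 control subclones define the
background. For a treatment with $g$ subclones, the null distribution of
its mean burden is the bootstrap distribution of means of $g$ control
burdens resampled with replacement ($10^4$ resamples by default). The
p-value is one-sided with an add-one correction,

$$p = \frac{1 + \#\{\bar N^{*} \ge \bar N_{\mathrm{treat}}\}}{1 + B},$$

because only an *increase* over background is of interest and the
resolution floor $1/(B+1)$ avoids zero p-values. Benjamini–Hochberg
correction is applied across treatments separately within each mutation
class (substitutions, doublets, indels), mirroring the per-class reporting
of such screens. Neither the resample count, the estimator, the sidedness
nor the correction family is prescribed by the source methodology, so all
four are explicit, configurable decisions here. Effect size is the
mutagenicity index $(\bar N_{\mathrm{treat}} - \bar N_{\mathrm{ctrl}}) /
\bar N_{\mathrm{ctrl}}$.

## Background model and signature extraction

Control subclone substitution profiles are highly mutually similar (~2.6
mutations per channel), so the background substitution signature is the
*mean* control profile. Indels are ~10 per subclone over 29 channels, far
too sparse for per-subclone profiles to be stable, so the background indel
profile is the *aggregate* over controls, while subtraction still uses the
mean. Background doublets (~1 per subclone) are negligible and no doublet
background is subtracted.

The treatment profile is modelled as a two-component mixture,
$M_{\mathrm{subclone}} = N_{\mathrm{bg}} P_{\mathrm{bg}} +
N_{\mathrm{mut}} P_{\mathrm{mut}}$, and since controls carry only the
background process,

$$P_{\mathrm{mut}} =
\frac{\bar M_{\mathrm{subclone}} - \bar M_{\mathrm{control}}}
     {\bar N_{\mathrm{subclone}} - \bar N_{\mathrm{control}}}.$$

The numerator sums to the denominator, so the result sums to one by
construction; sampling noise can push individual channels negative, and the
model itself says nothing about how to handle that. We clip negative
channels to zero, renormalize, and *report the clipped mass* on the
signature object so the decision is auditable — in calibration runs the
clipped mass shrinks toward zero as the excess burden grows, and a large
clipped mass is itself a symptom that there is no real signal to extract.

Three gates decide whether an extracted signature is reported:

1. **Burden**: BH-adjusted bootstrap p < 0.01.
2. **Signal-to-noise**: $\mathrm{SNR} = \lVert \bar M_{\mathrm{treat}} -
   \bar M_{\mathrm{ctrl}} \rVert_2 / (\sigma_{\mathrm{treat}} +
   \sigma_{\mathrm{ctrl}}) \ge 2$, computed on raw count profiles. The
   group dispersion $\sigma$ is reduced to a scalar as the root mean square
   Euclidean distance of member profiles from their centroid; the
   alternative reduction (norm of the per-channel SD vector) is available
   via `snr(..., sigma = "per_channel")`. Raw counts are used because the
   quantities entering the ratio are count profiles, not normalized
   signatures.
3. **Stability**: the maximum pairwise cosine similarity between the
   signatures extracted from individual subclones (each against the shared
   background mean burden) — >= 0.8 for substitutions, >= 0.7 for indels,
   i.e. the signature must be consistent in at least two subclones. Indel
   calls additionally require a mean of >= 20 indels per subclone, and
   doublet signatures require > 20 doublets in total (and are aggregated
   without subtraction).

With a single informative subclone, stability is undefined (NA) and the
gate fails — by design, one subclone cannot corroborate itself.

## The doublet chance model

Double substitutions occur more often than two independent hits would
predict. To quantify "would predict", the package computes the probability
that $n$ substitutions drawn from a sample's signature land with no two
adjacent, by sequential placement: the $i$-th mutation of trinucleotide
class $t$ succeeds with probability $A_t / N_t$, where $A_t$ is the
expected number of class-$t$ positions not yet excluded and each placed
mutation removes its own position plus, in expectation over the genome's
neighbour composition, its two neighbours (a precomputed 32 x 32 removal
matrix). Mutations are apportioned to classes by largest remainder and
processed in decreasing class-probability order; the product of the
$P_i$ is $P(\text{no doublet})$.

This expected-case bookkeeping is *exact for pairs* (the first availability
update is an exact expectation) and an approximation beyond, because it
ignores the covariance between overlapping exclusion zones. Two oracles
bound the error: exhaustive enumeration over all placements (exact, tiny
genomes only: `enum_doublet_prob()`) and a Monte-Carlo placement oracle
(`mc_doublet_oracle()`). On a 1 kb genome the sequential estimate agrees
with the Monte-Carlo oracle within 3 standard errors at $10^5$ replicates
for $n \in \{2, 10, 50\}$; on sub-12-bp contigs it is exact at $n = 2$ and
within a few percent at $n \in \{3, 4\}$. One boundary case worth stating:
on a 5-bp homopolymer (three eligible positions in a row), two mutations
escape adjacency with probability exactly 1/3 — the middle placement forces
adjacency, the outer pair does not — and both the sequential method and the
enumeration return 1/3.

Observed doublet counts are compared with the null through a Poisson
approximation, $\lambda = -\log P(\text{no doublet})$, with an upper-tail
p-value for the observed count.

## Topography analyses

* **Transcriptional strand asymmetry**: within unambiguous gene footprints,
  the pyrimidine of each mutated pair lies on the coding (non-transcribed)
  or template (transcribed) strand. Per substitution class, a Pearson
  chi-square goodness-of-fit tests the split against 50:50, BH-corrected
  across the six classes; classes with fewer than 5 genic mutations are
  skipped and flagged. The 50:50 null conditions on genic, unambiguous
  sites; whether a composition-adjusted expectation should be preferred is
  left as a configuration question, and gene footprints are whole
  transcript intervals (intron/exon not distinguished).
* **Replication timing**: observed mutation counts per RTD decile are
  compared with the distribution expected from the signature and the
  genome's per-decile trinucleotide availability, obtained by simulating
  catalogs of equal size; a Monte-Carlo chi-square flags distributions that
  deviate from the expectation.
* **CpG enrichment**: a Fisher exact test on mutated vs eligible-unmutated
  G:C sites inside vs outside the CpG track.
* **Asymmetry by timing**: per-decile transcribed fractions with an
  early-minus-late gradient summary.

## The synthetic-data generator

Every statistical claim above is exercised on synthetic experiments with
known truth. The generator emulates the screen's design: 35 control
subclones carrying a background process of ~245 substitutions, ~10 indels
and ~1 doublet per subclone, and treatment groups of 2–4 subclones carrying
background plus a configurable treatment signature and excess burden per
mutation class. Specific choices:

* **Between-subclone dispersion** of burdens is Poisson. The source design
  does not state a dispersion; Poisson is the minimal assumption and is
  documented as such — real subclones may be overdispersed, which would
  make the burden test anti-conservative relative to this null.
* **Background substitution signature**: flattish with C>A enrichment at
  NpCpA/NpCpT, mimicking the culture-associated oxidative background;
  configurable.
* **VAF model**: Beta(20, 20) around 0.5 for clonal mutations, plus a
  configurable contamination fraction of sub-0.2-VAF records to exercise
  the VAF filter.
* **Doublets are placed jointly** at an eligible dinucleotide site and
  emitted as two adjacent records — not as two independent substitutions —
  since the doublet analysis exists precisely because joint events exceed
  chance adjacency.
* **Indel placement is repeat-tract aware**: 1-bp events are placed in (or
  next to) homopolymer runs matching the target tract bin; multi-bp,
  repeat and microhomology events are generated by targeted proposals
  verified through the classifier, so every emitted indel re-classifies to
  its intended channel by construction.
* **Topography injection**: substitution placement can be biased by a
  transcriptional strand factor and a replication-timing gradient;
  replicative strand asymmetry is intentionally absent from the nulls.
* **Shared parental mutations** (default 25 per culture) are injected into
  every subclone of a group to exercise shared-mutation removal.

What the generator does *not* emulate: sequencing error and read-level
artifacts, copy-number or rearrangement events, selection during culture,
mutation-rate heterogeneity beyond the injected gradients, and real human
genome composition (toy genomes are i.i.d. base sequences at a chosen GC
fraction). Passing tests therefore demonstrate the statistics are
implemented correctly and calibrated under the stated model, not that the
thresholds are optimal for any particular real dataset.

## Problem sizes, determinism and numerical choices

Calibration studies in the test-suite and acceptance script use a 150 kb
toy genome for per-treatment statistics (channel availability, not genome
size, drives these quantities) and a 1 Mb genome with 35 controls plus 10
treatments of 3 subclones for the end-to-end determinism check; these sizes
were chosen so that the full validation battery completes in minutes on a
single CPU while leaving every per-subclone burden at the study's scale.
Bootstrap resamples default to $10^4$; replication-timing expectations use
100 simulated catalogs. All randomness flows from explicit seeds —
experiment generation from `sim_config(seed = )`, analysis stages from
stage-scoped seeds derived from `mutagen_screen(seed = )` so that adding a
stage never perturbs an earlier stage's stream — and identical inputs with
identical seeds produce byte-identical outputs.

Degenerate inputs are handled explicitly rather than silently: zero
dispersion with equal centroids gives SNR 0, zero dispersion with different
centroids gives a flagged infinite SNR; extraction with no excess burden is
an error; a signature channel with positive probability but no matching
genomic site is an error naming the channel; mutations whose context
contains N (or indels spanning a contig edge) are excluded and counted.

## Known limitations

* The expected-case doublet bookkeeping understates adjacency covariance
  for $n \ge 3$ on very small genomes; at genomic scales the error is well
  inside Monte-Carlo noise (see above), and the enumeration oracle is the
  arbiter where it is feasible.
* The ID29 grid is a declared reconstruction of an underdetermined schema;
  swapping the channel-definition table re-derives the classifier.
* Stability uses the shared background mean burden in each per-subclone
  denominator; per-subclone background burdens are not identifiable from
  the data.
* De novo multi-signature decomposition (NMF-style) and signature
  attribution to external genomes are out of scope; `match_reference()`
  compares against a provided catalog instead.
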