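---
title: "Di-cistronic genome annotation and composition-based host prediction"
author: "dicistro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Di-cistronic genome annotation and composition-based host prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicistro)
```

## The problem

Metagenomic and serendipitous virus discovery regularly yields complete
+ssRNA genomes with no close relative in the databases. Two questions then
dominate the initial characterization. First, *what is the genome's
organization*: picorna-like viruses split into mono-cistronic genomes (one
polyprotein ORF) and di-cistronic genomes (two non-overlapping large ORFs —
ORF1 carrying the replicase module, ORF2 the capsid proteins — separated by
an intergenic region, as in *Dicistroviridae*). Second, *what host does the
virus infect*: a sequence recovered from intestinal content of an omnivore
may derive from the animal itself or from its diet, and sequence similarity
alone cannot settle the question for a highly divergent virus.

`dicistro` implements both analyses as reusable, testable components:

1. **Architecture annotation** — codon maps, ORF enumeration, detection of
   the 5'UTR / ORF1 / IGR / ORF2 / 3'UTR partition, segment accounting, and
   GFF3 output.
2. **Polyprotein annotation** — conserved motif scanning (helicase,
   VPg, protease, polymerase, capsid), verification of the conserved
   Hel-(VPg)x-Pro-Pol domain order, VPg tandem-repeat detection, and
   cleavage of polyproteins into mature peptides from named schemes.
3. **Nucleotide composition analysis (NCA)** — mono/dinucleotide
   frequencies, observed/expected dinucleotide bias ratios, and a canonical
   (Fisher) discriminant model over host-labeled control sequences that
   assigns a host class to an unknown genome.
4. **Synthetic data** — a first-order Markov generator for host-typical
   control panels and a builder for fully specified di-cistronic genomes
   with known ground truth, so that every stage above can be validated
   without any external download.

## ORF model and architecture detection

An ORF is an AUG-initiated codon run ending at the first in-frame stop
(UAA/UAG/UGA), reported with 1-based inclusive coordinates on the forward
strand where the end is the last base of the stop codon; an ORF of `3k` nt
encodes `k - 1` amino acids. Within each stop-bounded stretch of a reading
frame the 5'-most AUG defines the ORF — the convention under which a
genome's published ORF start coordinate is the first AUG after the
preceding in-frame stop. Downstream-AUG enumeration is available behind the
`all_starts` flag for completeness.

Architecture detection selects the two longest non-overlapping
forward-strand ORFs and orders them 5' to 3'. The two ORFs may lie in
different frames (they typically do; frames are recorded but
unconstrained). Fewer than two qualifying ORFs is a hard error
("not di-cistronic"); a top candidate that overlaps every other candidate
is an ambiguity error listing the candidates. Reverse-strand ORFs longer
than `large_orf_min_nt` raise a flag rather than an error, since their
absence is evidence for (not a precondition of) a positive-strand genome.

Two thresholds deserve explicit defaults because "large ORF" is otherwise
a judgement call: `min_aa = 100` for candidate listing and
`large_orf_min_nt = 300` for the reverse-strand flag. Both are
configurable; the defaults correspond to the usual working definition of a
"large" ORF in picorna-like genomes (several hundred nt) while staying far
below the thousands-of-aa polyproteins they are meant to single out. Ties
in ORF selection are broken by length first, then by smaller start
coordinate, for determinism.

In-silico PCR uses exact matching: the sense primer on the forward strand,
the antisense primer as its reverse complement. IUPAC degenerate bases in
primers (R, V, ...) match their expansion sets while the template is read
literally — screening primer sets are routinely degenerate, templates are
not. Product length includes both primer footprints. A missing primer site
is a *no-amplicon result*, not an error, because that is an informative
assay outcome.

## Motif language and cleavage schemes

Every catalogued motif is fixed-length, so the pattern language is
deliberately minimal: one alternative set per position, written in bracket
notation (`[QH]CAIGLFVKD`), with no gaps or quantifiers. This keeps the
matcher trivially verifiable against a positionwise brute-force scan (a
property the test suite asserts), and it is exactly expressive enough for
slash-notation ambiguity (Q/H) in published motifs.

Short motifs of up to 3 residues (PSG, GE, APL) match by chance roughly
once per few hundred residues, so each short hit carries a `proximity_ok`
flag: `TRUE` when it lies within ±50 aa of a longer hit of the same region.
Standalone short hits stay in the table (they are data) but are excluded
from the replication-module order verdict, which would otherwise be noise-
driven on any real-sized polyprotein.

The VPg tandem repeat is handled as a unit pattern matched in maximal runs
of adjacent copies (consecutive starts one unit length apart). The shipped
unit is the per-position union of the two printed copy readings of the
reference repeat — the published notation is internally inconsistent about
the exact per-copy sequence (21 symbols for two 11-aa copies), so the
catalogue deliberately encodes the union rather than guessing one reading;
the synthetic builder embeds the two concrete readings at positions 1116
and 1127.

Cleavage schemes are *data*, not inference: the sites were predicted by
alignment in the source analyses, and this package does not re-derive
them. A scheme is an ordered list of cut positions with peptide names;
applying one partitions the polyprotein exactly (peptide lengths must sum
to the polyprotein length — asserted at run time). Site dipeptide patterns
(e.g. `ESMQ/DPY`) are checked against the protein and reported as matches
or mismatches rather than enforced, since a scheme may legitimately be
applied to a divergent polyprotein. The VP2/VP4 junction preset (Q/T at
262/263) is marked tentative, mirroring the provisional status of that
prediction. One catalogued discrepancy is resolved arithmetically: the
inclusive span 1318..1816 contains 499 residues, and the package reports
499 for the polymerase peptide even though the source table prints
"498 aa" for that span.

## Composition features and the discriminant model

For a sequence over A,C,G,U(T), mononucleotide frequencies are taken over
non-N positions and dinucleotide frequencies over overlapping adjacent
non-N pairs (linear, not circular — there is no biological basis for
wrapping a linear RNA genome). The observed/expected ratio of dinucleotide
`xy` is `obs(xy) / (f(x) f(y))`; values below 1 mark under-representation.
CpG suppression in viruses of vertebrate hosts and broad UpA depletion are
the classic signals this statistic captures, and their presence or absence
is what separates host classes.

The feature vector for discriminant analysis is 20-dimensional in fixed
order (A,C,G,T; then AA..TT), in one of two modes: raw frequencies
(mono + dinucleotide; the default) or mono frequencies + the 16 O/E
ratios. Both are first-class because the two representations are both in
legitimate use for this analysis and the original description of the method
is ambiguous about which one the fitting software ingested; no intent is
assumed, and the mode is a recorded parameter of every run.

The discriminant model is classical canonical discriminant analysis:
between-class scatter `B` (class-size weighted) against pooled
within-class scatter `W`, canonical factors the generalized eigenvectors
of `B v = λ (W + εI) v`, at most `#classes − 1` of them, scaled to unit
pooled within-class variance so that Euclidean distance in canonical space
is Mahalanobis distance. Classification is nearest class centroid in that
space, with scores reported per class.

Three numerical choices matter:

* **Ridge regularization** `ε = ridge · trace(W)/p` with `ridge = 1e-6`.
  The feature blocks each sum to 1 (exact linear dependence) and the
  smallest class may have fewer members than features, so `W` is singular
  without it. The ridge is small enough to leave well-conditioned problems
  numerically unchanged (the solver matches a dense generalized-eigen
  oracle to 1e-8 on such problems).
* **Equal class priors** by default. With proportional priors a 5-member
  class among 352 sequences would be nearly impossible to call — the prior
  penalty `−2 log(5/352)` dwarfs typical Mahalanobis margins — which would
  defeat the point of including a small reference class at all.
  Proportional priors remain available.
* **Deterministic sign convention** (largest-magnitude loading positive
  per factor), so identical inputs give byte-identical reports.

Concordance — the fraction of control sequences whose predicted host
matches their annotation — defaults to resubstitution, which is the scheme
behind the published figure for this method; leave-one-out, the honest
generalization estimate, is one argument away and is reported alongside it
in the analysis scripts. Confidence ellipses around class centroids in a
canonical-factor plane use the Gaussian construction: semi-axes
`sqrt(eigenvalue · χ²₂(level))` of the 2-D sample covariance along its
eigenvectors.

## What the synthetic data emulate — and what they do not

The control-panel generator draws each class from a first-order Markov
chain targeting a host-typical composition: class sizes (117, 63, 167, 5)
and minimum length 3000 nt mirror the structure of the real picorna-like
control set, and the default class profiles encode the qualitative
biology — CpG suppression in mammal- and plant-virus-like classes
(requested O/E 0.45 and 0.55), none in the insect- and fish-like classes
(1.05, 1.00), UpA depletion everywhere (0.60–0.85), an AU-rich insect
class (60% AU), and a fish-like class with the balanced base composition
seen in the genome that motivated the fish control group (~52% AU). These
profiles are invented simulation parameters, documented as such; they are
not measurements of any real sequence set.

Two properties of the generator are deliberate design decisions:

* **Feasibility projection.** A requested target of the form "CpG at 0.45,
  every other ratio 1" is not realizable by any sequence: the dinucleotide
  joint distribution must have the mononucleotide vector as both margins,
  so depleting one pair necessarily enriches others (real genomes do
  compensate). `host_composition_spec()` therefore projects requested
  ratios onto the nearest realizable set (iterative proportional fitting
  of `f(x)f(y)ρ(xy)` to margins `f`) and stores the projected values as
  the spec's contract (`$oe`, with `$oe_requested` retained). A chain
  built from the projected joint has stationary mononucleotide
  distribution exactly `f`, and its stationary O/E ratios equal `$oe`.
* **Tolerance metric.** The O/E estimator divides two estimated
  frequencies, and at L = 10,000 its per-pair sampling standard deviation
  is ~0.02–0.03 — so no generator, however exact, can promise every one of
  the 16 ratios within 0.05 of target in a single draw. The generator's
  contract is therefore stated on the *mean absolute deviation* across the
  16 ratios: ≤ 0.08 at L = 3,000, ≤ 0.05 at L = 10,000, ≤ 0.02 at
  L = 100,000. The test suite asserts this ladder, which a calibrated
  chain meets comfortably and an uncalibrated product-form chain fails.

The genome builder realizes a fully specified architecture: ORFs begin
with ATG, end with TAA, and contain no internal in-frame stop (non-motif
codons are drawn from the background chain with stop codons rejected);
motif residues are reverse-translated with the lexicographically first
codon per residue, a fixed choice that keeps output deterministic given
the seed. Because a chance AUG upstream of a designed start (in the same
stop-bounded region) would legally shift the detected ORF, the builder
verifies its own output with the package's detector and resamples until
the detected architecture equals the specification exactly — so
"detection inverts the builder" is a true invariant, not a probabilistic
one. Retry caps (10,000 codon-level, 200 genome-level) bound the loop;
realistic specs converge on the first draw almost always.

What passing these tests does **not** show: the panel sequences are
first-order Markov text, with none of the phylogenetic correlation, coding
constraint, or within-class heterogeneity of real viral genomes, and the
class profiles are chosen to be separable. Concordance of ~100% on this
panel demonstrates that the estimator and classifier are implemented
correctly and that the pipeline recovers planted structure — not that real
host assignment achieves any particular accuracy, and not that the
provisional fish call for the motivating genome is biologically confirmed.
The published control set and the real genome record are external data;
analyses that depend on them are exactly the ones this package replaces
with synthetic equivalents.

## Problem sizes and determinism

The shipped analyses and tests run at the study's own scale: one 9,565-nt
genome, a 352-sequence panel of 3,000-nt controls, oracle comparisons over
hundreds of random sequences of 0.5–1.5 kb, 50 random genome specs for the
builder round-trip, and composition checks up to L = 100,000. Every
stochastic procedure takes an explicit seed and is byte-reproducible given
it; pipeline reports echo their configuration and seed, and every number
in a report is recomputable from the TSV intermediates.

## Known limitations

* Exact-match primer placement only — no melting-temperature or mismatch
  model; degenerate bases are supported in primers but not in templates.
* The motif language has no gaps or quantifiers; profile/HMM-style search
  is out of scope by design.
* Cleavage sites are applied, never inferred; a scheme for a new virus
  must come from alignment evidence outside this package.
* The discriminant model is linear with a shared within-class covariance;
  quadratic discriminants and phylogenetically informed host inference are
  out of scope.
* Secondary-structure analysis of the UTRs/IGR (IRES elements) is not
  modeled.
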