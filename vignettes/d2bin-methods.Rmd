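---
title: "Alignment-free metagenome comparison with GC-binned Markov backgrounds"
author: "d2bin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free metagenome comparison with GC-binned Markov backgrounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shotgun metagenomic samples can be compared without assembly or alignment by
summarising each sample as a vector of k-tuple (k-mer) counts and measuring
the similarity of those vectors. Raw k-tuple frequencies, however, are
dominated by neutral sequence composition (above all GC content), so the
useful signal is the *deviation* of each count from what a background model
of the sequences predicts. `d2bin` implements this centralized-count
approach together with a refinement: instead of one background model per
sample, reads are first classified into C bins derived from GC-stratified
reference genomes, and the centralized statistics are accumulated per bin
and then combined.

## The statistics

For a sample X, let $X_w$ be the count of tuple $w$ over all reads and
their reverse complements, $n_X = \sum_w X_w$, and $p_{X,w}$ the probability
of $w$ under an order-$r$ Markov background model. The centralized count is

$$\bar X_w = X_w - n_X\, p_{X,w},$$

and with reads partitioned into $C$ bins the bin-combined version is

$$\bar X_w = \sum_{c=1}^{C}\left(X^c_w - n^c\, p^c_w\right),$$

with per-bin counts, totals and background probabilities. Two normalised
dissimilarities are built from the centralized vectors of two samples:

$$D_2^S = \sum_w \frac{\bar X_w \bar Y_w}{\sqrt{\bar X_w^2+\bar Y_w^2}},
\qquad
d_2^S = \frac12\left(1-\frac{D_2^S}
{\sqrt{\sum_w \frac{\bar X_w^2}{\sqrt{\bar X_w^2+\bar Y_w^2}}}
 \sqrt{\sum_w \frac{\bar Y_w^2}{\sqrt{\bar X_w^2+\bar Y_w^2}}}}\right)$$

$$D_2^* = \sum_w \frac{\bar X_w \bar Y_w}{\sqrt{E_{X,w}\,E_{Y,w}}},
\qquad
d_2^* = \frac12\left(1-\frac{D_2^*}
{\sqrt{\sum_w \bar X_w^2/E_{X,w}}\;\sqrt{\sum_w \bar Y_w^2/E_{Y,w}}}\right)$$

where $E_{X,w}$ is the total expected count of $w$ (summed over bins). Both
lie in $[0,1]$ by the Cauchy–Schwarz inequality, equal 0 for identical
samples and 0.5 for uncorrelated centralized profiles. Tuples whose
denominator vanishes carry no information and are skipped; this preserves
the bounds. Under binning, the $d_2^*$ denominator uses the bin-summed
expected count — the natural mixture analogue of the single-model
definition, recorded here as a modelling assumption.

## Read binning

Reference genomes are ranked by GC fraction and split into C consecutive
rank groups of equal size (remainder assigned to the lowest-GC bins), and an
order-$r$ Markov model is estimated from each bin's pooled sequences plus
reverse complements, with transition probabilities as smoothed ratios of
$(r{+}1)$-tuple to context counts. A read $Y = y_1\dots y_N$ is assigned to
the bin maximising the forward-strand log-likelihood
$\sum_{i=1}^{N-r} \log P(y_{i+r} \mid y_i \dots y_{i+r-1})$, ties to the
lowest bin index. Classification models default to pseudocount 0.5 so a
single never-seen transition cannot veto a bin.

Two sources for the per-bin expectation $p^c_w$ are implemented:

* `expectation_from = "sample"` (the `bin_sample()` default) re-estimates an
  order-$r$ model from the reads the sample placed in that bin. With C = 1
  this reproduces the classic un-binned statistic exactly — the background
  estimated from the sample itself — which anchors the package's
  equivalence tests.
* `expectation_from = "reference"` evaluates the expectation under the
  reference-trained bin models. This is the reading used by the package's
  binned benchmarks: the bin models are estimated from megabases of genome
  sequence rather than from a bin's read subset, and all samples share the
  same expectation, so between-sample differences are not partially
  absorbed into per-sample background fits.

The background order must satisfy $r \le k - 2$: at $r = k-1$ the Markov
expectation reproduces the observed counts up to edge effects and the
centralized signal degenerates. `validate_config()` enforces this.

## Evaluation stack

*Group designs.* Samples are clustered by UPGMA (size-weighted average
linkage, merge height $d/2$, deterministic lexicographic tie-breaking) and
the tree is scored against a reference tree that places each group as one
polytomy under the root, using the rooted triplet distance. A triplet
resolves as $xy|z$ when the MRCA of $x,y$ lies strictly below the MRCA of
all three. Two conventions exist for scoring a resolved triplet against an
unresolved star; `d2bin` defaults to treating the star as *compatible*
(only triplets resolved differently in both trees count). The alternative —
counting resolved-vs-unresolved as different — is available via
`unresolved = "mismatch"`, but under that rule a perfect binary clustering
of a 3-group reference already scores about a third of all triplets, so it
cannot discriminate good clusterings of polytomous references; the
compatible convention is the one consistent with published triplet-distance
values for group references and is used throughout.

*Gradient designs.* Classical PCoA (double-centred $-D^2/2$,
eigendecomposition, axes scaled by the square roots of positive
eigenvalues) ordinates the samples and the magnitude of the Pearson
correlation between PC1 and the known gradient scores recovery; the
magnitude is used because a PCoA axis has arbitrary sign. The signed value
is available for exploratory work.

## The simulator

`synth_genomes()` emits a panel of genomes from per-genome Markov chains
whose GC targets are spread evenly over a range, with log-normal jitter on
transition rows (rows are then re-pinned to the genome's GC target so the
panel's GC design is exact). `simulate_sample()` draws read pairs by
abundance (weighted by genome length, treating abundance as organism
abundance), uniform fragment starts, mate 2 reverse-complemented from the
fragment end, and iid substitution errors uniform over the three
alternative bases. `simulate_study()` wires these into the two supported
designs: a *group* design (independent Zipf centers per group, perturbed
per replicate) and a *gradient* design (one Zipf ordering shifted along a
strictly increasing $\alpha$ grid, perturbed per sample). All randomness
descends from one seed through per-sample substreams, so studies are
bit-reproducible.

### Abundance noise

The perturbation adds the absolute value of a zero-mean Gaussian to each
component and renormalises. The gradient convention is unambiguous: sd
equal to the component (`"sd1"`). For the group design we also use a
proportional noise: a scale *proportional to the component* is the only
dimensionally coherent choice for relative abundances — a variance
proportional to the component itself (mode `"variance10"`, kept for
completeness) makes the noise an order of magnitude larger than any
component at realistic panel sizes and provably erases all community
structure, which contradicts the very possibility of recovering groups from
such data. Mode `"variance10sq"` (variance ten times the squared component)
is the stronger proportional variant.

### Desk-scale benchmark conditions

The two benchmark functions fix the package's reference experiments at
sizes a single CPU handles in minutes; these sizes are the package's own
choices and are stated here once:

* **Group benchmark**: 3 groups × 5 samples, 12 genomes of 100 kb spanning
  GC 0.30–0.70, 20 000 read pairs of 150 bp per sample, k = 5, order 2,
  C = 4 vs C = 1, measure $d_2^S$. The Zipf exponent defaults to
  $0.3\,\ln 100 / \ln 12 \approx 0.556$: the exponent is meaningful only
  relative to the panel size, and this choice preserves the
  most-to-least-abundant dynamic range $N^\alpha \approx 4$ of a 100-genome
  community at $\alpha = 0.3$.
* **Gradient benchmark**: 9 samples on the $\alpha$ grid 0.30–0.70 step
  0.05, 100 genomes (the gradient signal scales with the community's
  effective dimensionality, so the panel is not scaled down), 20 000 read
  pairs, k = 7, order 2, C = 4 vs C = 1, measure $d_2^*$.
* Panels are generated from **order-3 chains** but analysed with order-2
  backgrounds. This asymmetry is deliberate: if the background family can
  represent the generator exactly, centralization removes the entire
  genome signal and the statistics measure only sampling noise. Real
  genomes are never low-order Markov, so an analysable panel must carry
  structure beyond the background order.

## What the synthetic data does and does not show

The simulator reproduces the statistical skeleton of real comparative
studies — controlled GC spread, Zipf-like abundance, proportional
perturbation, paired-end sampling with substitution errors — but genomes
generated from jittered Markov chains are far more homogeneous than real
bacteria, whose k-tuple signatures are shaped by codon usage, repeats,
mobile elements and strand biases. Two consequences: passing benchmarks
demonstrate correctness of the statistics and the expected qualitative
behaviour, not real-data effect sizes; and the benefit of binning is
understated, because a single background model fits a smooth synthetic
panel far better than it fits a real community. In our gradient benchmark
the un-binned statistic indeed performs on par with (even marginally better
than) the binned one, while the group benchmark shows a clear binning
advantage; on real data the published experience is that binning helps
both tasks.

## Numerical choices

* Tuples are indexed lexicographically with A < C < G < T, fixed for
  reproducible serialization.
* Windows containing N are skipped entirely, in counting and in
  log-likelihoods (no IUPAC expansion).
* "Complement" is implemented as reverse complement; the resulting tuple
  multiset is identical to the base-complement convention read 3'→5'.
* Background-expectation models default to pseudocount 0 (contexts never
  observed fall back to uniform and are flagged); classification models
  default to 0.5.
* Dissimilarities are clamped to $[0,1]$ against float rounding at the
  boundaries; summation order is fixed, so matrices are bit-reproducible.
* Reads shorter than the classification order + 1 are dropped with a
  logged count rather than routed to an "unclassified" bin; the simulator
  emits fixed-length reads, so this path only triggers on degenerate input.
* Paired mates are classified independently and pooled for counting; the
  statistics are strand-symmetric and mate-agnostic.

## Limitations

* Dense count vectors limit practical tuple sizes to k ≤ 12 (the published
  parameter space stops at k = 9).
* No indel or platform-specific error models; substitutions only.
* The triplet distance is exact but $O(n^3)$ in the number of samples;
  fine for hundreds of samples, not for thousands.
* Variance-stabilised alternatives (CVTree, Manhattan-family statistics)
  and significance testing of dissimilarities are out of scope.
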