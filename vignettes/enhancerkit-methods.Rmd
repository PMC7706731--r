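---
title: "Modeling enhancer grammar with an explainable sequence classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling enhancer grammar with an explainable sequence classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

enhancerkit trains a multiclass, multilabel neural network that reads a
500-bp DNA sequence and predicts, for each "topic" of co-accessible
chromatin regions, the probability that the sequence belongs to it. Around
that model it implements the analyses that turn a black-box classifier
into a readable account of enhancer logic: which motifs the network
learned, where their instances sit in each enhancer, what every possible
point mutation would do to accessibility, how conserved each motif is
across a phylogeny, and which enhancers in two species are orthologous.
This vignette explains the model, the synthetic study design that the
package ships for validating every component, and the numerical decisions
taken where the design was genuinely open.

## The model

The network follows the DanQ-style hybrid layout used for melanoma
enhancer classification: a 1D convolution (128 filters of width 20, ReLU)
scans the one-hot encoded sequence for local motifs; non-overlapping max
pooling (10/10) condenses the activation maps; a position-wise
(time-distributed) dense layer feeds a bidirectional LSTM that captures
dependencies between motifs; the recurrent outputs are flattened into a
fully connected ReLU layer (256 units); and a sigmoid output unit per
topic makes the classifier multilabel. Dropout (0.2 after pooling, 0.1 on
LSTM inputs and recurrent state, 0.2 after the LSTM, 0.4 after the dense
layer) regularizes training. The loss is mean binary cross-entropy,
optimized with Adam at learning rate 0.001, batch size 128.

Every prediction is strand-symmetric by construction: the forward and
reverse-complement strands pass through the network separately and the
per-class sigmoid outputs are averaged. The averaging is applied after
the sigmoid; applying it to pre-sigmoid logits would also be symmetric,
but post-sigmoid averaging keeps each strand's output an interpretable
probability, and the symmetry property (`predict(s) ==
predict(revcomp(s))`, exact to machine precision) holds either way. The
dense-layer embedding used for enhancer similarity is averaged the same
way. The width of the position-wise dense layer preceding the LSTM is not
fixed by the published description; we default it to 128 (matching the
recurrent width) and expose it in `model_config()`.

The network is implemented directly in R with the batched linear algebra
delegated to BLAS, and the inner loops that R executes poorly (im2col,
pooling, the LSTM time-step recursions and their backward pass) in C++
via Rcpp/RcppArmadillo. No deep-learning framework is involved; the
backward pass is verified against central-difference numerical gradients
in the test suite (tolerance 1e-4 relative on sampled entries, which the
implementation passes with ~1e-7 slack in double precision). Training is
deterministic given `model_config()$seed`: parameter initialization
(Glorot-uniform, LSTM forget-gate bias 1), epoch shuffling and dropout
masks all derive from it.

### Desk scale

The published configuration is the default, but examples, tests and the
bundled study run a reduced "desk" configuration
(`desk_config()`: 32 filters, 32-unit position-wise dense, 32 recurrent
units, 64 dense units) so that a full training fits in minutes on one
CPU. A desk-scale dataset (thousands rather than hundreds of thousands
of regions) sees far fewer gradient updates per epoch, so desk trainings
use more epochs than the production default of two; the bundled study
trains for 10 epochs (~1,900 updates, still an order of magnitude fewer
than a production run, and the point where held-out auROC plateaus near
1 on the synthetic classes). Epoch count is exposed everywhere. Raising
the Adam step to compensate instead was tried and rejected: at 2.5x the
default learning rate the loss plateaus early.

## The synthetic study

Because real chromatin data cannot ship with a package, all components
are exercised on a generator with known ground truth
(`simulate_regions()`). Its defaults define the bundled study:

* **Four classes, 3,000 regions each, 500 bp**: a melanocytic-like class
  (two SOX-dimer instances, one E-box/MITF, one TFAP2A, one RUNX per
  region), a mesenchymal-like class (two AP-1, two TEAD), a GC-rich
  promoter-like class (three SP-like motifs, GC fraction 0.55) and a
  pure-background class. Counts mirror the observed architecture of
  melanocytic enhancers (SOX sites ubiquitous and often duplicated,
  other core motifs present in about one copy) and give each class an
  unambiguous signature while keeping single-motif information content
  realistic.
* **Motifs** are near-deterministic PWMs (consensus-base probability
  0.97) built on the consensus cores of the relevant families (SOX dimer
  `AACAATGGCATTGTT`, E-box `TCACGTGA`, TFAP2A `GCCTSAGGC`, RUNX
  `CTGTGGTTT`, AP-1 `TGASTCA`, TEAD `GGAATGC`, SP `GGGGCGGGG`).
  Instances are placed uniformly at random (non-overlapping, at least
  50 bp from the region edge) on a uniformly random strand, and recorded
  as ground truth.
* **Background** is i.i.d. with configurable GC content (0.41, a typical
  mammalian value). There is no dinucleotide structure — a documented
  limitation: tests passing on this background say nothing about
  confounders such as CpG islands or repeats in real genomes.
* Regions are laid out round-robin on ten synthetic chromosomes, so a
  chromosome-held-out split (chr2, mirroring standard practice) is
  stratified across classes.
* **Accessibility** per region is a fixed, documented function of motif
  content (`activity_model()`): a weighted sum over motif families of
  the best PWM log-odds match minus 75% of the family maximum, with
  MITF-like weighted 2, SOX-like 1.5, others 1 — encoding the
  observation that activity tracks MITF binding while accessibility
  tracks SOX. It is an oracle for mutagenesis and cross-species
  correlation tests, not a model of real MPRA measurements.
* **Evolution** (`evolve_cohort()`) applies Jukes–Cantor substitutions
  along each branch of a user phylogeny — the simplest substitution
  model, sufficient for testing conservation and orthology logic, which
  consume only sequence identity and motif presence. Implanted instances
  can be conserved (exempt from substitutions) or lost wholesale with a
  per-branch probability, emulating motif turnover. Indels are off by
  default; when enabled they have geometric lengths (p = 0.5) and never
  land inside motif instances, which keeps truth-hit remapping exact.

What passing tests on this cohort demonstrates: that the architecture can
learn motif-defined classes from sequence alone, that the interpretation
machinery recovers exactly the implanted signals, and that the
cross-species statistics behave correctly under a known evolutionary
process. What it does not demonstrate: performance on real ATAC-seq
topics, where labels are noisy, classes unbalanced, motif grammar softer,
and background structured.

## Interpretation machinery

**Filter→PWM conversion** scores each convolutional filter on unique
random 20-mers and builds a PWM from the 100 highest-activating ones.
The desk default is 200,000 random k-mers (the production-scale 4,000,000
is one argument away); ties in activation are broken by generation order,
which for uniformly generated k-mers keeps the tie-broken tail unbiased
(a lexicographic tie-break would skew the PWM toward A-rich k-mers).

**Filter importance** follows the mean-ablation recipe: a filter's
activation map is replaced by its mean activation over the dataset and
the increase in per-class binary cross-entropy is the importance. Loss
(not accuracy) is used — it is smooth and defined per class in a
multilabel setting.

**Attribution** uses integrated gradients against a reference set
(expected-gradients style): for each sampled reference, gradients of the
strand-averaged class score are averaged along the straight path from
reference to input (midpoint rule) and multiplied by (input − reference).
The algorithm is chosen for its completeness contract — observed-base
contributions sum to the prediction minus the mean reference prediction,
up to path-discretization error — which is asserted in the acceptance
suite (residual within 5% on at least 95% of a 200-region panel).
Hypothetical (absent-base) contributions are reported in the full L×4
matrix but never summed into completeness. Defaults of 20 references and
20 path steps per reference keep one attribution under a second at desk
scale; both are arguments. The discretization error grows with how
sharply the class score changes along the reference-to-input path:
models with near-saturated sigmoid outputs need finer paths, and the
completeness panel in the validation study uses 40 steps (10 steps
roughly quadruple the residuals there).

**Motif instance localization** multiplies the filter activation at each
alignment position by the attribution mass in the filter window, on both
strands — a convolutional filter detects one orientation of a motif, so
the reverse complement of the sequence is scanned as well and hit
coordinates are mapped back. Scores are min-max normalized per filter
over a calibration corpus and hits are called above a per-filter
threshold (ties at the threshold are excluded), with non-maximum
suppression across strands. Hit centers are corrected by the filter's
alignment offset to its annotated motif when a family annotation is
supplied (falling back to the filter PWM's information-content
centroid), so a motif sitting off-center inside a 20-bp filter window is
still localized at its core.

Threshold calibration compares the positive-class corpus with a contrast
corpus in which every region carries attributions for *its own* class —
if the contrast corpus were attributed for the positive class its scores
would all be near zero and any threshold would separate the corpora,
carrying no information. Two calibration rules are provided. Youden's J
on the pooled position scores is the published-style rule, but on
sparse-motif corpora it is degenerate: most positive-corpus positions
are themselves background, so the J-optimal threshold drifts far into
the noise. The default is therefore a fixed-specificity rule — the
threshold above which only 0.3% of contrast-corpus positions score —
which ties the expected false-positive rate directly to a corpus the
user controls. Both are exposed in `calibrate_motif_thresholds()`.

**In silico saturation mutagenesis** scores all 3L single-nucleotide
variants; reference-base cells are exactly zero and the map is exactly
antisymmetric under mutate-and-restore, both asserted in tests.

## Cross-species machinery

**CRM scoring** is a documented simplification of HMM-based cluster
scorers: within the best 500-bp window, the optimal non-overlapping
placement sum of positive best-strand log-odds hits (uniform background,
optimal placement by weighted-interval dynamic programming, verified
against exhaustive enumeration). Downstream conservation scores consume
only relative values, for which this is sufficient.

**Branch length score (BLS)** marks a species motif-positive when its CRM
score is strictly positive (threshold exposed) and sums the branch
lengths of the minimal subtree connecting positive leaves — equal, on a
tree, to the union of pairwise paths, which the tests exploit as an
independent oracle alongside exhaustive edge-subset minimization. Whether
the original analysis used binary presence or score weighting is not
stated; binary presence is the default and a score-weighted variant sits
behind `weight_by_score = TRUE`. Per-motif totals are normalized by
subtracting the same computation on composition-preserving shuffles of
every sequence.

**Ortholog pairs** are built from a region correspondence table, aligned
with Needleman–Wunsch affine-gap alignment (match 5, mismatch −4, gap
open 10, gap extend 0.5, the EDNAFULL-style parameters of `needle`;
computed by Biostrings, whose gap convention — a gap of length L costs
open + L·extend — matches the brute-force oracle in the tests, and whose
traceback is deterministic). Pairs pass at identity strictly above 80%.
Point substitutions between the pair are then simulated individually on
the first species' sequence; indels are reported but not individually
simulated, since single-base deltas are only well-defined for
substitutions. Accessibility differences are log2 ratios with a
pseudocount of 1.

**Embedding orthology**: dense-layer embeddings are compared by Pearson
correlation; zero-variance embeddings are defined to have correlation 0
(with a warning) rather than NaN.

## Region handling conventions

Coordinates are 0-based, half-open everywhere (BED convention); the
summit of a region is `floor((start + end) / 2)`. Overlap thresholds
(topic labelling at 60% of the window, conserved accessibility at 60% of
the mapped region) are inclusive (`>=`), matching `bedtools intersect
-f`. Topic binarization at probability 0.995 is inclusive. Class calls
at a score threshold are strict (`>`), matching "scores above
threshold". Ambiguous bases one-hot encode to zero rows; genome tiles
containing any `N` are removed before genome-wide scoring, while
training windows with `N` are kept (the published pipeline states the
tiling rule but is silent on training windows; keeping them is flagged
as a choice, not inferred intent).

## Degenerate inputs and numerical choices

Sigmoid outputs are clamped to [1e-7, 1 − 1e-7] inside the loss; training
aborts with a diagnostic on non-finite loss. auROC/auPR use rank-based
formulas with tie handling and report `NA` (flagged undefined) for splits
without positives. PWM log-odds use a uniform 0.25 background with a 1e-3
pseudo-frequency so zero counts stay finite. PWM similarity is the
maximum, over offsets and orientations, of a weighted Pearson
correlation between aligned columns, with each column pair weighted by
the mean of the two columns' information contents; weighting the
correlation (rather than rescaling the probabilities by IC) keeps the
measure invariant to how sharp two representations of the same motif
are, so a count-matrix-derived filter PWM and a near-deterministic truth
PWM of the same motif score high. Alignments must cover at least 75% of
the shorter PWM — smaller overlaps otherwise produce spuriously perfect
correlations from a handful of columns. Comparisons involving only
zero-IC columns are defined as 0.

## The bundled validation study

Beyond the main four-class study, the package ships a motif-recovery
study (`recovery_run()` and friends): six classes of 150-bp regions,
each driven by two instances of a single motif family, classified by a
16-filter desk model trained for 32 epochs. One family per class makes
two claims well-posed that are ill-posed on the multi-family design:
that each family's best-matching filter ranks among the top filters by
per-class importance (a four-family class cannot put four filters into
the top three; and redundant families — an E-box inside a class that is
already identifiable by its SOX dimer — need not be learned at all), and
that instance localization can be scored per family against ground
truth. The scan study (`recovery_scan()`) scans each family's regions
with its representative filter and measures center accuracy within
+/- 2 bp against the implanted truth.

## Known limitations

* The i.i.d. background and deterministic class recipes make the
  synthetic classification task easier than real topic classification;
  held-out auROC near 1 here does not predict real-data auROC.
* The CRM score is not an HMM cluster score; absolute values are not
  comparable to Cluster-Buster outputs.
* The desk-scale attribution defaults trade a little completeness
  residual for speed; for publication-grade attribution maps raise
  `n_refs` and `n_steps`.
* Indel handling in evolution is deliberately conservative (never inside
  motifs), so motif-disrupting indels are out of scope for the synthetic
  truth.
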