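---
title: "Constructing glucose-responsive regulatory trans-omic networks"
author: "transomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing glucose-responsive regulatory trans-omic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transomix)
```

## The problem

Skeletal muscle clears most of an oral glucose load, and obesity blunts
that response. Comparing how a healthy (WT) and a leptin-deficient obese
(ob/ob-type, "OB") animal rewire metabolism after a glucose bolus requires
integrating several omic layers measured over the same time course:
metabolite abundances, gene expression of metabolic enzymes and
transcription factors, and phosphorylation of insulin-signaling proteins.
`transomix` turns such two-genotype multi-omic time courses into a
five-layer regulatory network — InsulinSignal, TF, Enzyme, Reaction,
Metabolite — in which edges are direct regulatory relations drawn from
knowledge tables (enzyme-reaction assignments, substrates/products,
allosteric effectors, binding-motif targets, kinase targets), and then
condenses the reaction level into pathway-level summaries.

Because the real study data live in external repositories, the package
ships a first-class synthetic-data module that emulates the study design
and plants known ground truth, so that every stage — and the pipeline end
to end — is testable offline.

## Responsiveness model

For each molecule and genotype, abundance is sampled at 0 (fasting
baseline), 20, 60, 120 and 240 min with n = 5 replicates. The per-time
fold change is the ratio of replicate means against the 0-min mean,
reported as log2. Significance per time point comes from a two-tailed
Welch test (metabolites, phosphorylation) or a pluggable count test for
genes; the default count test is a Welch test on log2(count + 1) after
scaling each replicate library to the median total. A dedicated
negative-binomial machinery is deliberately not re-implemented: the count
test is an interface, and any two-group method can be registered with
`register_count_method()`.

P-values are converted to Storey q-values across molecules. The null
proportion pi0 is estimated on the lambda grid 0.05–0.95 (step 0.05) with
a cubic smoothing spline evaluated at the largest lambda and clamped to
(0, 1]; a fixed-lambda mode exists for exact unit checks, and pi0 = 1
reduces the estimator exactly to Benjamini–Hochberg. Q-values are computed
per time point within one layer and genotype; pooling across time points
is available behind `pool_qvalues_across_times` because the original
analysis does not state the pooling scope and per-time-point pooling is
the most common reading.

A molecule is **glucose-responsive** when, at any post-administration
time, q ≤ 0.1 *and* |log2 fold change| ≥ 0.585 (2^0.585 = 1.5, i.e. a
1.5-fold change); both comparisons are inclusive. The direction is the
sign of the fold change at the earliest significant time point, which
disambiguates traces that cross zero. Cross-genotype classes are
WT-specific, OB-specific, common (both, same direction) and opposite
(both, conflicting directions).

### Response speed (T1/2)

T1/2 is the first time the trace reaches half of its extremal deviation
from baseline, linearly interpolated between sampled points; responses
with T1/2 < 20 min are rapid (blood insulin peaks near 20 min) and
T1/2 > 60 min slow (insulin is back to baseline near 60 min); the
boundary values are intermediate, as are all times between. Two choices
here were genuinely open:

* **Scale.** T1/2 is computed on the log2 fold-change trace rather than
  raw means. The source analysis defines T1/2 only verbally; the log2
  scale is consistent with the log2-based calling thresholds and makes
  the half-amplitude time of the generator's saturating-exponential
  trajectory equal its planted half-time exactly, so recovery is testable
  without bias. `half_time()` itself is scale-generic.
* **Non-monotone traces.** The amplitude is the extremum in the called
  direction over all time points and the first crossing (left to right)
  wins. A flat trace on a responsive molecule yields an undefined T1/2
  with a warning.

### Detection filter and degenerate inputs

Molecules detected in fewer than half of the replicates (strictly less
than `min_detected_fraction`) in either genotype at any
post-administration time point are removed before testing. Welch tests on
two constant, equal groups return p = 1 by convention; constant but
unequal groups are undefined and flagged rather than forced to p = 0;
groups with fewer than two observations are undefined. Zero or missing
baselines make the fold change (and hence the call) undefined for that
molecule and genotype.

## Clustering and transcription-factor inference

Metabolite time courses are normalized by the geometric mean of the two
genotypes' fasting means and log2-transformed; the WT and OB traces are
concatenated and clustered with Ward's method on Euclidean distances
(`hclust` "ward.D2", whose merge heights are monotone). The number of
display clusters (default 8) is a configuration choice, mirroring a
by-inspection decision in the original analysis.

For genes, the clustering input is the union of genes whose fasting
baseline differs between genotypes (q ≤ 0.1) and genes with a significant
response at any time in either genotype; selected traces are z-scored
over the concatenated WT+OB mean time course. Clustering uses
replicate-averaged traces — per-replicate clustering would mix replicate
noise into the dendrogram without changing the enrichment contract.

Motif enrichment is evaluated at **every** dendrogram node holding at
least 100 genes, not at one fixed cut: the exclusion rule needs
parent/child comparisons. Each (TF, node) pair gets a one-tailed Fisher
p-value (hypergeometric tail) over the clustered-gene background, a
sample odds ratio with exact 0/Inf for zero cells (no Haldane correction,
which would silently change tie behaviour between clusters), and a BH
q-value across all pairs; enrichment requires q ≤ 0.1. A TF is assigned
to a node only if no descendant node above the size threshold is *more*
enriched; "more enriched" compares odds ratios by default (a p-value
comparator is available), and ties keep the ancestor. One edge then runs
from each assigned TF to every gene of its node, deduplicated. Inferred
target sets can be compared against external (ChIP-derived) target
tables with `validate_against_external_targets()`.

## Network assembly

Responsive molecules become nodes: metabolites on the Metabolite layer;
metabolic-enzyme genes (by knowledge-base role) on the Enzyme layer;
transcription factors on the TF layer; and phosphorylation carries
signaling molecules onto the InsulinSignal layer and can also place
enzymes or TFs whose transcript is flat (the basis is recorded; when both
transcript and phosphorylation respond, the transcript basis wins and the
phosphorylation is kept as an annotation). Role sets must be disjoint.

A metabolic reaction becomes a Reaction node exactly when a responsive
enzyme maps to it or a responsive metabolite touches it as allosteric
effector or as substrate/product — reaction reversibility is not
resolved, so substrates and products both count as regulators. Reaction
nodes carry no direction.

Edges among InsulinSignal/TF/Enzyme are signed by direction concordance —
positive when regulator and target change the same way, negative
otherwise — evaluated per genotype, and exist in a genotype only when
both endpoints respond in it. The genotype class of an edge follows the
conjunction rule: common only when present in both genotypes with the
same sign, opposite when present in both with conflicting signs. This
rule is a documented design choice; it is the only composition consistent
with requiring both endpoints to be glucose-responsive. TF repressor
status (from the knowledge base's TF-mode table) annotates the edge and
does not flip the concordance sign, and TF→enzyme edges act on
transcription, so their targets must respond at the transcript level.
`validate_network()` enforces the allowed layer pairs, endpoint
responsiveness and the regulated-reaction property on every assembled
network.

Summaries report, per genotype, reactions regulated by the Enzyme layer
only / Metabolite layer only / both (which partition the Reaction nodes),
reactions reached per regulator speed bin, and the regulators of strictly
more than 15 reactions.

## Condensation

Reactions are grouped into pathway nodes (multi-membership preserved, as
pathway definitions overlap). A pathway node is kept when it has a
significant association with any responsive regulator — a one-tailed
Fisher test of "reaction in pathway" against "reaction regulated by the
molecule" over all knowledge-base reactions, BH-adjusted, q ≤ 0.01 — or
when its fraction of regulated reactions is in the top 10% by
metabolites or by enzyme genes. The top set is the ceiling of the
fraction times the number of pathways with at least one regulated
reaction, ties included, which keeps the selection order-independent and
monotone in the fraction. In the condensed view, enzyme regulation counts
only transcript-level responders (phosphorylation-only enzymes are a
reaction-layer phenomenon). Metabolite→pathway edges need at least 5
regulated reactions; metabolite nodes need a significant association with
a selected pathway; TF nodes need at least 5 regulated reactions in
total — their edges are not filtered per pathway. The figure legend and
methods text of the source analysis disagree on whether the TF rule
counts reactions or enzymes; reactions is the default and
`tf_condense_criterion = "enzymes"` switches the reading.

## The synthetic study and what it does (not) show

`generate_study_bundle()` draws, from one seed, the omic tables, a
matching knowledge base, and the planted truth:

* **Design**: 5 times (0/20/60/120/240 min), n = 5, two genotypes.
* **Metabolites**: 104, of which 29 respond — 21 decreasing only in WT, 4
  increasing and 4 decreasing only in OB, none in common — matching the
  observed composition; speeds mostly rapid (70/20/10%), as observed for
  the decreasing metabolites.
* **Genes**: 700 by default, containing three planted 120-gene
  co-regulated clusters with distinct temporal fingerprints (common-rapid
  up, WT-specific-intermediate up, OB-specific-slow down), each driven by
  a planted TF whose binding motif occurs in 40% of cluster genes versus
  5% of the background; a further 15% of the remaining genes respond with
  random patterns. Planted TFs respond in the genotypes their clusters
  respond in.
* **Phosphoproteins**: 10, spanning signaling molecules, TFs and enzymes,
  with a composition including common, specific and opposite responses
  (the opposite class mirrors glycogen-synthase-like behaviour).
* **Trajectories**: responders deviate on the log2 scale by
  d(t) = A·(1 − 2^(−t/T1/2)) with |A| = 1.5 log2 units, so planted
  responders clear the calling threshold by a margin and the half-time is
  analytically exact. Planted half-times are drawn from 5–15 (rapid),
  30–50 (intermediate) and 90–200 min (slow).
* **Noise**: lognormal with CV 0.2 for abundances; negative binomial with
  dispersion 0.04 for counts; 2% of abundance cells missing completely at
  random. Each table draws from its own named sub-stream of the seed so
  single tables regenerate in isolation.

The generator targets the statistical contracts of the pipeline, not
biological realism: there are no kinetic dynamics, no correlation between
molecules beyond the planted co-regulation, no batch structure, no
intensity-dependent missingness, and the knowledge-base wiring is random
rather than shaped like real metabolism. Passing recovery tests therefore
demonstrates that the algorithms implement their contracts and have the
expected operating characteristics at the study's design point — not that
the thresholds are optimal for any particular real data set.

The planted network oracle is derived inside the generator by direct set
logic over truth labels and knowledge tables, independently of the
assembler, so the "perfect calls reproduce the planted network exactly"
test compares two routes rather than one function with itself.

## Problem sizes and numeric choices

The bundled analyses and tests run the default bundle (104 metabolites,
700 genes, 10 phosphoproteins, 150 reactions, 12 pathways) and smaller
variants; these sizes give stable recovery statistics while keeping a
full run in seconds. Key tolerances: Fisher p-values are exact
hypergeometric tails; Welch p-values use the t distribution with
Satterthwaite degrees of freedom; q-value estimators clamp pi0 into
(0, 1]; odds-ratio ties in the exclusion rule keep the ancestor; all
threshold comparisons at the calling and condensation boundaries are
inclusive on the "kept" side exactly as stated above. GML serialisation
pins the creator header so identical networks are byte-identical, which
the determinism tests rely on.

## Known limitations

* The gene count test is a scaled log2 Welch test by default, not a
  negative-binomial exact test; with n = 5 and moderate dispersion this
  is slightly conservative for low counts. The interface accepts
  registered alternatives.
* Storey's smoother estimate of pi0 can be unstable for very short
  p-vectors (e.g. a 10-protein phosphorylation panel); the fixed-lambda
  and fixed-pi0 modes are the stable fallbacks.
* Directions are genotype-local; a molecule responding in both genotypes
  at different times may earn different earliest-significant directions,
  which is intended behaviour of the earliest-significant rule.
* Edge genotype classes depend on the conjunction rule described above;
  other colourings of mixed-class endpoint pairs are conceivable but not
  implemented.
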