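---
title: "Methods: transcript-aware variant classification with per-class random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-aware variant classification with per-class random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Clinical exome analysis leaves a researcher with thousands of rare
intragenic DNA variants, of which at most a handful cause the patient's
monogenic disease. `vepforest` implements a transcript-aware prediction
framework for this setting: every variant is interpreted on every
transcript it overlaps, routed to one of five class-specific models, and
either labelled automatically by population-frequency or
clinical-assertion rules, or scored by a Random Forest trained for
balanced accuracy.

# The five model classes

Different kinds of variants carry entirely different evidence, so one
model per kind beats one model for all:

* `simple_aae` — exactly one amino-acid substitution,
* `complex_aae` — any larger protein change (two or more substitutions,
  in-frame or frameshifting indels, premature stop, start or stop loss),
* `utr5`, `utr3` — variants in the untranslated regions,
* `without_aae` — all other intragenic variants (synonymous, intronic).

Routing (`classify_variant()`) works on the *consequence*, not the
position alone: a variant is applied to the transcript in silico
(`apply_variant()`), the mutated mRNA is re-spliced with shifted exon
boundaries and translated from the (mapped) annotated start codon, and
the protein-level difference decides the class. Precedence for
region-spanning variants is: protein change beats UTR, UTR beats
`without_aae`. Two boundary decisions were genuinely open and are fixed
here: canonical splice-site variants that leave the protein unchanged
route to `without_aae` (their splice evidence lives in the feature
vector — there is no dedicated splice class), and destruction of the
start codon is a protein change (`complex_aae`), not a UTR event.

# Automatic labels

Two rules bypass the classifier entirely. A variant with at least one
homozygous carrier in any population source (gnomAD/ExAC/1000G-style
tables) is `benign_automatic`: a healthy homozygote is direct evidence
against fully penetrant pathogenicity. A variant clearly asserted
`pathogenic` is `deleterious_automatic`, and the associated disease is
carried into the output. `likely_pathogenic` and `conflicting`
assertions never auto-label (they are displayed only); a pathogenic
assertion outranks homozygous carriers. Stored genotype counts are
capped at 32 000 — beyond that the count adds no information about
benignity and only costs space. pLI scores are attached to transcripts
for display but are deliberately excluded from every feature vector:
gene-level loss-of-function intolerance is evidence about the gene, not
about the allele under test.

# Splice-site scoring

Variant effects on splicing are scored only at *canonical* sites: each
intron's annotated donor (3 exonic + 6 intronic bases, 9-mer) and
acceptor (20 intronic + 3 exonic bases, 23-mer) windows. The scorer
never scans for cryptic sites activated elsewhere — experience with such
scans is that they drown the signal in false positives, and the
package's property tests enforce that variants outside canonical
windows produce exactly zero deltas.

The score is a maximum-entropy log-odds,
`log2(P_signal(w) / P_background(w))`. The signal distribution is the
maximum-entropy distribution consistent with the empirical marginals of
all contiguous blocks of `constraint_order` positions (default 2),
fitted by iterative proportional fitting on a chain-structured factor
graph with exact forward–backward marginals. This representation is what
makes the 23-mer acceptor tractable (a full joint over 4^23 states is
not representable), while two limiting cases give free correctness
checks: `constraint_order = window_length` recovers the empirical window
distribution exactly, and `constraint_order = 1` reduces to a product of
positional base frequencies whose log-odds scores are additive. IPF runs
to a marginal tolerance of 1e-6 (at most 500 iterations; on a chain it
converges in one sweep). A pseudocount of 0.5 per marginal cell keeps
every probability positive, so scores are always finite. The background
is a position-independent base composition.

For indels overlapping a window, the alternate window is re-read from
the mutated sequence anchored at the annotated exon/intron boundary
mapped through the edit — a deterministic convention chosen over
realignment heuristics.

# UTR checks

Both UTR checks are deliberately simple, documented stand-ins for the
tasks they name; neither claims to reproduce a published discriminant.

* **Kozak context** (`kozak_change()`): the 10-base context
  `gccRccATGG` (positions −6..+4 around the A of the start codon, R = A
  or G) is scored as the number of consensus-matching positions (0–10)
  in the reference versus mutated mRNA. A position-match count was
  chosen over a PWM because no training corpus for initiation strength
  ships with the package; the triple (ref score, alt score, changed)
  feeds the `utr5` feature vector and the forest learns its weight.
* **Polyadenylation signal** (`polya_signal_change()`): occurrences of
  the canonical hexamers AATAAA and ATTAAA (configurable) are counted in
  the reference and mutated 3' UTR; fewer hits means `disrupted`, more
  means `created`. This replaces a quadratic-discriminant polyA
  detector with a transparent rule that captures the dominant signal —
  loss of the hexamer itself.

# Feature vectors

Each class has a fixed, versioned schema (`feature_schema()`): a shared
block (conservation at the site with an explicit missing sentinel of
−999 plus indicator — never a silent 0 —, min and max-magnitude
canonical splice deltas, splice-window overlap flag, allele length
change) plus class-specific features: Grantham distance, hydropathy and
charge change for `simple_aae`; frameshift/premature-stop flags and
truncated protein fraction for `complex_aae`; the Kozak triple and
distance to the start for `utr5`; the polyA triple and distance to the
stop for `utr3`; distance to the nearest exon boundary for
`without_aae`. Grantham distances are computed from the published
composition/polarity/volume properties with the scale constant fixed so
the mean over the 190 amino-acid pairs is 100; spot checks (Leu–Ile 5,
Gly–Trp 184) match the published table, and the handful of cells where
the 1974 table's internal rounding differs by ±1 are accepted in favour
of a transparent formula. Conservation is treated as an opaque per-base
scalar (bedGraph input); the package does not mandate a particular
score. The expanded per-contig lookup built by `conservation_track()`
targets desk-scale genomes; a bigWig-backed query would replace it at
full genome scale.

# Training sets and forests

Training-set construction follows three rules: benign = intragenic
variants with at least one homozygous carrier (`hom_count >= 1`, an
inclusive boundary); deleterious = disease-mutation (DM) entries plus
`pathogenic`/`likely_pathogenic` assertions, with identities carrying a
`conflicting` assertion excluded from the assertion-derived part (a DM
entry stands on its own — the exclusion targets unreliable assertions,
not the independent DM evidence); and any identity present in both sets
is removed from *both*.

Forests are standard CART/Gini ensembles (grown by the `randomForest`
package) wrapped in the package's training policy: each tree's
bootstrap draws equal numbers from both classes with replacement (the
balanced bootstrap), which is the mechanism behind the balanced-accuracy
objective — with plain bootstraps a 100:1 imbalanced training set yields
grossly unequal sensitivity and specificity, and the regression test in
`test-forest.R` demonstrates exactly that contrast. The balancing
mechanism sits behind a `balance =` switch. Prediction reports the
number of trees voting deleterious out of the total — deliberately not a
probability or confidence score, which small forests cannot support —
and the label uses a strict-majority threshold, exposed as
configuration.

`grid_search_forest()` evaluates stratified k-fold (default 5)
cross-validated balanced accuracy over a tree-count × features-per-split
grid and selects the *smallest* forest (fewest trees, ties by fewer
features) within 0.12 percentage points of the grid maximum: accuracy
plateaus well before the largest forest, and prediction cost is linear
in trees. Per-fold training seeds are `seed + fold`, identical across
grid points, so an independent fold-by-fold recomputation reproduces the
score table bit-for-bit (this is how the tests verify it).

# Pipeline, cache and privacy

`run_vcf()` accepts exactly one-sample VCFs (multi-sample files are
rejected outright rather than silently analysed on the first sample);
malformed records are skipped and counted, never fatal. Variants are
normalized (trimmed, anchored, left-aligned — one identity per allele)
before anything else, because the cache is keyed by that identity plus
genome-build tag, transcript and model version. Warm- and cold-cache
runs produce bitwise-identical tables; cached records carry *no* sample,
file or upload identifiers, so a deleted upload cannot be reconstructed
from the cache. Uploads live in a separate store with a 4-week default
retention, deletable on demand; the retention sweep is an explicit
subcommand, not a daemon. Batch queries (`query_batch()`, capped at 50
variants per call) read the cache but never write it: their results are
not persisted anywhere.

# The synthetic study generator

`make_genome_and_transcripts()` and `make_labelled_variants()` generate
the entire study: multi-exon transcripts on both strands with valid
ATG…stop CDSs, canonical GT/AG introns with consensus-like context,
strong Kozak contexts and planted AATAAA signals; labelled variant sets
per class; and the frequency/assertion/DM/conservation resources, all
deterministically from one seed.

Conservation is modelled as a property of *positions*: each base carries
a latent "evolutionarily constrained" flag (probability 0.5), flagged
bases draw their score from N(0.3 + `effect_size`·0.15, 0.15) and
unflagged from N(0.3, 0.15). Deleterious variants are sampled from
constrained positions, benign from unconstrained ones, so the class
separation in the conservation feature equals `effect_size` pooled SDs
by construction and the two pools never collide on a base. At
`effect_size = 0` the pools are exchangeable and every separation
vanishes — the null construction the generator's own tests verify.
`effect_size` also scales positional enrichment (at its full strength of
3 SD, half the deleterious non-coding variants sit in canonical splice
windows, 5'-UTR ones target the Kozak prefix, 3'-UTR ones the planted
polyA signal) and, for coding classes, the preference for severe
(high-Grantham) exchanges. Default nuisance fractions: 40% of benign
variants get a homozygous carrier, 60% of deleterious ones a
pathogenic/likely-pathogenic assertion, 5% a conflicting one, 30% a DM
tag.

What the generator does *not* emulate: linkage structure, mutation-rate
heterogeneity, population-specific frequencies, annotation errors, and
realistic conservation autocorrelation along the genome. Passing tests
therefore demonstrate that the machinery is correct and that the
training policy recovers a known separation — not that any particular
real-data accuracy will be achieved.

# Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale problems chosen
to exercise every code path: the classifier-recovery check uses 40
transcripts and 2 000 + 2 000 `without_aae` variants at `effect_size`
3 with a 100-tree, 10-fold cross-validated forest; routing is verified
by exhaustive enumeration (~5 000 variants per transcript strand);
splice fidelity by 10 000 fuzz variants. Coordinates are 0-based
half-open internally, converted from 1-based formats (VCF, GTF, resource
tables) at the parser boundary. Translation stops at the first stop
codon; incomplete CDS annotations (length not divisible by 3) warn and
truncate rather than fail, because real annotation releases contain
them. The intron-midpoint tie in donor/acceptor distance resolves to the
donor side. Codon translation uses an internal lookup table for speed
and is cross-checked against `Biostrings::translate` in the tests.

# Known limitations

* Single reference build per resource bundle; no liftover. The cache key
  carries a build tag so caches for several builds can coexist.
* The splice scorer is trainable but ships no pre-trained human model;
  scores are only comparable within one trained model.
* UTR checks are coarse; mRNA-stability and uORF effects are out of
  scope.
* Mitochondrial and RNA-gene variants are outside the model: routing is
  defined only for variants overlapping protein-coding transcripts.
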