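# vepforest

Transcript-aware variant effect prediction with class-specific Random
Forests, for researchers hunting causal variants of monogenic disease
in single-sample VCFs.

Every intragenic DNA variant is interpreted on each transcript it
overlaps: the variant is applied to the transcript in silico, the
mutated mRNA is re-spliced and translated, and the consequence routes it
to one of **five dedicated prediction models** —

| class | variants |
|---|---|
| `simple_aae` | exactly one amino-acid substitution |
| `complex_aae` | >1 substitution, indels, frameshifts, premature stop, start/stop loss |
| `utr5` / `utr3` | untranslated-region variants |
| `without_aae` | all other intragenic variants (synonymous, intronic) |

Each class has its own feature schema (conservation, maximum-entropy
splice-score changes at canonical donor/acceptor windows, Grantham /
hydropathy / charge for substitutions, Kozak-context and
polyadenylation-signal checks for the UTRs) and its own Random Forest,
trained on per-tree **balanced bootstraps** so that sensitivity and
specificity carry equal weight: the balanced accuracy
(sensitivity + specificity)/2 is the training objective and the
model-selection criterion. A grid search picks the **smallest** forest
within 0.12 percentage points of the best cross-validated score.
Predictions report **tree votes** (how many trees call the variant
deleterious), never a pseudo-probability.

Two rules bypass the classifier: at least one homozygous carrier in a
population resource labels a variant automatically benign (genotype
counts are stored capped at 32 000), and a clear `pathogenic` clinical
assertion labels it automatically deleterious, with the disease shown.

Splice effects are scored **only at canonical splice sites** (the
annotated donor 9-mer and acceptor 23-mer of each intron) with a
trainable maximum-entropy model: `log2(P_signal/P_background)` where the
signal distribution is fitted by iterative proportional fitting to match
all empirical block marginals. Cryptic-site scanning is deliberately
absent.

The VCF pipeline caches every (variant, transcript) prediction under a
normalized, origin-free key — re-running a file costs zero classifier
calls, uploads expire after 4 weeks or on demand, and nothing in the
cache can reconstruct a deleted file. A batch API entry point accepts up
to 50 variants per call and never writes the cache.

A deterministic synthetic-data generator (`simulation_config()`,
`make_genome_and_transcripts()`, `make_labelled_variants()`) emulates
the whole study — toy genomes with multi-exon transcripts on both
strands, labelled variant sets with tunable class separation, and all
resource tables — so every component is testable offline.

## Worked example

```r
library(vepforest)

# simulate a study: genome + transcripts + labelled variants + resources
cfg <- simulation_config(seed = 42, n_benign = 20, n_deleterious = 20)
study <- file.path(tempdir(), "study")
fx <- make_genome_and_transcripts(cfg, dir = study)
lv <- make_labelled_variants(cfg, fx, dir = study)

# splice models and per-class forests
donor <- train_splice_model(make_splice_training_windows(500, "donor", 1),
                            constraint_order = 2, site_type = "donor")
acceptor <- train_splice_model(make_splice_training_windows(500, "acceptor", 2),
                               constraint_order = 2, site_type = "acceptor")
mats <- build_training_matrices(lv$variants, fx$genome, fx$transcripts,
                                lv$cons_track, donor, acceptor)
forests <- Filter(Negate(is.null), lapply(mats, function(m) {
  if (is.null(m) || min(table(m$label)) < 2) return(NULL)
  train_forest(m[, setdiff(names(m), "label")], m$label,
               n_trees = 50, n_features_per_split = 3, seed = 7)
}))

# analyse the simulated single-sample VCF with a prediction cache
res <- analysis_resources(fx$genome, fx$transcripts,
                          load_frequency_table(lv$files$frequency),
                          load_assertion_table(lv$files$assertions),
                          lv$cons_track, donor, acceptor, forests)
cache <- prediction_cache()
out <- run_vcf(lv$files$vcf, res, cache)
head(out[, c("contig", "pos", "ref", "alt", "model_class", "label",
             "votes_deleterious", "n_trees", "disease")], 8)
```

```
 contig pos ref alt model_class                 label votes_deleterious n_trees        disease
   ctg1  81   A   G        utr5                benign                 2      50           <NA>
   ctg1  96   G   A        utr5 deleterious_automatic                NA      NA disorder-gene1
   ctg1 111   G   T        utr5           deleterious                39      50           <NA>
   ctg1 114   C   G        utr5           deleterious                40      50           <NA>
   ctg1 248   T   G without_aae           deleterious                45      50           <NA>
   ctg1 260   T   C        utr5                benign                 0      50           <NA>
   ctg1 264   C   G        utr5                benign                16      50           <NA>
   ctg1 267   C   G        utr5                benign                17      50           <NA>
```

One row per (variant, transcript). `votes_deleterious`/`n_trees` is the
tree vote — 40/50 means 40 trees consider the variant deleterious.
Automatically labelled variants (here a ClinVar-style `pathogenic`
assertion, with its disease) bypass the forest and carry no votes. The
first run made 200 model calls; running the same file again makes **0**
— every row is a cache hit:

```
model calls: 200 | cache hits: 0
second run model calls: 0 | cache hits: 200
```

A thin command-line front end over the same functions ships at
`inst/scripts/vepforest-cli.R` (subcommands `simulate`, `train`,
`grid-search`, `run-vcf`, `batch`, `sweep-cache`).

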