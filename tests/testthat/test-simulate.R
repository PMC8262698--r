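# Synthetic-data generator: determinism, geometry contracts, resource
# tables, class separation.

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 71, n_benign = 5, n_deleterious = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a <- make_genome_and_transcripts(cfg, dir = d1)
  b <- make_genome_and_transcripts(cfg, dir = d2)
  expect_identical(a$genome, b$genome)
  expect_identical(readLines(a$files$fasta), readLines(b$files$fasta))
  expect_identical(readLines(a$files$gtf), readLines(b$files$gtf))
  va <- make_labelled_variants(cfg, a, dir = d1)
  vb <- make_labelled_variants(cfg, b, dir = d2)
  expect_identical(va$variants, vb$variants)
  expect_identical(readLines(va$files$vcf), readLines(vb$files$vcf))
  expect_identical(readLines(va$files$frequency),
                   readLines(vb$files$frequency))
  expect_identical(va$cons_track$df, vb$cons_track$df)
})

test_that("generated transcripts satisfy the genome-model contracts", {
  cfg <- simulation_config(seed = 72, n_transcripts = 8)
  fx <- make_genome_and_transcripts(cfg)
  expect_equal(length(fx$transcripts), 8L)
  strands <- vapply(fx$transcripts, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
  for (tx in fx$transcripts) {
    # valid ATG...stop CDS, no internal stop
    tp <- transcript_protein(tx, fx$genome)
    expect_equal(substr(tp$protein, 1, 1), "M")
    expect_equal(substr(tp$protein, nchar(tp$protein), nchar(tp$protein)),
                 "*")
    expect_equal(cds_length(tx) %% 3L, 0L)
    expect_false(grepl("\\*", substr(tp$protein, 1, nchar(tp$protein) - 1)))
    # canonical dinucleotides at every intron boundary
    win <- splice_windows(tx, fx$genome)
    for (r in seq_len(nrow(win))) {
      s <- vepforest:::.window_seq(fx$genome$contigs[[tx$contig]],
                                   win$gstart[r], win$gend[r], tx$strand)
      if (win$site_type[r] == "donor") expect_equal(substr(s, 4, 5), "GT")
      else expect_equal(substr(s, 19, 20), "AG")
    }
    # a planted polyA signal in every 3' UTR
    cdna <- spliced_seq(tx, fx$genome)
    utr3 <- substr(cdna, utr5_length(tx) + cds_length(tx) + 1L, nchar(cdna))
    expect_true(grepl("AATAAA", utr3, fixed = TRUE))
  }
})

test_that("every generated variant matches the reference and its intended class", {
  cfg <- simulation_config(seed = 73, n_benign = 10, n_deleterious = 10)
  fx <- make_genome_and_transcripts(cfg)
  lv <- make_labelled_variants(cfg, fx)
  expect_equal(nrow(lv$variants), 100L)
  for (i in seq_len(nrow(lv$variants))) {
    r <- lv$variants[i, ]
    seq <- fx$genome$contigs[[r$contig]]
    expect_equal(substr(seq, r$pos + 1L, r$pos + nchar(r$ref)), r$ref)
    v <- normalized_variant(r$contig, r$pos, r$ref, r$alt, fx$genome)
    expect_equal(
      classify_variant(v, fx$transcripts[[r$transcript]],
                       fx$genome)$model_class,
      r$model_class)
  }
})

test_that("the stated fraction of benign variants has homozygous carriers", {
  cfg <- simulation_config(seed = 74, n_benign = 60, n_deleterious = 10,
                           frac_hom = 0.4)
  fx <- make_genome_and_transcripts(cfg)
  lv <- make_labelled_variants(cfg, fx)
  ben <- lv$variants[lv$variants$label == "benign", ]
  hom_keys <- unique(lv$frequency_table$key[lv$frequency_table$hom_count >= 1])
  frac <- mean(ben$key %in% hom_keys)
  expect_gt(frac, 0.3); expect_lt(frac, 0.5)
  # deleterious variants never get homozygote support
  del <- lv$variants[lv$variants$label == "deleterious", ]
  expect_false(any(del$key %in% hom_keys))
})

test_that("conservation separation matches effect_size and vanishes at zero", {
  # null construction: labels are exchangeable at effect_size 0
  cfg0 <- simulation_config(seed = 75, n_benign = 40, n_deleterious = 40,
                            effect_size = 0)
  fx0 <- make_genome_and_transcripts(cfg0)
  lv0 <- make_labelled_variants(cfg0, fx0)
  cons_of <- function(lv) {
    vapply(seq_len(nrow(lv$variants)), function(i) {
      r <- lv$variants[i, ]
      conservation_at(lv$cons_track, r$contig, r$pos, r$pos + nchar(r$ref))
    }, numeric(1))
  }
  c0 <- cons_of(lv0)
  p <- stats::wilcox.test(c0[lv0$variants$label == "benign"],
                          c0[lv0$variants$label == "deleterious"])$p.value
  expect_gt(p, 0.01)
  # at effect 3 the standardized separation is near 3 pooled SDs
  cfg3 <- simulation_config(seed = 75, n_benign = 40, n_deleterious = 40,
                            effect_size = 3)
  fx3 <- make_genome_and_transcripts(cfg3)
  lv3 <- make_labelled_variants(cfg3, fx3)
  c3 <- cons_of(lv3)
  lab <- lv3$variants$label
  d <- (mean(c3[lab == "deleterious"]) - mean(c3[lab == "benign"])) /
    sqrt((stats::var(c3[lab == "deleterious"]) +
          stats::var(c3[lab == "benign"])) / 2)
  expect_gt(d, 2.4); expect_lt(d, 3.6)
})

test_that("classifier performance rises monotonically with effect_size", {
  sm <- fixture_splice_models()
  ba_at <- function(effect) {
    cfg <- simulation_config(seed = 76, n_transcripts = 8,
                             n_benign = c(without_aae = 120),
                             n_deleterious = c(without_aae = 120),
                             effect_size = effect)
    fx <- make_genome_and_transcripts(cfg)
    lv <- make_labelled_variants(cfg, fx)
    mats <- build_training_matrices(lv$variants, fx$genome, fx$transcripts,
                                    lv$cons_track, sm$donor, sm$acceptor)
    m <- mats$without_aae
    x <- m[, setdiff(names(m), "label")]
    fold <- make_stratified_folds(m$label, 4, seed = 5)
    mean(vapply(1:4, function(f) {
      tr <- fold != f
      fm <- train_forest(x[tr, ], m$label[tr], 60, 3, seed = 5 + f)
      balanced_accuracy(m$label[!tr], predict(fm, x[!tr, ])$label)
    }, numeric(1)))
  }
  bas <- c(ba_at(0), ba_at(1.5), ba_at(3))
  expect_lt(bas[1], 0.65)           # no signal at the null
  expect_true(all(diff(bas) > 0))   # monotone in effect size
  expect_gt(bas[3], 0.85)
})
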