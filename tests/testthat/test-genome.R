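# Reference loading, transcript models, coordinate mapping, in-silico
# variant application.

test_that("FASTA loading normalizes case and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "acgu"), fa)
  g <- load_reference(fa)
  expect_equal(names(g$contigs), "c1")
  expect_equal(g$contigs[["c1"]], "ACGT")
  expect_equal(nchar(g$contigs[["c1"]]), 4L)

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), dup)
  expect_error(load_reference(dup), "duplicate")
  expect_error(load_reference(file.path(tempdir(), "nope.fa")), "not found")
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(load_reference(empty))
})

test_that("transcript invariants are enforced", {
  ex <- cbind(c(10L, 50L), c(30L, 80L))
  expect_error(transcript("t", "g", "c", "+", rbind(c(10, 35), c(30, 80)),
                          12, 60), "overlap")
  expect_error(transcript("t", "g", "c", "+", ex, 35, 60), "outside exons")
  # CDS not divisible by 3: flagged with a warning, not an error
  expect_warning(tx <- transcript("t", "g", "c", "+", ex, 10, 53),
                 "not divisible by 3")
  expect_true(tx$cds_incomplete)
})

test_that("GTF round trip reproduces hand-built transcripts on both strands", {
  for (strand in c("+", "-")) {
    fx <- fixture_tx(strand)
    dir <- withr::local_tempdir()
    fa <- file.path(dir, "g.fa"); gtf <- file.path(dir, "a.gtf")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(fx$genome$contigs), fa)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     fx$tx$gene, fx$tx$id)
    lines <- character(0)
    for (e in seq_len(nrow(fx$tx$exons))) {
      lines <- c(lines, paste(fx$tx$contig, "test", "exon",
                              fx$tx$exons[e, 1] + 1L, fx$tx$exons[e, 2],
                              ".", strand, ".", attrs, sep = "\t"))
      cs <- max(fx$tx$exons[e, 1], fx$tx$cds_start)
      ce <- min(fx$tx$exons[e, 2], fx$tx$cds_end)
      if (ce > cs)
        lines <- c(lines, paste(fx$tx$contig, "test", "CDS", cs + 1L, ce,
                                ".", strand, "0", attrs, sep = "\t"))
    }
    writeLines(lines, gtf)
    g <- load_reference(fa)
    txs <- load_transcripts(gtf, g)
    expect_equal(length(txs), 1L)
    got <- txs[[fx$tx$id]]
    expect_identical(got$exons, fx$tx$exons)
    expect_identical(got$cds_start, fx$tx$cds_start)
    expect_identical(got$cds_end, fx$tx$cds_end)
    expect_identical(got$strand, strand)
  }
})

test_that("annotation referencing an unknown contig errors", {
  fx <- fixture_tx("+")
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "bad.gtf")
  writeLines(paste("cZZ", "t", "exon", 1, 10, ".", "+", ".",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), gtf)
  expect_error(load_transcripts(gtf, fx$genome), "unknown contig")
})

test_that("map_genomic boundary definitions hold", {
  fx <- fixture_tx("+")
  m <- map_genomic(fx$tx, fx$tx$cds_start)
  expect_equal(m$region, "cds"); expect_equal(m$offset, 0L)
  # first intronic base after exon 1 on the plus strand: donor distance 1
  m <- map_genomic(fx$tx, fx$tx$exons[1, 2])
  expect_equal(m$region, "intron")
  expect_equal(m$distance, 1L); expect_equal(m$side, "donor")
  # last intronic base before exon 2: acceptor distance 1
  m <- map_genomic(fx$tx, fx$tx$exons[2, 1] - 1L)
  expect_equal(m$side, "acceptor"); expect_equal(m$distance, 1L)
  expect_equal(map_genomic(fx$tx, 0L)$region, "upstream")
  expect_equal(map_genomic(fx$tx, 241L)$region, "downstream")
  # strand-awareness of up/downstream
  fm <- fixture_tx("-")
  expect_equal(map_genomic(fm$tx, 0L)$region, "downstream")
  expect_equal(map_genomic(fm$tx, 241L)$region, "upstream")
})

test_that("every exonic base maps to the layout-predicted region, both strands", {
  for (strand in c("+", "-")) {
    fx <- fixture_tx(strand)
    n <- cdna_length(fx$tx)
    expect_equal(n, 102L)
    for (cpos in 0:(n - 1L)) {
      g <- cdna_to_genomic(fx$tx, cpos)
      m <- map_genomic(fx$tx, g)
      expect_equal(m$region, fixture_region_of_cdna(cpos),
                   info = sprintf("%s cpos=%d", strand, cpos))
      # round trip through the region-relative offset
      expect_equal(region_to_genomic(fx$tx, m$region, m$offset), g)
      expect_equal(genomic_to_cdna(fx$tx, g), cpos)
    }
  }
})

test_that("fixture CDS translates to the fixture protein; codon table agrees with Biostrings", {
  for (strand in c("+", "-")) {
    fx <- fixture_tx(strand)
    tp <- transcript_protein(fx$tx, fx$genome)
    expect_equal(tp$protein, fixture_protein)
  }
  set.seed(42)
  for (i in 1:20) {
    cds <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    mine <- translate_cds(cds, stop_at_stop = FALSE)
    bs <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             no.init.codon = TRUE))
    expect_equal(mine, bs)
  }
})

test_that("apply_variant: synonymous, frameshift and missense behave as hand-computed", {
  fx <- fixture_tx("+")
  g <- fx$genome; tx <- fx$tx
  # codon 2 GAA at genomic [45,48); GAA->GAG is synonymous (both Glu)
  v <- normalized_variant("c1", 47L, "A", "G", g)
  av <- apply_variant(tx, v, g)
  expect_equal(av$n_aa_sub, 0L)
  expect_false(av$frameshift || av$premature_stop || av$protein_change)
  # 1 bp CDS deletion (drops the A at 46): frameshift
  v <- normalized_variant("c1", 45L, "GA", "G", g)
  av <- apply_variant(tx, v, g)
  expect_true(av$frameshift)
  expect_equal(av$length_change, -1L)
  # missense GAA->CAA at codon 2: E2Q, verified by manual translation
  v <- normalized_variant("c1", 45L, "G", "C", g)
  av <- apply_variant(tx, v, g)
  expect_equal(av$n_aa_sub, 1L)
  expect_equal(av$protein_alt, sub("^ME", "MQ", fixture_protein))
  # ref mismatch is rejected
  expect_error(normalized_variant("c1", 45L, "T", "C", g), "mismatch")
})

test_that("a variant and its inverse restore the original cDNA", {
  fx <- fixture_tx("-")
  g <- fx$genome; tx <- fx$tx
  expect_error(normalized_variant("c2", 60L, "A", "A"), "identical")
  ref_base <- substr(g$contigs[["c2"]], 101L, 101L)
  v <- normalized_variant(tx$contig, 100L, ref_base,
                          setdiff(c("A", "T"), ref_base)[1])
  av <- apply_variant(tx, v, g)
  mutated <- reference_genome(setNames(
    vepforest:::mutate_contig(g$contigs[["c2"]], v), "c2"))
  inv <- normalized_variant("c2", v$pos, v$alt, v$ref)
  av2 <- apply_variant(tx, inv, mutated)
  expect_equal(av2$cdna_alt, av$cdna_ref)
})

test_that("variant normalization trims, anchors and left-aligns", {
  g <- reference_genome(c(c = "GGAACCCCGGTT"))
  # shared prefix/suffix trimmed down to the changed base
  v <- normalized_variant("c", 2L, "AAC", "AGC", g)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "A"); expect_equal(v$alt, "G")
  # deletion in the C-run left-aligns to the run start (anchor kept)
  v <- normalized_variant("c", 6L, "CC", "C", g)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "AC"); expect_equal(v$alt, "A")
  # insertion in the same run also left-aligns
  v <- normalized_variant("c", 7L, "C", "CC", g)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "A"); expect_equal(v$alt, "AC")
})
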