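# Hand-built fixture transcripts with fully known layout, so every
# expected coordinate below is derivable by paper-and-pencil arithmetic.
#
# Sense layout (0-based):
#   [0,30)    5' flank
#   [30,63)   exon 1 = 12 bp 5'UTR ("TTTTTTGCCACC") + 21 bp CDS
#   [63,103)  intron 1 = GTAAGT + C*12 + T*20 + AG (40 bp)
#   [103,127) exon 2 = 24 bp CDS
#   [127,167) intron 2 (as intron 1)
#   [167,212) exon 3 = 15 bp CDS (ends TAA) + 30 bp 3'UTR (one AATAAA)
#   [212,242) 3' flank
# CDS = 60 bp = 20 codons; protein MEAKLDWSRAIVKELARKG*

fixture_codons <- c("ATG", "GAA", "GCT", "AAA", "CTG", "GAT", "TGG",
                    "TCT", "CGT", "GCA", "ATC", "GTG", "AAA", "GAA",
                    "CTG", "GCT", "CGT", "AAA", "GGT", "TAA")
fixture_protein <- "MEAKLDWSRAIVKELARKG*"

fixture_sense <- function() {
  flank <- "GATTACAGATTACAGATTACAGATTACAGA"  # 30 bp
  utr5 <- "TTTTTTGCCACC"                     # 12 bp, strong Kozak tail
  cds <- paste(fixture_codons, collapse = "")
  utr3 <- paste0(strrep("C", 8), "AATAAA", strrep("C", 16))
  intron <- paste0("GTAAGT", strrep("C", 12), strrep("T", 20), "AG")
  stopifnot(nchar(intron) == 40L, nchar(cds) == 60L)
  paste0(flank,
         utr5, substr(cds, 1, 21),
         intron,
         substr(cds, 22, 45),
         intron,
         substr(cds, 46, 60), utr3,
         flank)
}

fixture_tx <- function(strand = "+") {
  sense <- fixture_sense()
  ex_sense <- cbind(c(30L, 103L, 167L), c(63L, 127L, 212L))
  cds_s <- 42L; cds_e <- 182L
  if (strand == "+") {
    genome <- reference_genome(c(c1 = sense))
    tx <- transcript("txA", "geneA", "c1", "+", ex_sense, cds_s, cds_e,
                     pli = 0.9)
  } else {
    L <- nchar(sense)
    genome <- reference_genome(c(c2 = revcomp(sense)))
    ex <- cbind(L - ex_sense[, 2], L - ex_sense[, 1])
    tx <- transcript("txB", "geneB", "c2", "-", ex, L - cds_e, L - cds_s,
                     pli = 0.1)
  }
  list(genome = genome, tx = tx,
       layout = list(utr5_len = 12L, cds_len = 60L, utr3_len = 30L,
                     n_exons = 3L))
}

# expected region of every sense-layout mRNA index, independent of the
# package's coordinate code: pure layout arithmetic
fixture_region_of_cdna <- function(cpos) {
  if (cpos < 12L) "utr5" else if (cpos < 72L) "cds" else "utr3"
}

# consensus-trained toy splice models shared across test files
fixture_splice_models <- function() {
  dm <- train_splice_model(make_splice_training_windows(200, "donor", 101),
                           constraint_order = 2, site_type = "donor")
  am <- train_splice_model(make_splice_training_windows(200, "acceptor", 102),
                           constraint_order = 2, site_type = "acceptor")
  list(donor = dm, acceptor = am)
}

# Independent routing oracle: decides the model class from raw
# apply_variant string output and per-base map_genomic tags, re-deriving
# the precedence rules rather than reusing classify_variant's flags.
route_oracle <- function(v, tx, genome) {
  av <- apply_variant(tx, v, genome)
  p_ref <- av$protein_ref; p_alt <- av$protein_alt
  if (p_ref != p_alt || av$start_loss) {
    same_len <- nchar(p_ref) == nchar(p_alt)
    nsub <- if (same_len) {
      a <- strsplit(p_ref, "")[[1]]; b <- strsplit(p_alt, "")[[1]]
      sum(a != b)
    } else Inf
    if (same_len && nsub == 1L && !av$start_loss) return("simple_aae")
    return("complex_aae")
  }
  iv <- c(v$pos, v$pos + nchar(v$ref))
  regions <- unique(vapply(seq.int(iv[1], iv[2] - 1L), function(p)
    map_genomic(tx, p)$region, character(1)))
  if ("utr5" %in% regions) return("utr5")
  if ("utr3" %in% regions) return("utr3")
  "without_aae"
}

# enumerate all SNVs and 1-3 bp indels across a transcript span
enumerate_variants <- function(tx, genome) {
  seq <- genome$contigs[[tx$contig]]
  out <- list()
  span <- seq.int(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2] - 4L)
  for (p in span) {
    ref1 <- substr(seq, p + 1L, p + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref1))
      out[[length(out) + 1L]] <- list(pos = p, ref = ref1, alt = alt)
    if (p >= 1L) {
      anchor <- substr(seq, p, p)
      for (len in 1:3) {  # deletions
        ref <- substr(seq, p, p + len)
        out[[length(out) + 1L]] <- list(pos = p - 1L, ref = ref, alt = anchor)
      }
      for (ins in c("A", "AC", "ACG")) {  # insertions
        out[[length(out) + 1L]] <-
          list(pos = p - 1L, ref = anchor, alt = paste0(anchor, ins))
      }
    }
  }
  out
}

overlaps_tx <- function(v, tx) {
  v$pos < tx$exons[nrow(tx$exons), 2] && (v$pos + nchar(v$ref)) > tx$exons[1, 1]
}

strip_run_attrs <- function(df) {
  attributes(df)[setdiff(names(attributes(df)),
                         c("names", "row.names", "class"))] <- NULL
  df
}
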