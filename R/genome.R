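#' Reference genome container
#'
#' A minimal in-memory reference: named uppercase contig sequences. All
#' coordinates in the package are 0-based, half-open; conversion from
#' 1-based formats (GTF, VCF, resource tables) happens at the parser
#' boundary.
#'
#' @param contigs named character vector, one DNA sequence per contig.
#' @return an object of class `ReferenceGenome`.
#' @export
reference_genome <- function(contigs) {
  if (length(contigs) == 0L) stop("reference genome has no contigs")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("all contigs must be named")
  if (anyDuplicated(names(contigs)))
    stop("duplicate contig name: ",
         paste(unique(names(contigs)[duplicated(names(contigs))]), collapse = ", "))
  contigs <- toupper(chartr("Uu", "Tt", contigs))
  if (any(nchar(contigs) == 0L)) stop("contig with empty sequence")
  structure(list(contigs = contigs), class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp total\n")
  invisible(x)
}

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased and U is converted to T. Duplicate record
#' names and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @return a [reference_genome()] object.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  reference_genome(setNames(as.character(seqs), nm))
}

contig_seq <- function(genome, contig) {
  s <- genome$contigs[[contig]]
  if (is.null(s)) stop("unknown contig: ", contig)
  s
}

#' Transcript model
#'
#' Exon/CDS structure of one transcript on a reference contig. Exons are
#' 0-based half-open genomic intervals sorted by genomic position and
#' must not overlap; `cds_start`/`cds_end` are the genomic bounds
#' (leftmost base, one past rightmost base) of the coding region and must
#' fall inside the exon union. A spliced CDS length not divisible by 3 is
#' flagged (`cds_incomplete`) with a warning, not an error, and trailing
#' bases are ignored at translation. UTRs are always derived, never
#' stored.
#'
#' @param id,gene transcript and gene identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), 0-based half-open.
#' @param cds_start,cds_end genomic CDS bounds, 0-based half-open.
#' @param pli optional per-gene loss-of-function intolerance score in
#'   \[0,1\]; carried as display-only annotation.
#' @return an object of class `Transcript`.
#' @export
transcript <- function(id, gene, contig, strand, exons, cds_start, cds_end,
                       pli = NA_real_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) stop("empty exon in transcript ", id)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in transcript ", id)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end <= cds_start) stop("empty CDS in transcript ", id)
  if (!.pos_in_exons(exons, cds_start) || !.pos_in_exons(exons, cds_end - 1L))
    stop("CDS bounds outside exons in transcript ", id)
  if (!is.na(pli) && (pli < 0 || pli > 1)) stop("pli must lie in [0,1]")
  tx <- structure(list(
    id = id, gene = gene, contig = contig, strand = strand,
    exons = exons, cds_start = cds_start, cds_end = cds_end, pli = pli),
    class = "Transcript")
  cl <- cds_length(tx)
  tx$cds_incomplete <- (cl %% 3L) != 0L
  if (tx$cds_incomplete)
    warning("CDS length of ", id, " (", cl, ") not divisible by 3; ",
            "trailing bases ignored at translation")
  tx
}

.pos_in_exons <- function(exons, p) {
  any(p >= exons[, 1L] & p < exons[, 2L])
}

#' @export
print.Transcript <- function(x, ...) {
  cat(sprintf("Transcript %s (%s) %s:%s %d exon(s), CDS [%d,%d)\n",
              x$id, x$gene, x$contig, x$strand, nrow(x$exons),
              x$cds_start, x$cds_end))
  invisible(x)
}

tx_start <- function(tx) tx$exons[1L, 1L]
tx_end <- function(tx) tx$exons[nrow(tx$exons), 2L]

exon_lengths <- function(tx) tx$exons[, 2L] - tx$exons[, 1L]

#' Spliced transcript length in bases
#' @param tx a [transcript()].
#' @return integer mRNA length.
#' @export
cdna_length <- function(tx) sum(exon_lengths(tx))

# spliced CDS length (genomic CDS interval intersected with exons)
cds_length <- function(tx) {
  s <- pmax(tx$exons[, 1L], tx$cds_start)
  e <- pmin(tx$exons[, 2L], tx$cds_end)
  sum(pmax(0L, e - s))
}

# cDNA index (0-based, transcript orientation) of the first CDS base
utr5_length <- function(tx) {
  g0 <- if (tx$strand == "+") tx$cds_start else tx$cds_end - 1L
  genomic_to_cdna(tx, g0)
}

utr3_length <- function(tx) cdna_length(tx) - utr5_length(tx) - cds_length(tx)

#' Map a genomic position to a spliced-transcript coordinate
#'
#' @param tx a [transcript()].
#' @param gpos 0-based genomic position.
#' @return 0-based index along the mRNA (5' to 3' in transcript
#'   orientation), or `NA` for non-exonic positions.
#' @export
genomic_to_cdna <- function(tx, gpos) {
  ex <- tx$exons
  i <- which(gpos >= ex[, 1L] & gpos < ex[, 2L])
  if (length(i) == 0L) return(NA_integer_)
  plus_idx <- sum(exon_lengths(tx)[seq_len(i - 1L)]) + (gpos - ex[i, 1L])
  if (tx$strand == "+") as.integer(plus_idx)
  else as.integer(cdna_length(tx) - 1L - plus_idx)
}

#' Map a spliced-transcript coordinate back to the genome
#'
#' Inverse of [genomic_to_cdna()].
#'
#' @param tx a [transcript()].
#' @param cpos 0-based mRNA index.
#' @return 0-based genomic position.
#' @export
cdna_to_genomic <- function(tx, cpos) {
  n <- cdna_length(tx)
  if (cpos < 0L || cpos >= n) stop("cDNA index out of range")
  plus_idx <- if (tx$strand == "+") cpos else n - 1L - cpos
  lens <- exon_lengths(tx)
  cum <- cumsum(lens)
  i <- which(plus_idx < cum)[1L]
  off <- plus_idx - (if (i > 1L) cum[i - 1L] else 0L)
  as.integer(tx$exons[i, 1L] + off)
}

# exon sequences on the genomic (plus) strand, in genomic order
.exon_seqs <- function(seq, exons) {
  substring(seq, exons[, 1L] + 1L, exons[, 2L])
}

#' Spliced mRNA sequence of a transcript
#'
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @return character mRNA sequence in transcript orientation.
#' @export
spliced_seq <- function(tx, genome) {
  spliced_from(contig_seq(genome, tx$contig), tx$exons, tx$strand)
}

spliced_from <- function(seq, exons, strand) {
  s <- paste(.exon_seqs(seq, exons), collapse = "")
  if (strand == "+") s else revcomp(s)
}

#' Coding sequence and protein of a transcript
#'
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @return list with `cds` (spliced coding sequence) and `protein`
#'   (translation, stop rendered `*`).
#' @export
transcript_protein <- function(tx, genome) {
  cdna <- spliced_seq(tx, genome)
  u <- utr5_length(tx)
  cds <- substr(cdna, u + 1L, u + cds_length(tx))
  list(cds = cds, protein = translate_cds(cds))
}

#' Load transcript models from a GTF-style annotation
#'
#' Reads `exon` and `CDS` features (via `rtracklayer`), groups them by
#' `transcript_id`, and builds [transcript()] objects. All referenced
#' contigs must exist in `genome`; CDS records must fall inside the
#' transcript's exons.
#'
#' @param path GTF/GFF annotation with exon and CDS records carrying
#'   `transcript_id` and `gene_id` attributes.
#' @param genome a [reference_genome()].
#' @param pli_table optional data.frame (gene, pli) attaching per-gene
#'   loss-of-function intolerance scores (annotation only).
#' @return named list of `Transcript` objects.
#' @export
load_transcripts <- function(path, genome, pli_table = NULL) {
  if (!file.exists(path)) stop("annotation not found: ", path)
  gr <- rtracklayer::import(path)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) stop("no exon/CDS records in ", path)
  bad <- setdiff(unique(df$contig), names(genome$contigs))
  if (length(bad)) stop("annotation references unknown contig(s): ",
                        paste(bad, collapse = ", "))
  out <- list()
  for (id in unique(df$transcript_id)) {
    rec <- df[df$transcript_id == id, , drop = FALSE]
    ex <- rec[rec$type == "exon", , drop = FALSE]
    cds <- rec[rec$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) stop("transcript ", id, " has no exon records")
    if (nrow(cds) == 0L) stop("transcript ", id, " has no CDS records")
    gene <- ex$gene_id[1L]
    pli <- NA_real_
    if (!is.null(pli_table)) {
      hit <- match(gene, pli_table$gene)
      if (!is.na(hit)) pli <- as.numeric(pli_table$pli[hit])
    }
    out[[id]] <- transcript(
      id = id, gene = gene, contig = ex$contig[1L], strand = ex$strand[1L],
      exons = cbind(ex$start, ex$end),
      cds_start = min(cds$start), cds_end = max(cds$end), pli = pli)
  }
  out
}

#' Load a per-gene pLI table
#'
#' Tab-separated with header columns `gene` and `pli`. Scores are carried
#' into transcript models for display only; they never enter a feature
#' vector.
#'
#' @param path TSV path.
#' @return data.frame with columns gene, pli.
#' @export
load_pli_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pli") %in% names(df)))
    stop("pLI table needs columns gene, pli")
  df
}
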