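#' Normalized variant
#'
#' Canonical variant identity: 0-based position, shared leading/trailing
#' bases trimmed (a single anchor base is kept for pure insertions and
#' deletions), left-aligned in repeat context. This identity is the key
#' for the prediction cache and all resource-table lookups.
#'
#' @param contig contig name.
#' @param pos 0-based position of the first ref base.
#' @param ref,alt reference and alternate alleles (A/C/G/T/N).
#' @param genome optional [reference_genome()]; when supplied the ref
#'   allele is checked against the reference and the variant is
#'   normalized (trim + left-align) before construction.
#' @return object of class `NormalizedVariant`.
#' @export
normalized_variant <- function(contig, pos, ref, alt, genome = NULL) {
  contig <- unname(as.character(contig))
  ref <- unname(toupper(as.character(ref)))
  alt <- unname(toupper(as.character(alt)))
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt))
    stop("alleles must be non-empty A/C/G/T/N strings")
  if (ref == alt) stop("ref and alt are identical")
  pos <- unname(as.integer(pos))
  if (pos < 0L) stop("negative position")
  if (!is.null(genome)) {
    seq <- contig_seq(genome, contig)
    if (substr(seq, pos + 1L, pos + nchar(ref)) != ref)
      stop("ref allele mismatch at ", contig, ":", pos,
           " (reference has ",
           substr(seq, pos + 1L, pos + nchar(ref)), ", variant says ", ref, ")")
    n <- .normalize_alleles(seq, pos, ref, alt)
    pos <- n$pos; ref <- n$ref; alt <- n$alt
  }
  structure(list(contig = contig, pos = pos, ref = ref, alt = alt),
            class = "NormalizedVariant")
}

#' @export
print.NormalizedVariant <- function(x, ...) {
  cat(sprintf("%s:%d %s>%s\n", x$contig, x$pos, x$ref, x$alt))
  invisible(x)
}

#' Stable string key of a variant identity
#' @param v a `NormalizedVariant` (or contig/pos/ref/alt fields).
#' @return character key `contig:pos:ref:alt` (0-based pos).
#' @export
variant_key <- function(v) sprintf("%s:%d:%s:%s", v$contig, v$pos, v$ref, v$alt)

# Trim shared bases and left-align against the reference sequence
# (standard VCF normalization; seq is the full contig, pos 0-based).
.normalize_alleles <- function(seq, pos, ref, alt) {
  repeat {
    changed <- FALSE
    # drop common trailing base while both alleles keep >=1 base
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
    }
    # left-align: indel whose alleles end with the same base slides left
    if (nchar(ref) != nchar(alt) && pos > 0L &&
        substr(ref, nchar(ref), nchar(ref)) ==
        substr(alt, nchar(alt), nchar(alt))) {
      prev <- substr(seq, pos, pos)
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # drop common leading bases, keeping an anchor base for indels
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# genomic interval of reference bases the variant replaces
variant_interval <- function(v) c(v$pos, v$pos + nchar(v$ref))

# Monotone map from original to mutated contig coordinates: positions in
# the replaced span clamp into the replacement allele.
.coord_map <- function(v) {
  vpos <- v$pos; rl <- nchar(v$ref); al <- nchar(v$alt)
  delta <- al - rl
  function(p) {
    ifelse(p < vpos, p,
           ifelse(p >= vpos + rl, p + delta,
                  vpos + pmin(p - vpos, al)))
  }
}

mutate_contig <- function(seq, v) {
  if (substr(seq, v$pos + 1L, v$pos + nchar(v$ref)) != v$ref)
    stop("ref allele mismatch at ", v$contig, ":", v$pos)
  paste0(substr(seq, 1L, v$pos), v$alt,
         substr(seq, v$pos + nchar(v$ref) + 1L, nchar(seq)))
}

#' Apply a variant to a transcript in silico
#'
#' Mutates the contig, re-extracts the spliced mRNA with shifted exon
#' boundaries, translates from the (mapped) annotated start codon, and
#' summarizes the protein-level consequence. Translation of the mutated
#' coding sequence runs to the first stop codon, so premature stops and
#' stop-loss read-through are both captured.
#'
#' @param tx a [transcript()].
#' @param variant a [normalized_variant()] overlapping the transcript span.
#' @param genome a [reference_genome()].
#' @return list with reference and mutated cDNA/protein plus a change
#'   summary: `n_aa_sub` (positional substitutions over the aligned
#'   prefix), `frameshift`, `premature_stop`, `start_loss`, `stop_loss`,
#'   `aa_length_change`, `length_change` (alt minus ref allele length),
#'   `cds_overlap`, `protein_change`, and the mutated 5'UTR length
#'   `mut_utr5`.
#' @export
apply_variant <- function(tx, variant, genome) {
  if (variant$contig != tx$contig)
    stop("variant on ", variant$contig, " but transcript on ", tx$contig)
  seq <- contig_seq(genome, tx$contig)
  mut <- mutate_contig(seq, variant)
  f <- .coord_map(variant)
  mut_exons <- cbind(f(tx$exons[, 1L]), f(tx$exons[, 2L]))
  keep <- mut_exons[, 2L] > mut_exons[, 1L]
  mut_exons <- mut_exons[keep, , drop = FALSE]

  cdna_ref <- spliced_from(seq, tx$exons, tx$strand)
  cdna_alt <- if (nrow(mut_exons))
    spliced_from(mut, mut_exons, tx$strand) else ""

  u <- utr5_length(tx)
  cl <- cds_length(tx)
  cds_ref <- substr(cdna_ref, u + 1L, u + cl)
  p_ref <- translate_cds(cds_ref)

  # translation start in the mutated mRNA: the annotated start base
  # mapped through the edit (clamped if deleted)
  g0 <- if (tx$strand == "+") tx$cds_start else tx$cds_end - 1L
  g0m <- f(g0)
  mu <- .cdna_index(mut_exons, tx$strand, g0m)
  if (is.na(mu)) mu <- u  # start base spliced out entirely; keep frame anchor
  cds_alt_region <- substr(cdna_alt, mu + 1L, nchar(cdna_alt))
  p_alt <- translate_cds(cds_alt_region)

  iv <- variant_interval(variant)
  cds_ex_s <- pmax(tx$exons[, 1L], tx$cds_start)
  cds_ex_e <- pmin(tx$exons[, 2L], tx$cds_end)
  cds_overlap <- any(cds_ex_e > cds_ex_s &
                     iv[1L] < cds_ex_e & iv[2L] > cds_ex_s)

  n_r <- nchar(p_ref); n_m <- nchar(p_alt)
  ncmp <- min(n_r, n_m)
  n_sub <- if (ncmp > 0L) {
    a <- strsplit(substr(p_ref, 1L, ncmp), "")[[1L]]
    b <- strsplit(substr(p_alt, 1L, ncmp), "")[[1L]]
    sum(a != b)
  } else 0L
  delta <- nchar(variant$alt) - nchar(variant$ref)
  start_loss <- substr(cds_ref, 1L, 3L) == "ATG" &&
    substr(cds_alt_region, 1L, 3L) != "ATG"
  ends_stop <- function(p) nchar(p) > 0L && substr(p, nchar(p), nchar(p)) == "*"
  premature_stop <- ends_stop(p_alt) && n_m < n_r
  stop_loss <- ends_stop(p_ref) && (!ends_stop(p_alt) || n_m > n_r)
  frameshift <- cds_overlap && delta != 0L && (delta %% 3L) != 0L

  list(cdna_ref = cdna_ref, cdna_alt = cdna_alt,
       protein_ref = p_ref, protein_alt = p_alt,
       n_aa_sub = n_sub, frameshift = frameshift,
       premature_stop = premature_stop, start_loss = start_loss,
       stop_loss = stop_loss, aa_length_change = n_m - n_r,
       length_change = delta, cds_overlap = cds_overlap,
       protein_change = (n_sub > 0L || n_m != n_r || start_loss),
       mut_utr5 = mu)
}

# cDNA index of a genomic position under an arbitrary exon matrix
.cdna_index <- function(exons, strand, gpos) {
  lens <- exons[, 2L] - exons[, 1L]
  i <- which(gpos >= exons[, 1L] & gpos < exons[, 2L])
  if (length(i) == 0L) return(NA_integer_)
  plus_idx <- sum(lens[seq_len(i - 1L)]) + (gpos - exons[i, 1L])
  if (strand == "+") as.integer(plus_idx)
  else as.integer(sum(lens) - 1L - plus_idx)
}
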