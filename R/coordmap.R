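#' Map a genomic position onto transcript regions
#'
#' Assigns exactly one region tag to any genomic position on the
#' transcript's contig: `utr5`, `cds`, `utr3`, `intron`, `upstream` or
#' `downstream` (the last two strand-aware, relative to transcript
#' orientation). Exonic offsets are 0-based within the region along the
#' spliced mRNA; `cds` offsets are 0-based within the spliced CDS.
#' Intronic positions report the distance (in bases, first intronic base
#' = 1) to the nearest exon boundary and which side it is (`donor` = the
#' exon that donates the intron 5' end, `acceptor` = the 3' end); the
#' exact midpoint of an even-length intron resolves to the donor side.
#'
#' @param tx a [transcript()].
#' @param gpos 0-based genomic position on the transcript's contig.
#' @return list with `region`, `offset` (exonic regions), and for introns
#'   `distance` and `side`.
#' @export
map_genomic <- function(tx, gpos) {
  gpos <- as.integer(gpos)
  s <- tx_start(tx); e <- tx_end(tx)
  if (gpos < s) {
    tag <- if (tx$strand == "+") "upstream" else "downstream"
    return(list(region = tag, offset = s - gpos))
  }
  if (gpos >= e) {
    tag <- if (tx$strand == "+") "downstream" else "upstream"
    return(list(region = tag, offset = gpos - e + 1L))
  }
  c0 <- genomic_to_cdna(tx, gpos)
  if (!is.na(c0)) {
    u <- utr5_length(tx); cl <- cds_length(tx)
    if (c0 < u) return(list(region = "utr5", offset = c0))
    if (c0 < u + cl) return(list(region = "cds", offset = c0 - u))
    return(list(region = "utr3", offset = c0 - u - cl))
  }
  # intronic: locate flanking exons
  ex <- tx$exons
  i <- max(which(ex[, 2L] <= gpos))   # exon to the genomic left
  d_left <- gpos - ex[i, 2L] + 1L     # distance into intron from left exon
  d_right <- ex[i + 1L, 1L] - gpos    # distance to right exon start
  if (tx$strand == "+") {
    donor_d <- d_left; acceptor_d <- d_right
  } else {
    donor_d <- d_right; acceptor_d <- d_left
  }
  side <- if (donor_d <= acceptor_d) "donor" else "acceptor"
  list(region = "intron", offset = min(donor_d, acceptor_d),
       distance = min(donor_d, acceptor_d), side = side,
       intron_index = if (tx$strand == "+") i else nrow(ex) - i)
}

#' Map a region-relative offset back to the genome
#'
#' Inverse of [map_genomic()] for the exonic regions.
#'
#' @param tx a [transcript()].
#' @param region one of `"utr5"`, `"cds"`, `"utr3"`.
#' @param offset 0-based offset within the region.
#' @return 0-based genomic position.
#' @export
region_to_genomic <- function(tx, region, offset) {
  u <- utr5_length(tx); cl <- cds_length(tx)
  cpos <- switch(region,
    utr5 = offset,
    cds = u + offset,
    utr3 = u + cl + offset,
    stop("region must be utr5, cds or utr3"))
  cdna_to_genomic(tx, cpos)
}
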