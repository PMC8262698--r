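# UTR-specific sequence checks. Both are deliberately simple, documented
# stand-ins for the tasks they name: the Kozak check is a consensus
# position-match count (not a PWM), and the polyadenylation check counts
# canonical signal hexamers rather than re-implementing a discriminant.

# Kozak consensus gccRccATGG over positions -6..+4 (A of ATG = +1).
.KOZAK <- strsplit("GCCRCCATGG", "")[[1L]]

.kozak_score <- function(window) {
  if (is.na(window) || nchar(window) != 10L) return(NA_integer_)
  b <- strsplit(toupper(window), "")[[1L]]
  sum(ifelse(.KOZAK == "R", b %in% c("A", "G"), b == .KOZAK))
}

#' Kozak-context change at the translation start
#'
#' Scores the 10-base start context (consensus `gccRccATGG`, positions
#' -6..+4 around the A of the start codon, R = A or G) in the reference
#' and mutated mRNA. The score is the number of consensus-matching
#' positions (0-10). Intended for variants routed to the 5' UTR; a
#' variant destroying the ATG itself is an amino-acid-affecting change
#' and is routed to `complex_aae` upstream of this check.
#'
#' @param variant a [normalized_variant()].
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @return list of class `KozakChange`: `ref_score`, `alt_score`,
#'   `changed`, `ref_window`, `alt_window`. Transcripts whose start
#'   context is not fully within the mRNA yield `NA` scores and
#'   `changed = NA` (no-score sentinel).
#' @export
kozak_change <- function(variant, tx, genome) {
  cons <- apply_variant(tx, variant, genome)
  u <- utr5_length(tx)
  ref_w <- .context10(cons$cdna_ref, u)
  alt_w <- .context10(cons$cdna_alt, cons$mut_utr5)
  rs <- .kozak_score(ref_w); as_ <- .kozak_score(alt_w)
  changed <- if (is.na(rs) || is.na(as_)) NA else !identical(ref_w, alt_w)
  structure(list(ref_score = rs, alt_score = as_, changed = changed,
                 ref_window = ref_w, alt_window = alt_w),
            class = "KozakChange")
}

# 10-base window -6..+4 around the start base at 0-based mRNA index u
.context10 <- function(cdna, u) {
  if (is.na(u) || u < 6L || nchar(cdna) < u + 4L) return(NA_character_)
  substr(cdna, u - 5L, u + 4L)
}

#' Polyadenylation-signal change in the 3' UTR
#'
#' Counts occurrences of the canonical polyadenylation signal hexamers
#' (default AATAAA and ATTAAA, counted with overlap) in the reference
#' versus mutated 3' UTR sequence. Status is `disrupted` when the mutated
#' UTR has fewer hits, `created` when it has more, `unchanged` otherwise.
#' Intended for variants routed to the 3' UTR.
#'
#' @param variant a [normalized_variant()].
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @param hexamers signal hexamer set.
#' @return list of class `PolyASignalChange`: `ref_hits`, `alt_hits`,
#'   `status`.
#' @export
polya_signal_change <- function(variant, tx, genome,
                                hexamers = c("AATAAA", "ATTAAA")) {
  cons <- apply_variant(tx, variant, genome)
  u <- utr5_length(tx); cl <- cds_length(tx)
  ref_utr3 <- substr(cons$cdna_ref, u + cl + 1L, nchar(cons$cdna_ref))
  alt_utr3 <- substr(cons$cdna_alt, cons$mut_utr5 + cl + 1L,
                     nchar(cons$cdna_alt))
  ref_hits <- .count_hexamers(ref_utr3, hexamers)
  alt_hits <- .count_hexamers(alt_utr3, hexamers)
  status <- if (alt_hits < ref_hits) "disrupted"
            else if (alt_hits > ref_hits) "created" else "unchanged"
  structure(list(ref_hits = ref_hits, alt_hits = alt_hits, status = status),
            class = "PolyASignalChange")
}

.count_hexamers <- function(seq, hexamers) {
  if (!nzchar(seq)) return(0L)
  sum(vapply(hexamers, function(h) {
    m <- gregexpr(paste0("(?=", h, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1)))
}
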