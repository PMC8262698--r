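#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict rnorm runif setNames aggregate quantile
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' Plain-character helper used throughout the coordinate code where
#' constructing `DNAString` objects per call would dominate run time.
#'
#' @param x character scalar over A/C/G/T/N.
#' @return reverse complement, same case.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Standard genetic code keyed by codon; stops rendered '*'.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  g <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                   stringsAsFactors = FALSE)  # third base varies fastest
  codons <- paste0(g$b1, g$b2, g$b3)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

#' Translate a coding DNA sequence
#'
#' Lookup-table translation with the standard genetic code. Translation
#' stops after the first stop codon (rendered `*`); a trailing partial
#' codon is dropped. Codons containing N translate to `X`.
#'
#' @param cds character scalar, coding sequence starting at the first codon.
#' @param stop_at_stop stop translating after the first stop codon
#'   (default `TRUE`).
#' @return amino-acid string (may end in `*`).
#' @export
translate_cds <- function(cds, stop_at_stop = TRUE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- unname(.codon_table[toupper(codons)])
  aa[is.na(aa)] <- "X"
  if (stop_at_stop) {
    s <- which(aa == "*")
    if (length(s)) aa <- aa[seq_len(s[1L])]
  }
  paste(aa, collapse = "")
}

random_dna <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
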