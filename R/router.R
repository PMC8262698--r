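#' The five prediction model classes
#'
#' Intragenic variants are routed to exactly one of five dedicated
#' prediction models: `simple_aae` (a single amino-acid substitution),
#' `complex_aae` (any larger protein change: two or more substitutions,
#' in-frame or frameshifting indels, premature stop, start or stop loss),
#' `utr5`, `utr3`, and `without_aae` (all other intragenic variants,
#' including synonymous and intronic ones).
#'
#' @return character vector of the five class names.
#' @export
model_classes <- function() {
  c("simple_aae", "complex_aae", "utr5", "utr3", "without_aae")
}

#' Route a variant on a transcript to its prediction class
#'
#' Precedence for region-spanning variants: any amino-acid-affecting
#' consequence outranks the UTR classes, which outrank `without_aae`.
#' Exactly one amino-acid substitution routes to `simple_aae`; anything
#' more (>=2 substitutions, protein length change, frameshift, premature
#' stop, start or stop loss) routes to `complex_aae`. Canonical
#' splice-site variants that leave the protein unchanged route to
#' `without_aae`; their splice-score change lives in the feature vector,
#' not in the class.
#'
#' @param variant a [normalized_variant()].
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @return list with `model_class`, the [apply_variant()] `consequence`,
#'   and the set of `regions` the variant touches.
#' @export
classify_variant <- function(variant, tx, genome) {
  iv <- variant_interval(variant)
  if (variant$contig != tx$contig || iv[2L] <= tx_start(tx) ||
      iv[1L] >= tx_end(tx))
    stop("variant ", variant_key(variant),
         " lies entirely outside transcript ", tx$id)
  cons <- apply_variant(tx, variant, genome)
  regions <- unique(vapply(seq.int(iv[1L], iv[2L] - 1L), function(p) {
    map_genomic(tx, p)$region
  }, character(1)))
  cls <- if (cons$protein_change) {
    if (cons$frameshift || cons$premature_stop || cons$start_loss ||
        cons$stop_loss || cons$aa_length_change != 0L || cons$n_aa_sub >= 2L)
      "complex_aae"
    else "simple_aae"
  } else if ("utr5" %in% regions) {
    "utr5"
  } else if ("utr3" %in% regions) {
    "utr3"
  } else {
    "without_aae"
  }
  list(model_class = cls, consequence = cons, regions = regions)
}

#' Cap a genotype count for storage
#'
#' Heterozygous and homozygous genotype counts from population resources
#' are stored capped at 32 000: that many healthy carriers already
#' indicates a benign allele, and exact larger counts add nothing.
#'
#' @param count non-negative integer vector.
#' @return `pmin(count, 32000)`.
#' @export
cap_genotype_count <- function(count) {
  if (any(is.na(count)) || any(count < 0)) stop("negative genotype count")
  pmin(as.integer(count), 32000L)
}

#' Read a genotype-frequency table
#'
#' Tab-separated with header columns contig, pos (1-based), ref, alt,
#' source, het_count, hom_count. Counts are capped at 32 000 on load;
#' positions convert to 0-based internally.
#'
#' @param path TSV path.
#' @return data.frame keyed by variant identity (`key` column added).
#' @export
load_frequency_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "source", "het_count", "hom_count")
  if (!all(need %in% names(df)))
    stop("frequency table needs columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos) - 1L
  df$het_count <- cap_genotype_count(df$het_count)
  df$hom_count <- cap_genotype_count(df$hom_count)
  df$key <- sprintf("%s:%d:%s:%s", df$contig, df$pos, df$ref, df$alt)
  df
}

#' Read a clinical-assertion table
#'
#' Tab-separated with header columns contig, pos (1-based), ref, alt,
#' significance (pathogenic | likely_pathogenic | benign | conflicting |
#' other), disease.
#'
#' @param path TSV path.
#' @return data.frame with a `key` column.
#' @export
load_assertion_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "significance", "disease")
  if (!all(need %in% names(df)))
    stop("assertion table needs columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos) - 1L
  df$key <- sprintf("%s:%d:%s:%s", df$contig, df$pos, df$ref, df$alt)
  df
}

#' Automatic benign/deleterious labelling rules
#'
#' Two rules bypass the classifier entirely: a variant with at least one
#' homozygous carrier in any population source is labelled
#' `benign_automatic`; a variant clearly asserted `pathogenic` is
#' labelled `deleterious_automatic`, with its disease attached for
#' display. A pathogenic assertion takes precedence over homozygous
#' carriers. `likely_pathogenic` and `conflicting` assertions never
#' auto-label (they are still reported). Absent records yield no label.
#'
#' @param variant a [normalized_variant()].
#' @param frequency_table data.frame from [load_frequency_table()] (or
#'   `NULL`).
#' @param assertion_table data.frame from [load_assertion_table()] (or
#'   `NULL`).
#' @return list with `label` (`benign_automatic`, `deleterious_automatic`
#'   or `none`), `reason` (`homozygous_carrier`, `clinvar_pathogenic` or
#'   `none`), `disease` (string or `NA`), and the raw
#'   `clinvar_significance` seen (for display).
#' @export
apply_auto_rules <- function(variant, frequency_table = NULL,
                             assertion_table = NULL) {
  key <- variant_key(variant)
  sig <- NA_character_; disease <- NA_character_
  if (!is.null(assertion_table)) {
    hit <- assertion_table[assertion_table$key == key, , drop = FALSE]
    if (nrow(hit)) {
      sig <- hit$significance[1L]
      disease <- hit$disease[1L]
      if (identical(sig, "pathogenic"))
        return(list(label = "deleterious_automatic",
                    reason = "clinvar_pathogenic", disease = disease,
                    clinvar_significance = sig))
    }
  }
  if (!is.null(frequency_table)) {
    hit <- frequency_table[frequency_table$key == key, , drop = FALSE]
    if (nrow(hit) && any(hit$hom_count >= 1L))
      return(list(label = "benign_automatic", reason = "homozygous_carrier",
                  disease = NA_character_, clinvar_significance = sig))
  }
  list(label = "none", reason = "none", disease = NA_character_,
       clinvar_significance = sig)
}
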