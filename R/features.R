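# Amino-acid exchange properties and per-class feature assembly.

# Grantham's composition, polarity and molecular-volume properties; the
# pairwise distance is the published chemical distance
# D = rho * sqrt(1.833 dc^2 + 0.1018 dp^2 + 0.000399 dv^2), with rho
# fixed so the mean over the 190 pairs is 100.
.aa_props <- data.frame(
  aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
         "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
  stringsAsFactors = FALSE)

.grantham_matrix <- local({
  n <- nrow(.aa_props)
  raw <- matrix(0, n, n, dimnames = list(.aa_props$aa, .aa_props$aa))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    raw[i, j] <- sqrt(1.833 * (.aa_props$c[i] - .aa_props$c[j])^2 +
                      0.1018 * (.aa_props$p[i] - .aa_props$p[j])^2 +
                      0.000399 * (.aa_props$v[i] - .aa_props$v[j])^2)
  }
  rho <- 100 / mean(raw[upper.tri(raw)])
  round(raw * rho)
})

#' Grantham distance between two amino acids
#'
#' Physicochemical substitution-severity distance (composition, polarity,
#' molecular volume), normalized to a mean of 100 over all amino-acid
#' pairs. Identical residues score 0; stops and unknowns return `NA`.
#'
#' @param aa1,aa2 single-letter amino-acid codes.
#' @return numeric distance.
#' @export
grantham_distance <- function(aa1, aa2) {
  if (!(aa1 %in% rownames(.grantham_matrix)) ||
      !(aa2 %in% rownames(.grantham_matrix))) return(NA_real_)
  .grantham_matrix[aa1, aa2]
}

# Kyte-Doolittle hydropathy
.hydropathy <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                 E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                 M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                 Y = -1.3, V = 4.2)

# side-chain charge at physiological pH (His weakly positive)
.aa_charge <- c(D = -1, E = -1, K = 1, R = 1, H = 0.1)

aa_hydropathy <- function(aa) unname(.hydropathy[aa])
aa_charge <- function(aa) {
  v <- unname(.aa_charge[aa])
  v[is.na(v) & aa %in% names(.hydropathy)] <- 0
  v
}

#' Sentinel for missing conservation
#'
#' Feature vectors never encode missing conservation as 0; sites without
#' track coverage carry this sentinel plus the `cons_missing` indicator.
#' @export
CONS_SENTINEL <- -999

#' Per-base conservation track
#'
#' Generic per-base scalar conservation (bedGraph-style, 0-based
#' half-open runs). An expanded per-contig lookup is built once for fast
#' point queries; suitable for the desk-scale genomes this package
#' targets (a bigWig-backed lookup would replace it at genome scale).
#'
#' @param df data.frame with columns contig, start, end, score.
#' @return object of class `ConservationTrack`.
#' @export
conservation_track <- function(df) {
  stopifnot(all(c("contig", "start", "end", "score") %in% names(df)))
  idx <- lapply(split(df, df$contig), function(d) {
    v <- rep(NA_real_, max(d$end))
    for (r in seq_len(nrow(d)))
      v[(d$start[r] + 1L):d$end[r]] <- d$score[r]
    v
  })
  structure(list(df = df, idx = idx), class = "ConservationTrack")
}

#' Load a conservation track from bedGraph
#' @param path bedGraph file (0-based half-open intervals, score column).
#' @return a [conservation_track()].
#' @export
load_conservation <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  conservation_track(data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = gr$score, stringsAsFactors = FALSE))
}

#' Mean conservation over a genomic interval
#' @param track a [conservation_track()] or `NULL`.
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @return mean score, or `NA` when uncovered or `track` is `NULL`.
#' @export
conservation_at <- function(track, contig, start, end) {
  if (is.null(track)) return(NA_real_)
  v <- track$idx[[contig]]
  if (is.null(v) || start + 1L > length(v)) return(NA_real_)
  vals <- v[(start + 1L):min(end, length(v))]
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Feature schema of a model class
#'
#' Fixed, versioned per-class feature lists. Shared block: conservation
#' (with missing indicator), canonical splice-score deltas, splice-window
#' overlap, allele length change. Class-specific blocks add amino-acid
#' exchange properties (`simple_aae`), protein-truncation descriptors
#' (`complex_aae`), the Kozak triple and start distance (`utr5`), the
#' polyA triple and stop distance (`utr3`), or the distance to the
#' nearest exon boundary (`without_aae`). pLI is display-only and never
#' appears here.
#'
#' @param model_class one of [model_classes()].
#' @return character vector of feature names.
#' @export
feature_schema <- function(model_class) {
  shared <- c("cons_score", "cons_missing", "splice_delta_min",
              "splice_delta_absmax", "in_splice_window", "length_change")
  extra <- switch(model_class,
    simple_aae = c("grantham", "hydropathy_change", "charge_change"),
    complex_aae = c("frameshift", "premature_stop", "truncated_fraction"),
    utr5 = c("kozak_ref", "kozak_alt", "kozak_changed", "dist_to_start"),
    utr3 = c("polya_ref_hits", "polya_alt_hits", "polya_status",
             "dist_to_stop"),
    without_aae = "dist_to_exon_boundary",
    stop("unknown model class: ", model_class))
  c(shared, extra)
}

#' Schema version tag
#' @return character version of the feature schema.
#' @export
feature_schema_version <- function() "1"

#' Annotate a variant on a transcript
#'
#' Bundles routing and consequence information for feature extraction
#' and prediction.
#'
#' @param variant a [normalized_variant()].
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @return object of class `AnnotatedVariant`.
#' @export
annotate_variant <- function(variant, tx, genome) {
  r <- classify_variant(variant, tx, genome)
  structure(list(variant = variant, transcript = tx,
                 model_class = r$model_class, consequence = r$consequence,
                 regions = r$regions), class = "AnnotatedVariant")
}

#' Build the per-class feature vector of an annotated variant
#'
#' Deterministic for fixed inputs; the result carries its model class and
#' schema version as attributes and always matches [feature_schema()] of
#' that class. Missing conservation is encoded as [CONS_SENTINEL] with
#' `cons_missing = 1`, never silently 0.
#'
#' @param annotated an [annotate_variant()] result.
#' @param genome a [reference_genome()].
#' @param cons_track a [conservation_track()] or `NULL`.
#' @param donor_model,acceptor_model splice models for
#'   [splice_deltas()].
#' @return named numeric vector.
#' @export
build_features <- function(annotated, genome, cons_track = NULL,
                           donor_model = NULL, acceptor_model = NULL) {
  v <- annotated$variant; tx <- annotated$transcript
  cls <- annotated$model_class; cons <- annotated$consequence
  iv <- variant_interval(v)

  cs <- conservation_at(cons_track, v$contig, iv[1L], iv[2L])
  cons_missing <- as.numeric(is.na(cs))
  if (is.na(cs)) cs <- CONS_SENTINEL

  if (!is.null(donor_model) && !is.null(acceptor_model)) {
    sd_ <- splice_deltas(v, tx, genome, donor_model, acceptor_model)
  } else {
    sd_ <- data.frame(delta = numeric(0))
  }
  d_min <- if (nrow(sd_)) min(sd_$delta) else 0
  d_absmax <- if (nrow(sd_)) max(abs(sd_$delta)) else 0
  in_win <- as.numeric(nrow(sd_) > 0L)

  feats <- c(cons_score = cs, cons_missing = cons_missing,
             splice_delta_min = d_min, splice_delta_absmax = d_absmax,
             in_splice_window = in_win,
             length_change = cons$length_change)

  extra <- switch(cls,
    simple_aae = {
      sub <- .single_substitution(cons)
      c(grantham = grantham_distance(sub[1L], sub[2L]) %||% NA_real_,
        hydropathy_change = aa_hydropathy(sub[2L]) - aa_hydropathy(sub[1L]),
        charge_change = aa_charge(sub[2L]) - aa_charge(sub[1L]))
    },
    complex_aae = {
      n_r <- nchar(cons$protein_ref)
      c(frameshift = as.numeric(cons$frameshift),
        premature_stop = as.numeric(cons$premature_stop),
        truncated_fraction = if (n_r > 0L)
          max(0, (n_r - nchar(cons$protein_alt)) / n_r) else 0)
    },
    utr5 = {
      kz <- kozak_change(v, tx, genome)
      cpos <- .first_exonic_cdna(tx, iv)
      c(kozak_ref = kz$ref_score %||% NA_real_,
        kozak_alt = kz$alt_score %||% NA_real_,
        kozak_changed = as.numeric(isTRUE(kz$changed)),
        dist_to_start = utr5_length(tx) - cpos)
    },
    utr3 = {
      pa <- polya_signal_change(v, tx, genome)
      cpos <- .first_exonic_cdna(tx, iv)
      c(polya_ref_hits = pa$ref_hits, polya_alt_hits = pa$alt_hits,
        polya_status = switch(pa$status, disrupted = -1, unchanged = 0,
                              created = 1),
        dist_to_stop = cpos - (utr5_length(tx) + cds_length(tx)) + 1)
    },
    without_aae = {
      m <- map_genomic(tx, iv[1L])
      c(dist_to_exon_boundary = if (m$region == "intron") m$distance else 0)
    })

  out <- c(feats, extra)
  # integer NAs from scoreless Kozak contexts become the sentinel
  out[is.na(out)] <- CONS_SENTINEL
  stopifnot(identical(names(out), feature_schema(cls)))
  structure(out, model_class = cls,
            schema_version = feature_schema_version())
}

# the single (ref, alt) amino-acid pair of a simple substitution
.single_substitution <- function(cons) {
  a <- strsplit(cons$protein_ref, "")[[1L]]
  b <- strsplit(cons$protein_alt, "")[[1L]]
  n <- min(length(a), length(b))
  i <- which(a[seq_len(n)] != b[seq_len(n)])[1L]
  c(a[i], b[i])
}

# cDNA index of the first affected exonic base (falls back to nearest)
.first_exonic_cdna <- function(tx, iv) {
  for (p in seq.int(iv[1L], iv[2L] - 1L)) {
    c0 <- genomic_to_cdna(tx, p)
    if (!is.na(c0)) return(c0)
  }
  0L
}
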