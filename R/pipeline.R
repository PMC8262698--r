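# End-to-end single-sample VCF analysis and the size-capped batch query.

.BATCH_CAP <- 50L

#' Bundle analysis resources
#'
#' @param genome a [reference_genome()].
#' @param transcripts named list of [transcript()] objects.
#' @param frequency_table,assertion_table resource tables (or `NULL`).
#' @param cons_track a [conservation_track()] (or `NULL`).
#' @param donor_model,acceptor_model splice models (or `NULL`).
#' @param forests named list of [train_forest()] models per model class
#'   (missing classes simply yield no classifier call).
#' @return object of class `AnalysisResources`.
#' @export
analysis_resources <- function(genome, transcripts, frequency_table = NULL,
                               assertion_table = NULL, cons_track = NULL,
                               donor_model = NULL, acceptor_model = NULL,
                               forests = list()) {
  structure(list(genome = genome, transcripts = transcripts,
                 frequency_table = frequency_table,
                 assertion_table = assertion_table,
                 cons_track = cons_track, donor_model = donor_model,
                 acceptor_model = acceptor_model, forests = forests),
            class = "AnalysisResources")
}

# transcripts overlapping a variant interval
.overlapping_transcripts <- function(res, variant) {
  iv <- variant_interval(variant)
  Filter(function(tx) tx$contig == variant$contig &&
           iv[1L] < tx_end(tx) && iv[2L] > tx_start(tx),
         res$transcripts)
}

# one result row per (variant, transcript); pure computation, no cache
.predict_one <- function(variant, tx, res) {
  av <- annotate_variant(variant, tx, res$genome)
  auto <- apply_auto_rules(variant, res$frequency_table, res$assertion_table)
  fv <- build_features(av, res$genome, res$cons_track,
                       res$donor_model, res$acceptor_model)
  label <- auto$label
  votes <- NA_integer_; ntrees <- NA_integer_
  if (label == "none") {
    fm <- res$forests[[av$model_class]]
    if (!is.null(fm)) {
      p <- predict(fm, as.data.frame(t(fv)))
      label <- p$label; votes <- p$votes_deleterious; ntrees <- p$n_trees
    } else {
      label <- "no_model"
    }
  }
  list(contig = variant$contig, pos = variant$pos + 1L,  # 1-based out
       ref = variant$ref, alt = variant$alt,
       transcript = tx$id, gene = tx$gene, model_class = av$model_class,
       label = label, votes_deleterious = votes, n_trees = ntrees,
       auto_reason = auto$reason,
       clinvar_significance = auto$clinvar_significance,
       disease = auto$disease,
       pli = tx$pli,
       splice_delta_min = unname(fv[["splice_delta_min"]]),
       splice_delta_absmax = unname(fv[["splice_delta_absmax"]]),
       cons_score = unname(fv[["cons_score"]]))
}

.result_row_df <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      transcript = character(), gene = character(),
                      model_class = character(), label = character(),
                      votes_deleterious = integer(), n_trees = integer(),
                      auto_reason = character(),
                      clinvar_significance = character(),
                      disease = character(), pli = numeric(),
                      splice_delta_min = numeric(),
                      splice_delta_absmax = numeric(),
                      cons_score = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df[order(df$contig, df$pos, df$ref, df$alt, df$transcript), ,
     drop = FALSE]
}

# cache-aware prediction for a list of NormalizedVariant
.predict_variants <- function(variants, res, cache = NULL,
                              write_cache = TRUE) {
  rows <- list()
  n_calls <- 0L; n_hits <- 0L; n_outside <- 0L
  for (v in variants) {
    txs <- .overlapping_transcripts(res, v)
    if (length(txs) == 0L) { n_outside <- n_outside + 1L; next }
    for (tx in txs) {
      key <- if (!is.null(cache)) cache_key(cache, v, tx$id) else NULL
      hit <- if (!is.null(key)) cache_get(cache, key) else NULL
      if (!is.null(hit)) {
        rows[[length(rows) + 1L]] <- hit
        n_hits <- n_hits + 1L
      } else {
        r <- .predict_one(v, tx, res)
        n_calls <- n_calls + 1L
        if (!is.null(key) && write_cache) cache_put(cache, key, r)
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  df <- .result_row_df(rows)
  rownames(df) <- NULL
  attr(df, "n_model_calls") <- n_calls
  attr(df, "n_cache_hits") <- n_hits
  attr(df, "n_outside_transcripts") <- n_outside
  df
}

#' Analyse a single-sample VCF
#'
#' Parses a VCF (exactly one sample; multi-sample files are rejected),
#' normalizes every variant, routes each onto every overlapping
#' transcript, applies the automatic labelling rules, computes features,
#' and predicts with the per-class forest. The prediction cache is
#' consulted before any computation and populated afterwards, so
#' re-running the same file makes zero classifier calls; warm- and
#' cold-cache outputs are identical. Malformed records are skipped and
#' counted, never fatal.
#'
#' @param vcf_path path to a VCF 4.x file with one genotype column.
#' @param resources an [analysis_resources()] bundle.
#' @param cache optional [prediction_cache()] (read and written).
#' @param store optional [upload_store()]; when given the file's variant
#'   list is registered as an upload and the id returned in the
#'   `upload_id` attribute.
#' @param now upload creation time.
#' @return data.frame, one row per (variant, transcript), ordered by
#'   position; attributes `n_model_calls`, `n_cache_hits`, `n_skipped`,
#'   `n_outside_transcripts`, `upload_id`.
#' @export
run_vcf <- function(vcf_path, resources, cache = NULL, store = NULL,
                    now = Sys.time()) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcf@gt
  n_samples <- if (is.null(gt) || ncol(gt) == 0L) 0L else ncol(gt) - 1L
  if (n_samples != 1L)
    stop("VCF analysis is limited to files containing a single sample (",
         "found ", n_samples, ")")
  fix <- vcfR::getFIX(vcf)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1L,
                                        dimnames = list(NULL, names(fix)))
  variants <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]; pos1 <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- fix[i, "REF"]; alts <- fix[i, "ALT"]
    if (is.na(chrom) || is.na(pos1) || is.na(ref) || is.na(alts) ||
        !grepl("^[ACGTNacgtn]+$", ref)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (alt in strsplit(alts, ",", fixed = TRUE)[[1L]]) {
      if (!grepl("^[ACGTNacgtn]+$", alt) || toupper(alt) == toupper(ref)) {
        n_skipped <- n_skipped + 1L
        next
      }
      v <- tryCatch(
        normalized_variant(chrom, pos1 - 1L, ref, alt, resources$genome),
        error = function(e) NULL)
      if (is.null(v)) { n_skipped <- n_skipped + 1L; next }
      variants[[length(variants) + 1L]] <- v
    }
  }
  df <- .predict_variants(variants, resources, cache, write_cache = TRUE)
  attr(df, "n_skipped") <- n_skipped
  if (!is.null(store)) {
    vl <- if (length(variants))
      data.frame(contig = vapply(variants, `[[`, character(1), "contig"),
                 pos = vapply(variants, `[[`, integer(1), "pos"),
                 ref = vapply(variants, `[[`, character(1), "ref"),
                 alt = vapply(variants, `[[`, character(1), "alt"),
                 stringsAsFactors = FALSE)
      else data.frame()
    attr(df, "upload_id") <- register_upload(store, vl, now = now)
  }
  df
}

#' Uncached batch query
#'
#' Same per-variant output as [run_vcf()] for an in-memory list of
#' variants, capped at 50 per call. The cache is read (a previously
#' computed prediction is reused) but never written: batch results are
#' not persisted.
#'
#' @param variants data.frame with columns contig, pos (1-based), ref,
#'   alt, or a list of [normalized_variant()] objects.
#' @param resources an [analysis_resources()] bundle.
#' @param cache optional [prediction_cache()] (read-only here).
#' @return data.frame as in [run_vcf()].
#' @export
query_batch <- function(variants, resources, cache = NULL) {
  if (is.data.frame(variants)) {
    if (nrow(variants) < 1L) stop("empty variant batch")
    if (nrow(variants) > .BATCH_CAP)
      stop("batch queries are restricted to ", .BATCH_CAP,
           " variants in one call (got ", nrow(variants), ")")
    variants <- lapply(seq_len(nrow(variants)), function(i)
      normalized_variant(variants$contig[i], variants$pos[i] - 1L,
                         variants$ref[i], variants$alt[i],
                         resources$genome))
  } else {
    if (length(variants) < 1L) stop("empty variant batch")
    if (length(variants) > .BATCH_CAP)
      stop("batch queries are restricted to ", .BATCH_CAP,
           " variants in one call (got ", length(variants), ")")
  }
  .predict_variants(variants, resources, cache, write_cache = FALSE)
}

#' Write a results table as TSV
#' @param results data.frame from [run_vcf()] or [query_batch()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
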