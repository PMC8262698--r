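# Training-set construction: population-frequency-driven benign set,
# assertion-driven deleterious set, and symmetric intersection removal.

.keys_of <- function(df) {
  if ("key" %in% names(df)) return(df$key)
  sprintf("%s:%d:%s:%s", df$contig, df$pos, df$ref, df$alt)
}

#' Select benign training variants
#'
#' Keeps exactly the candidate (intragenic) variants with at least one
#' homozygous carrier in any population source of the frequency table.
#'
#' @param candidates data.frame of variant identities (contig, pos
#'   0-based, ref, alt, plus any annotation columns).
#' @param frequency_table data.frame from [load_frequency_table()].
#' @return the retained subset of `candidates` with a `label` column set
#'   to `"benign"`.
#' @export
build_benign_training <- function(candidates, frequency_table) {
  hom_keys <- unique(frequency_table$key[frequency_table$hom_count >= 1L])
  out <- candidates[.keys_of(candidates) %in% hom_keys, , drop = FALSE]
  if (nrow(out)) out$label <- "benign"
  out
}

#' Select deleterious training variants
#'
#' Deleterious cases are the union of disease-mutation (DM) entries and
#' assertions of `pathogenic` or `likely_pathogenic`; identities with a
#' `conflicting` assertion are excluded from the assertion-derived part
#' (a DM entry still stands on its own).
#'
#' @param assertion_table data.frame from [load_assertion_table()].
#' @param dm_table optional data.frame of DM identities (contig, pos
#'   0-based, ref, alt or a `key` column).
#' @return data.frame of deleterious variant identities with a `label`
#'   column.
#' @export
build_deleterious_training <- function(assertion_table, dm_table = NULL) {
  conflicted <- unique(assertion_table$key[
    assertion_table$significance == "conflicting"])
  clin <- assertion_table[
    assertion_table$significance %in% c("pathogenic", "likely_pathogenic") &
    !(assertion_table$key %in% conflicted), , drop = FALSE]
  keys <- clin$key
  rows <- clin[, c("contig", "pos", "ref", "alt", "key"), drop = FALSE]
  if (!is.null(dm_table) && nrow(dm_table)) {
    dmk <- .keys_of(dm_table)
    newk <- !(dmk %in% keys)
    if (any(newk)) {
      dm_rows <- data.frame(contig = dm_table$contig[newk],
                            pos = dm_table$pos[newk],
                            ref = dm_table$ref[newk],
                            alt = dm_table$alt[newk],
                            key = dmk[newk], stringsAsFactors = FALSE)
      rows <- rbind(rows, dm_rows)
    }
  }
  rows <- rows[!duplicated(rows$key), , drop = FALSE]
  if (nrow(rows)) rows$label <- "deleterious"
  rows
}

#' Remove the benign/deleterious intersection from both sets
#'
#' A variant identity present in both training sets is excluded from
#' BOTH; the outputs are disjoint.
#'
#' @param benign_set,deleterious_set data.frames of variant identities.
#' @return list with `benign` and `deleterious` data.frames and the
#'   removed `shared` keys.
#' @export
deduplicate_training <- function(benign_set, deleterious_set) {
  bk <- .keys_of(benign_set); dk <- .keys_of(deleterious_set)
  shared <- intersect(bk, dk)
  list(benign = benign_set[!(bk %in% shared), , drop = FALSE],
       deleterious = deleterious_set[!(dk %in% shared), , drop = FALSE],
       shared = shared)
}

#' Build per-class labelled training matrices
#'
#' Routes every labelled variant on its transcript, builds the
#' class-schema feature vector, and returns one matrix per model class.
#'
#' @param variants data.frame with contig, pos (0-based), ref, alt,
#'   transcript, label columns.
#' @param genome a [reference_genome()].
#' @param transcripts named list of [transcript()] objects.
#' @param cons_track optional [conservation_track()].
#' @param donor_model,acceptor_model optional splice models.
#' @return named list (per model class) of data.frames holding the class
#'   schema columns plus `label`.
#' @export
build_training_matrices <- function(variants, genome, transcripts,
                                    cons_track = NULL, donor_model = NULL,
                                    acceptor_model = NULL) {
  out <- setNames(vector("list", length(model_classes())), model_classes())
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    r <- variants[i, ]
    v <- normalized_variant(r$contig, r$pos, r$ref, r$alt, genome)
    av <- annotate_variant(v, transcripts[[r$transcript]], genome)
    fv <- build_features(av, genome, cons_track, donor_model, acceptor_model)
    list(class = av$model_class, fv = fv, label = r$label)
  })
  for (cls in model_classes()) {
    sel <- Filter(function(x) x$class == cls, rows)
    if (length(sel) == 0L) next
    m <- as.data.frame(do.call(rbind, lapply(sel, `[[`, "fv")))
    m$label <- vapply(sel, `[[`, character(1), "label")
    out[[cls]] <- m
  }
  out
}
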