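# Prediction cache and upload store. Cache records are keyed purely by
# (genome build, variant identity, transcript, model version) and carry
# NO sample, file or upload identifiers: a cached prediction can never
# be traced back to the file it came from.

#' Create a prediction cache
#'
#' @param genome_build build tag included in every key (default
#'   `"GRCh37"`), so caches for different builds/annotations coexist.
#' @param model_version model version tag included in every key.
#' @return object of class `PredictionCache`.
#' @export
prediction_cache <- function(genome_build = "GRCh37", model_version = "1") {
  structure(list(env = new.env(parent = emptyenv()),
                 genome_build = genome_build,
                 model_version = model_version),
            class = "PredictionCache")
}

cache_key <- function(cache, variant, transcript_id) {
  paste(cache$genome_build, variant$contig, variant$pos, variant$ref,
        variant$alt, transcript_id, cache$model_version, sep = "|")
}

cache_get <- function(cache, key) {
  if (is.null(cache)) return(NULL)
  get0(key, envir = cache$env, inherits = FALSE)
}

cache_put <- function(cache, key, value) {
  assign(key, value, envir = cache$env)
  invisible(key)
}

#' Number of cached predictions
#' @param cache a [prediction_cache()].
#' @return integer count.
#' @export
cache_size <- function(cache) length(ls(cache$env))

#' Serialize the cache to a data.frame
#'
#' One row per cached (variant, transcript) prediction; contains only
#' the key fields and the prediction/feature summary.
#'
#' @param cache a [prediction_cache()].
#' @return data.frame (0 rows for an empty cache).
#' @export
serialize_cache <- function(cache) {
  keys <- sort(ls(cache$env))
  if (length(keys) == 0L)
    return(data.frame(key = character(), stringsAsFactors = FALSE))
  rows <- lapply(keys, function(k) {
    v <- get(k, envir = cache$env)
    cbind(data.frame(key = k, stringsAsFactors = FALSE),
          as.data.frame(v, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Write / read the cache as TSV
#' @param cache a [prediction_cache()].
#' @param path file path.
#' @export
write_cache <- function(cache, path) {
  write.table(serialize_cache(cache), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Create an upload store
#'
#' Tracks uploaded variant lists with a retention window (default 4
#' weeks). Uploads can be deleted on demand; deleting or expiring an
#' upload never touches cached predictions, which are permanently
#' stored and origin-free.
#'
#' @param retention_days days until automatic removal (default 28).
#' @return object of class `UploadStore`.
#' @export
upload_store <- function(retention_days = 28) {
  e <- new.env(parent = emptyenv())
  assign(".counter", 0L, envir = e)
  structure(list(env = e, retention_days = retention_days),
            class = "UploadStore")
}

#' Register an upload
#' @param store an [upload_store()].
#' @param variants data.frame of the uploaded variants.
#' @param now creation time (default `Sys.time()`).
#' @return the upload id.
#' @export
register_upload <- function(store, variants, now = Sys.time()) {
  n <- get(".counter", envir = store$env) + 1L
  assign(".counter", n, envir = store$env)
  id <- sprintf("upload-%06d", n)
  assign(id, list(id = id, variants = variants, created = now,
                  expiry = now + store$retention_days * 86400),
         envir = store$env)
  id
}

#' Fetch an upload by id
#' @param store an [upload_store()].
#' @param upload_id id from [register_upload()].
#' @return the upload record.
#' @export
get_upload <- function(store, upload_id) {
  u <- get0(upload_id, envir = store$env, inherits = FALSE)
  if (is.null(u)) stop("unknown upload id: ", upload_id)
  u
}

#' Delete an upload on demand
#'
#' Removes the upload's variant list; cached predictions are untouched.
#'
#' @param store an [upload_store()].
#' @param upload_id id to delete.
#' @return invisibly, the deleted id.
#' @export
delete_upload <- function(store, upload_id) {
  get_upload(store, upload_id)  # errors on unknown id
  rm(list = upload_id, envir = store$env)
  invisible(upload_id)
}

#' Remove expired uploads
#'
#' @param store an [upload_store()].
#' @param now reference time (default `Sys.time()`).
#' @return character vector of removed upload ids.
#' @export
sweep_uploads <- function(store, now = Sys.time()) {
  ids <- setdiff(ls(store$env), ".counter")
  gone <- ids[vapply(ids, function(i)
    get(i, envir = store$env)$expiry <= now, logical(1))]
  if (length(gone)) rm(list = gone, envir = store$env)
  gone
}

#' List live upload ids
#' @param store an [upload_store()].
#' @return character vector of ids.
#' @export
list_uploads <- function(store) setdiff(ls(store$env), ".counter")
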