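# Maximum-entropy splice-site models.
#
# A window distribution is represented as a product of potentials over
# contiguous blocks of `constraint_order` positions (a chain-structured
# factor graph), fitted by iterative proportional fitting so that all
# block marginals match the empirical ones. With constraint_order equal
# to the window length there is a single block and the fit recovers the
# empirical distribution; with order 1 it is the product of positional
# base frequencies. The chain structure keeps the 23-mer acceptor
# tractable: inference is exact via forward-backward over 4^(k-1)
# overlap states.

.BASES <- c("A", "C", "G", "T")

.all_kmers <- function(k) {
  g <- do.call(expand.grid, rev(replicate(k, .BASES, simplify = FALSE)))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

# windows -> matrix of base codes (rows = windows), validated
.window_codes <- function(windows) {
  if (length(windows) == 0L) stop("empty window set")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("windows have mixed lengths")
  m <- matrix(match(unlist(strsplit(toupper(windows), "", fixed = TRUE)),
                    .BASES) - 1L,
              nrow = length(windows), byrow = TRUE)
  if (anyNA(m)) stop("windows contain non-ACGT symbols")
  m
}

# empirical block marginal with pseudocount 0.5 per cell
.block_marginal <- function(codes, start, k) {
  idx <- rep(0L, nrow(codes))
  for (j in seq_len(k))
    idx <- idx * 4L + codes[, start + j - 1L]
  tab <- tabulate(idx + 1L, nbins = 4L^k) + 0.5
  tab / sum(tab)
}

# exact block marginals of the chain model given log-potentials
.chain_marginals <- function(logphi, k) {
  B <- length(logphi)
  nk <- 4L^k; ns <- 4L^(k - 1L)
  psi <- lapply(logphi, exp)
  # leftmost base most significant: idx = prefix*4 + last base, so the
  # (k-1)-overlap with the next clique is idx %% 4^(k-1)
  idx0 <- seq_len(nk) - 1L
  prefix <- idx0 %/% 4L + 1L
  suffix <- idx0 %% ns + 1L
  A <- vector("list", B); Bk <- vector("list", B)
  A[[1L]] <- psi[[1L]]
  if (B > 1L) {
    for (j in 2L:B) {
      msg <- rowsum(A[[j - 1L]], suffix)[, 1L]  # sum over configs by suffix
      A[[j]] <- psi[[j]] * msg[prefix]
    }
  }
  Z <- sum(A[[B]])
  Bk[[B]] <- rep(1, nk)
  if (B > 1L) {
    for (j in (B - 1L):1L) {
      msg <- rowsum(psi[[j + 1L]] * Bk[[j + 1L]], prefix)[, 1L]
      Bk[[j]] <- msg[suffix]
    }
  }
  list(marginals = lapply(seq_len(B), function(j)
         unname(A[[j]] * Bk[[j]] / Z)),
       logZ = unname(log(Z)))
}

#' Train a maximum-entropy splice-site model
#'
#' Fits the maximum-entropy distribution whose marginals over every
#' contiguous block of `constraint_order` positions match the empirical
#' training-window marginals (iterative proportional fitting, tolerance
#' 1e-6, at most 500 iterations). A pseudocount of 0.5 per marginal cell
#' keeps all probabilities positive, so scores are always finite. The
#' background is a position-independent base composition, taken from
#' `background_windows` when given, else from the training windows.
#'
#' @param training_windows character vector of equal-length ACGT windows.
#' @param background_windows optional windows for the background
#'   composition.
#' @param constraint_order marginal block width (default 2); values
#'   larger than the window length are clamped to it.
#' @param site_type optional `"donor"` or `"acceptor"` tag; donor windows
#'   are 9-mers (3 exonic + 6 intronic), acceptor windows 23-mers (20
#'   intronic + 3 exonic).
#' @param max_iter,tol IPF controls.
#' @return object of class `SpliceModel`.
#' @export
train_splice_model <- function(training_windows, background_windows = NULL,
                               constraint_order = 2L, site_type = NA_character_,
                               max_iter = 500L, tol = 1e-6) {
  codes <- .window_codes(training_windows)
  L <- ncol(codes)
  if (!is.na(site_type)) {
    want <- c(donor = 9L, acceptor = 23L)[[site_type]]
    if (L != want)
      stop(site_type, " windows must be ", want, "-mers, got ", L)
  }
  k <- min(as.integer(constraint_order), L)
  if (k < 1L) stop("constraint_order must be >= 1")
  B <- L - k + 1L
  emp <- lapply(seq_len(B), function(j) .block_marginal(codes, j, k))

  if (k == 1L) {
    logphi <- lapply(emp, log)   # independent positions: closed form
    logZ <- 0
    dev <- 0
  } else {
    logphi <- replicate(B, rep(0, 4L^k), simplify = FALSE)
    dev <- Inf
    for (it in seq_len(max_iter)) {
      cm <- .chain_marginals(logphi, k)
      dev <- max(vapply(seq_len(B), function(j)
        max(abs(cm$marginals[[j]] - emp[[j]])), numeric(1)))
      if (dev < tol) break
      for (j in seq_len(B)) {
        cm <- .chain_marginals(logphi, k)
        logphi[[j]] <- logphi[[j]] + log(emp[[j]]) - log(cm$marginals[[j]])
      }
    }
    logZ <- .chain_marginals(logphi, k)$logZ
  }

  bg_codes <- if (is.null(background_windows)) codes
              else .window_codes(background_windows)
  bg_tab <- tabulate(as.vector(bg_codes) + 1L, nbins = 4L) + 0.5
  bg <- setNames(bg_tab / sum(bg_tab), .BASES)

  structure(list(
    site_type = site_type, window_length = L, constraint_order = k,
    logphi = logphi, logZ = logZ, background = bg,
    empirical_marginals = emp, fit_deviation = dev, version = "1"),
    class = "SpliceModel")
}

#' @export
print.SpliceModel <- function(x, ...) {
  cat(sprintf("SpliceModel (%s): %d-mer, constraint order %d, fit dev %.2e\n",
              x$site_type, x$window_length, x$constraint_order,
              x$fit_deviation))
  invisible(x)
}

# log P_signal(window) under the chain model
.signal_logp <- function(model, codes_row) {
  k <- model$constraint_order
  B <- length(model$logphi)
  lp <- -model$logZ
  for (j in seq_len(B)) {
    idx <- 0L
    for (t in seq_len(k)) idx <- idx * 4L + codes_row[j + t - 1L]
    lp <- lp + model$logphi[[j]][idx + 1L]
  }
  lp
}

#' Score a window against a splice model
#'
#' `log2(P_signal(window) / P_background(window))`, the maximum-entropy
#' log-odds score. Always finite thanks to the training pseudocounts.
#'
#' @param model a [train_splice_model()] fit.
#' @param window ACGT string of the model's window length.
#' @return numeric log2-odds score.
#' @export
score_window <- function(model, window) {
  codes <- .window_codes(window)
  if (ncol(codes) != model$window_length)
    stop("window length ", ncol(codes), " does not match model (",
         model$window_length, ")")
  lp_s <- .signal_logp(model, codes[1L, ])
  lp_b <- sum(log(model$background[codes[1L, ] + 1L]))
  unname((lp_s - lp_b) / log(2))
}

#' Full signal distribution of a small model
#'
#' Enumerates `P_signal` over every window; for inspection and testing
#' only (window length capped at 10).
#'
#' @param model a `SpliceModel` with window length <= 10.
#' @return named numeric vector over all 4^L windows.
#' @export
window_probabilities <- function(model) {
  L <- model$window_length
  if (L > 10L) stop("enumeration limited to windows of length <= 10")
  kmers <- .all_kmers(L)
  p <- vapply(kmers, function(w)
    exp(.signal_logp(model, .window_codes(w)[1L, ])), numeric(1))
  setNames(p, kmers)
}

#' Canonical splice windows of a transcript
#'
#' One donor and one acceptor window per intron, with MaxEnt-style
#' geometry: donor = 3 exonic + 6 intronic bases (9-mer), acceptor = 20
#' intronic + 3 exonic bases (23-mer). Minus-strand windows are read as
#' the reverse complement of the corresponding genomic span. Windows
#' running off the contig are dropped.
#'
#' @param tx a [transcript()].
#' @param genome a [reference_genome()] (for bounds checking).
#' @return data.frame: intron_index (transcript order), site_type,
#'   gstart, gend (0-based half-open genomic span), anchor (the annotated
#'   exon/intron boundary coordinate).
#' @export
splice_windows <- function(tx, genome) {
  n <- nrow(tx$exons)
  if (n < 2L) return(.empty_windows())
  clen <- nchar(contig_seq(genome, tx$contig))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    a <- tx$exons[i, 2L]        # intron genomic start
    b <- tx$exons[i + 1L, 1L]   # intron genomic end
    intron_idx <- if (tx$strand == "+") i else n - i
    if (tx$strand == "+") {
      rows[[length(rows) + 1L]] <- list(intron_idx, "donor", a - 3L, a + 6L, a)
      rows[[length(rows) + 1L]] <- list(intron_idx, "acceptor", b - 20L, b + 3L, b)
    } else {
      rows[[length(rows) + 1L]] <- list(intron_idx, "donor", b - 6L, b + 3L, b)
      rows[[length(rows) + 1L]] <- list(intron_idx, "acceptor", a - 3L, a + 20L, a)
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(intron_index = r[[1L]], site_type = r[[2L]],
               gstart = r[[3L]], gend = r[[4L]], anchor = r[[5L]],
               stringsAsFactors = FALSE)))
  df[df$gstart >= 0L & df$gend <= clen, , drop = FALSE]
}

.empty_windows <- function() {
  data.frame(intron_index = integer(), site_type = character(),
             gstart = integer(), gend = integer(), anchor = integer(),
             stringsAsFactors = FALSE)
}

# window sequence in transcript orientation from an arbitrary contig string
.window_seq <- function(seq, gstart, gend, strand) {
  if (gstart < 0L || gend > nchar(seq)) return(NA_character_)
  s <- substr(seq, gstart + 1L, gend)
  if (strand == "+") s else revcomp(s)
}

#' Splice-score changes at canonical sites only
#'
#' Scores the reference and mutated sequence at every canonical
#' donor/acceptor window the variant overlaps. The mutated window is
#' re-read from the mutated contig anchored at the annotated exon/intron
#' boundary (mapped through the edit), so indels shift the window content
#' deterministically. Variants touching no canonical window return an
#' empty frame: the scorer never scans for cryptic splice sites.
#'
#' @param variant a [normalized_variant()].
#' @param tx a [transcript()].
#' @param genome a [reference_genome()].
#' @param donor_model,acceptor_model [train_splice_model()] fits with
#'   window lengths 9 and 23.
#' @return data.frame of `SpliceDelta` rows: transcript, intron_index,
#'   site_type, ref_window, alt_window, ref_score, alt_score, delta
#'   (= alt_score - ref_score).
#' @export
splice_deltas <- function(variant, tx, genome, donor_model, acceptor_model) {
  win <- splice_windows(tx, genome)
  iv <- variant_interval(variant)
  out <- data.frame(transcript = character(), intron_index = integer(),
                    site_type = character(), ref_window = character(),
                    alt_window = character(), ref_score = numeric(),
                    alt_score = numeric(), delta = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(win) == 0L) return(out)
  hit <- win[iv[1L] < win$gend & iv[2L] > win$gstart, , drop = FALSE]
  if (nrow(hit) == 0L) return(out)
  seq <- contig_seq(genome, tx$contig)
  mut <- mutate_contig(seq, variant)
  f <- .coord_map(variant)
  for (r in seq_len(nrow(hit))) {
    w <- hit[r, ]
    model <- if (w$site_type == "donor") donor_model else acceptor_model
    ref_w <- .window_seq(seq, w$gstart, w$gend, tx$strand)
    # mutated window: same geometry around the mapped boundary anchor
    off_s <- w$gstart - w$anchor; off_e <- w$gend - w$anchor
    am <- f(w$anchor)
    alt_w <- .window_seq(mut, am + off_s, am + off_e, tx$strand)
    if (is.na(ref_w) || is.na(alt_w)) next
    rs <- score_window(model, ref_w)
    as_ <- score_window(model, alt_w)
    out <- rbind(out, data.frame(
      transcript = tx$id, intron_index = w$intron_index,
      site_type = w$site_type, ref_window = ref_w, alt_window = alt_w,
      ref_score = rs, alt_score = as_, delta = as_ - rs,
      stringsAsFactors = FALSE))
  }
  out
}

#' Serialize a splice model to a tab-separated table
#'
#' Versioned plain-text representation: header comment lines with the
#' model metadata, one row per (block, k-mer) log-potential, and the
#' background composition.
#'
#' @param model a `SpliceModel`.
#' @param path output path.
#' @export
write_splice_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vepforest_splice_model\tversion=%s", model$version), con)
  writeLines(sprintf("# site_type=%s\twindow_length=%d\tconstraint_order=%d\tlogZ=%.17g",
                     model$site_type, model$window_length,
                     model$constraint_order, model$logZ), con)
  writeLines("block\tkmer\tlogphi", con)
  kmers <- .all_kmers(model$constraint_order)
  for (j in seq_along(model$logphi))
    writeLines(sprintf("%d\t%s\t%.17g", j, kmers, model$logphi[[j]]), con)
  writeLines(sprintf("bg\t%s\t%.17g", names(model$background),
                     log(model$background)), con)
}

#' Read back a serialized splice model
#' @param path path written by [write_splice_model()].
#' @return a `SpliceModel` (without training marginals).
#' @export
read_splice_model <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# vepforest_splice_model", lines[1L]))
    stop("not a vepforest splice model file: ", path)
  meta <- strsplit(sub("^# ", "", lines[2L]), "\t")[[1L]]
  kv <- strsplit(meta, "=")
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  df <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                   stringsAsFactors = FALSE)
  k <- as.integer(vals[["constraint_order"]])
  bg_rows <- df$block == "bg"
  bg <- setNames(exp(as.numeric(df$logphi[bg_rows])), df$kmer[bg_rows])
  body <- df[!bg_rows, , drop = FALSE]
  blocks <- sort(unique(as.integer(body$block)))
  kmers <- .all_kmers(k)
  logphi <- lapply(blocks, function(j) {
    sub <- body[as.integer(body$block) == j, ]
    as.numeric(sub$logphi[match(kmers, sub$kmer)])
  })
  structure(list(
    site_type = vals[["site_type"]],
    window_length = as.integer(vals[["window_length"]]),
    constraint_order = k, logphi = logphi,
    logZ = as.numeric(vals[["logZ"]]), background = bg[.BASES],
    empirical_marginals = NULL, fit_deviation = NA_real_,
    version = "1"), class = "SpliceModel")
}
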