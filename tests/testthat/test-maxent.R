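# Maximum-entropy splice model: training fidelity, scoring, and the
# canonical-sites-only contract.

all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- ""
  for (i in seq_len(k)) out <- as.vector(outer(out, b, paste0))
  sort(out)
}

test_that("full-order constraints recover the empirical distribution", {
  set.seed(21)
  w <- replicate(60, paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                           collapse = ""))
  m <- train_splice_model(w, constraint_order = 3)
  p <- window_probabilities(m)
  counts <- table(factor(w, levels = names(p)))
  emp <- (as.numeric(counts) + 0.5) / sum(counts + 0.5)
  expect_lt(max(abs(p - emp)), 1e-6)
})

test_that("order-1 model is the product of positional frequencies and scores add", {
  set.seed(22)
  w <- replicate(40, paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE,
                                  prob = c(.4, .3, .2, .1)), collapse = ""))
  m <- train_splice_model(w, constraint_order = 1)
  # positional frequencies with the 0.5 pseudocount, computed directly
  posfreq <- lapply(1:5, function(i) {
    tab <- table(factor(substr(w, i, i), levels = c("A", "C", "G", "T")))
    (tab + 0.5) / sum(tab + 0.5)
  })
  for (win in c("AAAAA", "ACGTA", "TTTTT", "GCGCG")) {
    expected <- sum(vapply(1:5, function(i) {
      b <- substr(win, i, i)
      log2(posfreq[[i]][[b]] / m$background[[b]])
    }, numeric(1)))
    expect_equal(score_window(m, win), expected, tolerance = 1e-12)
  }
})

test_that("training input validation", {
  expect_error(train_splice_model(character(0)), "empty")
  expect_error(train_splice_model(c("ACG", "ACGT")), "mixed")
  expect_error(train_splice_model(c("ACX")), "non-ACGT")
  expect_error(score_window(train_splice_model(c("ACG", "GGG")), "ACGT"),
               "length")
})

test_that("signal equal to background scores zero everywhere", {
  # a model whose single-block distribution is exactly uniform
  m <- train_splice_model(all_kmers(2), constraint_order = 2)
  for (w in c("AA", "CG", "TT", "GA"))
    expect_equal(score_window(m, w), 0, tolerance = 1e-12)
})

test_that("log-odds arithmetic on a printed toy model", {
  # P_signal(AA) = 0.5 against a uniform background: log2(0.5/0.0625) = 3
  m <- structure(list(
    site_type = NA_character_, window_length = 2L, constraint_order = 2L,
    logphi = list(log(c(0.5, rep(0.5 / 15, 15)))), logZ = 0,
    background = c(A = .25, C = .25, G = .25, T = .25),
    version = "1"), class = "SpliceModel")
  expect_equal(score_window(m, "AA"), 3, tolerance = 1e-12)
})

test_that("scores equal the table-lookup oracle on all windows of a 4-mer model", {
  set.seed(23)
  w <- replicate(80, paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE,
                                  prob = c(.1, .2, .3, .4)), collapse = ""))
  m <- train_splice_model(w, constraint_order = 2)
  p <- window_probabilities(m)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  for (win in names(p)) {
    bg <- prod(vapply(strsplit(win, "")[[1]],
                      function(b) m$background[[b]], numeric(1)))
    expect_equal(score_window(m, win), log2(p[[win]] / bg),
                 tolerance = 1e-9)
  }
})

test_that("IPF matches empirical block marginals on random training sets", {
  set.seed(24)
  for (rep in 1:3) {
    L <- sample(5:8, 1)
    w <- replicate(50, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                                    prob = runif(4, 0.5, 2)), collapse = ""))
    m <- train_splice_model(w, constraint_order = 2)
    expect_lt(m$fit_deviation, 1e-6)
  }
})

test_that("serialization round-trips scores exactly", {
  sm <- fixture_splice_models()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_splice_model(sm$donor, path)
  m2 <- read_splice_model(path)
  set.seed(25)
  for (i in 1:20) {
    w <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    expect_equal(score_window(m2, w), score_window(sm$donor, w),
                 tolerance = 1e-12)
  }
})

test_that("canonical windows have MaxEnt geometry on both strands", {
  sm <- fixture_splice_models()
  for (strand in c("+", "-")) {
    fx <- fixture_tx(strand)
    win <- splice_windows(fx$tx, fx$genome)
    expect_equal(nrow(win), 4L)  # 2 introns x donor+acceptor
    expect_equal(win$gend - win$gstart,
                 ifelse(win$site_type == "donor", 9L, 23L))
    for (r in seq_len(nrow(win))) {
      s <- vepforest:::.window_seq(fx$genome$contigs[[fx$tx$contig]],
                                   win$gstart[r], win$gend[r], strand)
      if (win$site_type[r] == "donor") expect_equal(substr(s, 4, 5), "GT")
      else expect_equal(substr(s, 19, 20), "AG")
    }
  }
})

test_that("disrupting the invariant GT lowers the donor score", {
  sm <- fixture_splice_models()
  fx <- fixture_tx("+")
  g <- fx$genome; tx <- fx$tx
  v <- normalized_variant("c1", 63L, "G", "C", g)  # G of the first GT
  d <- splice_deltas(v, tx, g, sm$donor, sm$acceptor)
  expect_equal(nrow(d), 1L)
  expect_equal(d$site_type, "donor")
  expect_lt(d$delta, 0)
  expect_equal(d$delta, d$alt_score - d$ref_score)
})

test_that("variants outside canonical windows yield no deltas, ever", {
  sm <- fixture_splice_models()
  set.seed(26)
  for (strand in c("+", "-")) {
    fx <- fixture_tx(strand)
    g <- fx$genome; tx <- fx$tx
    win <- splice_windows(tx, g)
    seq <- g$contigs[[tx$contig]]
    n <- 0L
    while (n < 500L) {
      p <- sample(nchar(seq) - 1L, 1L) - 1L
      if (any(p >= win$gstart & p < win$gend)) next
      ref <- substr(seq, p + 1L, p + 1L)
      v <- normalized_variant(tx$contig, p, ref,
                              sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
      expect_equal(nrow(splice_deltas(v, tx, g, sm$donor, sm$acceptor)), 0L)
      n <- n + 1L
    }
  }
})

test_that("an indel shifts the boundary-anchored alternate window deterministically", {
  sm <- fixture_splice_models()
  fx <- fixture_tx("+")
  g <- fx$genome; tx <- fx$tx
  # delete the last exonic base before the first donor (anchor 63)
  v <- normalized_variant("c1", 61L, "GG", "G", g)
  d <- splice_deltas(v, tx, g, sm$donor, sm$acceptor)
  expect_gte(nrow(d), 1L)
  don <- d[d$site_type == "donor", ]
  expect_equal(nchar(don$alt_window), 9L)
  expect_false(identical(don$alt_window, don$ref_window))
})
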