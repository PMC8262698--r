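# Deterministic synthetic-data generator: toy genomes with multi-exon
# transcripts on both strands, splice-site training windows, resource
# tables and labelled benign/deleterious variant sets with tunable,
# class-dependent feature separation. Everything downstream is testable
# from these fixtures without any download.

.NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. `effect_size` is
#' the separation, in pooled standard deviations, between the benign and
#' deleterious conservation-score distributions; it also scales the
#' positional enrichment of deleterious variants (canonical splice
#' windows, Kozak context, polyA signals), reaching its full strength at
#' 3 SD and vanishing at 0 so that `effect_size = 0` yields exchangeable
#' labels.
#'
#' @param seed RNG seed; identical config + seed gives identical output.
#' @param n_transcripts transcripts (alternating strand, one contig each).
#' @param exon_range min/max exons per transcript.
#' @param n_benign,n_deleterious variants per model class (scalar or
#'   named per-class vector).
#' @param effect_size class separation in pooled SDs (>= 0).
#' @param cons_mean,cons_sd baseline conservation level and noise SD.
#' @param frac_hom fraction of benign variants given >=1 homozygous
#'   carrier in the frequency table.
#' @param frac_pathogenic fraction of deleterious variants given a
#'   pathogenic / likely_pathogenic assertion.
#' @param frac_conflicting fraction of deleterious variants whose
#'   assertion is `conflicting` instead.
#' @param frac_dm fraction of deleterious variants tagged DM.
#' @param intron_range,utr5_range,utr3_range,codon_range,flank geometry.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, n_transcripts = 6L,
                              exon_range = c(2L, 4L),
                              n_benign = 40L, n_deleterious = 40L,
                              effect_size = 3, cons_mean = 0.3,
                              cons_sd = 0.15, frac_hom = 0.4,
                              frac_pathogenic = 0.6,
                              frac_conflicting = 0.05, frac_dm = 0.3,
                              intron_range = c(80L, 160L),
                              utr5_range = c(30L, 60L),
                              utr3_range = c(40L, 80L),
                              codon_range = c(40L, 80L), flank = 80L) {
  stopifnot(effect_size >= 0, frac_hom >= 0, frac_hom <= 1,
            all(n_benign >= 0), all(n_deleterious >= 0))
  structure(as.list(environment()), class = "SimulationConfig")
}

.resolve_counts <- function(n) {
  cls <- model_classes()
  if (is.null(names(n))) return(setNames(rep_len(as.integer(n), 5L), cls))
  out <- setNames(rep(0L, 5L), cls)
  out[names(n)] <- as.integer(n)
  out
}

.sample_base <- function(p) sample(names(p), 1L, prob = p)

.intron_seq <- function(len) {
  stopifnot(len >= 30L)
  donor_tail <- c(
    .sample_base(c(A = .6, C = .1, G = .2, T = .1)),
    .sample_base(c(A = .7, C = .1, G = .1, T = .1)),
    .sample_base(c(A = .07, C = .06, G = .8, T = .07)),
    .sample_base(c(A = .17, C = .19, G = .19, T = .45)))
  py <- paste(sample(c("C", "T", "A", "G"), 16L, replace = TRUE,
                     prob = c(.4, .4, .1, .1)), collapse = "")
  mid <- random_dna(len - 2L - 4L - 16L - 2L)
  paste0("GT", paste(donor_tail, collapse = ""), mid, py, "AG")
}

#' Generate a toy genome with multi-exon transcripts
#'
#' One contig per transcript, strands alternating. Every transcript has
#' a valid ATG...stop CDS (no internal stop), canonical GT/AG intron
#' dinucleotides with consensus-like donor/acceptor context, a strong
#' Kozak context (`GCCACC` before the ATG, G at +4), and a planted
#' AATAAA polyadenylation signal in the 3' UTR. Per-gene pLI scores are
#' drawn uniformly. Fully deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf` and `pli.tsv`.
#' @return list with `genome`, `transcripts`, `pli_table`, `files`.
#' @export
make_genome_and_transcripts <- function(config, dir = NULL) {
  set.seed(config$seed)
  contigs <- character(0)
  txs <- list()
  pli <- data.frame(gene = character(), pli = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(config$n_transcripts)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    u5 <- sample(config$utr5_range[1L]:config$utr5_range[2L], 1L)
    u3 <- max(24L, sample(config$utr3_range[1L]:config$utr3_range[2L], 1L))
    ncod <- sample(config$codon_range[1L]:config$codon_range[2L], 1L)
    codon2 <- sample(grep("^G", .NONSTOP_CODONS, value = TRUE), 1L)
    body <- paste(sample(.NONSTOP_CODONS, ncod - 3L, replace = TRUE),
                  collapse = "")
    cds <- paste0("ATG", codon2, body, sample(c("TAA", "TAG", "TGA"), 1L))
    utr5seq <- paste0(random_dna(u5 - 6L), "GCCACC")
    utr3seq <- paste0(random_dna(u3 - 21L), "AATAAA", random_dna(15L))
    mrna <- paste0(utr5seq, cds, utr3seq)
    L <- nchar(mrna)
    n_ex <- sample(config$exon_range[1L]:config$exon_range[2L], 1L)
    cuts <- if (n_ex > 1L) {
      repeat {
        cand <- sort(sample(12:(L - 12L), n_ex - 1L))
        if (all(diff(c(0L, cand, L)) >= 12L)) break
      }
      cand
    } else integer(0)
    bounds <- c(0L, cuts, L)  # mRNA segments per exon
    introns <- vapply(seq_len(n_ex - 1L), function(j)
      .intron_seq(sample(config$intron_range[1L]:config$intron_range[2L], 1L)),
      character(1))
    # assemble sense-strand contig and exon coordinates
    pieces <- character(0)
    sense <- random_dna(config$flank)
    ex_sense <- matrix(0L, nrow = n_ex, ncol = 2L)
    mrna2sense <- integer(L)  # genomic sense position of each mRNA base
    gpos <- config$flank
    for (e in seq_len(n_ex)) {
      seg <- substr(mrna, bounds[e] + 1L, bounds[e + 1L])
      ex_sense[e, ] <- c(gpos, gpos + nchar(seg))
      mrna2sense[(bounds[e] + 1L):bounds[e + 1L]] <-
        gpos + seq_len(nchar(seg)) - 1L
      sense <- paste0(sense, seg)
      gpos <- gpos + nchar(seg)
      if (e < n_ex) {
        sense <- paste0(sense, introns[e])
        gpos <- gpos + nchar(introns[e])
      }
    }
    sense <- paste0(sense, random_dna(config$flank))
    cds_s_sense <- mrna2sense[u5 + 1L]
    cds_e_sense <- mrna2sense[u5 + nchar(cds)] + 1L
    if (strand == "+") {
      contig <- sense
      exons <- ex_sense
      cds_s <- cds_s_sense; cds_e <- cds_e_sense
    } else {
      Lc <- nchar(sense)
      contig <- revcomp(sense)
      exons <- cbind(Lc - ex_sense[, 2L], Lc - ex_sense[, 1L])
      cds_s <- Lc - cds_e_sense; cds_e <- Lc - cds_s_sense
    }
    gene <- paste0("gene", i)
    pli <- rbind(pli, data.frame(gene = gene, pli = round(runif(1L), 3L),
                                 stringsAsFactors = FALSE))
    txs[[paste0("tx", i)]] <- transcript(
      id = paste0("tx", i), gene = gene, contig = paste0("ctg", i),
      strand = strand, exons = exons, cds_start = cds_s, cds_end = cds_e,
      pli = pli$pli[nrow(pli)])
    contigs[paste0("ctg", i)] <- contig
  }
  genome <- reference_genome(contigs)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$contigs), fa)
    gtf <- file.path(dir, "annotation.gtf")
    writeLines(.gtf_lines(txs), gtf)
    plif <- file.path(dir, "pli.tsv")
    write.table(pli, plif, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list(fasta = fa, gtf = gtf, pli = plif)
  }
  list(genome = genome, transcripts = txs, pli_table = pli, files = files)
}

.gtf_lines <- function(txs) {
  out <- character(0)
  for (tx in txs) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene, tx$id)
    for (e in seq_len(nrow(tx$exons))) {
      out <- c(out, paste(tx$contig, "sim", "exon",
                          tx$exons[e, 1L] + 1L, tx$exons[e, 2L],
                          ".", tx$strand, ".", attrs, sep = "\t"))
      cs <- max(tx$exons[e, 1L], tx$cds_start)
      ce <- min(tx$exons[e, 2L], tx$cds_end)
      if (ce > cs)
        out <- c(out, paste(tx$contig, "sim", "CDS", cs + 1L, ce,
                            ".", tx$strand, "0", attrs, sep = "\t"))
    }
  }
  out
}

#' Sample splice-site training windows from a consensus model
#'
#' Donor 9-mers (3 exonic + 6 intronic, near-invariant GT at intron
#' positions 1-2) or acceptor 23-mers (20 intronic with a pyrimidine
#' tract and near-invariant AG, + 3 exonic), drawn position-wise from
#' consensus-like base frequencies.
#'
#' @param n number of windows.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param seed optional RNG seed.
#' @return character vector of windows.
#' @export
make_splice_training_windows <- function(n, site_type, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  b <- c("A", "C", "G", "T")
  pwm <- if (site_type == "donor") {
    rbind(c(.33, .37, .18, .12), c(.60, .13, .14, .13),
          c(.08, .04, .81, .07),
          c(.003, .003, .991, .003),  # G of GT
          c(.003, .003, .003, .991),  # T of GT
          c(.50, .03, .45, .02), c(.70, .08, .12, .10),
          c(.07, .06, .80, .07), c(.17, .19, .19, .45))
  } else if (site_type == "acceptor") {
    rbind(matrix(rep(c(.10, .40, .10, .40), 18L), ncol = 4L, byrow = TRUE),
          c(.991, .003, .003, .003),  # A of AG
          c(.003, .003, .991, .003),  # G of AG
          c(.25, .15, .45, .15), c(.25, .25, .25, .25),
          c(.25, .25, .25, .25))
  } else stop("site_type must be donor or acceptor")
  vapply(seq_len(n), function(i)
    paste(apply(pwm, 1L, function(p) sample(b, 1L, prob = p)),
          collapse = ""), character(1))
}

# per-transcript position tables used by the variant samplers
.position_tables <- function(tx, genome) {
  span <- seq.int(tx_start(tx), tx_end(tx) - 1L)
  region <- character(length(span))
  cds_off <- rep(NA_integer_, length(span))
  for (j in seq_along(span)) {
    m <- map_genomic(tx, span[j])
    region[j] <- m$region
    if (m$region == "cds") cds_off[j] <- m$offset
  }
  # donor/acceptor distances for intronic positions
  ex <- tx$exons
  d_don <- rep(NA_integer_, length(span)); d_acc <- d_don
  intr <- which(region == "intron")
  for (j in intr) {
    p <- span[j]
    i <- max(which(ex[, 2L] <= p))
    dl <- p - ex[i, 2L] + 1L
    dr <- ex[i + 1L, 1L] - p
    if (tx$strand == "+") { d_don[j] <- dl; d_acc[j] <- dr }
    else { d_don[j] <- dr; d_acc[j] <- dl }
  }
  data.frame(pos = span, region = region, cds_off = cds_off,
             d_donor = d_don, d_acceptor = d_acc)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# transcript-orientation base at a genomic position
.tx_base <- function(seq, strand, p) {
  bs <- substr(seq, p + 1L, p + 1L)
  if (strand == "+") bs else unname(.complement[bs])
}

#' Generate labelled variant sets with resource tables
#'
#' Draws benign and deleterious variants per model class with
#' class-dependent feature separation controlled by
#' `config$effect_size`: deleterious variants sit on conservation scores
#' shifted by `effect_size` pooled SDs, are positionally enriched in
#' canonical splice windows / Kozak context / polyA signals, and (for
#' coding classes) favor severe amino-acid exchanges. Every variant's
#' intended class is verified against the router. Also emits the
#' per-base conservation track and frequency / assertion / DM tables
#' (genotype counts capped), plus the corresponding plain-text files
#' when `dir` is given.
#'
#' @param config a [simulation_config()].
#' @param fixtures result of [make_genome_and_transcripts()].
#' @param dir optional output directory (`variants.vcf`,
#'   `frequency.tsv`, `assertions.tsv`, `dm.tsv`,
#'   `conservation.bedGraph`).
#' @return list: `variants` (contig, pos 0-based, ref, alt, transcript,
#'   gene, model_class, label), `frequency_table`, `assertion_table`,
#'   `dm_table` (internal form, 0-based with `key`), `cons_track`,
#'   `files`, `n_class_mismatch`.
#' @export
make_labelled_variants <- function(config, fixtures, dir = NULL) {
  set.seed(config$seed + 1L)
  genome <- fixtures$genome; txs <- fixtures$transcripts
  nb <- .resolve_counts(config$n_benign)
  nd <- .resolve_counts(config$n_deleterious)
  bias <- 0.5 * min(1, config$effect_size / 3)
  # conservation is a property of positions: a latent evolutionarily
  # constrained flag (p = 0.5) decides each base's score distribution;
  # deleterious variants are drawn from constrained positions, benign
  # from unconstrained ones, so the class separation in conservation
  # equals effect_size pooled SDs by construction
  constrained <- lapply(genome$contigs, function(s)
    runif(nchar(s)) < 0.5)
  shift <- config$effect_size * config$cons_sd
  scores <- lapply(names(genome$contigs), function(cn) {
    L <- nchar(genome$contigs[[cn]])
    round(rnorm(L, config$cons_mean + shift * constrained[[cn]],
                config$cons_sd), 4L)
  })
  names(scores) <- names(genome$contigs)
  ptabs <- lapply(txs, .position_tables, genome = genome)
  for (nm in names(ptabs)) {
    cn <- txs[[nm]]$contig
    ptabs[[nm]]$constrained <- constrained[[cn]][ptabs[[nm]]$pos + 1L]
  }

  rows <- list(); mism <- 0L
  seen <- new.env(parent = emptyenv())
  for (cls in model_classes()) {
    for (lab in c("benign", "deleterious")) {
      n <- if (lab == "benign") nb[[cls]] else nd[[cls]]
      made <- 0L
      guard <- 0L
      while (made < n) {
        guard <- guard + 1L
        if (guard > 200L * max(1L, n))
          stop("cannot place requested ", cls, " variants (geometry too small)")
        ti <- sample(length(txs), 1L)
        tx <- txs[[ti]]
        want <- lab == "deleterious"
        v <- switch(cls,
          simple_aae = .sample_simple(tx, genome, ptabs[[ti]], lab, want,
                                      config$effect_size),
          complex_aae = .sample_complex(tx, genome, ptabs[[ti]], lab, want),
          utr5 = .sample_utr(tx, genome, ptabs[[ti]], lab, want, bias, "utr5"),
          utr3 = .sample_utr3(tx, genome, ptabs[[ti]], lab, want, bias),
          without_aae = .sample_without(tx, genome, ptabs[[ti]], lab, want,
                                        bias))
        if (is.null(v)) next
        nv <- tryCatch(
          normalized_variant(v$contig, v$pos, v$ref, v$alt, genome),
          error = function(e) NULL)
        if (is.null(nv)) { mism <- mism + 1L; next }
        key <- variant_key(nv)
        if (!is.null(get0(key, envir = seen))) next
        cl <- tryCatch(classify_variant(nv, tx, genome)$model_class,
                       error = function(e) NA_character_)
        if (is.na(cl) || cl != cls) { mism <- mism + 1L; next }
        assign(key, TRUE, envir = seen)
        # store the normalized identity so table keys match cache keys
        rows[[length(rows) + 1L]] <-
          data.frame(contig = nv$contig, pos = nv$pos, ref = nv$ref,
                     alt = nv$alt, transcript = tx$id, gene = tx$gene,
                     model_class = cls, label = lab,
                     stringsAsFactors = FALSE)
        made <- made + 1L
      }
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  variants$key <- sprintf("%s:%d:%s:%s", variants$contig, variants$pos,
                          variants$ref, variants$alt)

  cons <- conservation_track(do.call(rbind, lapply(
    names(scores), function(cn)
      data.frame(contig = cn, start = seq_along(scores[[cn]]) - 1L,
                 end = seq_along(scores[[cn]]), score = scores[[cn]],
                 stringsAsFactors = FALSE))))
  freq <- .make_frequency(config, variants)
  assert <- .make_assertions(config, variants)
  dm <- .make_dm(config, variants)

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      vcf = file.path(dir, "variants.vcf"),
      frequency = file.path(dir, "frequency.tsv"),
      assertions = file.path(dir, "assertions.tsv"),
      dm = file.path(dir, "dm.tsv"),
      conservation = file.path(dir, "conservation.bedGraph"))
    write_variant_vcf(variants, files$vcf)
    .write_external(freq, files$frequency,
                    c("contig", "pos", "ref", "alt", "source",
                      "het_count", "hom_count"))
    .write_external(assert, files$assertions,
                    c("contig", "pos", "ref", "alt", "significance",
                      "disease"))
    .write_external(dm, files$dm, c("contig", "pos", "ref", "alt", "tag"))
    ct <- cons$df
    write.table(ct[, c("contig", "start", "end", "score")], files$conservation,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  list(variants = variants, frequency_table = freq,
       assertion_table = assert, dm_table = dm, cons_track = cons,
       files = files, n_class_mismatch = mism)
}

# write a table in external (1-based) form
.write_external <- function(df, path, cols) {
  out <- df[, cols, drop = FALSE]
  out$pos <- out$pos + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write variants as a minimal single-sample VCF
#'
#' @param variants data.frame with contig, pos (0-based), ref, alt.
#' @param path output path.
#' @param sample_name genotype column name.
#' @export
write_variant_vcf <- function(variants, path, sample_name = "SAMPLE1") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_name, sep = "\t"))
  ord <- order(variants$contig, variants$pos)
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1",
                  variants$contig[ord], variants$pos[ord] + 1L,
                  variants$ref[ord], variants$alt[ord])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.make_frequency <- function(config, variants) {
  rows <- list()
  src <- c("gnomad", "exac", "kg1000")
  for (i in seq_len(nrow(variants))) {
    if (variants$label[i] == "benign") {
      hom <- if (runif(1) < config$frac_hom) sample(1:40, 1L) else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        contig = variants$contig[i], pos = variants$pos[i],
        ref = variants$ref[i], alt = variants$alt[i],
        source = sample(src, 1L), het_count = sample(0:300, 1L),
        hom_count = hom, stringsAsFactors = FALSE)
    } else if (runif(1) < 0.2) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = variants$contig[i], pos = variants$pos[i],
        ref = variants$ref[i], alt = variants$alt[i],
        source = sample(src, 1L), het_count = sample(0:2, 1L),
        hom_count = 0L, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$het_count <- cap_genotype_count(df$het_count)
  df$hom_count <- cap_genotype_count(df$hom_count)
  df$key <- sprintf("%s:%d:%s:%s", df$contig, df$pos, df$ref, df$alt)
  df
}

.make_assertions <- function(config, variants) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    sig <- NA_character_
    if (variants$label[i] == "deleterious") {
      u <- runif(1)
      if (u < config$frac_pathogenic)
        sig <- sample(c("pathogenic", "likely_pathogenic"), 1L,
                      prob = c(.6, .4))
      else if (u < config$frac_pathogenic + config$frac_conflicting)
        sig <- "conflicting"
    } else if (runif(1) < 0.1) {
      sig <- "benign"
    }
    if (is.na(sig)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig = variants$contig[i], pos = variants$pos[i],
      ref = variants$ref[i], alt = variants$alt[i], significance = sig,
      disease = if (sig %in% c("pathogenic", "likely_pathogenic"))
        paste0("disorder-", variants$gene[i]) else ".",
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), significance = character(),
               disease = character(), stringsAsFactors = FALSE)
  df$key <- sprintf("%s:%d:%s:%s", df$contig, df$pos, df$ref, df$alt)
  df
}

.make_dm <- function(config, variants) {
  sel <- variants$label == "deleterious" & runif(nrow(variants)) < config$frac_dm
  df <- variants[sel, c("contig", "pos", "ref", "alt"), drop = FALSE]
  df$tag <- "DM"
  df$key <- sprintf("%s:%d:%s:%s", df$contig, df$pos, df$ref, df$alt)
  rownames(df) <- NULL
  df
}

# --- per-class variant samplers -------------------------------------------

.sample_simple <- function(tx, genome, ptab, label, want, effect_size) {
  seq <- contig_seq(genome, tx$contig)
  cl <- cds_length(tx)
  cand <- ptab[!is.na(ptab$cds_off) & ptab$cds_off >= 3L &
               ptab$cds_off < cl - 3L & ptab$constrained == want, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  r <- cand[sample(nrow(cand), 1L), ]
  ref_g <- substr(seq, r$pos + 1L, r$pos + 1L)
  # evaluate the three alternate bases at codon level
  off <- r$cds_off
  u <- utr5_length(tx)
  cdna <- spliced_seq(tx, genome)
  cds <- substr(cdna, u + 1L, u + cl)
  ci <- off %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  pic <- off %% 3L + 1L
  ref_aa <- unname(.codon_table[codon])
  opts <- list()
  for (alt_g in setdiff(c("A", "C", "G", "T"), ref_g)) {
    alt_t <- if (tx$strand == "+") alt_g else unname(.complement[alt_g])
    mcodon <- codon
    substr(mcodon, pic, pic) <- alt_t
    alt_aa <- unname(.codon_table[mcodon])
    if (alt_aa == ref_aa || alt_aa == "*" || ref_aa == "*") next
    opts[[length(opts) + 1L]] <-
      list(alt = alt_g, g = grantham_distance(ref_aa, alt_aa))
  }
  if (length(opts) == 0L) return(NULL)
  gs <- vapply(opts, `[[`, numeric(1), "g")
  p_extreme <- min(1, effect_size / 3)
  pick <- if (runif(1) < p_extreme) {
    if (label == "deleterious") which.max(gs) else which.min(gs)
  } else sample(length(opts), 1L)
  list(contig = tx$contig, pos = r$pos, ref = ref_g, alt = opts[[pick]]$alt)
}

.sample_complex <- function(tx, genome, ptab, label, want) {
  seq <- contig_seq(genome, tx$contig)
  cl <- cds_length(tx)
  len <- if (label == "deleterious") sample(1:2, 1L) else 3L
  # deletion fully inside one exon's CDS, clear of start/stop codons;
  # the first deleted base carries the class's conservation flag
  cand <- ptab[!is.na(ptab$cds_off) & ptab$cds_off >= 4L &
               ptab$cds_off < cl - 4L - len & ptab$constrained == want, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  for (try in 1:10) {
    r <- cand[sample(nrow(cand), 1L), ]
    span <- (r$pos - 1L):(r$pos + len - 1L)
    rows <- ptab[match(span, ptab$pos), ]
    if (any(is.na(rows$cds_off))) next  # anchor or deletion leaves the exon
    ref <- substr(seq, r$pos, r$pos + len)       # anchor + deleted bases
    alt <- substr(seq, r$pos, r$pos)
    return(list(contig = tx$contig, pos = r$pos - 1L, ref = ref, alt = alt))
  }
  NULL
}

.sample_utr <- function(tx, genome, ptab, label, want, bias, region) {
  seq <- contig_seq(genome, tx$contig)
  u <- utr5_length(tx)
  cand <- ptab[ptab$region == region & ptab$constrained == want, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  if (label == "deleterious" && runif(1) < bias) {
    # target the Kozak prefix (-6..-1): last 6 bases of the 5' UTR
    koz <- vapply((u - 6L):(u - 1L), function(cp) cdna_to_genomic(tx, cp),
                  integer(1))
    cand <- cand[cand$pos %in% koz, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
  }
  r <- cand[sample(nrow(cand), 1L), ]
  ref <- substr(seq, r$pos + 1L, r$pos + 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(contig = tx$contig, pos = r$pos, ref = ref, alt = alt)
}

.sample_utr3 <- function(tx, genome, ptab, label, want, bias) {
  seq <- contig_seq(genome, tx$contig)
  u <- utr5_length(tx); cl <- cds_length(tx)
  cdna <- spliced_seq(tx, genome)
  utr3 <- substr(cdna, u + cl + 1L, nchar(cdna))
  hex <- regexpr("AATAAA", utr3, fixed = TRUE)[1L]
  cand <- ptab[ptab$region == "utr3" & ptab$constrained == want, ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  if (label == "deleterious" && runif(1) < bias && hex > 0L) {
    cp <- u + cl + hex - 1L + sample(0:5, 1L)  # 0-based mRNA index in hexamer
    gp <- cdna_to_genomic(tx, cp)
    if (gp %in% cand$pos) {
      ref <- substr(seq, gp + 1L, gp + 1L)
      alt <- if (tx$strand == "+") "C" else "G"  # breaks the A/T-rich signal
      if (alt == ref) alt <- if (tx$strand == "+") "G" else "C"
      return(list(contig = tx$contig, pos = gp, ref = ref, alt = alt))
    }
  }
  for (try in 1:20) {
    r <- cand[sample(nrow(cand), 1L), ]
    ref <- substr(seq, r$pos + 1L, r$pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    v <- normalized_variant(tx$contig, r$pos, ref, alt, genome)
    pa <- polya_signal_change(v, tx, genome)
    if (pa$status == "unchanged")
      return(list(contig = tx$contig, pos = r$pos, ref = ref, alt = alt))
  }
  NULL
}

.sample_without <- function(tx, genome, ptab, label, want, bias) {
  seq <- contig_seq(genome, tx$contig)
  intr <- ptab[ptab$region == "intron" & ptab$constrained == want, ,
               drop = FALSE]
  if (nrow(intr) == 0L) return(NULL)
  in_window <- (intr$d_donor <= 6L) | (intr$d_acceptor <= 20L)
  deep <- intr$d_donor > 8L & intr$d_acceptor > 22L
  pool <- if (label == "deleterious" && runif(1) < bias) {
    intr[in_window, , drop = FALSE]
  } else {
    intr[deep, , drop = FALSE]
  }
  if (nrow(pool) == 0L) return(NULL)
  r <- pool[sample(nrow(pool), 1L), ]
  ref <- substr(seq, r$pos + 1L, r$pos + 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  list(contig = tx$contig, pos = r$pos, ref = ref, alt = alt)
}
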