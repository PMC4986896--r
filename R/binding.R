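#' Annotate peak summits by gene feature
#'
#' Assigns each peak one category among `CDS_exon`, `UTR5`, `UTR3`,
#' `intron` by the summit position, with precedence
#' CDS_exon > UTR5 > UTR3 > intron across isoforms (the representative
#' transcript is consulted first, then any other transcript of the gene).
#' Summits outside every gene get `intergenic` and are excluded from
#' category fractions.
#'
#' @param peaks `GRanges` with a `summit` column (genomic space).
#' @param ann A [tx_annotation].
#' @return `peaks` with an added `category` factor column.
#' @export
annotate_peaks <- function(peaks, ann) {
  rep <- select_representative(ann)
  lv <- c("CDS_exon", "UTR5", "UTR3", "intron", "intergenic")
  if (!length(peaks)) {
    S4Vectors::mcols(peaks)$category <- factor(character(), levels = lv)
    return(peaks)
  }
  tx <- ann$transcripts
  sp <- gene_spans(ann, biotype = unique(ann$genes$biotype))
  summit_gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(S4Vectors::mcols(peaks)$summit, width = 1L),
    strand = BiocGenerics::strand(peaks))
  hits <- GenomicRanges::findOverlaps(summit_gr, sp, ignore.strand = FALSE)
  cat <- rep("intergenic", length(peaks))
  for (i in unique(S4Vectors::queryHits(hits))) {
    gids <- sp$gene_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == i]]
    txs <- tx$transcript_id[tx$gene_id %in% gids]
    # representative transcripts first, then the rest
    is_rep <- txs %in% rep$transcript_id
    txs <- c(txs[is_rep], txs[!is_rep])
    pos <- S4Vectors::mcols(peaks)$summit[i]
    best <- "intergenic"
    for (t in txs) {
      ct <- summit_category(ann, t, pos)
      if (match(ct, lv) < match(best, lv)) best <- ct
      if (best == "CDS_exon") break
    }
    # any gene hit that is not exonic in any isoform is intronic
    if (best == "intergenic") best <- "intron"
    cat[i] <- best
  }
  S4Vectors::mcols(peaks)$category <- factor(cat, levels = lv)
  peaks
}

# Category of one position within one transcript: CDS_exon/UTR5/UTR3 when
# exonic, intron when inside the transcript span but not exonic,
# intergenic otherwise.
summit_category <- function(ann, transcript_id, pos) {
  tx <- ann$transcripts[ann$transcripts$transcript_id == transcript_id, ]
  off <- genomic_to_transcriptomic(ann, transcript_id, pos)
  if (!is.na(off)) {
    if (is.na(tx$cds_start)) return("UTR5")  # noncoding guard
    co <- sort(genomic_to_transcriptomic(
      ann, transcript_id, c(tx$cds_start, tx$cds_end)))
    if (off < co[1]) return("UTR5")
    if (off > co[2]) return("UTR3")
    return("CDS_exon")
  }
  e <- transcript_exons(ann, transcript_id)
  if (pos >= min(BiocGenerics::start(e)) && pos <= max(BiocGenerics::end(e)))
    return("intron")
  "intergenic"
}

#' Peak category fractions
#'
#' @param peaks Annotated peaks from [annotate_peaks()], or directly
#'   their `category` factor.
#' @return Named numeric vector of fractions over
#'   CDS_exon/UTR5/UTR3/intron, after excluding intergenic peaks.
#' @export
category_fractions <- function(peaks) {
  cat <- if (is.factor(peaks) || is.character(peaks)) peaks
         else S4Vectors::mcols(peaks)$category
  cat <- cat[cat != "intergenic"]
  tab <- table(factor(cat, levels = c("CDS_exon", "UTR5", "UTR3",
                                      "intron")))
  stats::setNames(as.vector(tab / sum(tab)), names(tab))
}

#' Associate peaks of two data sets by summit distance
#'
#' A peak in `setA` is associated when some peak in `setB` on the same
#' strand (and chromosome/transcript) has a summit within `tol`
#' nucleotides (boundary inclusive).
#'
#' @param setA,setB `GRanges` with `summit` columns, same coordinate
#'   space.
#' @param tol Maximal summit distance in nt (default 10).
#' @return Logical vector along `setA`.
#' @export
associate_peaks <- function(setA, setB, tol = 10L) {
  if (!length(setA)) return(logical(0))
  if (!length(setB)) return(rep(FALSE, length(setA)))
  a <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(setA),
    IRanges::IRanges(S4Vectors::mcols(setA)$summit, width = 1L),
    strand = BiocGenerics::strand(setA))
  b <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(setB),
    IRanges::IRanges(S4Vectors::mcols(setB)$summit, width = 1L),
    strand = BiocGenerics::strand(setB))
  IRanges::overlapsAny(a, b, maxgap = tol - 1L, ignore.strand = FALSE)
}

#' Motif occurrence fractions in summit windows
#'
#' Scans the `window`-nt sequence centred on each peak summit (strand
#' oriented: minus-strand windows are reverse-complemented, so the
#' reverse complement is never scanned separately) for at least one match
#' of each motif. Motifs are IUPAC strings (exact degenerate match) or
#' position weight matrices (match when the log-odds score reaches
#' `pwm_min_score`, default 80 percent of the maximum). Windows running
#' off a contig end are clipped.
#'
#' @param peaks `GRanges` with `summit` (and optionally `category` from
#'   [annotate_peaks()]).
#' @param motifs Named list: character IUPAC strings and/or 4-row PWMs
#'   (rows A, C, G, T).
#' @param genome `DNAStringSet` (chromosomes, or transcript sequences for
#'   transcriptomic peaks).
#' @param window Window width in nt (default 20, split evenly around the
#'   summit).
#' @param pwm_min_score Passed to [Biostrings::matchPWM()] (default
#'   "80%").
#' @return List with `by_peak` (logical matrix peaks x motifs, plus an
#'   `any` column when several motifs are given) and `fractions`
#'   (data.frame of per-motif fractions for all peaks and per category
#'   when present). Fractions are `NA` for empty peak sets.
#' @export
motif_fraction <- function(peaks, motifs, genome, window = 20L,
                           pwm_min_score = "80%") {
  stopifnot(window %% 2L == 0L)
  nm <- names(motifs)
  if (is.null(nm)) nm <- paste0("motif", seq_along(motifs))
  if (!length(peaks)) {
    fr <- data.frame(motif = c(nm, if (length(motifs) > 1) "any"),
                     all = NA_real_)
    return(list(by_peak = matrix(logical(0), 0, length(nm),
                                 dimnames = list(NULL, nm)),
                fractions = fr))
  }
  seqs <- summit_windows(peaks, genome, window)
  hit <- vapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    if (is.character(m)) {
      Biostrings::vcountPattern(m, seqs, fixed = FALSE) > 0
    } else {
      vapply(seq_along(seqs), function(j)
        length(Biostrings::matchPWM(m, seqs[[j]],
                                    min.score = pwm_min_score)) > 0, TRUE)
    }
  }, logical(length(seqs)))
  hit <- matrix(hit, ncol = length(motifs), dimnames = list(NULL, nm))
  if (length(motifs) > 1L) hit <- cbind(hit, any = rowSums(hit) > 0)
  fr <- data.frame(motif = colnames(hit), all = colMeans(hit))
  cat <- S4Vectors::mcols(peaks)$category
  if (!is.null(cat)) {
    exonic <- cat %in% c("CDS_exon", "UTR5", "UTR3")
    intronic <- cat == "intron"
    fr$exonic <- if (any(exonic)) colMeans(hit[exonic, , drop = FALSE])
                 else NA_real_
    fr$intronic <- if (any(intronic))
      colMeans(hit[intronic, , drop = FALSE]) else NA_real_
  }
  rownames(fr) <- NULL
  list(by_peak = hit, fractions = fr)
}

# Strand-oriented summit-centred windows; clipped at contig ends.
summit_windows <- function(peaks, genome, window = 20L) {
  half <- window %/% 2L
  ch <- as.character(GenomicRanges::seqnames(peaks))
  su <- S4Vectors::mcols(peaks)$summit
  st <- as.character(BiocGenerics::strand(peaks))
  len <- stats::setNames(Biostrings::width(genome), names(genome))
  s <- pmax(1L, su - half)
  e <- pmin(len[ch], su + half - 1L)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(peaks), function(i)
    as.character(Biostrings::subseq(genome[[ch[i]]], s[i], e[i])), ""))
  minus <- st == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  seqs
}

#' Exon-end metaprofile of transcriptomic peak summits
#'
#' For peaks whose summits fall in internal exons of the representative
#' transcriptome, tabulates the frequency of summit distances to the exon
#' 5' end and to the exon 3' end (transcript orientation), normalized by
#' the number of contributing peaks. The null profile re-draws each summit
#' uniformly within its host exon `n_random` times and averages the
#' per-draw frequencies; it therefore integrates to the same mass as the
#' observed profile.
#'
#' @param peaks `GRanges` in transcriptomic space (seqnames = transcript
#'   ids, 1-based positions) with a `summit` column.
#' @param internal_exons data.frame from [internal_exons_tx()].
#' @param max_dist Maximal distance tabulated (default 200 nt).
#' @param n_random Number of null redraws (default 100).
#' @param seed RNG seed for the null.
#' @return List with `n_peaks` and data.frames `dist5` / `dist3`
#'   (`distance`, `observed`, `null` frequency columns).
#' @export
exon_end_profile <- function(peaks, internal_exons, max_dist = 200L,
                             n_random = 100L, seed = NULL) {
  su <- S4Vectors::mcols(peaks)$summit
  txp <- as.character(GenomicRanges::seqnames(peaks))
  ie <- internal_exons
  d5 <- integer(0); d3 <- integer(0); w <- integer(0)
  for (i in seq_along(peaks)) {
    rows <- which(ie$transcript_id == txp[i] & ie$tx_start <= su[i] &
                    ie$tx_end >= su[i])
    if (!length(rows)) next
    r <- rows[1]
    d5 <- c(d5, su[i] - ie$tx_start[r])
    d3 <- c(d3, ie$tx_end[r] - su[i])
    w <- c(w, ie$tx_end[r] - ie$tx_start[r] + 1L)
  }
  n <- length(d5)
  # distances beyond max_dist are dropped (profile truncated, not clamped)
  freq <- function(d) tabulate(d[d <= max_dist] + 1L,
                               nbins = max_dist + 1L) / max(1L, n)
  null5 <- null3 <- numeric(max_dist + 1L)
  if (n) with_seed_(seed, {
    for (it in seq_len(n_random)) {
      u <- floor(runif(n) * w)
      null5 <- null5 + freq(as.integer(u))
      null3 <- null3 + freq(as.integer(w - 1L - u))
    }
  })
  list(n_peaks = n,
       dist5 = data.frame(distance = 0:max_dist, observed = freq(d5),
                          null = null5 / max(1L, n_random)),
       dist3 = data.frame(distance = 0:max_dist, observed = freq(d3),
                          null = null3 / max(1L, n_random)))
}

#' Internal exons in transcript coordinates
#'
#' First and last exons of each representative transcript are dropped.
#'
#' @param ann A [tx_annotation].
#' @return data.frame `transcript_id`, `exon_rank`, `tx_start`, `tx_end`
#'   (1-based transcript coordinates).
#' @export
internal_exons_tx <- function(ann) {
  rep <- select_representative(ann)
  out <- list()
  for (i in seq_len(nrow(rep))) {
    e <- transcript_exons(ann, rep$transcript_id[i])
    n <- length(e)
    if (n < 3L) next
    w <- BiocGenerics::width(e)
    ends <- cumsum(w)
    starts <- ends - w + 1L
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = rep$transcript_id[i], exon_rank = 2:(n - 1L),
      tx_start = starts[2:(n - 1L)], tx_end = ends[2:(n - 1L)])
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), exon_rank = integer(),
                      tx_start = integer(), tx_end = integer()))
  do.call(rbind, out)
}

#' Intron-boundary distance histograms of intronic peak summits
#'
#' For each intronic peak summit, the strand-aware distance into the
#' intron from the 5' splice site and the distance to the 3' splice site.
#'
#' @param peaks `GRanges` with `summit` columns (genomic space).
#' @param introns `GRanges` from [derive_introns()].
#' @param max_dist Maximal distance tabulated (default 300).
#' @return List of data.frames `from5` and `to3` (`distance`, `count`);
#'   empty when no summit falls in an intron.
#' @export
intron_boundary_histogram <- function(peaks, introns, max_dist = 300L) {
  if (!length(peaks))
    return(list(from5 = data.frame(distance = integer(), count = integer()),
                to3 = data.frame(distance = integer(), count = integer())))
  su <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(S4Vectors::mcols(peaks)$summit, width = 1L),
    strand = BiocGenerics::strand(peaks))
  hits <- GenomicRanges::findOverlaps(su, introns, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- !duplicated(q)  # one host intron per summit
  q <- q[keep]; s <- s[keep]
  pos <- S4Vectors::mcols(peaks)$summit[q]
  minus <- as.character(BiocGenerics::strand(introns))[s] == "-"
  i5 <- ifelse(minus, BiocGenerics::end(introns)[s] - pos,
               pos - BiocGenerics::start(introns)[s])
  i3 <- ifelse(minus, pos - BiocGenerics::start(introns)[s],
               BiocGenerics::end(introns)[s] - pos)
  mk <- function(d) {
    d <- d[d <= max_dist]
    if (!length(d))
      return(data.frame(distance = integer(), count = integer()))
    tab <- table(d)
    data.frame(distance = as.integer(names(tab)),
               count = as.integer(tab))
  }
  list(from5 = mk(i5), to3 = mk(i3))
}

#' Pairwise replicate correlation on per-gene read counts
#'
#' @param counts Numeric matrix, genes x replicates.
#' @param warn_below Emit a warning when any off-diagonal Pearson r falls
#'   below this QC gate (default 0.9; `NULL` disables).
#' @return Pearson correlation matrix.
#' @export
replicate_correlation <- function(counts, warn_below = 0.9) {
  stopifnot(ncol(counts) >= 2L)
  r <- stats::cor(counts, method = "pearson")
  if (!is.null(warn_below)) {
    lo <- min(r[upper.tri(r)])
    if (lo < warn_below)
      warning(sprintf("replicate correlation %.3f below QC gate %.2f",
                      lo, warn_below))
  }
  r
}

#' Count reads per gene per replicate
#'
#' Support table for [replicate_correlation()]: same-strand overlap counts
#' of reads within gene spans.
#'
#' @param read_sets List of `GRanges` read sets.
#' @param spans `GRanges` with `gene_id` (e.g. [gene_spans()]).
#' @return Integer matrix genes x replicates.
#' @export
gene_read_counts <- function(read_sets, spans) {
  m <- vapply(read_sets, function(r)
    GenomicRanges::countOverlaps(spans, r, ignore.strand = FALSE),
    integer(length(spans)))
  rownames(m) <- spans$gene_id
  colnames(m) <- names(read_sets) %||%
    paste0("rep", seq_along(read_sets))
  m
}
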