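#' Count reads overlapping introns
#'
#' A read increments an intron's count when it overlaps the intron by at
#' least `min_overlap` nucleotides on the same strand. A read contributes
#' to at most one intron: the one with the largest overlap (leftmost
#' intron on ties).
#'
#' @param reads `GRanges` of (trimmed) reads.
#' @param introns `GRanges` from [derive_introns()] with `intron_id`.
#' @param min_overlap Minimal overlap in nt (default 5).
#' @return Named integer vector of counts along `introns`.
#' @export
count_intron_reads <- function(reads, introns, min_overlap = 5L) {
  out <- stats::setNames(integer(length(introns)),
                         S4Vectors::mcols(introns)$intron_id)
  if (!length(reads) || !length(introns)) return(out)
  hits <- GenomicRanges::findOverlaps(reads, introns,
                                      minoverlap = min_overlap,
                                      ignore.strand = FALSE)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::ranges(reads)[q], GenomicRanges::ranges(introns)[s]))
  # per read: keep largest overlap, leftmost intron start on ties
  o <- order(q, -ov, BiocGenerics::start(introns)[s])
  first <- !duplicated(q[o])
  sel <- s[o][first]
  tab <- tabulate(sel, nbins = length(introns))
  out[] <- tab
  out
}

#' Median-of-ratios size factors and normalized counts
#'
#' The DESeq median-of-ratios estimator: per sample, the median over genes
#' of the ratio of the gene's count to its geometric mean across samples;
#' genes with a zero count in any sample are excluded from the median.
#'
#' @param counts Numeric matrix, genes x samples.
#' @return List with `size_factors` (per sample) and `normalized`
#'   (counts divided by their sample's factor).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- rowMeans(log(counts))
  if (!any(is.finite(lg)))
    stopf("no gene has nonzero counts in every sample")
  sf <- apply(counts, 2, function(x)
    exp(median((log(x) - lg)[is.finite(lg)])))
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Classify introns as CLIP+/CLIP- from read counts
#'
#' Per experiment, the CLIP+ rule holds when the iCLIP count is at least
#' `fold` times the matched control count, or, when the control has no
#' read, when the iCLIP count is at least `min_reads`. An intron is
#' `CLIP_plus` when the rule holds in at least `k` experiments,
#' `CLIP_minus` when its count is less than or equal to the control count
#' in every experiment, and `neither` otherwise. `support` is the number
#' of experiments meeting the CLIP+ rule (the `support == 3` stratum is
#' the stringent "CLIP++" set).
#'
#' Counts are compared raw (no depth scaling) by default, matching the
#' published rule; `control_scale` rescales the control columns (e.g. the
#' experiment/control depth ratio) for a sensitivity analysis.
#'
#' @param counts Integer matrix, introns x experiments (iCLIP).
#' @param controls Integer matrix, introns x experiments (matched
#'   controls, same dimensions).
#' @param fold Enrichment fold (default 5).
#' @param min_reads Minimal reads when the control is empty (default 5).
#' @param k Experiments required for CLIP+ (default 2).
#' @param control_scale Multiplier(s) applied to the control columns
#'   before comparison (default 1: raw counts).
#' @return data.frame `intron_id` (rownames of `counts`, when present),
#'   `status` factor (`CLIP_plus`, `CLIP_minus`, `neither`), `support`.
#' @export
classify_introns <- function(counts, controls, fold = 5, min_reads = 5L,
                             k = 2L, control_scale = 1) {
  counts <- as.matrix(counts); controls <- as.matrix(controls)
  controls <- sweep(controls, 2, rep_len(control_scale, ncol(controls)),
                    "*")
  if (!identical(dim(counts), dim(controls)))
    stopf("counts and controls must have identical dimensions")
  plus_rule <- (controls > 0 & counts >= fold * controls) |
    (controls == 0 & counts >= min_reads)
  support <- rowSums(plus_rule)
  minus_rule <- rowSums(counts <= controls) == ncol(counts)
  status <- ifelse(support >= k, "CLIP_plus",
                   ifelse(minus_rule, "CLIP_minus", "neither"))
  # disjointness guard: a CLIP+ call wins (cannot co-occur when fold > 1
  # and min_reads >= 1, but keep the precedence explicit)
  data.frame(intron_id = rownames(counts) %||%
               sprintf("intron%d", seq_len(nrow(counts))),
             status = factor(status, levels = c("CLIP_plus", "CLIP_minus",
                                                "neither")),
             support = as.integer(support), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene-level expression filter
#'
#' Genes whose median-of-ratios normalized count falls below `min_norm`
#' in every sample are "not expressed"; their introns are dropped from the
#' classification universe.
#'
#' @param gene_counts Integer matrix, genes x RNA-seq samples.
#' @param min_norm Threshold on the mean normalized count (default 1).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(gene_counts, min_norm = 1) {
  nm <- size_factors(gene_counts)$normalized
  keep <- rowMeans(nm) >= min_norm
  rownames(gene_counts)[keep]
}

#' Splice-site strength scorer trained on the annotation
#'
#' Builds first-order position weight matrix log-odds scorers for the
#' donor (9-mer: 3 exonic + 6 intronic bases) and acceptor (23-mer: 20
#' intronic + 3 exonic bases) contexts, trained on the splice sites of the
#' supplied introns against a uniform background. The published
#' maximum-entropy parameterization can be plugged in as any function
#' with the same signature.
#'
#' @param introns `GRanges` of training introns.
#' @param genome `DNAStringSet`.
#' @param pseudocount Added to base counts (default 0.5).
#' @return Function `(donor_seqs, acceptor_seqs) -> list(ss5, ss3)` of
#'   numeric log2-odds scores; sequences with ambiguous bases score `NA`.
#' @export
train_splice_pwm <- function(introns, genome, pseudocount = 0.5) {
  ctx <- splice_contexts(introns, genome)
  mk <- function(seqs) {
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    cm <- cm[c("A", "C", "G", "T"), , drop = FALSE] + pseudocount
    log2(sweep(cm, 2, colSums(cm), "/") / 0.25)
  }
  pwm5 <- mk(ctx$donor); pwm3 <- mk(ctx$acceptor)
  score <- function(pwm, seqs) {
    vapply(seqs, function(s) {
      b <- strsplit(toupper(s), "")[[1]]
      if (length(b) != ncol(pwm) || !all(b %in% rownames(pwm)))
        return(NA_real_)
      sum(pwm[cbind(match(b, rownames(pwm)), seq_along(b))])
    }, 0, USE.NAMES = FALSE)
  }
  function(donor_seqs, acceptor_seqs)
    list(ss5 = score(pwm5, donor_seqs), ss3 = score(pwm3, acceptor_seqs))
}

# Strand-aware donor 9-mers and acceptor 23-mers of introns.
splice_contexts <- function(introns, genome) {
  ch <- as.character(GenomicRanges::seqnames(introns))
  minus <- as.character(BiocGenerics::strand(introns)) == "-"
  s <- BiocGenerics::start(introns); e <- BiocGenerics::end(introns)
  len <- stats::setNames(Biostrings::width(genome), names(genome))
  get <- function(chrom, from, to, rc) {
    from <- max(1L, from); to <- min(len[chrom], to)
    x <- Biostrings::subseq(genome[[chrom]], from, to)
    if (rc) x <- Biostrings::reverseComplement(x)
    as.character(x)
  }
  donor <- vapply(seq_along(introns), function(i) {
    if (!minus[i]) get(ch[i], s[i] - 3L, s[i] + 5L, FALSE)
    else get(ch[i], e[i] - 5L, e[i] + 3L, TRUE)
  }, "")
  acceptor <- vapply(seq_along(introns), function(i) {
    if (!minus[i]) get(ch[i], e[i] - 19L, e[i] + 3L, FALSE)
    else get(ch[i], s[i] - 3L, s[i] + 19L, TRUE)
  }, "")
  list(donor = donor, acceptor = acceptor)
}

#' Intron sequence features
#'
#' Length, GC fraction over the intron body, and donor/acceptor
#' splice-site strengths from a pluggable scorer.
#'
#' @param introns `GRanges` from [derive_introns()].
#' @param genome `DNAStringSet`.
#' @param ss_scorer Function `(donor_seqs, acceptor_seqs) -> list(ss5,
#'   ss3)`; default: [train_splice_pwm()] trained on `introns` themselves.
#' @return data.frame `intron_id`, `length`, `gc`, `ss5_score`,
#'   `ss3_score`.
#' @export
intron_features <- function(introns, genome, ss_scorer = NULL) {
  if (is.null(ss_scorer)) ss_scorer <- train_splice_pwm(introns, genome)
  ch <- as.character(GenomicRanges::seqnames(introns))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(introns), function(i)
    as.character(Biostrings::subseq(genome[[ch[i]]],
                                    BiocGenerics::start(introns)[i],
                                    BiocGenerics::end(introns)[i])), ""))
  gc <- Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)[, 1]
  ctx <- splice_contexts(introns, genome)
  sc <- ss_scorer(ctx$donor, ctx$acceptor)
  data.frame(intron_id = S4Vectors::mcols(introns)$intron_id,
             length = BiocGenerics::width(introns), gc = unname(gc),
             ss5_score = sc$ss5, ss3_score = sc$ss3,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare intron features between CLIP+ and CLIP- groups
#'
#' Two-sided Wilcoxon rank-sum test per feature, with group medians and
#' the direction of the difference.
#'
#' @param features data.frame from [intron_features()].
#' @param clip_plus,clip_minus Character vectors of intron ids.
#' @param feature_cols Feature columns to compare.
#' @return data.frame `feature`, `median_plus`, `median_minus`,
#'   `direction`, `p_value`.
#' @export
compare_intron_groups <- function(features, clip_plus, clip_minus,
                                  feature_cols = c("length", "gc",
                                                   "ss5_score",
                                                   "ss3_score")) {
  a <- features[features$intron_id %in% clip_plus, , drop = FALSE]
  b <- features[features$intron_id %in% clip_minus, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stopf("both groups must be non-empty")
  rows <- lapply(feature_cols, function(f) {
    x <- a[[f]]; y <- b[[f]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    p <- ranksum_test(x, y, alternative = "two.sided")
    mp <- median(x); mm <- median(y)
    data.frame(feature = f, median_plus = mp, median_minus = mm,
               direction = if (mp > mm) "plus_higher" else
                 if (mp < mm) "minus_higher" else "equal",
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
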