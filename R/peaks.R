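#' Trim reads to a fixed maximal length
#'
#' Clips each read's 3' end so its length is at most `L` nucleotides; the
#' strand-aware 5' coordinate is unchanged. Reads shorter than `L` are left
#' as they are.
#'
#' @param reads `GRanges` of mapped reads.
#' @param L Maximal read length after trimming (default 10 nt).
#' @return `GRanges` of trimmed reads.
#' @export
trim_reads <- function(reads, L = 10L) {
  stopifnot(L >= 1)
  GenomicRanges::resize(reads, width = pmin(BiocGenerics::width(reads), L),
                        fix = "start")
}

#' Extend cross-link points to fixed-length reads
#'
#' The simulator emits reads as single-nucleotide cross-link points (the
#' iCLIP truncation convention); the peak caller works on fixed-length
#' reads. This sets every read's width to exactly `L`, anchored at its 5'
#' end.
#'
#' @inheritParams trim_reads
#' @export
extend_reads <- function(reads, L = 10L) {
  stopifnot(L >= 1)
  GenomicRanges::resize(reads, width = L, fix = "start")
}

#' Randomization FDR table for one region
#'
#' For each coverage height h the false discovery rate is estimated as the
#' mean over `n_iter` randomizations (same number of reads with the same
#' lengths, placed uniformly at random in the region; reads may overlap) of
#' the number of positions with randomized coverage >= h, divided by the
#' number of positions with observed coverage >= h (floored at 1).
#'
#' @param read_starts Integer vector of read start positions, relative to
#'   the region (1-based).
#' @param read_lengths Integer vector of read lengths (recycled).
#' @param width Region width in nucleotides.
#' @param n_iter Number of randomizations.
#' @param seed Optional RNG seed.
#' @return data.frame with columns `height`, `obs_positions`,
#'   `rand_positions`, `fdr`. `fdr` is capped at 1 and monotonized to be
#'   non-increasing in height (running minimum; this cannot change the
#'   smallest height with `fdr < alpha`, which is what callers threshold
#'   on).
#' @export
peak_fdr_table <- function(read_starts, read_lengths, width, n_iter = 100L,
                           seed = NULL) {
  n <- length(read_starts)
  read_lengths <- rep_len(as.integer(read_lengths), n)
  obs <- coverage_vec(read_starts, read_lengths, width)
  hmax <- max(obs)
  if (hmax == 0L) return(data.frame(height = integer(), obs_positions =
    integer(), rand_positions = numeric(), fdr = numeric()))
  obs_ge <- positions_ge(obs, hmax)
  rand_ge <- numeric(hmax)
  with_seed_(seed, {
    maxstart <- pmax(width - read_lengths + 1L, 1L)
    for (it in seq_len(n_iter)) {
      starts <- 1L + floor(runif(n) * maxstart)
      rc <- coverage_vec(starts, read_lengths, width)
      rand_ge <- rand_ge + positions_ge(rc, hmax)
    }
  })
  rand_ge <- rand_ge / n_iter
  data.frame(height = seq_len(hmax), obs_positions = obs_ge,
             rand_positions = rand_ge,
             fdr = cummin(pmin(1, rand_ge / pmax(1, obs_ge))))
}

#' Call peaks in one gene region by randomization FDR
#'
#' Builds the coverage profile of the (trimmed) reads in the region,
#' estimates a per-height false discovery rate by uniform re-placement of
#' the same reads ([peak_fdr_table()]), takes the smallest height h* with
#' FDR below `alpha`, and reports maximal runs of positions with observed
#' coverage >= h* as peaks. The summit is the leftmost position of maximal
#' coverage within the run; the reported `fdr` is the FDR estimate at the
#' peak height.
#'
#' @param reads `GRanges` of reads, assumed on the gene's strand.
#' @param span `GRanges` of length 1: the gene region searched.
#' @param alpha FDR threshold (default 0.01).
#' @param n_iter Number of randomizations (default 100).
#' @param seed Optional RNG seed.
#' @param summit_on `"starts"` (default) places the summit at the leftmost
#'   position of maximal read 5'-end density within the run -- the
#'   cross-link point under the point-plus-extension read model;
#'   `"coverage"` uses the leftmost maximal-coverage position.
#' @return `GRanges` of peaks with metadata `summit`, `height`, `fdr`;
#'   empty when no reads fall in the region or no height reaches the
#'   threshold.
#' @export
call_peaks_gene <- function(reads, span, alpha = 0.01, n_iter = 100L,
                            seed = NULL,
                            summit_on = c("starts", "coverage")) {
  summit_on <- match.arg(summit_on)
  stopifnot(length(span) == 1L)
  width <- BiocGenerics::width(span)
  s0 <- BiocGenerics::start(span)
  strand <- as.character(BiocGenerics::strand(span))
  chrom <- as.character(GenomicRanges::seqnames(span))
  reads <- reads[as.character(GenomicRanges::seqnames(reads)) == chrom]
  if (strand %in% c("+", "-"))
    reads <- reads[as.character(BiocGenerics::strand(reads)) %in%
                     c(strand, "*")]
  empty <- GenomicRanges::GRanges(summit = integer(), height = integer(),
                                  fdr = numeric())
  if (!length(reads)) return(empty)
  rs <- BiocGenerics::start(reads) - s0 + 1L
  rl <- BiocGenerics::width(reads)
  keep <- rs + rl - 1L >= 1L & rs <= width
  rs <- rs[keep]; rl <- rl[keep]
  if (!length(rs)) return(empty)

  tab <- peak_fdr_table(rs, rl, width, n_iter = n_iter, seed = seed)
  ok <- which(tab$fdr < alpha)
  if (!length(ok)) return(empty)
  hstar <- tab$height[ok[1]]

  obs <- coverage_vec(rs, rl, width)
  r <- rle(obs >= hstar)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  ps <- starts[runs]; pe <- ends[runs]
  # strand-aware 5' ends of the reads (cross-link points)
  p5 <- if (strand == "-") rs + rl - 1L else rs
  cnt5 <- tabulate(p5[p5 >= 1L & p5 <= width], nbins = width)
  summit <- vapply(seq_along(ps), function(i) {
    seg5 <- cnt5[ps[i]:pe[i]]
    if (summit_on == "starts" && any(seg5 > 0))
      return(ps[i] + which.max(seg5) - 1L)
    seg <- obs[ps[i]:pe[i]]
    ps[i] + which.max(seg) - 1L
  }, 0L)
  height <- vapply(seq_along(ps), function(i) max(obs[ps[i]:pe[i]]), 0)
  fdr <- tab$fdr[pmin(height, nrow(tab))]
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(ps + s0 - 1L, pe + s0 - 1L), strand = strand,
    summit = as.integer(summit + s0 - 1L), height = as.integer(height),
    fdr = fdr)
}

#' Call peaks over all gene regions
#'
#' Assigns reads to same-strand gene spans, optionally removes reads
#' overlapping a mask of repeats and noncoding RNAs, and runs
#' [call_peaks_gene()] per gene. Each gene gets an independent seed derived
#' from `seed` so results do not depend on gene order.
#'
#' @param reads `GRanges` of (trimmed or extended) reads.
#' @param spans `GRanges` of gene regions with a `gene_id` column, e.g. from
#'   [gene_spans()].
#' @param mask Optional `GRanges`; reads overlapping it are dropped first.
#' @param alpha,n_iter,seed Passed to [call_peaks_gene()].
#' @return `GRanges` of peaks with an additional `gene_id` column.
#' @export
call_peaks <- function(reads, spans, mask = NULL, alpha = 0.01,
                       n_iter = 100L, seed = NULL) {
  if (!is.null(mask) && length(mask))
    reads <- reads[!IRanges::overlapsAny(reads, mask, ignore.strand = TRUE)]
  hits <- GenomicRanges::findOverlaps(reads, spans, ignore.strand = FALSE)
  out <- lapply(seq_along(spans), function(i) {
    ri <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    if (!length(ri)) return(NULL)
    p <- call_peaks_gene(reads[ri], spans[i], alpha = alpha,
                         n_iter = n_iter,
                         seed = derive_seed(seed, spans$gene_id[i]))
    if (!length(p)) return(NULL)
    S4Vectors::mcols(p)$gene_id <- spans$gene_id[i]
    p
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(GenomicRanges::GRanges(summit = integer(), height = integer(),
                                  fdr = numeric(), gene_id = character()))
  do.call(c, out)
}

#' Remove peaks overlapping control peaks
#'
#' A peak is removed when its interval overlaps a control peak by at least
#' one nucleotide on the same strand.
#'
#' @param peaks,control_peaks `GRanges` of peaks in the same coordinate
#'   space.
#' @return The retained subset of `peaks`.
#' @export
subtract_control <- function(peaks, control_peaks) {
  if (!length(control_peaks) || !length(peaks)) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, control_peaks, ignore.strand = FALSE)]
}

#' Consensus peaks across replicate experiments
#'
#' Finds regions supported by at least `k` of the experiment peak sets
#' (support means >= 1 nt same-strand overlap between peaks of different
#' sets; the merged region is the union of the contributing peaks), keeps
#' the pooled reads intersecting those regions, and re-calls peaks with
#' [call_peaks_gene()] restricted to each region. Output peaks carry a
#' `support` column: the number of experiment sets whose peaks overlap the
#' region.
#'
#' @param peak_sets List of `GRanges`, one per experiment.
#' @param all_reads `GRanges`: pooled reads from all experiments (already
#'   trimmed/extended).
#' @param k Minimal number of supporting experiments (default 2).
#' @param alpha,n_iter,seed Passed to the re-call.
#' @param spans Optional `GRanges` of gene regions (with `gene_id`). When
#'   given, the re-call randomizes the kept reads over the whole gene
#'   span (the published procedure re-runs the caller on pooled reads per
#'   gene) and only peaks overlapping a consensus region are returned.
#'   Without `spans`, the randomization is restricted to each merged
#'   region, which is very conservative for regions barely wider than a
#'   peak.
#' @return `GRanges` of consensus peaks with `summit`, `height`, `fdr`,
#'   `support` (and `gene_id` when present on the inputs).
#' @export
consensus_peaks <- function(peak_sets, all_reads, k = 2L, alpha = 0.01,
                            n_iter = 100L, seed = NULL, spans = NULL) {
  if (k > length(peak_sets))
    stopf("k = %d exceeds the number of peak sets (%d)", k,
          length(peak_sets))
  sets <- lapply(peak_sets, function(p) {
    p <- GenomicRanges::granges(p)
    GenomicRanges::reduce(p, ignore.strand = FALSE)
  })
  regions <- consensus_regions(sets, k)
  if (!length(regions))
    return(GenomicRanges::GRanges(summit = integer(), height = integer(),
                                  fdr = numeric(), support = integer()))
  # merged region = union of contributing peaks around each >=k core
  allp <- do.call(c, sets)
  contrib <- IRanges::overlapsAny(allp, regions, ignore.strand = FALSE)
  merged <- GenomicRanges::reduce(c(regions, allp[contrib]),
                                  ignore.strand = FALSE)
  merged <- merged[IRanges::overlapsAny(merged, regions,
                                        ignore.strand = FALSE)]
  support <- vapply(seq_along(merged), function(i) {
    sum(vapply(sets, function(s)
      any(IRanges::overlapsAny(s, merged[i], ignore.strand = FALSE)), TRUE))
  }, 0L)

  reads <- all_reads[IRanges::overlapsAny(all_reads, merged,
                                          ignore.strand = FALSE)]
  empty <- GenomicRanges::GRanges(summit = integer(), height = integer(),
                                  fdr = numeric(), support = integer())
  if (is.null(spans)) {
    out <- lapply(seq_along(merged), function(i) {
      p <- call_peaks_gene(reads, merged[i], alpha = alpha,
                           n_iter = n_iter,
                           seed = derive_seed(seed, sprintf("region%d", i)))
      if (!length(p)) return(NULL)
      S4Vectors::mcols(p)$support <- support[i]
      p
    })
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) return(empty)
    return(do.call(c, out))
  }
  keep <- IRanges::overlapsAny(spans, merged, ignore.strand = FALSE)
  out <- lapply(which(keep), function(i) {
    ri <- IRanges::overlapsAny(reads, spans[i], ignore.strand = FALSE)
    p <- call_peaks_gene(reads[ri], spans[i], alpha = alpha,
                         n_iter = n_iter,
                         seed = derive_seed(seed, spans$gene_id[i]))
    if (!length(p)) return(NULL)
    if (!is.null(spans$gene_id))
      S4Vectors::mcols(p)$gene_id <- spans$gene_id[i]
    p
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  out <- do.call(c, out)
  hit <- GenomicRanges::findOverlaps(out, merged, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  keep_idx <- unique(q)
  sup <- vapply(keep_idx, function(i) max(support[s[q == i]]), 0L)
  out <- out[keep_idx]
  S4Vectors::mcols(out)$support <- as.integer(sup)
  out
}

# Positions covered by >= k of the reduced per-set peak ranges, same strand.
consensus_regions <- function(sets, k) {
  allp <- do.call(c, sets)
  if (!length(allp)) return(GenomicRanges::GRanges())
  dj <- GenomicRanges::disjoin(allp, ignore.strand = FALSE)
  hit <- vapply(sets, function(s)
    IRanges::overlapsAny(dj, s, ignore.strand = FALSE),
    logical(length(dj)))
  n <- rowSums(matrix(hit, nrow = length(dj)))
  GenomicRanges::reduce(dj[n >= k], ignore.strand = FALSE)
}
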