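# Shared in-code fixtures. Everything is generated; no files on disk.

gr <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

# A tiny two-gene annotation built by hand:
#  gA (+, chr1): tA1 exons 101-200, 301-400, 501-600 (CDS 151-550)
#                tA2 exons 101-200, 501-600           (CDS 151-550)
#  gB (-, chr1): tB1 exons 1001-1100, 1301-1400       (CDS 1051-1350)
tiny_annotation <- function() {
  ex <- c(
    gr("chr1", c(101, 301, 501), c(200, 400, 600), "+",
       transcript_id = "tA1", gene_id = "gA"),
    gr("chr1", c(101, 501), c(200, 600), "+",
       transcript_id = "tA2", gene_id = "gA"),
    gr("chr1", c(1001, 1301), c(1100, 1400), "-",
       transcript_id = "tB1", gene_id = "gB"))
  cds <- c(
    gr("chr1", 151, 550, "+", transcript_id = "tA1"),
    gr("chr1", 151, 550, "+", transcript_id = "tA2"),
    gr("chr1", 1051, 1350, "-", transcript_id = "tB1"))
  tx_annotation(ex, cds = cds)
}

# Cached small simulated world shared by read-level tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sim_genome(15, seed = 101L)
    cache
  }
})

# Exact two-sided rank-sum p-value by enumeration of all group
# assignments (oracle; small n only).
rank_sum_exact <- function(x, y, alternative = "two.sided") {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats <- apply(combs, 2, function(i) sum(rank(pooled)[i]))
  mu <- nx * (n + 1) / 2
  switch(alternative,
         two.sided = mean(abs(stats - mu) >= abs(obs - mu)),
         greater = mean(stats >= obs),
         less = mean(stats <= obs))
}
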