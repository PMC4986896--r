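test_that("summit annotation follows the CDS > UTR5 > UTR3 > intron rule", {
  ann <- tiny_annotation()
  mk <- function(pos, strand = "+")
    gr("chr1", pos, pos, strand, summit = as.integer(pos))
  # CDS of representative transcript
  expect_equal(as.character(annotate_peaks(mk(350), ann)$category),
               "CDS_exon")
  # 5'UTR (upstream of CDS start 151 on +)
  expect_equal(as.character(annotate_peaks(mk(120), ann)$category),
               "UTR5")
  # 3'UTR (downstream of CDS end 550)
  expect_equal(as.character(annotate_peaks(mk(580), ann)$category),
               "UTR3")
  # intron of tA1 AND tA2 -> intron
  expect_equal(as.character(annotate_peaks(mk(250), ann)$category),
               "intron")
  # intergenic
  expect_equal(as.character(annotate_peaks(mk(5000), ann)$category),
               "intergenic")
  # minus strand gene: 1380 is upstream of CDS end in transcription
  # sense (5'UTR spans 1351..1400 on tB1)
  expect_equal(as.character(annotate_peaks(mk(1380, "-"),
                                           ann)$category), "UTR5")

  # isoform precedence: 350 is exonic (CDS) in tA1 but intronic in tA2;
  # annotate with tA2 as representative still must return CDS_exon
  expect_equal(as.character(annotate_peaks(mk(450), ann)$category),
               "intron")  # intronic in every isoform
})

test_that("category fractions match a brute-force per-summit scan", {
  sim <- shared_sim()
  ann <- sim$annotation
  set.seed(31)
  spans <- gene_spans(ann)
  idx <- sample(length(spans), 200, replace = TRUE)
  pos <- BiocGenerics::start(spans)[idx] +
    floor(runif(200) * BiocGenerics::width(spans)[idx])
  pk <- gr(as.character(GenomicRanges::seqnames(spans))[idx], pos, pos,
           as.character(BiocGenerics::strand(spans))[idx],
           summit = as.integer(pos))
  got <- annotate_peaks(pk, ann)$category
  # brute force: per summit, evaluate category on the (only) transcript
  rep <- select_representative(ann)
  brute <- vapply(seq_along(pk), function(i) {
    g <- spans$gene_id[idx[i]]
    clipmap:::summit_category(ann, rep$transcript_id[rep$gene_id == g],
                              pos[i])
  }, "")
  expect_equal(as.character(got), brute)
  fr <- category_fractions(got)
  expect_equal(sum(fr), 1)
})

test_that("summit association is boundary-inclusive and symmetric", {
  mk <- function(pos, strand = "+")
    gr("chr1", pos, pos, strand, summit = as.integer(pos))
  a <- mk(100)
  expect_true(associate_peaks(a, mk(110), tol = 10))
  expect_false(associate_peaks(a, mk(111), tol = 10))
  expect_false(associate_peaks(a, mk(110, "-"), tol = 10))

  set.seed(17)
  pa <- sample(1:2000, 300, replace = TRUE)
  pb <- sample(1:2000, 300, replace = TRUE)
  A <- gr("chr1", pa, pa, "+", summit = as.integer(pa))
  B <- gr("chr1", pb, pb, "+", summit = as.integer(pb))
  got <- associate_peaks(A, B, tol = 10)
  brute <- vapply(pa, function(x) any(abs(x - pb) <= 10), TRUE)
  expect_equal(got, brute)
  # symmetry: every associated A peak has a B partner associated back
  gotB <- associate_peaks(B, A, tol = 10)
  for (i in which(got)) {
    j <- which(abs(pb - pa[i]) <= 10)
    expect_true(all(gotB[j] | !gotB[j]))  # partners exist
    expect_true(any(gotB[j]))
  }
})

test_that("motif fractions match a naive scan", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "AAAATTTTAAAAAAAAAAAA",
    paste(rep("ACGT", 200), collapse = ""))))
  pk <- gr("chr1", 10, 10, "+", summit = 10L)
  r <- motif_fraction(pk, list(t4 = "TTTT"), genome)
  expect_equal(r$fractions$all, 1)

  # empty set -> NA fractions
  r0 <- motif_fraction(GenomicRanges::GRanges(summit = integer()),
                       list(t4 = "TTTT"), genome)
  expect_true(is.na(r0$fractions$all[1]))

  # degenerate motif on random windows equals a regex-style scan
  set.seed(23)
  pos <- sample(30:700, 150)
  pks <- gr("chr1", pos, pos, "+", summit = as.integer(pos))
  rr <- motif_fraction(pks, list(m = "GYGT"), genome)
  win <- clipmap:::summit_windows(pks, genome, 20L)
  brute <- vapply(as.character(win), function(s)
    grepl("G[CT]GT", s), TRUE, USE.NAMES = FALSE)
  expect_equal(unname(rr$by_peak[, "m"]), brute)

  # minus-strand windows are reverse-complemented (sense-oriented)
  pkm <- gr("chr1", 10, 10, "-", summit = 10L)
  rm_ <- motif_fraction(pkm, list(a4 = "AAAA"), genome)
  expect_equal(rm_$fractions$all, 1)  # revcomp of T-run is A-run
})

test_that("PWM motif matching honors the score threshold", {
  pwm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["G", ] <- 1  # motif GGGG
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 30), "GGGG", strrep("A", 30))))
  hit <- motif_fraction(gr("chr1", 32, 32, "+", summit = 32L),
                        list(g4 = pwm), genome)
  miss <- motif_fraction(gr("chr1", 15, 15, "+", summit = 15L),
                         list(g4 = pwm), genome)
  expect_equal(hit$fractions$all, 1)
  expect_equal(miss$fractions$all, 0)
})

test_that("exon-end profile recovers planted -24 sites with a flat null", {
  sim <- shared_sim()
  ann <- sim$annotation
  sites <- sim_binding_sites(sim, 60, classes = c(exon_minus24 = 1),
                             seed = 6)
  off <- mapply(function(tx, s) genomic_to_transcriptomic(ann, tx, s),
                sites$transcript_id, sites$summit)
  pk <- GenomicRanges::GRanges(sites$transcript_id,
                               IRanges::IRanges(off + 1L, width = 1L),
                               strand = "+",
                               summit = as.integer(off + 1L))
  prof <- exon_end_profile(pk, internal_exons_tx(ann), max_dist = 35,
                           n_random = 100, seed = 3)
  expect_equal(prof$n_peaks, nrow(sites))
  m <- prof$dist3
  expect_equal(m$distance[which.max(m$observed)], 24)
  # with no truncation, null integrates to the observed mass
  full <- exon_end_profile(pk, internal_exons_tx(ann),
                           max_dist = 3000, n_random = 50, seed = 3)
  expect_equal(sum(full$dist3$observed), 1)
  expect_lt(abs(sum(full$dist3$null) - 1), 0.02)
})

test_that("uniform summits give observed approximately equal to null", {
  sim <- shared_sim()
  ann <- sim$annotation
  ie <- internal_exons_tx(ann)
  set.seed(41)
  idx <- sample(nrow(ie), 300, replace = TRUE)
  pos <- ie$tx_start[idx] +
    floor(runif(300) * (ie$tx_end[idx] - ie$tx_start[idx] + 1L))
  pk <- GenomicRanges::GRanges(ie$transcript_id[idx],
                               IRanges::IRanges(pos, width = 1L),
                               strand = "+", summit = as.integer(pos))
  prof <- exon_end_profile(pk, ie, max_dist = 35, n_random = 200,
                           seed = 4)
  m <- prof$dist5
  mc_sd <- sqrt(pmax(m$null, 1e-4) / prof$n_peaks)
  expect_lt(max(abs(m$observed - m$null) / (mc_sd + 1e-9)), 4.5)
})

test_that("intron boundary histogram is strand-aware", {
  sim <- shared_sim()
  ii <- sim$introns
  # one peak 30 nt after the 5' splice site of a minus-strand intron
  im <- ii[as.character(BiocGenerics::strand(ii)) == "-"][1]
  pos <- BiocGenerics::end(im) - 30L
  pk <- gr(as.character(GenomicRanges::seqnames(im)), pos, pos, "-",
           summit = as.integer(pos))
  h <- intron_boundary_histogram(pk, ii)
  expect_equal(h$from5$distance, 30L)
  expect_equal(h$from5$count, 1L)
  # empty set -> empty histograms
  h0 <- intron_boundary_histogram(GenomicRanges::GRanges(
    summit = integer()), ii)
  expect_equal(nrow(h0$from5), 0L)
})

test_that("replicate correlation is scale-invariant with QC gate", {
  set.seed(51)
  x <- rpois(200, 50)
  m <- cbind(a = x, b = 2L * x)
  r <- replicate_correlation(m)
  expect_equal(unname(r["a", "b"]), 1)
  noisy <- cbind(a = x, b = rpois(200, 50))
  expect_warning(replicate_correlation(noisy, warn_below = 0.99),
                 "QC gate")
  # deep shared-strength replicates correlate > 0.95
  sim <- shared_sim()
  sites <- sim_binding_sites(sim, 40, strength = 50, seed = 8)
  reads <- sim_iclip(sim, sites, depth_factors = c(1, 1), seed = 9,
                     n_replicates = 2)
  counts <- gene_read_counts(reads, gene_spans(sim$annotation))
  rr <- replicate_correlation(counts, warn_below = NULL)
  expect_gt(rr[1, 2], 0.95)
})
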