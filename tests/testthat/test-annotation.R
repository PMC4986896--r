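test_that("representative transcript selection maximizes CDS length", {
  ann <- tiny_annotation()
  rep <- select_representative(ann)
  # tA1 has CDS across 3 exons (50+100+50 = 200) vs tA2 (50+50 = 100)
  expect_equal(rep$transcript_id[rep$gene_id == "gA"], "tA1")
  expect_equal(rep$transcript_id[rep$gene_id == "gB"], "tB1")

  # tie on CDS length: longer spliced length, then smallest id
  ex <- c(gr("chr1", c(1, 101), c(50, 150), "+",
             transcript_id = "tB", gene_id = "g"),
          gr("chr1", c(1, 101), c(50, 160), "+",
             transcript_id = "tC", gene_id = "g"),
          gr("chr1", 1, 30, "+", transcript_id = "tA", gene_id = "g"))
  cds <- c(gr("chr1", 1, 40, "+", transcript_id = "tB"),
           gr("chr1", 1, 40, "+", transcript_id = "tC"),
           gr("chr1", 1, 20, "+", transcript_id = "tA"))
  a2 <- tx_annotation(ex, cds = cds)
  expect_equal(select_representative(a2)$transcript_id, "tC")

  # exact tie on CDS and spliced length: lexicographically smallest id
  ex3 <- c(gr("chr1", 1, 100, "+", transcript_id = "tB", gene_id = "g"),
           gr("chr1", 201, 300, "+", transcript_id = "tC",
              gene_id = "g"))
  cds3 <- c(gr("chr1", 1, 50, "+", transcript_id = "tB"),
            gr("chr1", 201, 250, "+", transcript_id = "tC"))
  expect_equal(select_representative(tx_annotation(ex3, cds3))$transcript_id,
               "tB")
})

test_that("representative selection matches brute-force argmax", {
  set.seed(20)
  for (rep_i in 1:5) {
    ntx <- sample(2:5, 1)
    cdsl <- sample(50:500, ntx) * 2L
    exl <- list(); cdl <- list()
    for (t in seq_len(ntx)) {
      s <- 1000 * t
      exl[[t]] <- gr("chr1", s, s + 999, "+",
                     transcript_id = sprintf("t%d", t), gene_id = "g")
      cdl[[t]] <- gr("chr1", s, s + cdsl[t] - 1, "+",
                     transcript_id = sprintf("t%d", t))
    }
    ann <- tx_annotation(do.call(c, exl), do.call(c, cdl))
    want <- sprintf("t%d", which.max(cdsl))
    expect_equal(select_representative(ann)$transcript_id, want)
  }
})

test_that("intron derivation tiles exon gaps", {
  ann <- tiny_annotation()
  ii <- derive_introns(ann, "tA1")
  expect_equal(length(ii), 2L)
  expect_equal(BiocGenerics::start(ii), c(201L, 401L))
  expect_equal(BiocGenerics::end(ii), c(300L, 500L))
  expect_equal(ii$intron_id, c("tA1.I1", "tA1.I2"))

  # single-exon transcript -> no introns
  one <- tx_annotation(gr("chr1", 1, 500, "+", transcript_id = "t1",
                          gene_id = "g"))
  expect_equal(length(derive_introns(one, "t1")), 0L)

  # minus strand: intron rank follows transcription order
  ib <- derive_introns(ann, "tB1")
  expect_equal(length(ib), 1L)
  expect_equal(ib$intron_id, "tB1.I1")
  expect_equal(BiocGenerics::start(ib), 1101L)
})

test_that("exons and introns tile the gene span (interval algebra)", {
  sim <- shared_sim()
  rep <- select_representative(sim$annotation)
  for (t in rep$transcript_id[1:10]) {
    e <- transcript_exons(sim$annotation, t)
    ii <- derive_introns(sim$annotation, t)
    u <- GenomicRanges::reduce(c(GenomicRanges::granges(e),
                                 GenomicRanges::granges(ii)))
    expect_equal(length(u), 1L)  # contiguous
    expect_equal(BiocGenerics::width(u),
                 sum(BiocGenerics::width(e)) +
                   sum(BiocGenerics::width(ii)))
  }
})

test_that("coordinate conversion round-trips and handles strand", {
  ann <- tiny_annotation()
  # + strand: genomic 350 is offset 100 (exon1) + 50 into exon2
  expect_equal(genomic_to_transcriptomic(ann, "tA1", 350), 149L)
  # 5' end of first exon is offset 0
  expect_equal(genomic_to_transcriptomic(ann, "tA1", 101), 0L)
  # intronic -> NA
  expect_true(is.na(genomic_to_transcriptomic(ann, "tA1", 250)))
  # minus strand: transcript 5' end is the genomic end
  expect_equal(genomic_to_transcriptomic(ann, "tB1", 1400), 0L)
  expect_equal(transcriptomic_to_genomic(ann, "tB1", 0L), 1400L)
  # inverse bounds are enforced
  expect_error(transcriptomic_to_genomic(ann, "tB1", 200L), "offset")
  expect_error(transcriptomic_to_genomic(ann, "tB1", -1L), "offset")
})

test_that("overlapping exons are rejected", {
  expect_error(tx_annotation(
    gr("chr1", c(1, 50), c(100, 150), "+",
       transcript_id = c("t", "t"), gene_id = c("g", "g"))),
    "overlapping")
})

test_that("transcript sequence extraction is spliced and stranded", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 500), collapse = "")))
  ann <- tiny_annotation()
  s <- transcript_seq(ann, genome, "tA1")
  expect_equal(length(s), 300L)
  sb <- transcript_seq(ann, genome, "tB1")
  # manually: revcomp of concatenated exon sequences
  e1 <- Biostrings::subseq(genome[["chr1"]], 1001, 1100)
  e2 <- Biostrings::subseq(genome[["chr1"]], 1301, 1400)
  want <- Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(as.character(e1), as.character(e2))))
  expect_equal(as.character(sb), as.character(want))
})

test_that("GTF writer round-trips through rtracklayer", {
  sim <- shared_sim()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(sim$annotation, path)
  back <- read_annotation(path)
  expect_equal(nrow(back$transcripts), nrow(sim$annotation$transcripts))
  m <- match(back$transcripts$transcript_id,
             sim$annotation$transcripts$transcript_id)
  expect_equal(back$transcripts$spliced_length,
               sim$annotation$transcripts$spliced_length[m])
  expect_equal(back$transcripts$cds_length,
               sim$annotation$transcripts$cds_length[m])
})

test_that("representative transcriptome FASTA/BED12 writers emit all genes", {
  sim <- shared_sim()
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  rep <- write_transcriptome(sim$annotation, sim$genome, fasta = fa,
                             bed = bed)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_setequal(names(seqs), rep$transcript_id)
  m <- match(names(seqs), sim$annotation$transcripts$transcript_id)
  expect_equal(unname(Biostrings::width(seqs)),
               sim$annotation$transcripts$spliced_length[m])
  b12 <- rtracklayer::import(bed, format = "bed")
  expect_equal(length(b12), nrow(rep))
})
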