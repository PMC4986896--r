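#' Gene model container
#'
#' A `tx_annotation` bundles an exon table with per-transcript and per-gene
#' metadata. Exons are held as a [GenomicRanges::GRanges] (1-based, closed,
#' the Bioconductor convention; BED/GTF conversion is delegated to
#' rtracklayer) with `transcript_id` and `gene_id` metadata columns.
#' Coding-sequence (CDS) boundaries, when annotated, are stored per
#' transcript as genomic coordinates; `cds_length` is the summed exonic
#' overlap with the CDS interval and `spliced_length` the summed exon width.
#'
#' @param exons `GRanges` of exons with metadata columns `transcript_id` and
#'   `gene_id`.
#' @param cds optional `GRanges` of CDS segments with a `transcript_id`
#'   column; collapsed to one genomic interval per transcript.
#' @param biotype named character vector mapping `gene_id` to one of
#'   `"protein_coding"`, `"noncoding"`, `"repeat"`; genes absent from the
#'   vector default to `"protein_coding"`.
#' @return An object of class `tx_annotation` with components `exons`
#'   (GRanges), `transcripts` (data.frame) and `genes` (data.frame).
#' @export
tx_annotation <- function(exons, cds = NULL, biotype = NULL) {
  stopifnot(is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id))
    stopf("exons need transcript_id and gene_id metadata columns")
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)

  tx_id <- as.character(mc <- S4Vectors::mcols(exons)$transcript_id)
  by_tx <- split(seq_along(exons), tx_id)

  # invariants: one chrom/strand per transcript, exons disjoint
  for (ids in by_tx) {
    e <- exons[ids]
    if (length(unique(as.character(GenomicRanges::seqnames(e)))) != 1L ||
        length(unique(as.character(BiocGenerics::strand(e)))) != 1L)
      stopf("transcript %s spans multiple chromosomes or strands",
            S4Vectors::mcols(e)$transcript_id[1])
    if (length(e) > 1L && !all(BiocGenerics::start(e)[-1] >
                               BiocGenerics::end(e)[-length(e)]))
      stopf("transcript %s has overlapping exons",
            S4Vectors::mcols(e)$transcript_id[1])
  }

  tx <- data.frame(
    transcript_id = names(by_tx),
    gene_id = vapply(by_tx, function(i)
      as.character(S4Vectors::mcols(exons)$gene_id[i[1]]), ""),
    chrom = vapply(by_tx, function(i)
      as.character(GenomicRanges::seqnames(exons)[i[1]]), ""),
    strand = vapply(by_tx, function(i)
      as.character(BiocGenerics::strand(exons)[i[1]]), ""),
    spliced_length = vapply(by_tx, function(i)
      sum(BiocGenerics::width(exons[i])), 0),
    cds_start = NA_integer_, cds_end = NA_integer_, cds_length = 0,
    row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(cds) && length(cds)) {
    cid <- as.character(S4Vectors::mcols(cds)$transcript_id)
    cs <- tapply(BiocGenerics::start(cds), cid, min)
    ce <- tapply(BiocGenerics::end(cds), cid, max)
    m <- match(tx$transcript_id, names(cs))
    tx$cds_start <- as.integer(cs[m])
    tx$cds_end <- as.integer(ce[m])
    has <- !is.na(tx$cds_start)
    tx$cds_length[has] <- vapply(which(has), function(j) {
      e <- exons[by_tx[[tx$transcript_id[j]]]]
      sum(pmax(0, pmin(BiocGenerics::end(e), tx$cds_end[j]) -
                   pmax(BiocGenerics::start(e), tx$cds_start[j]) + 1L))
    }, 0)
  }

  gn <- unique(tx[, c("gene_id", "chrom", "strand")])
  gspan <- tapply(seq_along(exons),
                  as.character(S4Vectors::mcols(exons)$gene_id),
                  function(i) c(min(BiocGenerics::start(exons[i])),
                                max(BiocGenerics::end(exons[i]))))
  gn$start <- vapply(gspan[gn$gene_id], `[`, 0, 1L)
  gn$end <- vapply(gspan[gn$gene_id], `[`, 0, 2L)
  gn$biotype <- "protein_coding"
  if (!is.null(biotype)) {
    m <- match(gn$gene_id, names(biotype))
    gn$biotype[!is.na(m)] <- unname(biotype[m[!is.na(m)]])
  }
  rownames(gn) <- NULL

  structure(list(exons = exons, transcripts = tx, genes = gn),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("tx_annotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), length(x$exons)))
  invisible(x)
}

#' Read a gene annotation from GTF
#'
#' Imports `exon` and `CDS` records via rtracklayer (converting GTF's
#' 1-based closed coordinates) and assembles a [tx_annotation]. The
#' `gene_biotype` (or `gene_type`) attribute, when present, fills the gene
#' biotype partition used to mask noncoding/repeat genes.
#'
#' @param path GTF file path.
#' @return A [tx_annotation].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  bt <- NULL
  btcol <- intersect(c("gene_biotype", "gene_type"),
                     colnames(S4Vectors::mcols(gr)))
  if (length(btcol)) {
    g <- !duplicated(gr$gene_id) & !is.na(gr$gene_id)
    bt <- stats::setNames(as.character(S4Vectors::mcols(gr)[[btcol[1]]][g]),
                          gr$gene_id[g])
    bt[is.na(bt)] <- "protein_coding"
  }
  tx_annotation(ex, cds = if (length(cds)) cds else NULL, biotype = bt)
}

#' Write an annotation as GTF
#'
#' @param ann A [tx_annotation].
#' @param path Output GTF path.
#' @export
write_annotation <- function(ann, path) {
  ex <- ann$exons
  S4Vectors::mcols(ex)$type <- "exon"
  tx <- ann$transcripts
  has <- !is.na(tx$cds_start)
  if (any(has)) {
    cds <- GenomicRanges::GRanges(
      tx$chrom[has],
      IRanges::IRanges(tx$cds_start[has], tx$cds_end[has]),
      strand = tx$strand[has],
      type = "CDS", transcript_id = tx$transcript_id[has],
      gene_id = tx$gene_id[has])
    # clip CDS to exon structure so the GTF round-trips
    cdsl <- lapply(seq_along(cds), function(i) {
      e <- transcript_exons(ann, cds$transcript_id[i])
      out <- GenomicRanges::pintersect(
        e, rep(cds[i], length(e)), drop.nohit.ranges = TRUE)
      S4Vectors::mcols(out) <- NULL
      S4Vectors::mcols(out)$type <- "CDS"
      S4Vectors::mcols(out)$transcript_id <- cds$transcript_id[i]
      S4Vectors::mcols(out)$gene_id <- cds$gene_id[i]
      # transcription-order phase: bases needed to reach a codon start
      o <- order(BiocGenerics::start(out))
      if (as.character(BiocGenerics::strand(out))[1] == "-") o <- rev(o)
      cum <- cumsum(c(0L, BiocGenerics::width(out)[o]))
      S4Vectors::mcols(out)$phase[o] <-
        (3L - cum[seq_along(o)] %% 3L) %% 3L
      out
    })
    ex2 <- ex
    S4Vectors::mcols(ex2) <-
      S4Vectors::mcols(ex2)[, c("type", "transcript_id", "gene_id")]
    S4Vectors::mcols(ex2)$phase <- NA_integer_
    all <- c(ex2, do.call(c, cdsl))
  } else {
    S4Vectors::mcols(ex) <-
      S4Vectors::mcols(ex)[, c("transcript_id", "gene_id", "type")]
    all <- ex
  }
  m <- match(all$gene_id, ann$genes$gene_id)
  S4Vectors::mcols(all)$gene_biotype <- ann$genes$biotype[m]
  S4Vectors::mcols(all)$source <- "clipmap"
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Exons of one transcript, sorted 5' to 3'
#'
#' @param ann A [tx_annotation].
#' @param transcript_id Transcript identifier.
#' @return `GRanges` of exons in transcription order (reversed genomic order
#'   on the minus strand).
#' @export
transcript_exons <- function(ann, transcript_id) {
  e <- ann$exons[S4Vectors::mcols(ann$exons)$transcript_id == transcript_id]
  if (!length(e)) stopf("unknown transcript: %s", transcript_id)
  e <- e[order(BiocGenerics::start(e))]
  if (as.character(BiocGenerics::strand(e))[1] == "-") e <- rev(e)
  e
}

#' Select the representative transcript per gene
#'
#' Keeps for each gene the transcript with the longest CDS. Ties are broken
#' by longer spliced length, then by lexicographically smallest transcript
#' id; genes with no annotated CDS fall back to the longest spliced
#' transcript (the same tie-break applies).
#'
#' @param ann A [tx_annotation].
#' @return data.frame with columns `gene_id`, `transcript_id`.
#' @export
select_representative <- function(ann) {
  tx <- ann$transcripts
  if (!nrow(tx)) stopf("annotation has no transcripts")
  pick <- vapply(split(seq_len(nrow(tx)), tx$gene_id), function(i) {
    t <- tx[i, ]
    o <- order(-t$cds_length, -t$spliced_length, t$transcript_id)
    t$transcript_id[o[1]]
  }, "")
  data.frame(gene_id = names(pick), transcript_id = unname(pick),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive introns from a transcript's exon structure
#'
#' An n-exon transcript yields n-1 introns that exactly tile the gaps
#' between consecutive exons. Intron ids are `<transcript_id>.I<k>` with k
#' counted in transcription order (the intron after the k-th exon).
#'
#' @param ann A [tx_annotation].
#' @param transcript_ids Transcripts to process; default: representative
#'   transcript of every gene.
#' @return `GRanges` of introns with metadata `intron_id`, `transcript_id`,
#'   `gene_id`, `upstream_exon`, `downstream_exon` (indices in transcription
#'   order).
#' @export
derive_introns <- function(ann, transcript_ids = NULL) {
  if (is.null(transcript_ids))
    transcript_ids <- select_representative(ann)$transcript_id
  out <- lapply(transcript_ids, function(txid) {
    e <- transcript_exons(ann, txid)  # errors on overlap via constructor
    n <- length(e)
    if (n < 2L) return(GenomicRanges::GRanges())
    strand <- as.character(BiocGenerics::strand(e))[1]
    # genomic order for gap arithmetic
    eg <- e[order(BiocGenerics::start(e))]
    s <- BiocGenerics::end(eg)[-n] + 1L
    t <- BiocGenerics::start(eg)[-1] - 1L
    if (any(t < s)) stopf("transcript %s exons abut or overlap", txid)
    rank <- if (strand == "-") rev(seq_len(n - 1L)) else seq_len(n - 1L)
    gr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(e))[1],
      IRanges::IRanges(s, t), strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      intron_id = sprintf("%s.I%d", txid, rank),
      transcript_id = txid,
      gene_id = as.character(S4Vectors::mcols(e)$gene_id)[1],
      upstream_exon = rank, downstream_exon = rank + 1L)
    gr[order(rank)]
  })
  out <- out[vapply(out, length, 0L) > 0]
  if (!length(out)) return(GenomicRanges::GRanges(
    intron_id = character(), transcript_id = character(),
    gene_id = character()))
  do.call(c, out)
}

#' Genomic to transcriptomic coordinate conversion
#'
#' Maps genomic positions to 0-based offsets from the transcript 5' end
#' along the spliced sequence. Intronic or out-of-transcript positions map
#' to `NA`.
#'
#' @param ann A [tx_annotation].
#' @param transcript_id Transcript identifier.
#' @param pos Integer vector of genomic positions (1-based).
#' @return Integer vector of 0-based offsets, `NA` where non-exonic.
#' @export
genomic_to_transcriptomic <- function(ann, transcript_id, pos) {
  e <- transcript_exons(ann, transcript_id)
  minus <- as.character(BiocGenerics::strand(e))[1] == "-"
  w <- BiocGenerics::width(e)
  off0 <- cumsum(c(0L, w[-length(w)]))  # offset of each exon's 5' base
  out <- rep(NA_integer_, length(pos))
  for (i in seq_along(e)) {
    s <- BiocGenerics::start(e)[i]; t <- BiocGenerics::end(e)[i]
    hit <- !is.na(pos) & pos >= s & pos <= t
    out[hit] <- off0[i] + if (minus) t - pos[hit] else pos[hit] - s
  }
  out
}

#' Transcriptomic to genomic coordinate conversion
#'
#' Inverse of [genomic_to_transcriptomic()]: a 0-based offset along the
#' spliced transcript maps back to the genomic base it came from.
#'
#' @param ann A [tx_annotation].
#' @param transcript_id Transcript identifier.
#' @param offset Integer vector of 0-based transcriptomic offsets.
#' @return Integer vector of genomic positions (1-based).
#' @export
transcriptomic_to_genomic <- function(ann, transcript_id, offset) {
  e <- transcript_exons(ann, transcript_id)
  minus <- as.character(BiocGenerics::strand(e))[1] == "-"
  w <- BiocGenerics::width(e)
  L <- sum(w)
  if (any(!is.na(offset) & (offset < 0 | offset >= L)))
    stopf("offset outside [0, %d) for transcript %s", L, transcript_id)
  off0 <- cumsum(c(0L, w[-length(w)]))
  out <- rep(NA_integer_, length(offset))
  for (i in seq_along(e)) {
    s <- BiocGenerics::start(e)[i]; t <- BiocGenerics::end(e)[i]
    hit <- !is.na(offset) & offset >= off0[i] & offset < off0[i] + w[i]
    d <- offset[hit] - off0[i]
    out[hit] <- if (minus) t - d else s + d
  }
  out
}

#' Spliced transcript sequence
#'
#' @param ann A [tx_annotation].
#' @param genome `DNAStringSet` of chromosome sequences (names must match
#'   seqnames used in the annotation).
#' @param transcript_id Transcript identifier.
#' @return A `DNAString`, reverse-complemented on the minus strand so the
#'   sequence reads 5' to 3'.
#' @export
transcript_seq <- function(ann, genome, transcript_id) {
  e <- transcript_exons(ann, transcript_id)
  chrom <- as.character(GenomicRanges::seqnames(e))[1]
  if (!chrom %in% names(genome)) stopf("chromosome %s not in genome", chrom)
  eg <- e[order(BiocGenerics::start(e))]
  parts <- Biostrings::extractAt(
    genome[[chrom]],
    IRanges::IRanges(BiocGenerics::start(eg), BiocGenerics::end(eg)))
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (as.character(BiocGenerics::strand(e))[1] == "-")
    s <- Biostrings::reverseComplement(s)
  s
}

#' Write the representative transcriptome as FASTA and BED12
#'
#' @param ann A [tx_annotation].
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param fasta,bed Output paths (either may be `NULL` to skip).
#' @return Invisibly, the representative table from
#'   [select_representative()].
#' @export
write_transcriptome <- function(ann, genome, fasta = NULL, bed = NULL) {
  rep <- select_representative(ann)
  if (!is.null(fasta)) {
    seqs <- Biostrings::DNAStringSet(lapply(
      rep$transcript_id, function(t) transcript_seq(ann, genome, t)))
    names(seqs) <- rep$transcript_id
    Biostrings::writeXStringSet(seqs, fasta)
  }
  if (!is.null(bed)) {
    grl <- GenomicRanges::GRangesList(lapply(rep$transcript_id, function(t) {
      e <- transcript_exons(ann, t)
      S4Vectors::mcols(e) <- NULL
      e[order(BiocGenerics::start(e))]
    }))
    names(grl) <- rep$transcript_id
    blk <- rtracklayer::asBED(grl)
    rtracklayer::export(blk, bed, format = "bed")
  }
  invisible(rep)
}

#' Gene spans as GRanges
#'
#' @param ann A [tx_annotation].
#' @param biotype Restrict to these biotypes (default: protein_coding, the
#'   calling universe; noncoding and repeat genes form the read mask).
#' @return `GRanges` with a `gene_id` column.
#' @export
gene_spans <- function(ann, biotype = "protein_coding") {
  g <- ann$genes[ann$genes$biotype %in% biotype, ]
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}
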