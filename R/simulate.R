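#' Simulate a genome and gene annotation with two intron classes
#'
#' Generates a single synthetic chromosome carrying `n_genes` multi-exon
#' protein-coding genes (alternating strands, one transcript per gene, CDS
#' from the middle of the first to the middle of the last exon). Introns
#' are drawn from two classes: "optimal" introns are longer, AT-richer and
#' carry strong consensus splice sites; "suboptimal" introns are shorter
#' (`subopt_len_factor` times the optimal mean), GC-richer and carry
#' weakened splice-site sequences (consensus position weight matrices mixed
#' with the uniform distribution, invariant GT..AG dinucleotides kept).
#' These are the properties the intron-level group comparisons are designed
#' to recover.
#'
#' All output is a pure function of the configuration and `seed`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed RNG seed.
#' @param n_exons Range of exon counts per gene (sampled uniformly).
#' @param exon_meanlog,exon_sdlog Log-normal exon length parameters
#'   (default: median 150 nt).
#' @param intron_meanlog,intron_sdlog Log-normal length parameters of
#'   optimal introns (default: median 1500 nt).
#' @param subopt_len_factor Multiplier on the optimal median length for
#'   suboptimal introns (default 0.5).
#' @param p_suboptimal Probability an intron is suboptimal (default 0.3).
#' @param gc_optimal,gc_suboptimal,gc_exon,gc_intergenic GC fractions.
#' @param ss_weak_mix Uniform-mixture weight applied to splice-site PWMs of
#'   suboptimal introns (default 0.5).
#' @param min_intron Minimal intron length (default 70 nt; must be >= 30 so
#'   donor and acceptor contexts do not collide).
#' @param min_exon Minimal exon length (default 40 nt).
#' @param intergenic Gap between genes (default 500 nt).
#' @param chrom Chromosome name.
#' @return List with `genome` (`DNAStringSet`), `annotation`
#'   ([tx_annotation]), `introns` (`GRanges` from [derive_introns()]),
#'   `intron_classes` (data.frame `intron_id`, `class`) and `params`.
#' @export
sim_genome <- function(n_genes, seed = 1L, n_exons = c(4L, 8L),
                       exon_meanlog = log(150), exon_sdlog = 0.35,
                       intron_meanlog = log(1500), intron_sdlog = 0.5,
                       subopt_len_factor = 0.5, p_suboptimal = 0.3,
                       gc_optimal = 0.40, gc_suboptimal = 0.55,
                       gc_exon = 0.50, gc_intergenic = 0.40,
                       ss_weak_mix = 0.5, min_intron = 70L, min_exon = 40L,
                       intergenic = 500L, chrom = "chrSim") {
  stopifnot(n_genes >= 1)
  if (min_intron < 30L)
    stopf("min_intron must be >= 30 (splice-site contexts collide)")
  if (exp(intron_meanlog) * subopt_len_factor < min_intron)
    stopf("suboptimal intron median below min_intron: infeasible lengths")

  pwm_donor <- donor_pwm()
  pwm_acc <- acceptor_pwm()
  pwm_donor_w <- weaken_pwm(pwm_donor, ss_weak_mix, fixed = 4:5)
  pwm_acc_w <- weaken_pwm(pwm_acc, ss_weak_mix, fixed = 19:20)

  with_seed_(seed, {
    seqs <- character(0)
    exon_rows <- list()
    tx_rows <- list()
    class_rows <- list()
    pos <- 1L
    for (g in seq_len(n_genes)) {
      gid <- sprintf("g%04d", g)
      txid <- paste0(gid, ".t1")
      strand <- if (g %% 2L) "+" else "-"
      ne_rng <- seq(n_exons[1], n_exons[2])
      ne <- ne_rng[sample.int(length(ne_rng), 1L)]
      elen <- pmax(min_exon, round(stats::rlnorm(ne, exon_meanlog,
                                                 exon_sdlog)))
      subopt <- runif(ne - 1L) < p_suboptimal
      imedlog <- ifelse(subopt, intron_meanlog + log(subopt_len_factor),
                        intron_meanlog)
      ilen <- pmax(min_intron, round(stats::rlnorm(ne - 1L, imedlog,
                                                   intron_sdlog)))
      # sense-strand sequence pieces, transcription order
      epieces <- lapply(elen, random_dna, gc = gc_exon)
      ipieces <- lapply(seq_len(ne - 1L), function(k)
        random_dna(ilen[k], gc = if (subopt[k]) gc_suboptimal
                   else gc_optimal))
      for (k in seq_len(ne - 1L)) {
        don <- sample_pwm(if (subopt[k]) pwm_donor_w else pwm_donor)
        acc <- sample_pwm(if (subopt[k]) pwm_acc_w else pwm_acc)
        e <- epieces[[k]]
        substr(e, nchar(e) - 2L, nchar(e)) <- substr(don, 1L, 3L)
        epieces[[k]] <- e
        i <- ipieces[[k]]
        substr(i, 1L, 6L) <- substr(don, 4L, 9L)
        substr(i, nchar(i) - 19L, nchar(i)) <- substr(acc, 1L, 20L)
        ipieces[[k]] <- i
        e2 <- epieces[[k + 1L]]
        substr(e2, 1L, 3L) <- substr(acc, 21L, 23L)
        epieces[[k + 1L]] <- e2
      }
      sense <- paste0(unlist(Map(function(e, i) paste0(e, i),
                                 epieces, c(ipieces, list(""))),
                             use.names = FALSE), collapse = "")
      glen <- nchar(sense)
      # exon spans along the sense sequence (1-based)
      a <- cumsum(c(1L, head_lens(elen, ilen)))
      b <- a + elen - 1L
      if (strand == "+") {
        gs <- pos + a - 1L; ge <- pos + b - 1L
        segment <- sense
      } else {
        gs <- pos + (glen - b); ge <- pos + (glen - a)
        segment <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sense)))
      }
      # CDS: middle of first exon to middle of last exon (sense coords)
      cds_a <- a[1] + elen[1] %/% 2L
      cds_b <- a[ne] + elen[ne] %/% 2L
      cds_g <- if (strand == "+") pos + c(cds_a, cds_b) - 1L
               else pos + glen - c(cds_b, cds_a)
      exon_rows[[g]] <- data.frame(start = gs, end = ge, strand = strand,
                                   transcript_id = txid, gene_id = gid)
      tx_rows[[g]] <- data.frame(transcript_id = txid,
                                 cds_start = cds_g[1], cds_end = cds_g[2])
      # subopt is indexed in transcription order, matching intron-id ranks
      class_rows[[g]] <- data.frame(
        intron_id = sprintf("%s.I%d", txid, seq_len(ne - 1L)),
        class = ifelse(subopt, "suboptimal", "optimal"))
      seqs <- c(seqs, segment,
                random_dna(intergenic, gc = gc_intergenic))
      pos <- pos + glen + intergenic
    }
    ex <- do.call(rbind, exon_rows)
    txi <- do.call(rbind, tx_rows)
    exons <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
      transcript_id = ex$transcript_id, gene_id = ex$gene_id)
    cds <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(txi$cds_start, txi$cds_end),
      strand = ex$strand[match(txi$transcript_id, ex$transcript_id)],
      transcript_id = txi$transcript_id)
    genome <- Biostrings::DNAStringSet(paste0(seqs, collapse = ""))
    names(genome) <- chrom
    ann <- tx_annotation(exons, cds = cds)
    list(genome = genome, annotation = ann,
         introns = derive_introns(ann),
         intron_classes = do.call(rbind, class_rows),
         params = list(n_genes = n_genes, seed = seed,
                       p_suboptimal = p_suboptimal,
                       subopt_len_factor = subopt_len_factor,
                       gc_optimal = gc_optimal,
                       gc_suboptimal = gc_suboptimal))
  })
}

head_lens <- function(elen, ilen) {
  n <- length(elen)
  if (n < 2L) return(integer(0))
  elen[-n] + ilen
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Donor 9-mer (last 3 exonic + first 6 intronic) base frequencies,
# approximating the human U2 consensus MAG|GTRAGT.
donor_pwm <- function() {
  m <- matrix(c(
    0.33, 0.37, 0.18, 0.12,   # -3
    0.60, 0.13, 0.12, 0.15,   # -2
    0.08, 0.04, 0.81, 0.07,   # -1
    0.00, 0.00, 1.00, 0.00,   # +1 G
    0.00, 0.00, 0.00, 1.00,   # +2 T
    0.59, 0.03, 0.35, 0.03,   # +3
    0.71, 0.08, 0.12, 0.09,   # +4
    0.07, 0.06, 0.82, 0.05,   # +5
    0.16, 0.16, 0.20, 0.48),  # +6
    nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

# Acceptor 23-mer (last 20 intronic incl. polypyrimidine tract and AG, plus
# first 3 exonic bases).
acceptor_pwm <- function() {
  ppt <- c(0.09, 0.33, 0.10, 0.48)  # generic pyrimidine-rich column
  cols <- replicate(16, ppt, simplify = FALSE)           # -20..-5
  cols <- c(cols, list(c(0.25, 0.30, 0.20, 0.25)))       # -4
  cols <- c(cols, list(c(0.05, 0.65, 0.05, 0.25)))       # -3 (C-rich)
  cols <- c(cols, list(c(1.00, 0.00, 0.00, 0.00)))       # -2 A
  cols <- c(cols, list(c(0.00, 0.00, 1.00, 0.00)))       # -1 G
  cols <- c(cols, list(c(0.25, 0.20, 0.40, 0.15)))       # +1..+3 exonic
  cols <- c(cols, list(c(0.30, 0.20, 0.25, 0.25)))
  cols <- c(cols, list(c(0.25, 0.25, 0.25, 0.25)))
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# Mix PWM columns with the uniform distribution; `fixed` columns (the
# invariant GT / AG dinucleotides) are left untouched.
weaken_pwm <- function(pwm, mix, fixed = integer(0)) {
  out <- (1 - mix) * pwm + mix * 0.25
  if (length(fixed)) out[, fixed] <- pwm[, fixed]
  out
}

sample_pwm <- function(pwm) {
  paste(apply(pwm, 2, function(p)
    sample(rownames(pwm), 1L, prob = p)), collapse = "")
}

#' Plant binding sites on a simulated annotation
#'
#' Places `n_sites` binding-site summits in the requested sequence contexts
#' of representative transcripts. Intronic site classes are preferentially
#' coupled to suboptimal introns (probability `couple_suboptimal`), so the
#' CLIP+ versus CLIP- feature comparison is recoverable by design.
#'
#' Context classes: `exon_CDS`, `5UTR`, `3UTR` (uniform within the
#' feature); `intron_5ss_proximal` (25-100 nt downstream of the intron 5'
#' splice site); `intron_3ss` (within 25 nt of the 3' splice site);
#' `exon_minus24` (exactly 24 nt upstream of an internal exon 3' end, the
#' canonical exon-junction-complex deposition position).
#'
#' @param sim Output of [sim_genome()].
#' @param n_sites Number of sites.
#' @param classes Named numeric vector of class weights.
#' @param strength Expected reads per site per unit-depth replicate.
#' @param couple_suboptimal Probability that an intronic site is placed in
#'   a suboptimal-class intron when one exists in the chosen gene.
#' @param seed RNG seed.
#' @return data.frame (one row per site): `site_id`, `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `summit` (genomic, 1-based),
#'   `class`, `strength`, `intron_id` (`NA` for exonic classes).
#' @export
sim_binding_sites <- function(sim, n_sites,
                              classes = c(exon_CDS = 0.45, `5UTR` = 0.05,
                                          `3UTR` = 0.10,
                                          intron_5ss_proximal = 0.15,
                                          intron_3ss = 0.10,
                                          exon_minus24 = 0.15),
                              strength = 30, couple_suboptimal = 0.8,
                              seed = 1L) {
  ann <- sim$annotation
  rep <- select_representative(ann)
  introns <- sim$introns
  icls <- sim$intron_classes
  with_seed_(seed, {
    cls <- sample(names(classes), n_sites, replace = TRUE,
                  prob = classes / sum(classes))
    rows <- lapply(seq_len(n_sites), function(i) {
      for (try in 1:50) {
        r <- rep[sample.int(nrow(rep), 1L), ]
        site <- place_site(ann, introns, icls, r, cls[i],
                           couple_suboptimal)
        if (!is.null(site)) {
          site$site_id <- sprintf("site%04d", i)
          site$class <- cls[i]
          site$strength <- strength
          return(site)
        }
      }
      NULL
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    out <- do.call(rbind, rows)
    out[, c("site_id", "gene_id", "transcript_id", "chrom", "strand",
            "summit", "class", "strength", "intron_id")]
  })
}

place_site <- function(ann, introns, icls, r, class, couple_suboptimal) {
  txid <- r$transcript_id
  tx <- ann$transcripts[ann$transcripts$transcript_id == txid, ]
  e <- transcript_exons(ann, txid)
  strand <- tx$strand
  base <- data.frame(gene_id = r$gene_id, transcript_id = txid,
                     chrom = tx$chrom, strand = strand,
                     summit = NA_integer_, intron_id = NA_character_,
                     stringsAsFactors = FALSE)
  if (class %in% c("exon_CDS", "5UTR", "3UTR")) {
    if (is.na(tx$cds_start)) return(NULL)
    L <- tx$spliced_length
    co <- sort(genomic_to_transcriptomic(ann, txid,
                                         c(tx$cds_start, tx$cds_end)))
    rng <- switch(class,
      exon_CDS = c(co[1], co[2]),
      `5UTR` = c(0L, co[1] - 1L),
      `3UTR` = c(co[2] + 1L, L - 1L))
    if (rng[2] < rng[1]) return(NULL)
    off <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    base$summit <- transcriptomic_to_genomic(ann, txid, off)
    return(base)
  }
  if (class == "exon_minus24") {
    if (length(e) < 3L) return(NULL)
    internal <- e[-c(1L, length(e))]
    internal <- internal[BiocGenerics::width(internal) >= 30L]
    if (!length(internal)) return(NULL)
    x <- internal[sample.int(length(internal), 1L)]
    base$summit <- if (strand == "+") BiocGenerics::end(x) - 24L
                   else BiocGenerics::start(x) + 24L
    return(base)
  }
  # intronic classes
  ii <- introns[S4Vectors::mcols(introns)$transcript_id == txid]
  if (!length(ii)) return(NULL)
  cl <- icls$class[match(S4Vectors::mcols(ii)$intron_id, icls$intron_id)]
  pick_sub <- runif(1) < couple_suboptimal && any(cl == "suboptimal")
  cand <- if (pick_sub) ii[cl == "suboptimal"] else ii
  iv <- cand[sample.int(length(cand), 1L)]
  w <- BiocGenerics::width(iv)
  base$intron_id <- S4Vectors::mcols(iv)$intron_id
  if (class == "intron_5ss_proximal") {
    if (w < 60L) return(NULL)
    off <- sample(25:min(100L, w - 25L), 1L)
    base$summit <- if (strand == "+") BiocGenerics::start(iv) + off
                   else BiocGenerics::end(iv) - off
  } else {  # intron_3ss
    d <- sample(0:min(24L, w - 1L), 1L)
    base$summit <- if (strand == "+") BiocGenerics::end(iv) - d
                   else BiocGenerics::start(iv) + d
  }
  base
}

#' Simulate iCLIP replicate read sets
#'
#' Emits cross-link reads as single-nucleotide points (extend with
#' [extend_reads()] before peak calling). Per replicate, each planted site
#' contributes `Poisson(strength x depth)` reads jittered around the summit
#' (normal, sd `jitter_sd`), on top of a uniform background over gene spans
#' at `background_rate` reads per nucleotide (scaled by depth). The default
#' depth factors `(1, 1, 0.5)` give one half-depth replicate, exercising
#' the 2-of-3 consensus. A control run (`control = TRUE`) keeps the
#' background but damps sites by `control_site_factor` (default 0:
#' removed) and scales overall depth by `control_depth` (default 0.2,
#' emulating the roughly fivefold shallower control libraries typical of
#' iCLIP designs).
#'
#' @param sim Output of [sim_genome()] (for gene spans and chromosome
#'   bounds).
#' @param sites data.frame from [sim_binding_sites()]; may be `NULL` or
#'   empty.
#' @param background_rate Background reads per nucleotide of gene span.
#' @param n_replicates Number of replicates (default 3).
#' @param control Logical; simulate the control experiment.
#' @param depth_factors Per-replicate depth multipliers (recycled).
#' @param jitter_sd Positional jitter sd in nt (default 2; 0 allowed).
#' @param control_site_factor Multiplier on site strength in the control.
#' @param control_depth Depth multiplier applied to control replicates.
#' @param seed RNG seed.
#' @return List of `GRanges` (width-1 reads), one per replicate.
#' @export
sim_iclip <- function(sim, sites, background_rate = 0.01,
                      n_replicates = 3L, control = FALSE,
                      depth_factors = c(1, 1, 0.5), jitter_sd = 2,
                      control_site_factor = 0, control_depth = 0.2,
                      seed = 1L) {
  ann <- sim$annotation
  spans <- gene_spans(ann)
  chrlen <- Biostrings::width(sim$genome)
  names(chrlen) <- names(sim$genome)
  depth <- rep_len(depth_factors, n_replicates) *
    (if (control) control_depth else 1)
  sfac <- if (control) control_site_factor else 1
  with_seed_(seed, {
    lapply(seq_len(n_replicates), function(r) {
      ch <- character(0); po <- integer(0); st <- character(0)
      if (!is.null(sites) && nrow(sites)) {
        n <- rpois(nrow(sites), sites$strength * depth[r] * sfac)
        if (sum(n)) {
          idx <- rep(seq_len(nrow(sites)), n)
          jit <- if (jitter_sd > 0) round(rnorm(sum(n), 0, jitter_sd))
                 else integer(sum(n))
          ch <- sites$chrom[idx]
          po <- sites$summit[idx] + jit
          st <- sites$strand[idx]
        }
      }
      nb <- rpois(length(spans),
                  background_rate * BiocGenerics::width(spans) * depth[r])
      if (sum(nb)) {
        idx <- rep(seq_along(spans), nb)
        u <- floor(runif(sum(nb)) * BiocGenerics::width(spans)[idx])
        ch <- c(ch, as.character(GenomicRanges::seqnames(spans))[idx])
        po <- c(po, BiocGenerics::start(spans)[idx] + as.integer(u))
        st <- c(st, as.character(BiocGenerics::strand(spans))[idx])
      }
      if (!length(po))
        return(GenomicRanges::GRanges())
      po <- pmax(1L, pmin(po, chrlen[ch]))
      gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(po, width = 1L),
                                   strand = st)
      GenomicRanges::sort(gr, ignore.strand = TRUE)
    })
  })
}

#' Write / read cross-link reads as BED6
#'
#' One record per read, `score = 1`; names are sequential read ids.
#'
#' @param reads `GRanges` of reads.
#' @param path BED file path.
#' @export
write_reads_bed <- function(reads, path) {
  r <- reads
  S4Vectors::mcols(r) <- NULL
  S4Vectors::mcols(r)$name <- sprintf("read%d", seq_along(r))
  S4Vectors::mcols(r)$score <- 1L
  rtracklayer::export(r, path, format = "bed")
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}
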