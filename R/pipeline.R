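#' Default pipeline configuration
#'
#' Returns the full parameter set of the analysis with its default values:
#' peak-call FDR `alpha = 0.01`, read trim length 10 nt, consensus
#' `k = 2` of 3, summit association tolerance 10 nt, CLIP+ fold 5 and
#' minimum 5 reads, expression floor 1 normalized count, differential
#' filters `m = 10` percent, `r = 0.95`, `e = 10` reads, dpir change
#' cutoff 5, co-regulation threshold 10, RNA-map bin 5 nt over 50-nt
#' windows, and 5-bp minimal intron overlap.
#'
#' @param ... Overrides (named).
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    alpha = 0.01, trim = 10L, n_iter = 100L, consensus_k = 2L,
    assoc_tol = 10L, fold = 5, min_reads = 5L, expr_min = 1,
    m = 10, r = 0.95, e = 10L, dpir_cutoff = 5, coreg_threshold = 10,
    bin = 5L, window = 50L, min_overlap = 5L, motif_window = 20L,
    simulate = list(n_genes = 60L, n_sites = 80L, site_strength = 30,
                    background_rate = 0.01, n_replicates = 3L,
                    n_cassette = 40L, n_ir = 60L, delta = 20,
                    splice_depth = 500),
    paths = list())
  ov <- list(...)
  for (n in names(ov)) cfg[[n]] <- ov[[n]]
  bad <- vapply(cfg[c("alpha", "trim", "consensus_k", "assoc_tol", "fold",
                      "min_reads", "expr_min", "m", "r", "e",
                      "dpir_cutoff", "coreg_threshold", "bin", "window",
                      "min_overlap")], function(x) !is.numeric(x) || x <= 0,
                TRUE)
  if (any(bad)) stopf("non-positive parameter(s): %s",
                      paste(names(bad)[bad], collapse = ", "))
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()] defaults.
#'
#' @param path YAML file path.
#' @return Named list of parameters.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (n in names(user)) {
    if (is.list(user[[n]]) && is.list(cfg[[n]])) {
      for (m in names(user[[n]])) cfg[[n]][[m]] <- user[[n]][[m]]
    } else cfg[[n]] <- user[[n]]
  }
  cfg
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate (when no input paths are configured) -> callpeaks ->
#' annotate -> introns -> splicing -> integrate, writing per-stage TSV/BED
#' outputs and a JSON manifest (parameters, seed, input checksums) under
#' `out_dir`. Reruns with the same configuration and seed are
#' byte-identical. A stage failure aborts with the stage name.
#'
#' @param config List from [default_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created).
#' @param stages Subset of stages to run (default: all, in order).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "callpeaks", "annotate",
                                    "introns", "splicing", "integrate")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  for (st in stages) {
    message(sprintf("[clipmap] stage %s ...", st))
    t0 <- Sys.time()
    res <- tryCatch(
      switch(st,
             simulate = stage_simulate(config, out_dir, res),
             callpeaks = stage_callpeaks(config, out_dir, res),
             annotate = stage_annotate(config, out_dir, res),
             introns = stage_introns(config, out_dir, res),
             splicing = stage_splicing(config, out_dir, res),
             integrate = stage_integrate(config, out_dir, res),
             stopf("unknown stage: %s", st)),
      error = function(e)
        stopf("stage '%s' failed: %s", st, conditionMessage(e)))
    message(sprintf("[clipmap] stage %s done (%.1f s)", st,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  manifest <- list(package = "clipmap",
                   version = as.character(utils::packageVersion("clipmap")),
                   seed = config$seed, stages = stages,
                   parameters = config[setdiff(names(config), "paths")],
                   inputs = lapply(config$paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Write peaks as BED6+3
#'
#' Columns: chrom, start (0-based), end, name, score (= height), strand,
#' summit (1-based), fdr, support.
#'
#' @param peaks Peak `GRanges`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::end(peaks),
    name = sprintf("peak%d", seq_along(peaks)),
    score = mc$height, strand = as.character(BiocGenerics::strand(peaks)),
    summit = mc$summit, fdr = signif(mc$fdr, 6),
    support = if (!is.null(mc$support)) mc$support else NA)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

stage_simulate <- function(cfg, out_dir, res) {
  sc <- cfg$simulate
  sim <- sim_genome(sc$n_genes, seed = derive_seed(cfg$seed, "genome"))
  sites <- sim_binding_sites(sim, sc$n_sites, strength = sc$site_strength,
                             seed = derive_seed(cfg$seed, "sites"))
  reads <- sim_iclip(sim, sites, background_rate = sc$background_rate,
                     n_replicates = sc$n_replicates,
                     seed = derive_seed(cfg$seed, "iclip"))
  ctrl <- sim_iclip(sim, sites, background_rate = sc$background_rate,
                    n_replicates = sc$n_replicates, control = TRUE,
                    seed = derive_seed(cfg$seed, "control"))
  Biostrings::writeXStringSet(sim$genome,
                              file.path(out_dir, "genome.fa"))
  write_annotation(sim$annotation, file.path(out_dir, "annotation.gtf"))
  for (i in seq_along(reads))
    write_reads_bed(reads[[i]],
                    file.path(out_dir, sprintf("iclip_rep%d.bed", i)))
  for (i in seq_along(ctrl))
    write_reads_bed(ctrl[[i]],
                    file.path(out_dir, sprintf("control_rep%d.bed", i)))
  write_tsv(sites, file.path(out_dir, "truth_sites.tsv"))

  ev <- sim_cassette_events(sim, sc$n_cassette,
                            seed = derive_seed(cfg$seed, "events"))
  tr_cas <- sim_truth_effects(round(sc$n_cassette / 2),
                              sc$n_cassette - round(sc$n_cassette / 2),
                              type = "cassette", delta = sc$delta,
                              two_sided = TRUE,
                              seed = derive_seed(cfg$seed, "cas_truth"))
  tr_cas$event_id <- ev$event_id[seq_len(nrow(tr_cas))]
  tr_ir <- sim_truth_effects(round(sc$n_ir / 3), sc$n_ir -
                               round(sc$n_ir / 3),
                             type = "intron_retention", delta = 15,
                             psi_range = c(2, 30),
                             seed = derive_seed(cfg$seed, "ir_truth"))
  truth <- rbind(tr_cas, tr_ir)
  counts <- sim_splice_counts(truth, depth = sc$splice_depth,
                              seed = derive_seed(cfg$seed, "counts"))
  write_tsv(truth, file.path(out_dir, "truth_splicing.tsv"))
  write_tsv(counts, file.path(out_dir, "splice_counts.tsv"))
  write_tsv(ev, file.path(out_dir, "cassette_events.tsv"))
  # RNA-seq style gene counts (3 + 3 samples) feeding the expression filter
  gc <- with_seed_(derive_seed(cfg$seed, "genecounts"), {
    mu <- stats::rlnorm(nrow(sim$annotation$genes), log(200), 1)
    m <- vapply(seq_len(6L), function(j) rpois(length(mu), mu),
                integer(length(mu)))
    rownames(m) <- sim$annotation$genes$gene_id
    colnames(m) <- c(sprintf("control_%d", 1:3), sprintf("kd_%d", 1:3))
    m
  })
  write_tsv(data.frame(gene_id = rownames(gc), gc),
            file.path(out_dir, "gene_counts.tsv"))
  res$sim <- sim; res$sites <- sites; res$reads <- reads
  res$control_reads <- ctrl; res$events <- ev; res$truth <- truth
  res$splice_counts <- counts; res$gene_counts <- gc
  res
}

stage_callpeaks <- function(cfg, out_dir, res) {
  ann <- res$sim$annotation
  spans <- gene_spans(ann)
  reads <- lapply(res$reads, extend_reads, L = cfg$trim)
  ctrl <- lapply(res$control_reads, extend_reads, L = cfg$trim)
  sets <- lapply(seq_along(reads), function(i) {
    p <- call_peaks(reads[[i]], spans, alpha = cfg$alpha,
                    n_iter = cfg$n_iter,
                    seed = derive_seed(cfg$seed, sprintf("peaks%d", i)))
    cp <- call_peaks(ctrl[[i]], spans, alpha = cfg$alpha,
                     n_iter = cfg$n_iter,
                     seed = derive_seed(cfg$seed, sprintf("ctrlp%d", i)))
    subtract_control(p, cp)
  })
  pooled <- do.call(c, reads)
  common <- consensus_peaks(sets, pooled, k = cfg$consensus_k,
                            alpha = cfg$alpha, n_iter = cfg$n_iter,
                            seed = derive_seed(cfg$seed, "consensus"),
                            spans = spans)
  for (i in seq_along(sets))
    write_peaks_bed(sets[[i]],
                    file.path(out_dir, sprintf("peaks_rep%d.bed", i)))
  write_peaks_bed(common, file.path(out_dir, "peaks_common.bed"))
  res$peak_sets <- sets; res$common_peaks <- common
  res
}

stage_annotate <- function(cfg, out_dir, res) {
  ann <- res$sim$annotation
  peaks <- annotate_peaks(res$common_peaks, ann)
  fr <- category_fractions(peaks)
  write_tsv(data.frame(category = names(fr), fraction = fr),
            file.path(out_dir, "peak_categories.tsv"))
  motifs <- list(T_rich = "TTTTT", GAAGAA_like = "GARGAR")
  mf <- motif_fraction(peaks, motifs, res$sim$genome,
                       window = cfg$motif_window)
  write_tsv(mf$fractions, file.path(out_dir, "motif_fractions.tsv"))
  ibh <- intron_boundary_histogram(
    peaks[S4Vectors::mcols(peaks)$category == "intron"],
    res$sim$introns)
  write_tsv(ibh$from5, file.path(out_dir, "intron_hist_from5.tsv"))
  write_tsv(ibh$to3, file.path(out_dir, "intron_hist_to3.tsv"))
  counts <- gene_read_counts(res$reads, gene_spans(ann))
  rc <- replicate_correlation(counts, warn_below = NULL)
  write_tsv(as.data.frame(rc), file.path(out_dir, "replicate_cor.tsv"))
  res$annotated_peaks <- peaks
  res
}

stage_introns <- function(cfg, out_dir, res) {
  introns <- res$sim$introns
  # point reads are extended to the trim length before overlap counting
  reads <- lapply(res$reads, extend_reads, L = cfg$trim)
  ctrl <- lapply(res$control_reads, extend_reads, L = cfg$trim)
  cnt <- vapply(reads, count_intron_reads, integer(length(introns)),
                introns = introns, min_overlap = cfg$min_overlap)
  ccnt <- vapply(ctrl, count_intron_reads, integer(length(introns)),
                 introns = introns, min_overlap = cfg$min_overlap)
  rownames(cnt) <- rownames(ccnt) <- S4Vectors::mcols(introns)$intron_id
  expressed <- expressed_genes(res$gene_counts, min_norm = cfg$expr_min)
  in_expr <- S4Vectors::mcols(introns)$gene_id %in% expressed
  cnt <- cnt[in_expr, , drop = FALSE]
  ccnt <- ccnt[in_expr, , drop = FALSE]
  cls <- classify_introns(cnt, ccnt, fold = cfg$fold,
                          min_reads = cfg$min_reads, k = cfg$consensus_k)
  feats <- intron_features(introns, res$sim$genome)
  tab <- cbind(cls, feats[match(cls$intron_id, feats$intron_id),
                          -1, drop = FALSE])
  write_tsv(tab, file.path(out_dir, "intron_clip.tsv"))
  res$intron_counts <- cnt; res$intron_status <- cls
  res$intron_feats <- feats
  res
}

stage_splicing <- function(cfg, out_dir, res) {
  calls <- differential_events(res$splice_counts, m = cfg$m, r = cfg$r,
                               e = cfg$e,
                               seed = derive_seed(cfg$seed, "diff"))
  write_tsv(calls, file.path(out_dir, "differential_calls.tsv"))
  if (any(calls$accepted))
    write_tsv(direction_bias_test(calls),
              file.path(out_dir, "direction_bias.tsv"))
  res$calls <- calls
  res
}

stage_integrate <- function(cfg, out_dir, res) {
  cas <- res$calls[res$calls$type == "cassette", , drop = FALSE]
  rm <- build_rna_map(cas, res$events, res$common_peaks,
                      window = cfg$window, bin = cfg$bin,
                      control_max_delta = cfg$dpir_cutoff)
  prof <- do.call(rbind, lapply(names(rm), function(g)
    cbind(group = g, rm[[g]]$exonic)))
  write_tsv(prof, file.path(out_dir, "rna_map_exonic.tsv"))
  res$rna_map <- rm
  res
}
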