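#' Define cassette-exon events on a simulated annotation
#'
#' Picks internal exons of representative transcripts as cassette exons,
#' with the adjacent exons as the flanking constitutive exons. Coordinates
#' are genomic; `c1` is the upstream constitutive exon in transcription
#' order, `c2` the downstream one.
#'
#' @param sim Output of [sim_genome()].
#' @param n_events Number of events (at most one per internal exon).
#' @param seed RNG seed.
#' @return data.frame: `event_id`, `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `c1_start`, `c1_end`, `a_start`, `a_end`, `c2_start`,
#'   `c2_end`.
#' @export
sim_cassette_events <- function(sim, n_events, seed = 1L) {
  ann <- sim$annotation
  rep <- select_representative(ann)
  cand <- list()
  for (i in seq_len(nrow(rep))) {
    e <- transcript_exons(ann, rep$transcript_id[i])
    ne <- length(e)
    if (ne < 4L) next
    for (j in 2:(ne - 1L)) {
      trio <- e[(j - 1L):(j + 1L)]
      cand[[length(cand) + 1L]] <- data.frame(
        gene_id = rep$gene_id[i], transcript_id = rep$transcript_id[i],
        chrom = as.character(GenomicRanges::seqnames(e))[1],
        strand = as.character(BiocGenerics::strand(e))[1],
        c1_start = BiocGenerics::start(trio)[1],
        c1_end = BiocGenerics::end(trio)[1],
        a_start = BiocGenerics::start(trio)[2],
        a_end = BiocGenerics::end(trio)[2],
        c2_start = BiocGenerics::start(trio)[3],
        c2_end = BiocGenerics::end(trio)[3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) stopf("no transcript with >= 4 exons in simulation")
  all <- do.call(rbind, cand)
  with_seed_(seed, {
    n <- min(n_events, nrow(all))
    out <- all[sample.int(nrow(all), n), , drop = FALSE]
    out$event_id <- sprintf("cas%04d", seq_len(n))
    rownames(out) <- NULL
    out[, c("event_id", setdiff(names(out), "event_id"))]
  })
}

#' Simulate splicing count tables with planted knockdown effects
#'
#' For each truth event with control level `psi_control` (percent) and
#' planted change `delta` (knockdown minus control), per-sample counts are
#' drawn independently as Poisson: the two supporting counts (inclusion
#' junctions for cassette/alt events, the two exon-intron boundary counts
#' for intron retention) with mean `depth * p`, and the opposing count
#' (skipping junction, or spliced exon-exon junction) with mean
#' `depth * (1 - p)`, where `p` is the condition's true level. The
#' [compute_psi()] / [compute_pir()] estimators are consistent for `p`
#' under this model.
#'
#' @param truth data.frame with columns `event_id`, `type` (one of
#'   `cassette`, `alt5`, `alt3`, `intron_retention`), `psi_control`,
#'   `delta` (percent; `psi_control + delta` must stay in `[0, 100]`).
#' @param depth Expected junction depth per sample.
#' @param n_reps Replicates per condition (default 3).
#' @param conditions Condition labels (reference first).
#' @param seed RNG seed.
#' @return Long data.frame: `event_id`, `type`, `condition`, `sample`,
#'   `inc1`, `inc2`, `exc`. For intron retention `inc1`/`inc2`/`exc` are
#'   the e1i / ie2 boundary and e1e2 spliced-junction counts.
#' @export
sim_splice_counts <- function(truth, depth = 2000, n_reps = 3L,
                              conditions = c("control", "kd"), seed = 1L) {
  stopifnot(depth > 0)
  bad <- truth$psi_control < 0 | truth$psi_control > 100 |
    truth$psi_control + truth$delta < 0 |
    truth$psi_control + truth$delta > 100
  if (any(bad)) stopf("psi/pir outside [0,100] for %d events", sum(bad))
  with_seed_(seed, {
    rows <- list()
    for (ci in seq_along(conditions)) {
      p <- (truth$psi_control +
              if (ci == 1L) 0 else truth$delta) / 100
      for (r in seq_len(n_reps)) {
        n <- nrow(truth)
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = truth$event_id, type = truth$type,
          condition = conditions[ci],
          sample = sprintf("%s_%d", conditions[ci], r),
          inc1 = rpois(n, depth * p), inc2 = rpois(n, depth * p),
          exc = rpois(n, depth * (1 - p)), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a planted truth table of splicing effects
#'
#' Convenience generator for truth events: `n_null` events get
#' `delta = 0`, `n_changed` get the planted `delta` (sign alternating when
#' `two_sided`). Control levels are drawn uniformly within `psi_range`,
#' clamped so the knockdown level stays in `[0, 100]`.
#'
#' @param n_changed,n_null Event counts.
#' @param type Event type label.
#' @param delta Planted change (percent).
#' @param psi_range Range of control levels (percent).
#' @param two_sided Alternate the sign of `delta` across changed events.
#' @param seed RNG seed.
#' @return data.frame usable as `truth` in [sim_splice_counts()], with a
#'   `changed` flag.
#' @export
sim_truth_effects <- function(n_changed, n_null, type = "cassette",
                              delta = 20, psi_range = c(20, 80),
                              two_sided = FALSE, seed = 1L) {
  with_seed_(seed, {
    n <- n_changed + n_null
    sgn <- if (two_sided) rep_len(c(1, -1), n_changed)
           else rep(1, n_changed)
    d <- c(delta * sgn, rep(0, n_null))
    psi <- runif(n, psi_range[1], psi_range[2])
    psi <- pmin(pmax(psi, pmax(0, -d)), pmin(100, 100 - d))
    data.frame(event_id = sprintf("%s%04d", substr(type, 1, 3), seq_len(n)),
               type = type, psi_control = psi, delta = d,
               changed = c(rep(TRUE, n_changed), rep(FALSE, n_null)),
               stringsAsFactors = FALSE)
  })
}
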