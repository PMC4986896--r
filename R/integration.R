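#' RNA map of binding around regulated cassette exons
#'
#' Partitions cassette-exon calls into `enhanced` (more skipped upon
#' depletion: the factor enhances inclusion), `silenced` (more included)
#' and `control` (reference inclusion between `control_psi[1]` and
#' `control_psi[2]` percent and `|delta| < control_max_delta`). Only
#' events with at least one peak summit inside the event region (upstream
#' constitutive exon through downstream constitutive exon) enter any
#' group. For each group, peak summits are profiled: 5-nt-bin histograms
#' over the 50-nt windows flanking each of the four splice sites (exonic
#' and intronic side: 8 flank windows), normalized by the number of
#' events in the group, plus the density of relative summit positions
#' (0 = 5' splice site, 1 = 3' splice site) within the upstream and
#' downstream introns.
#'
#' @param calls data.frame from [differential_events()] restricted to
#'   cassette events.
#' @param events Event coordinates from [sim_cassette_events()] (or any
#'   table with the same columns), joined by `event_id`.
#' @param peaks `GRanges` of peaks with `summit` (genomic).
#' @param window,bin Flank window width and bin width in nt (defaults 50
#'   and 5).
#' @param control_psi Reference-PSI band for control events (default
#'   `c(10, 90)`).
#' @param control_max_delta Maximal `|delta|` for control events (default
#'   5).
#' @return List per group (`enhanced`, `silenced`, `control`): `n_events`,
#'   `exonic` (data.frame `flank`, `side`, `bin_start`, `count_norm`) and
#'   `intronic` (data.frame `intron`, `rel_pos`). Empty groups have
#'   `n_events = 0`.
#' @export
build_rna_map <- function(calls, events, peaks, window = 50L, bin = 5L,
                          control_psi = c(10, 90),
                          control_max_delta = 5) {
  stopifnot(window %% bin == 0L)
  d <- merge(calls, events, by = "event_id")
  # strand-aware transcription-order region bounds
  lo <- pmin(d$c1_start, d$c2_start)
  hi <- pmax(d$c1_end, d$c2_end)
  su <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(S4Vectors::mcols(peaks)$summit, width = 1L),
    strand = BiocGenerics::strand(peaks))
  region <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(lo, hi),
                                   strand = d$strand)
  has_peak <- IRanges::overlapsAny(region, su, ignore.strand = FALSE)
  grp <- rep(NA_character_, nrow(d))
  grp[d$accepted & d$delta < 0] <- "enhanced"
  grp[d$accepted & d$delta > 0] <- "silenced"
  ctrl <- !d$accepted & d$psi_ref >= control_psi[1] &
    d$psi_ref <= control_psi[2] & abs(d$delta) < control_max_delta
  grp[ctrl] <- "control"
  grp[!has_peak] <- NA_character_
  out <- lapply(c(enhanced = "enhanced", silenced = "silenced",
                  control = "control"), function(g) {
    idx <- which(!is.na(grp) & grp == g)
    profile_events(d[idx, , drop = FALSE], su, window, bin)
  })
  out
}

# Profile peak summits over one group of cassette events.
profile_events <- function(d, summits, window, bin) {
  nb <- window %/% bin
  flanks <- c("c1_donor", "a_acceptor", "a_donor", "c2_acceptor")
  ex_counts <- matrix(0, nrow = nb, ncol = 4,
                      dimnames = list(NULL, flanks))
  in_counts <- matrix(0, nrow = nb, ncol = 4,
                      dimnames = list(NULL, flanks))
  rel_up <- numeric(0); rel_dn <- numeric(0)
  n <- nrow(d)
  if (n) for (i in seq_len(n)) {
    minus <- d$strand[i] == "-"
    ch <- d$chrom[i]
    s <- summits[as.character(GenomicRanges::seqnames(summits)) == ch &
                   as.character(BiocGenerics::strand(summits)) ==
                     d$strand[i]]
    pos <- BiocGenerics::start(s)
    # transcription-order splice-site coordinates
    if (!minus) {
      ss <- c(d$c1_end[i], d$a_start[i], d$a_end[i], d$c2_start[i])
      iv_up <- c(d$c1_end[i] + 1L, d$a_start[i] - 1L)
      iv_dn <- c(d$a_end[i] + 1L, d$c2_start[i] - 1L)
      tdist <- function(p, anchor) p - anchor  # + downstream in tx sense
    } else {
      ss <- c(d$c1_start[i], d$a_end[i], d$a_start[i], d$c2_end[i])
      iv_up <- c(d$a_end[i] + 1L, d$c1_start[i] - 1L)
      iv_dn <- c(d$c2_end[i] + 1L, d$a_start[i] - 1L)
      tdist <- function(p, anchor) anchor - p
    }
    for (f in 1:4) {
      tt <- tdist(pos, ss[f])
      if (f %in% c(1L, 3L)) {          # donor: exon upstream of the site
        exo <- -tt[tt <= 0 & tt > -window]       # 0..window-1 into exon
        intr <- tt[tt >= 1 & tt <= window] - 1L  # 0..window-1 into intron
      } else {                         # acceptor: exon downstream
        exo <- tt[tt >= 0 & tt < window]
        intr <- -tt[tt <= -1 & tt >= -window] - 1L
      }
      if (length(exo))
        ex_counts[, f] <- ex_counts[, f] +
          tabulate(exo %/% bin + 1L, nbins = nb)
      if (length(intr))
        in_counts[, f] <- in_counts[, f] +
          tabulate(intr %/% bin + 1L, nbins = nb)
    }
    for (which_iv in 1:2) {
      iv <- if (which_iv == 1) iv_up else iv_dn
      w <- iv[2] - iv[1] + 1L
      if (w < 1L) next
      inside <- pos[pos >= iv[1] & pos <= iv[2]]
      if (!length(inside)) next
      # relative position 0 at the intron 5' ss in transcription sense
      rel <- if (!minus) (inside - iv[1]) / max(1L, w - 1L)
             else (iv[2] - inside) / max(1L, w - 1L)
      # on the minus strand iv_up is genomically downstream of the exon
      if (which_iv == 1) rel_up <- c(rel_up, rel)
      else rel_dn <- c(rel_dn, rel)
    }
  }
  mk <- function(mat, side) {
    do.call(rbind, lapply(flanks, function(f) data.frame(
      flank = f, side = side, bin_start = seq(0, window - bin, by = bin),
      count_norm = mat[, f] / max(1L, n), stringsAsFactors = FALSE)))
  }
  list(n_events = n,
       exonic = rbind(mk(ex_counts, "exonic"), mk(in_counts, "intronic")),
       intronic = rbind(
         if (length(rel_up)) data.frame(intron = "upstream",
                                        rel_pos = rel_up),
         if (length(rel_dn)) data.frame(intron = "downstream",
                                        rel_pos = rel_dn)))
}

#' Intron-retention change by CLIP status
#'
#' Compares the distribution of `dpir` (knockdown minus control change in
#' percent intron retention) between CLIP+ and CLIP- introns with a
#' one-sided (greater) Mann-Whitney U test, and tabulates the fractions
#' of changed introns (`dpir` above / below `change_cutoff`) per group.
#'
#' @param records data.frame with columns `intron_id`, `dpir`,
#'   `clip_status` (values `CLIP_plus`, `CLIP_minus`, others allowed and
#'   kept only in the `all` stratum).
#' @param change_cutoff Changed-intron threshold in percent (default 5).
#' @return List: `p_value` (one-sided, CLIP+ greater), `groups`
#'   (named list of dpir vectors: all, CLIP_plus, CLIP_minus),
#'   `changed_fractions` (data.frame per group: fraction with
#'   `dpir > cutoff`, fraction with `dpir < -cutoff`).
#' @export
dpir_by_clip_status <- function(records, change_cutoff = 5) {
  gp <- records$dpir[records$clip_status == "CLIP_plus"]
  gm <- records$dpir[records$clip_status == "CLIP_minus"]
  if (!length(gp) || !length(gm))
    stopf("both CLIP+ and CLIP- groups must be non-empty")
  p <- ranksum_test(gp, gm, alternative = "greater")
  groups <- list(all = records$dpir, CLIP_plus = gp, CLIP_minus = gm)
  cf <- do.call(rbind, lapply(names(groups), function(g) data.frame(
    group = g, n = length(groups[[g]]),
    frac_up = mean(groups[[g]] > change_cutoff),
    frac_down = mean(groups[[g]] < -change_cutoff),
    stringsAsFactors = FALSE)))
  list(p_value = p, groups = groups, changed_fractions = cf)
}

#' CLIP+ enrichment among changed introns
#'
#' One-sided Fisher exact test of the 2x2 table changed x CLIP+ over the
#' expressed-intron universe, plus the support-level counts of changed
#' introns.
#'
#' @param changed Character vector of changed intron ids (subset of
#'   `universe`).
#' @param clip_plus Character vector of CLIP+ intron ids.
#' @param universe Character vector: all expressed introns.
#' @param support Optional named integer vector (intron id -> number of
#'   experiments meeting the CLIP+ rule) to report the stringent-support
#'   strata among changed introns.
#' @return List: `table` (2x2), `p_value` (one-sided, greater),
#'   `odds_ratio`, and `support_counts` when `support` is given.
#' @export
clip_enrichment_in_changed_introns <- function(changed, clip_plus,
                                               universe,
                                               support = NULL) {
  if (!all(changed %in% universe))
    stopf("changed set must be a subset of the universe")
  chg <- universe %in% changed
  cp <- universe %in% clip_plus
  tab <- table(changed = chg, clip_plus = cp)[c("TRUE", "FALSE"),
                                              c("TRUE", "FALSE")]
  ht <- stats::fisher.test(tab, alternative = "greater")
  out <- list(table = tab, p_value = ht$p.value,
              odds_ratio = unname(ht$estimate))
  if (!is.null(support)) {
    s <- support[changed]
    out$support_counts <- data.frame(
      support = 0:max(s, na.rm = TRUE),
      n = vapply(0:max(s, na.rm = TRUE), function(k)
        sum(s >= k, na.rm = TRUE), 0L))
  }
  out
}

#' Co-regulation overlap between two knockdown datasets
#'
#' The universe is the set of events evaluable (non-missing `delta`) in
#' both call tables; an event is "changed" in a dataset when
#' `|delta| > threshold`. Overlap and exclusive counts are reported per
#' event type, split by whether the direction agrees.
#'
#' @param callsA,callsB data.frames from [differential_events()] sharing
#'   `event_id`.
#' @param threshold Change threshold in percent (default 10).
#' @return List: `universe_size`, `overlap` data.frame per type
#'   (`n_both`, `n_both_same_direction`, `n_A_only`, `n_B_only`).
#' @export
coregulation_overlap <- function(callsA, callsB, threshold = 10) {
  m <- merge(callsA, callsB, by = c("event_id", "type"),
             suffixes = c("_A", "_B"))
  m <- m[!is.na(m$delta_A) & !is.na(m$delta_B) & m$comparable_A &
           m$comparable_B, , drop = FALSE]
  sa <- abs(m$delta_A) > threshold
  sb <- abs(m$delta_B) > threshold
  ov <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$type),
                              function(i) data.frame(
    type = m$type[i][1],
    n_both = sum(sa[i] & sb[i]),
    n_both_same_direction = sum(sa[i] & sb[i] &
                                  sign(m$delta_A[i]) ==
                                  sign(m$delta_B[i])),
    n_A_only = sum(sa[i] & !sb[i]),
    n_B_only = sum(!sa[i] & sb[i]), stringsAsFactors = FALSE)))
  rownames(ov) <- NULL
  list(universe_size = nrow(m), overlap = ov)
}
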