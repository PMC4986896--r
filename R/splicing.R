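#' Percent spliced in (PSI) from junction counts
#'
#' `psi = 100 * i / (i + exc)` with `i = (inc_up + inc_down) / 2`, the
#' mean of the two inclusion junction counts. All-zero events are `NA`.
#'
#' @param inc_up,inc_down Upstream / downstream inclusion junction reads.
#' @param exc Exclusion (skipping) junction reads.
#' @return Numeric vector of PSI values in `[0, 100]`.
#' @export
compute_psi <- function(inc_up, inc_down, exc) {
  i <- (inc_up + inc_down) / 2
  out <- 100 * i / (i + exc)
  out[inc_up + inc_down + exc == 0] <- NA_real_
  out
}

#' Percent intron retention (pir) from boundary and junction counts
#'
#' `pir = 100 * b / (b + e1e2)` with `b = (e1i + ie2) / 2`, the mean of
#' the two exon-intron boundary counts, against the spliced exon-exon
#' junction count. The estimate is flagged unreliable when total coverage
#' is below `min_coverage` or the two boundary counts are grossly
#' unbalanced (larger/smaller ratio above `balance_ratio`).
#'
#' @param e1i,ie2 Exon-intron and intron-exon boundary reads.
#' @param e1e2 Spliced exon-exon junction reads.
#' @param min_coverage Reliability floor on `e1i + ie2 + e1e2` (default
#'   10).
#' @param balance_ratio Maximal boundary imbalance (default 5).
#' @return data.frame with columns `pir` (`NA` when all counts are zero)
#'   and `reliable`.
#' @export
compute_pir <- function(e1i, ie2, e1e2, min_coverage = 10L,
                        balance_ratio = 5) {
  b <- (e1i + ie2) / 2
  pir <- 100 * b / (b + e1e2)
  tot <- e1i + ie2 + e1e2
  pir[tot == 0] <- NA_real_
  # one boundary empty while the other has reads is an infinite ratio
  hi <- pmax(e1i, ie2); lo <- pmin(e1i, ie2)
  unbal <- (lo == 0 & hi > 0) | (lo > 0 & hi / lo > balance_ratio)
  data.frame(pir = pir, reliable = tot >= min_coverage & !unbal & tot > 0)
}

#' Differential splicing call with probabilistic acceptance
#'
#' For one event, replicate counts are pooled per condition and the
#' inclusion fraction given a `Beta(supporting + 1, opposing + 1)`
#' posterior (uniform prior). `prob_accept` is the Monte-Carlo posterior
#' probability that the two conditions differ by at least `m` percent; the
#' event is accepted when `prob_accept >= r` and every sample's coverage
#' is at least `e` reads. Events with any sample below `e` are not
#' compared (`comparable = FALSE`, `prob_accept = NA`).
#'
#' @param counts Long data.frame for one or more events: columns
#'   `event_id`, `type`, `condition`, `sample`, `inc1`, `inc2`, `exc`
#'   (see [sim_splice_counts()] for the intron-retention reading).
#' @param conditions Length-2 character: reference condition first;
#'   `delta` is condition2 minus condition1 (knockdown minus control).
#' @param m Minimum difference in percent (default 10).
#' @param r Minimal acceptance probability (default 0.95).
#' @param e Minimal per-sample event coverage in reads (default 10).
#' @param n_draws Monte-Carlo posterior draws (default 4000).
#' @param seed RNG seed.
#' @return data.frame (one row per event): `event_id`, `type`, `psi_ref`,
#'   `psi_alt`, `delta`, `prob_accept`, `comparable`, `accepted`,
#'   `direction` (`more_inclusion` / `more_skipping`, or
#'   `more_retention` / `less_retention` for intron retention).
#' @export
differential_events <- function(counts, conditions = c("control", "kd"),
                                m = 10, r = 0.95, e = 10L,
                                n_draws = 4000L, seed = NULL) {
  stopifnot(length(conditions) == 2L)
  counts <- counts[counts$condition %in% conditions, , drop = FALSE]
  with_seed_(seed, {
    rows <- lapply(split(counts, counts$event_id), function(ev) {
      sup <- (ev$inc1 + ev$inc2) / 2
      opp <- ev$exc
      cov <- sup + opp
      is_ref <- ev$condition == conditions[1]
      psi_ref <- 100 * sum(sup[is_ref]) /
        max(sum(sup[is_ref]) + sum(opp[is_ref]), .Machine$double.eps)
      psi_alt <- 100 * sum(sup[!is_ref]) /
        max(sum(sup[!is_ref]) + sum(opp[!is_ref]), .Machine$double.eps)
      comparable <- all(cov >= e)
      pa <- NA_real_
      if (comparable) {
        da <- rbeta(n_draws, sum(sup[is_ref]) + 1, sum(opp[is_ref]) + 1)
        db <- rbeta(n_draws, sum(sup[!is_ref]) + 1, sum(opp[!is_ref]) + 1)
        pa <- mean(abs(da - db) * 100 >= m)
      }
      delta <- psi_alt - psi_ref
      type <- ev$type[1]
      dir <- if (type == "intron_retention") {
        if (delta >= 0) "more_retention" else "less_retention"
      } else if (delta >= 0) "more_inclusion" else "more_skipping"
      data.frame(event_id = ev$event_id[1], type = type,
                 psi_ref = psi_ref, psi_alt = psi_alt, delta = delta,
                 prob_accept = pa, comparable = comparable,
                 accepted = isTRUE(comparable && pa >= r),
                 direction = dir, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Direction-bias chi-squared test per event type
#'
#' Goodness-of-fit of the two direction counts of accepted calls against
#' a 50:50 split (1 degree of freedom, no continuity correction).
#'
#' @param calls data.frame from [differential_events()] (accepted calls
#'   are selected internally).
#' @return data.frame per type: direction counts, `chisq`, `p_value`.
#' @export
direction_bias_test <- function(calls) {
  acc <- calls[calls$accepted, , drop = FALSE]
  if (!nrow(acc)) stopf("no accepted calls")
  rows <- lapply(split(acc, acc$type), function(d) {
    up <- sum(d$direction %in% c("more_inclusion", "more_retention"))
    dn <- nrow(d) - up
    ht <- suppressWarnings(stats::chisq.test(c(up, dn), p = c(0.5, 0.5)))
    data.frame(type = d$type[1], n_up = up, n_down = dn,
               chisq = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
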