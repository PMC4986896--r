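# Internal helpers shared across modules.

#' @importFrom withr with_seed
#' @importFrom stats median rnorm rpois runif rbinom rbeta
NULL

# Evaluate `expr` under `seed` when non-NULL, restoring RNG state afterwards.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Derive a stage-specific child seed from a global seed. Kept < 2^31 so it is
# always representable as an R integer.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coverage vector over positions 1..width from relative starts and lengths.
# Starts may run off either end; the contribution is clipped to the window.
coverage_vec <- function(starts, lens, width) {
  s <- pmax(as.integer(starts), 1L)
  e <- pmin(as.integer(starts) + as.integer(lens) - 1L, width)
  keep <- s <= e
  s <- s[keep]; e <- e[keep]
  if (!length(s)) return(numeric(width))
  tab_s <- tabulate(s, nbins = width)
  tab_e <- tabulate(e + 1L, nbins = width + 1L)
  cumsum(tab_s - tab_e[seq_len(width)])
}

# Wilcoxon rank-sum / Mann-Whitney p-value. For small samples (total
# <= 12) the permutation distribution of the rank sum is enumerated
# exhaustively on mid-ranks, which stays exact under ties -- wilcox.test
# falls back to a normal approximation there. Larger samples delegate to
# stats::wilcox.test.
ranksum_test <- function(x, y, alternative = "two.sided") {
  nx <- length(x); n <- nx + length(y)
  if (n <= 12L) {
    rk <- rank(c(x, y))
    obs <- sum(rk[seq_len(nx)])
    stats <- apply(utils::combn(n, nx), 2, function(i) sum(rk[i]))
    mu <- nx * (n + 1) / 2
    return(switch(alternative,
                  two.sided = mean(abs(stats - mu) >= abs(obs - mu)),
                  greater = mean(stats >= obs),
                  less = mean(stats <= obs)))
  }
  stats::wilcox.test(x, y, alternative = alternative)$p.value
}

# Number of positions with coverage >= h for h = 1..hmax, from a coverage
# vector; a reverse cumulated tabulation.
positions_ge <- function(cov, hmax) {
  cov <- cov[cov > 0]
  if (!length(cov)) return(numeric(hmax))
  tab <- tabulate(pmin(cov, hmax), nbins = hmax)
  rev(cumsum(rev(tab)))
}
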