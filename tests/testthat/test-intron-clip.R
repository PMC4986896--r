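test_that("intron read counting enforces the 5 bp minimum overlap", {
  ii <- gr("chr1", c(1000, 2000), c(1500, 2500), "+",
           intron_id = c("i1", "i2"))
  # 10-nt read overlapping i1 by exactly 5 -> counted
  r5 <- gr("chr1", 995, 1004, "+")
  expect_equal(unname(count_intron_reads(r5, ii)), c(1L, 0L))
  # overlap 4 -> not counted
  r4 <- gr("chr1", 994, 1003, "+")
  expect_equal(sum(count_intron_reads(r4, ii)), 0L)
  # wrong strand -> not counted
  rs <- gr("chr1", 1100, 1109, "-")
  expect_equal(sum(count_intron_reads(rs, ii)), 0L)
})

test_that("a read counts toward exactly one intron (largest overlap)", {
  ii <- gr("chr1", c(100, 108), c(107, 200), "+",
           intron_id = c("a", "b"))
  # read 101-115: overlap a = 7, overlap b = 8 -> b
  r <- gr("chr1", 101, 115, "+")
  expect_equal(unname(count_intron_reads(r, ii)), c(0L, 1L))

  # random reads match brute force under the same assignment rule
  set.seed(61)
  s <- seq(1, 20000, by = 200)
  iv <- gr("chr1", s, s + 99, "+",
           intron_id = sprintf("i%d", seq_along(s)))
  rs <- sample(1:20000, 1000, replace = TRUE)
  reads <- gr("chr1", rs, rs + 9, "+")
  got <- count_intron_reads(reads, iv, min_overlap = 5)
  brute <- integer(length(iv))
  for (j in seq_along(reads)) {
    ov <- pmin(rs[j] + 9, BiocGenerics::end(iv)) -
      pmax(rs[j], BiocGenerics::start(iv)) + 1
    ov[ov < 5] <- 0
    if (any(ov > 0)) {
      w <- which(ov == max(ov))[1]
      brute[w] <- brute[w] + 1L
    }
  }
  expect_equal(unname(got), brute)
})

test_that("size factors follow the median-of-ratios formula", {
  m <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), ncol = 2)
  sf <- size_factors(m)$size_factors
  expect_equal(unname(sf), c(1, 1))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf2 <- size_factors(m2)$size_factors
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  # all-zero gene rows break no computation; zero-containing genes are
  # excluded from the median
  m3 <- rbind(m2, c(0, 100))
  expect_equal(unname(size_factors(m3)$size_factors[2] /
                        size_factors(m3)$size_factors[1]), 2)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
})

test_that("size factors match the DESeq2 oracle on random matrices", {
  skip_if_not_installed("DESeq2")
  set.seed(71)
  m <- matrix(rpois(200, 40) + 1L, ncol = 4)
  got <- size_factors(m)$size_factors
  want <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("CLIP classification reproduces the published rules", {
  # fivefold / min-5 rule in all three experiments -> CLIP+, support 3
  r <- classify_introns(matrix(c(10, 9, 8), 1), matrix(c(2, 1, 0), 1))
  expect_equal(as.character(r$status), "CLIP_plus")
  expect_equal(r$support, 3L)
  # all counts <= control -> CLIP-
  r2 <- classify_introns(matrix(c(1, 0, 2), 1), matrix(c(1, 1, 2), 1))
  expect_equal(as.character(r2$status), "CLIP_minus")
  # rule met in one experiment only -> neither at k = 2
  r3 <- classify_introns(matrix(c(10, 1, 1), 1), matrix(c(1, 1, 1), 1))
  expect_equal(as.character(r3$status), "neither")
  expect_equal(r3$support, 1L)
  # boundary: exactly fivefold counts as enriched
  r4 <- classify_introns(matrix(c(10, 10, 0), 1), matrix(c(2, 2, 2), 1))
  expect_equal(as.character(r4$status), "CLIP_plus")
  expect_error(classify_introns(matrix(1, 1, 3), matrix(1, 1, 2)),
               "identical dimensions")
})

test_that("expression filter drops introns of silent genes", {
  gc <- rbind(g1 = c(100, 120, 90, 110), g2 = c(0, 1, 0, 0),
              g3 = c(50, 60, 55, 45))
  expr <- expressed_genes(gc, min_norm = 1)
  expect_setequal(expr, c("g1", "g3"))
})

test_that("intron features report length, GC and splice strength", {
  sim <- shared_sim()
  f <- intron_features(sim$introns, sim$genome)
  expect_equal(f$length, BiocGenerics::width(sim$introns))
  expect_true(all(f$gc >= 0 & f$gc <= 1))
  # plug-in scorer contract: constant scorer passes through
  const0 <- function(d, a) list(ss5 = rep(0, length(d)),
                                ss3 = rep(0, length(a)))
  f0 <- intron_features(sim$introns, sim$genome, ss_scorer = const0)
  expect_true(all(f0$ss5_score == 0) && all(f0$ss3_score == 0))
})

test_that("PWM scorer ranks consensus donors above scrambled ones", {
  sim <- shared_sim()
  scorer <- train_splice_pwm(sim$introns, sim$genome)
  cons <- "CAGGTAAGT"
  scram <- "TACATGGAT"
  s <- scorer(c(cons, scram), c(paste0(strrep("T", 18), "AGGAA"),
                                paste0(strrep("G", 18), "AGGAA")))
  expect_gt(s$ss5[1], s$ss5[2])
  # log-odds of the consensus is positive
  expect_gt(s$ss5[1], 0)
})

test_that("group comparison returns exact rank-sum p-values", {
  f <- data.frame(intron_id = sprintf("i%d", 1:6),
                  length = c(1, 2, 3, 10, 20, 30),
                  gc = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                  ss5_score = 1:6, ss3_score = 6:1)
  r <- compare_intron_groups(f, sprintf("i%d", 1:3), sprintf("i%d", 4:6))
  lenrow <- r[r$feature == "length", ]
  expect_equal(lenrow$p_value, 0.1)  # exact enumeration: 2/C(6,3)
  expect_equal(lenrow$p_value,
               rank_sum_exact(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(lenrow$direction, "minus_higher")
  # identical groups -> p = 1, equal medians
  f2 <- data.frame(intron_id = sprintf("i%d", 1:4),
                   length = c(5, 6, 5, 6), gc = c(.4, .5, .4, .5),
                   ss5_score = c(1, 2, 1, 2), ss3_score = c(1, 2, 1, 2))
  r2 <- compare_intron_groups(f2, c("i1", "i2"), c("i3", "i4"))
  expect_true(all(r2$p_value == 1))
  expect_true(all(r2$direction == "equal"))
  expect_error(compare_intron_groups(f2, character(0), c("i3")),
               "non-empty")
})

test_that("planted suboptimal binding is recovered in feature shifts", {
  sim <- sim_genome(120, seed = 81)
  sites <- sim_binding_sites(sim, 150,
                             classes = c(intron_5ss_proximal = 0.6,
                                         intron_3ss = 0.4),
                             strength = 25, couple_suboptimal = 0.9,
                             seed = 82)
  # control at matched depth so background introns do not pass the
  # fivefold rule by depth alone
  reads <- sim_iclip(sim, sites, seed = 83)
  ctrl <- sim_iclip(sim, sites, control = TRUE, control_depth = 1,
                    seed = 84)
  ii <- sim$introns
  cnt <- vapply(lapply(reads, extend_reads),
                count_intron_reads, integer(length(ii)), introns = ii)
  ccn <- vapply(lapply(ctrl, extend_reads),
                count_intron_reads, integer(length(ii)), introns = ii)
  rownames(cnt) <- rownames(ccn) <- ii$intron_id
  cls <- classify_introns(cnt, ccn)
  f <- intron_features(ii, sim$genome)
  plus <- cls$intron_id[cls$status == "CLIP_plus"]
  minus <- cls$intron_id[cls$status != "CLIP_plus"]
  cmp <- compare_intron_groups(f, plus, minus)
  expect_equal(cmp$direction[cmp$feature == "length"], "minus_higher")
  expect_equal(cmp$direction[cmp$feature == "gc"], "plus_higher")
  expect_lt(cmp$p_value[cmp$feature == "length"], 0.01)
  expect_lt(cmp$p_value[cmp$feature == "ss5_score"], 0.01)
})
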