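test_that("flank_windows does forced arithmetic and discards overhangs", {
  cl <- c(c = 10000)
  g <- data.frame(chrom = "c", start = 100, end = 200)
  w <- flank_windows(g, 50, cl)
  expect_equal(w$start, c(50, 200))
  expect_equal(w$end, c(100, 250))

  ## gap at the chromosome start: right window only
  g0 <- data.frame(chrom = "c", start = 0, end = 100)
  w0 <- flank_windows(g0, 50, cl)
  expect_equal(nrow(w0), 1)
  expect_equal(c(w0$start, w0$end), c(100, 150))

  ## gap at the end: left window only
  g1 <- data.frame(chrom = "c", start = 9900, end = 10000)
  w1 <- flank_windows(g1, 50, cl)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(9850, 9900))

  ## random gaps against direct interval arithmetic
  set.seed(3)
  for (i in 1:200) {
    s <- sample(0:9900, 1); e <- s + sample(10:90, 1); d <- sample(10:500, 1)
    w <- flank_windows(data.frame(chrom = "c", start = s, end = e), d, cl)
    want <- rbind(if (s - d >= 0) c(s - d, s),
                  if (e + d <= 10000) c(e, e + d))
    expect_equal(unname(as.matrix(w[, c("start", "end")])),
                 unname(want))
  }
})

test_that("mean_flank_statistic agrees with per-base brute force", {
  set.seed(19)
  cl <- c(c1 = 2000, c2 = 1500)
  genome <- c(c1 = paste(sample(c("A", "C", "G", "T", "N"), 2000,
                                replace = TRUE, prob = c(.3, .2, .2, .25, .05)),
                         collapse = ""),
              c2 = paste(sample(c("A", "C", "G", "T"), 1500,
                                replace = TRUE), collapse = ""))
  repeats <- random_intervals(40, chroms = c("c1", "c2"), max_pos = 1400)
  gaps <- data.frame(chrom = c("c1", "c1", "c2"),
                     start = c(300, 900, 700), end = c(400, 1000, 800))
  for (d in c(25, 100)) {
    w <- flank_windows(gaps, d, cl)
    want_rep <- mean(vapply(seq_len(nrow(w)), function(i)
      oracle_covered(repeats, w$chrom[i], w$start[i], w$end[i]) /
        (w$end[i] - w$start[i]), 0))
    got_rep <- mean_flank_statistic(gaps, d, "repeat_fraction", cl,
                                    repeats = repeats)
    expect_equal(got_rep, want_rep, tolerance = 1e-12)
    want_gc <- mean(vapply(seq_len(nrow(w)), function(i)
      oracle_gc(substr(genome[[w$chrom[i]]], w$start[i] + 1, w$end[i])), 0))
    got_gc <- mean_flank_statistic(gaps, d, "gc_fraction", cl,
                                   genome = genome)
    expect_equal(got_gc, want_gc, tolerance = 1e-12)
  }
  ## repeats blanketing every flank give exactly 1
  blanket <- data.frame(chrom = c("c1", "c2"), start = 0,
                        end = c(2000, 1500))
  expect_equal(mean_flank_statistic(gaps, 50, "repeat_fraction", cl,
                                    repeats = blanket), 1)
})

test_that("shuffle_gaps preserves lengths, is seeded, and places uniformly", {
  cl <- c(a = 5000, b = 3000)
  gaps <- data.frame(chrom = c("a", "a", "b"),
                     start = c(10, 500, 100), end = c(110, 530, 400))
  set.seed(8); s1 <- shuffle_gaps(gaps, cl)
  set.seed(8); s2 <- shuffle_gaps(gaps, cl)
  expect_identical(s1, s2)
  expect_equal(sort(s1$end - s1$start), sort(gaps$end - gaps$start))
  ## no overlaps among placed gaps
  o <- order(s1$chrom, s1$start)
  ss <- s1[o, ]
  same <- ss$chrom[-1] == ss$chrom[-nrow(ss)]
  expect_true(all(ss$start[-1][same] >= ss$end[-nrow(ss)][same]))

  ## single gap on one chromosome: offset uniform over [0, L - len]
  set.seed(9)
  one <- data.frame(chrom = "a", start = 0, end = 50)
  draws <- vapply(1:4000, function(i)
    shuffle_gaps(one, c(a = 1000))$start, 0)
  expect_true(all(draws >= 0 & draws <= 950))
  cs <- suppressWarnings(
    chisq.test(tabulate(findInterval(draws, seq(0, 951, length.out = 11)),
                        nbins = 10)))
  expect_gt(cs$p.value, 1e-4)
})

test_that("permutation p-value is the strict-greater proportion", {
  cl <- c(c1 = 4000)
  gaps <- data.frame(chrom = "c1", start = c(1000, 2500),
                     end = c(1100, 2600))
  ## repeats packed exclusively around the observed gap flanks: observed
  ## tops every permutation
  repeats <- data.frame(chrom = "c1", start = c(900, 1100, 2400, 2600),
                        end = c(1000, 1200, 2500, 2700))
  res <- permutation_test(gaps, cl, repeats = repeats, n_perm = 60,
                          distances = 100, seed = 4)
  expect_equal(res$p_value, 0)
  perms <- attr(res, "permuted")[[1]]
  expect_length(perms, 60)
  expect_equal(res$p_value, mean(perms > res$observed))
  ## p is a plain proportion of the retained distribution
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("Monte-Carlo p matches the exhaustive placement oracle", {
  ## one gap on one tiny chromosome: every placement enumerable
  cl <- c(c1 = 400)
  gap <- data.frame(chrom = "c1", start = 150, end = 180)
  repeats <- data.frame(chrom = "c1", start = c(0, 120, 300),
                        end = c(60, 200, 340))
  d <- 20
  stat_at <- function(s) {
    g <- data.frame(chrom = "c1", start = s, end = s + 30)
    mean_flank_statistic(g, d, "repeat_fraction", cl, repeats = repeats)
  }
  obs <- stat_at(150)
  exact <- mean(vapply(0:370, stat_at, 0) > obs)
  res <- permutation_test(gap, cl, repeats = repeats, n_perm = 1500,
                          distances = d, seed = 12)
  se <- sqrt(exact * (1 - exact) / 1500)
  expect_lt(abs(res$p_value - exact), 3 * se + 1e-9)
})
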