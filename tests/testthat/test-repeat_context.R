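test_that("classify_repeats handles forced layouts", {
  genes <- data.frame(chrom = "c1", start = 100, end = 500, strand = "+",
                      gene_id = "g1")
  inside <- data.frame(chrom = "c1", start = 200, end = 300, class = "LTR",
                       family = "Copia", strand = "+")
  out <- classify_repeats(inside, genes)
  expect_equal(out$context, "genic")
  expect_equal(out$strand_relation, "same")

  outside <- transform(inside, start = 600, end = 700, strand = "-")
  out2 <- classify_repeats(outside, genes)
  expect_equal(out2$context, "non-genic")
  expect_equal(out2$strand_relation, "unstranded")

  ## one-base overlap is genic; opposite strand is "different"
  touch <- transform(inside, start = 499, end = 600, strand = "-")
  out3 <- classify_repeats(touch, genes)
  expect_equal(out3$context, "genic")
  expect_equal(out3$strand_relation, "different")
})

test_that("classification matches all-pairs brute force on random layouts", {
  set.seed(31)
  for (rep in 1:5) {
    genes <- random_intervals(30)
    genes$gene_id <- sprintf("g%02d", 1:30)
    rp <- random_intervals(100)
    rp$class <- sample(c("LTR", "LINE", "DNA"), 100, replace = TRUE)
    rp$family <- ""
    got <- classify_repeats(rp, genes)
    for (i in seq_len(nrow(rp))) {
      want <- oracle_classify(rp[i, ], genes)
      expect_identical(got$context[i], want$context)
      expect_identical(got$strand_relation[i], want$relation)
    }
  }
})

test_that("context_composition computes shares, folds and strand ratios", {
  ## 10 LINE genic of 100 genic total; 5 LINE non-genic of 500 non-genic
  genes <- data.frame(chrom = "c1", start = 0, end = 100000, strand = "+",
                      gene_id = "g1")
  n_genic <- 100; n_non <- 500
  mk <- function(n, chrom, class) {
    s <- seq(0, by = 150, length.out = n) + if (chrom == "c1") 0 else 0
    data.frame(chrom = chrom, start = s, end = s + 100, class = class,
               family = "", strand = "+")
  }
  genic <- mk(100, "c1", c(rep("LINE", 10), rep("LTR", 90)))
  nong <- mk(500, "c2", c(rep("LINE", 5), rep("LTR", 495)))
  comp <- context_composition(rbind(genic, nong), genes)
  bc <- comp$by_class
  line <- bc[bc$class == "LINE", ]
  expect_equal(line$genic_share, 0.1)
  expect_equal(line$nongenic_share, 0.01)
  expect_equal(line$fold_nongenic_vs_genic, 0.1)
  ## shares sum to 1 within each context
  expect_equal(sum(bc$genic_share), 1, tolerance = 1e-9)
  expect_equal(sum(bc$nongenic_share), 1, tolerance = 1e-9)
  ## genic + non-genic = total
  expect_equal(comp$genic_total + comp$nongenic_total, 600)
})

test_that("planted genic insertion bias is recovered", {
  cfg <- simulation_config(seed = 17, repeat_genic_bias = 4,
                           gene_count = 40L,
                           repeat_families = list(
                             list(label = "LINE/L1", count = 120L,
                                  mixture = list(c(1, 400, 0.2)))))
  g <- simulate_genome(cfg)
  cl <- classify_repeats(g$repeats, g$genes)
  genic_frac <- mean(cl$context == "genic")
  spans <- gene_spans(g$genes)
  gfrac <- sum(spans$end - spans$start) / g$truth$genome_length
  ## bias-4 zone probability, plus leakage: an off-zone element still hits
  ## a gene when its start falls within ~element length of a span
  q <- 4 * gfrac / (4 * gfrac + (1 - gfrac))
  hit <- sum(pmin(spans$end + 400, 200000) - spans$start) /
    g$truth$genome_length
  expected <- q + (1 - q) * hit
  se <- sqrt(expected * (1 - expected) / 120)
  expect_lt(abs(genic_frac - expected), 3.5 * se + 0.03)
  ## and the bias visibly exceeds the unbiased world
  expect_gt(genic_frac, hit + 3 * se)
})

test_that("class_count_ratio renders n:1 labels and validates", {
  r <- data.frame(chrom = "c", start = (0:3) * 10, end = (0:3) * 10 + 5,
                  class = c("LTR", "LTR", "LTR", "LINE"),
                  family = c("Gypsy", "Gypsy", "Copia", "L1"),
                  strand = "+")
  expect_equal(class_count_ratio(r, "LTR", "LINE")$ratio, 3)
  expect_equal(class_count_ratio(r, "LTR/Gypsy", "LTR/Copia")$label, "2:1")
  expect_equal(class_count_ratio(r, "LINE", "LINE")$ratio, 1)
  expect_error(class_count_ratio(r, "LTR", "SINE"), "zero denominator")
})

test_that("window_coverage matches per-base counting and is merge-invariant", {
  set.seed(41)
  cl <- c(c1 = 700, c2 = 900)
  feats <- random_intervals(60, max_pos = 690)
  feats$end <- pmin(feats$end, 690)
  wc <- window_coverage(feats, cl, 128)
  for (i in seq_len(nrow(wc))) {
    expect_equal(wc$covered_fraction[i],
                 oracle_covered(feats, wc$chrom[i], wc$start[i], wc$end[i]) /
                   (wc$end[i] - wc$start[i]))
  }
  expect_true(all(wc$covered_fraction >= 0 & wc$covered_fraction <= 1))
  ## full and empty windows
  one <- data.frame(chrom = "c1", start = 0, end = 128)
  wc1 <- window_coverage(one, cl, 128)
  expect_equal(wc1$covered_fraction[1], 1)
  expect_equal(wc1$covered_fraction[3], 0)
  ## pre-merging overlapping features changes nothing
  merged <- foxtail:::merge_intervals(feats)
  expect_equal(window_coverage(merged, cl, 128)$covered_fraction,
               wc$covered_fraction)
})
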