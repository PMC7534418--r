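mk_rec <- function(id = "V1", sv_type = "DEL", pos = 100, end = 6730,
                   precise = TRUE, pe = 7, sr = 3, mapq = 40,
                   filter = "PASS", chrom = "c1") {
  data.frame(id = id, sv_type = sv_type, chrom = chrom, pos = pos,
             end = end, precise = precise, pe = pe, sr = sr, mapq = mapq,
             filter = filter, stringsAsFactors = FALSE)
}

test_that("sv_length is end - pos for every type", {
  expect_equal(sv_length(mk_rec(pos = 100, end = 6730)), 6630)
  expect_equal(sv_length(mk_rec(pos = 5, end = 5)), 0)
  r <- rbind(mk_rec("a", "DEL"), mk_rec("b", "DUP", end = 2220),
             mk_rec("c", "INV", end = 150000))
  expect_equal(sv_length(r), r$end - r$pos)
})

test_that("passes_filters applies the curation chain with exact boundaries", {
  ## all thresholds met at the pe = 5 boundary
  ok <- passes_filters(mk_rec(pe = 5, mapq = 20, end = 6730))
  expect_true(ok$pass)
  expect_equal(ok$reasons, "")

  pe4 <- passes_filters(mk_rec(pe = 4))
  expect_false(pe4$pass)
  expect_equal(pe4$reasons, "min_pe")

  too_long <- passes_filters(mk_rec(pos = 1, end = 1 + 5e6))
  expect_false(too_long$pass)
  expect_equal(too_long$reasons, "max_length")
  expect_true(passes_filters(mk_rec(pos = 1, end = 5e6))$pass)  # 4,999,999

  expect_equal(suppressWarnings(
    passes_filters(mk_rec(precise = FALSE))$reasons), "precise")
  expect_equal(passes_filters(mk_rec(mapq = 0))$reasons, "mapq")
  expect_equal(passes_filters(mk_rec(filter = "LowQual"))$reasons,
               "filter_pass")
  ## multiple violations all reported
  multi <- passes_filters(mk_rec(pe = 1, mapq = 0))
  expect_equal(multi$reasons, "mapq,min_pe")
  ## PRECISE flag vs split-read count disagreement warns
  expect_warning(passes_filters(mk_rec(precise = TRUE, sr = 0)), "disagree")
})

test_that("filter agrees with an independent rule oracle on fuzzed records", {
  set.seed(23)
  n <- 1000
  recs <- data.frame(
    id = sprintf("V%04d", 1:n), sv_type = sample(c("DEL", "DUP", "INV"), n,
                                                 replace = TRUE),
    chrom = "c1", pos = sample.int(1e6, n),
    precise = sample(c(TRUE, FALSE), n, replace = TRUE),
    pe = sample(0:12, n, replace = TRUE), mapq = sample(0:60, n,
                                                        replace = TRUE),
    filter = sample(c("PASS", "LowQual"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  recs$sr <- ifelse(recs$precise, sample(1:9, n, replace = TRUE), 0)
  recs$end <- recs$pos + sample(c(50, 5000, 4999999, 5e6, 6e6), n,
                                replace = TRUE)
  got <- passes_filters(recs)
  expect_equal(got$pass, oracle_sv_pass(recs))
  ## monotonicity: relaxing any single threshold never shrinks the set
  base <- sum(got$pass)
  relax <- list(sv_filter_config(max_length = Inf),
                sv_filter_config(min_pe = 0),
                sv_filter_config(require_precise = FALSE),
                sv_filter_config(require_pass = FALSE))
  for (cfg in relax)
    expect_gte(sum(passes_filters(recs, cfg)$pass), base)
})

test_that("minor_allele_frequency folds and ignores missing calls", {
  expect_equal(minor_allele_frequency(rep("0/0", 10))$maf, 0)
  expect_equal(minor_allele_frequency(c("0/1", "0/1", rep("0/0", 8)))$maf,
               0.1)
  expect_equal(minor_allele_frequency(c(rep("1/1", 9), "0/0"))$maf, 0.1)
  r <- minor_allele_frequency(c("0/1", NA, "0/0", NA))
  expect_equal(r$called, 2)
  expect_equal(r$maf, 0.25)
  expect_error(minor_allele_frequency(c(NA_character_, NA)), "missing")
  ## invariant to sample order and to ref/alt relabelling
  set.seed(5)
  g <- sample(c("0/0", "0/1", "1/1", NA), 40, replace = TRUE)
  expect_equal(minor_allele_frequency(g)$maf,
               minor_allele_frequency(sample(g))$maf)
  swapped <- chartr("01", "10", g)
  swapped[swapped == "1/0"] <- "0/1"
  expect_equal(minor_allele_frequency(g)$maf,
               minor_allele_frequency(swapped)$maf)
})

test_that("summarize_population medians and MAF subsetting", {
  recs <- do.call(rbind, lapply(1:6, function(i)
    mk_rec(sprintf("D%d", i), "DEL", pos = 1, end = 1 + i * 1000)))
  gt <- matrix("0/1", nrow = 6, ncol = 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  sv <- sv_set(recs, gt)
  s <- summarize_population(sv)
  del <- s$per_type[s$per_type$sv_type == "DEL", ]
  expect_equal(del$n, 6)
  expect_equal(del$median_length, 3500)  # midpoint of 3000 and 4000
  expect_equal(del$n_maf, 6)
  ## maf threshold 0 keeps everything
  s0 <- summarize_population(sv, maf_threshold = 0)
  expect_equal(s0$per_type$n_maf, s0$per_type$n)
})

test_that("curated set equals simulator ground truth, reasons attributable", {
  svp <- simulate_sv_population(simulation_config(seed = 33,
                                                  sample_count = 50L))
  flt <- passes_filters(svp$sv)
  expect_identical(flt$pass, svp$truth$fate == "pass")
  bad <- flt$reasons[!flt$pass]
  expect_identical(bad, svp$truth$fate[svp$truth$fate != "pass"])
  ## per-type counts match the planted clean counts
  s <- summarize_population(svp$sv)
  expect_equal(setNames(s$per_type$n, s$per_type$sv_type),
               c(DEL = 150L, DUP = 186L, INV = 85L), ignore_attr = TRUE)
  ## lengths agree with planted truth on passing records
  pv <- s$per_variant
  expect_equal(pv$length,
               svp$truth$length[match(pv$id, svp$truth$id)])
})

test_that("deletion_te_length_overlap has identity/disjoint boundaries and a closed form", {
  x <- c(100, 600, 1200, 4800)
  expect_equal(deletion_te_length_overlap(x, x)$overlap, 1)
  expect_equal(deletion_te_length_overlap(c(100, 200), c(6000, 7000))$overlap,
               0)
  ## closed form: masses known exactly per 500-bp bin
  del <- c(rep(250, 3), rep(750, 1))        # bins 1,1,1 | 2 -> (0.75, 0.25)
  te <- c(rep(250, 1), rep(750, 3))         # (0.25, 0.75)
  got <- deletion_te_length_overlap(del, te)
  expect_equal(got$overlap, 0.25 + 0.25, tolerance = 1e-9)
  ## lengths outside the grid are dropped before normalization
  got2 <- deletion_te_length_overlap(c(del, 50000), te)
  expect_equal(got2$overlap, 0.5, tolerance = 1e-9)
})
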