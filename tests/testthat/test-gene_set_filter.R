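test_that("filter_by_aed keeps AED 0.50 and drops 0.51", {
  g50 <- mk_gene("g50", "c1", "+", cbind(0, 300), aed = 0.50)
  g51 <- mk_gene("g51", "c1", "+", cbind(1000, 1300), aed = 0.51)
  kept <- filter_by_aed(list(g50, g51))
  expect_equal(vapply(kept, `[[`, "", "gene_id"), "g50")
  ## the best isoform decides
  mixed <- gene_model("gm", list(
    mk_tx("gm.1", "gm", "c1", "+", cbind(0, 300), 0.9),
    mk_tx("gm.2", "gm", "c1", "+", cbind(0, 300), 0.2)))
  expect_length(filter_by_aed(list(mixed)), 1)
  ## identity on perfect support
  zeros <- lapply(1:5, function(i)
    mk_gene(paste0("z", i), "c1", "+", cbind(i * 1000, i * 1000 + 200),
            aed = 0))
  expect_length(filter_by_aed(zeros), 5)
})

test_that("select_primary uses AED, then length, then id", {
  g <- gene_model("g", list(
    mk_tx("g.a", "g", "c1", "+", cbind(0, 900), 0.4),
    mk_tx("g.b", "g", "c1", "+", cbind(0, 300), 0.2)))
  expect_equal(select_primary(g)$id, "g.b")
  ## AED tie: longer exonic length wins
  tie <- gene_model("t", list(
    mk_tx("t.a", "t", "c1", "+", cbind(0, 900), 0.3),
    mk_tx("t.b", "t", "c1", "+", cbind(0, 1200), 0.3)))
  expect_equal(select_primary(tie)$id, "t.b")
  ## full tie: lexicographically smaller id
  tie2 <- gene_model("u", list(
    mk_tx("u.b", "u", "c1", "+", cbind(0, 500), 0.3),
    mk_tx("u.a", "u", "c1", "+", cbind(100, 600), 0.3)))
  expect_equal(select_primary(tie2)$id, "u.a")
  single <- mk_gene("s", "c1", "+", cbind(0, 100))
  expect_equal(select_primary(single)$id, "s.1")
})

test_that("gene_tpm sums isoforms per sample", {
  g <- gene_model("g", list(
    mk_tx("g.1", "g", "c1", "+", cbind(0, 300), 0.1),
    mk_tx("g.2", "g", "c1", "+", cbind(0, 200), 0.2)))
  expr <- matrix(c(0.6, 0.6, 1.5, 2.5), nrow = 2, byrow = FALSE,
                 dimnames = list(c("g.1", "g.2"), c("s1", "s2")))
  expect_equal(gene_tpm(expr, g), c(s1 = 1.2, s2 = 4.0))
  single <- mk_gene("h", "c1", "+", cbind(0, 100))
  e1 <- matrix(5, 1, 1, dimnames = list("h.1", "s1"))
  expect_equal(gene_tpm(e1, single), c(s1 = 5))
  expect_error(gene_tpm(e1, g), "absent")
  ## random tables against independent summation
  set.seed(6)
  big <- matrix(runif(20), nrow = 10,
                dimnames = list(c("g.1", "g.2", paste0("x", 1:8)),
                                c("s1", "s2")))
  expect_equal(gene_tpm(big, g),
               c(s1 = big["g.1", 1] + big["g.2", 1],
                 s2 = big["g.1", 2] + big["g.2", 2]))
})

test_that("encompassment_fraction boundaries", {
  a <- genomic_intervals("c1", 100, 200)
  expect_equal(encompassment_fraction(a, genomic_intervals("c1", 0, 1000)), 1)
  expect_equal(encompassment_fraction(a, genomic_intervals("c1", 500, 600)), 0)
  expect_equal(encompassment_fraction(a, genomic_intervals("c1", 150, 600)),
               0.5)
  expect_equal(encompassment_fraction(a, genomic_intervals("c2", 100, 200)), 0)
})

test_that("apply_final_filter fires each clause as hand-derived", {
  ## six genes exercising every rule
  genes <- list(
    ## 1: long multi-exon, focal-specific: kept (no single-exon clause)
    mk_gene("gA", "c1", "+", rbind(c(1000, 1400), c(1600, 2000))),
    ## 2: single-exon specific, TPM 0.5: removed (unsupported)
    mk_gene("gB", "c1", "+", cbind(3000, 3600)),
    ## 3: single-exon specific, TPM 2, un-encompassed: kept
    mk_gene("gC", "c1", "+", cbind(5000, 5600)),
    ## 4: single-exon specific, TPM 2, 95% inside gA2: removed (encompassed)
    mk_gene("gD", "c1", "+", cbind(7000, 7400)),
    mk_gene("gA2", "c1", "+", rbind(c(6900, 7380), c(7390, 7800))),
    ## 5: single-exon, shared orthogroup, TPM 0: kept (not specific)
    mk_gene("gE", "c1", "+", cbind(9000, 9500)),
    ## 6: 30-base gene: removed (min_length)
    mk_gene("gF", "c1", "+", cbind(11000, 11030)))
  og <- data.frame(
    orthogroup = c("OG1", "OG2", "OG3", "OG4", "OG5", "OG6", "OG6", "OG7"),
    species = c("me", "me", "me", "me", "me", "me", "other", "me"),
    gene_id = c("gA", "gB", "gC", "gD", "gA2", "gE", "xx1", "gF"),
    stringsAsFactors = FALSE)
  expr <- matrix(c(10, 0.5, 2, 2, 10, 0, 5), ncol = 1,
                 dimnames = list(paste0(c("gA", "gB", "gC", "gD", "gA2",
                                          "gE", "gF"), ".1"), "s1"))
  rep <- apply_final_filter(genes, og, expr, "me")
  want <- c(gA = "", gB = "specific_og_unsupported", gC = "",
            gD = "specific_og_encompassed", gA2 = "", gE = "",
            gF = "min_length")
  expect_equal(setNames(rep$rule, rep$gene_id), want)
  expect_equal(rep$kept, rep$rule == "")

  ## boundary: 49-base removed, 50-base kept
  b49 <- mk_gene("b49", "c1", "+", cbind(0, 49))
  b50 <- mk_gene("b50", "c1", "+", cbind(100, 150))
  ogb <- data.frame(orthogroup = c("O1", "O2"), species = "me",
                    gene_id = c("b49", "b50"))
  eb <- matrix(c(5, 5), ncol = 1,
               dimnames = list(c("b49.1", "b50.1"), "s1"))
  repb <- apply_final_filter(list(b49, b50), ogb, eb, "me")
  expect_equal(setNames(repb$kept, repb$gene_id), c(b49 = FALSE, b50 = TRUE))
  expect_equal(repb$rule[1], "min_length")

  ## no focal-specific orthogroups: only the length rule can fire
  og_shared <- data.frame(orthogroup = "O1",
                          species = rep(c("me", "other"), each = 7),
                          gene_id = c(vapply(genes, `[[`, "", "gene_id"),
                                      paste0("y", 1:7)))
  rep2 <- apply_final_filter(genes, og_shared, expr, "me")
  expect_true(all(rep2$rule %in% c("", "min_length")))
})

test_that("final filtration is idempotent", {
  set.seed(44)
  g <- simulate_genome(simulation_config(seed = 44))
  expr <- simulate_expression(g$genes, seed = 44)
  ogs <- simulate_orthogroups(simulation_config(seed = 44),
                              focal_gene_ids =
                                vapply(g$genes, `[[`, "", "gene_id"))
  surv <- filter_by_aed(g$genes, 0.5)
  r1 <- apply_final_filter(surv, ogs$orthogroups, expr, "focal")
  kept <- surv[r1$kept]
  r2 <- apply_final_filter(kept, ogs$orthogroups, expr, "focal")
  expect_true(all(r2$kept))
})
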