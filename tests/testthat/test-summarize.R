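test_that("composed counts conserve loci and split groups", {
  set.seed(61)
  lb <- rep(c(21L, 20L), c(7, 3))
  loci <- SSRmine:::SSRCatalog(S4Vectors::DataFrame(
    seq_id = sprintf("u%d", 1:10),
    genus = c(rep("Oryza", 6), rep("Trifolium", 4)),
    start = 1L, end = lb, period = rep(c(3L, 2L), c(7, 3)),
    motif = rep(c("AAG", "AG"), c(7, 3)),
    repeat_count = rep(c(7L, 10L), c(7, 3)),
    length_bp = lb,
    canonical_family = rep(c("AAG", "AG"), c(7, 3)),
    display_alias = rep(c("AAG", "AG"), c(7, 3))))
  ct <- composeCounts(loci)
  d <- as.data.frame(ct)
  expect_equal(grandTotal(ct), 10)
  expect_equal(as.numeric(tapply(d$count, d$period, sum)), c(3, 7))
  expect_setequal(unique(d$taxonomic_group),
                  c("Monocotyledoneae", "Eudicotyledoneae"))
  # unmapped genera are kept and reported
  df2 <- as.data.frame(loci)
  df2$genus[1] <- "Atlantis"
  ct2 <- composeCounts(SSRmine:::SSRCatalog(df2))
  expect_equal(S4Vectors::metadata(ct2)$unmapped_genera, "Atlantis")
  expect_equal(grandTotal(ct2), 10)
})

test_that("percentages round half away from zero and sum to 100", {
  t1 <- loadPaperFixture("table1")
  byp <- percentOfTotal(t1, by = "period", within = "genus")
  expect_equal(byp$percent[byp$genus == "Oryza" & byp$period == 3], 61.96)
  expect_equal(byp$percent[byp$genus == "Arabidopsis" & byp$period == 3],
               69.78)
  for (g in c("Oryza", "Arabidopsis"))
    expect_lt(abs(sum(byp$percent[byp$genus == g]) - 100), 0.05)

  t2 <- loadPaperFixture("table2")
  shares <- percentOfTotal(t2, by = "period")
  expect_equal(shares$percent[shares$period == 6], 16.38)
  expect_equal(shares$percent[shares$period == 4], 6.76)
  expect_equal(shares$percent[shares$period == 5], 7.06)
  expect_lt(abs(sum(shares$percent) - 100), 0.05)

  single <- CountTable(data.frame(period = 2L, count = 5L), axes = "period")
  expect_equal(percentOfTotal(single, by = "period")$percent, 100)
  zero <- CountTable(data.frame(period = 2L, count = 0L), axes = "period")
  expect_error(percentOfTotal(zero, by = "period"), "zero")
})

test_that("location distribution reproduces the control-genome shares", {
  t1 <- loadPaperFixture("table1")
  ld <- locationDistribution(t1)
  bc <- ld$by_category
  expect_equal(bc$percent[bc$genus == "Oryza" & bc$category == "exon"], 42.57)
  expect_equal(bc$percent[bc$genus == "Oryza" & bc$category == "UTR"], 33.00)
  expect_equal(bc$percent[bc$genus == "Oryza" & bc$category == "intron"],
               12.34)
  expect_equal(bc$percent[bc$genus == "Oryza" & bc$category == "genomic"],
               12.09)
  expect_equal(bc$percent[bc$genus == "Arabidopsis" & bc$category == "exon"],
               56.12)
  pc <- ld$by_period_within_category
  expect_equal(pc$percent[pc$genus == "Arabidopsis" & pc$period == 2 &
                            pc$category == "UTR"], 66.67)
  expect_equal(pc$percent[pc$genus == "Oryza" & pc$period == 3 &
                            pc$category == "exon"], 57.72)
})

test_that("a uniform four-category table splits 25 each", {
  tab <- CountTable(data.frame(period = 2L,
                               category = c("genomic", "intron", "UTR",
                                            "exon"),
                               count = 5L), axes = c("period", "category"))
  p <- percentOfTotal(tab, by = "category")
  expect_true(all(p$percent == 25))
})

test_that("amplification counts stutter as amplified", {
  t3 <- loadPaperFixture("table3")
  amp <- summarizeAmplification(t3)
  expect_equal(amp$overall$amplified, 13)
  expect_equal(amp$overall$rate, 54.2)
  expect_equal(amp$by_genus$rate[amp$by_genus$genus == "Trifolium"], 41.7)
  expect_equal(amp$by_genus$amplified[amp$by_genus$genus == "Centaurea"], 8)
  # all failures: zero rate
  allno <- t3
  allno$outcome <- "no_product"
  allno$n_alleles <- NA_integer_
  expect_equal(summarizeAmplification(allno)$overall$rate, 0)
})

test_that("transferability drops stutter loci and demands polymorphism", {
  t4 <- loadPaperFixture("table4")
  tr <- summarizeTransferability(t4)
  expect_equal(tr$overall$retained, 12)
  expect_equal(tr$overall$transferable, 9)
  expect_equal(tr$overall$rate, 75)
  per <- tr$per_locus
  # single identical allele in both species: functional but monomorphic
  expect_false(per$transferable[per$locus == "C6"])
  expect_false(per$transferable[per$locus == "C2"])
  expect_false(per$transferable[per$locus == "T4"])
  # one allele each but different sizes counts as polymorphic
  expect_true(per$transferable[per$locus == "C8"])
  expect_false(per$retained[per$locus == "T1"])
  # a locus amplifying in only one species is not transferable
  t4b <- as.data.frame(t4)
  t4b$outcome[t4b$locus == "C7"][1] <- "no_product"
  t4b$n_alleles[t4b$locus == "C7"][1] <- NA
  trb <- summarizeTransferability(t4b)
  expect_false(trb$per_locus$transferable[trb$per_locus$locus == "C7"])
})

test_that("synthetic catalogs recover planted family frequencies", {
  set.seed(62)
  fams <- c(AAG = 0.5, AG = 0.3, AT = 0.2)
  n <- 600
  draw <- sample(names(fams), n, replace = TRUE, prob = fams)
  per <- ifelse(draw == "AAG", 3L, 2L)
  lb <- per * 10L
  loci <- SSRmine:::SSRCatalog(S4Vectors::DataFrame(
    seq_id = sprintf("u%d", seq_len(n)), genus = "Oryza",
    start = 1L, end = lb, period = per,
    motif = draw, repeat_count = 10L, length_bp = lb,
    canonical_family = draw, display_alias = draw))
  ct <- composeCounts(loci)
  d <- as.data.frame(ct)
  obs <- tapply(d$count, d$canonical_family, sum) / n
  for (f in names(fams)) {
    se <- sqrt(fams[[f]] * (1 - fams[[f]]) / n)
    expect_lt(abs(obs[[f]] - fams[[f]]), 2 * se + 1e-9)
  }
})
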