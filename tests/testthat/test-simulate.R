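test_that("planted repeats read back exactly from the genome", {
  p <- SimParams(seed = 71L, nGenes = 12L)
  sim <- simulateGenome(p)
  expect_equal(nrow(sim$truth), 12)
  g <- as.character(sim$genome[[1]])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    expect_equal(substr(g, tr$chrom_start, tr$chrom_end),
                 strrep(tr$motif, tr$repeat_count))
  }
  # transcript coordinates agree too
  ex <- sim$truth[sim$truth$context %in% c("CDS", "UTR"), ]
  for (i in seq_len(nrow(ex))) {
    tr <- ex[i, ]
    expect_equal(substr(as.character(sim$mrna[[tr$transcript_id]]),
                        tr$mrna_start, tr$mrna_end),
                 strrep(tr$motif, tr$repeat_count))
  }
})

test_that("context restriction and family concentration are honored", {
  p <- SimParams(seed = 72L, nGenes = 5L,
                 contextMix = c(CDS = 1, UTR = 0, intron = 0, intergenic = 0),
                 familyFreqs = list(CDS = c(AG = 1)))
  sim <- simulateGenome(p)
  expect_equal(nrow(sim$truth), 5)
  expect_true(all(sim$truth$context == "CDS"))
  expect_true(all(sim$truth$canonical_family == "AG"))
  # each planted interval lies inside an annotated CDS feature
  cds <- sim$genes[sim$genes$type == "CDS"]
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    hit <- any(BiocGenerics::start(cds) <= tr$chrom_start &
                 BiocGenerics::end(cds) >= tr$chrom_end)
    expect_true(hit)
  }
})

test_that("identical parameters and seed give byte-identical artifacts", {
  p <- SimParams(seed = 73L, nGenes = 8L)
  a <- simulateGenome(p)
  b <- simulateGenome(p)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  ea <- simulateEsts(a, p)
  eb <- simulateEsts(b, p)
  expect_identical(as.character(ea$ests), as.character(eb$ests))
  expect_identical(ea$fragments, eb$fragments)
})

test_that("EST sampling respects fragment bookkeeping", {
  p <- SimParams(seed = 74L, nGenes = 30L, errorRate = 0)
  sim <- simulateGenome(p)
  est <- simulateEsts(sim, p)
  fr <- est$fragments
  expect_equal(length(est$ests), nrow(fr))
  # every fragment re-extracts from its recorded source
  src <- list(mrna = sim$mrna, premrna = sim$premrna,
              intergenic = sim$intergenic)
  for (i in sample(nrow(fr), min(25, nrow(fr)))) {
    f <- fr[i, ]
    s <- as.character(src[[f$source_type]][[f$source_id]])
    want <- substr(s, f$src_start, f$src_end)
    got <- as.character(est$ests[[f$est_id]])
    if (f$strand == "-") got <- oracleRevcomp(got)
    expect_equal(got, want)
  }
  # duplicates share a group id and are identical at zero error
  dups <- split(fr$est_id, fr$dup_group)
  dups <- dups[lengths(dups) == 2]
  if (length(dups) > 0) {
    pair <- dups[[1]]
    a <- as.character(est$ests[[pair[1]]])
    b <- as.character(est$ests[[pair[2]]])
    expect_true(a == b || a == oracleRevcomp(b))
  }
})

test_that("short-fragment rate drives the length filter loss", {
  p <- SimParams(seed = 75L, nGenes = 60L, shortFragmentRate = 0.3,
                 coveragePerTranscript = 2)
  sim <- simulateGenome(p)
  est <- simulateEsts(sim, p)
  lens <- Biostrings::width(est$ests)
  frac <- mean(lens <= 100)
  n <- length(lens)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), 3 * se + 0.02)
})

test_that("substitution errors appear at the recorded rate", {
  p <- SimParams(seed = 76L, nGenes = 20L, errorRate = 0.01)
  sim <- simulateGenome(p)
  est <- simulateEsts(sim, p)
  fr <- est$fragments
  expect_gt(sum(fr$n_errors), 0)
  tot <- sum(fr$src_end - fr$src_start + 1)
  expect_lt(abs(sum(fr$n_errors) / tot - 0.01), 0.005)
})

test_that("infeasible geometry fails loudly", {
  expect_error(SimParams(seed = 1L, contextMix = c(CDS = 0.7, UTR = 0.2,
                                                   intron = 0.2,
                                                   intergenic = 0.1)),
               "sum to 1")
  expect_error(SimParams(seed = 1L, errorRate = 1.5), "probabilities")
})
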