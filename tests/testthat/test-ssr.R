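test_that("canonical families collapse rotations and reverse complements", {
  expect_equal(canonicalFamily("TC")$canonical, "AG")
  expect_equal(canonicalFamily("GGC")$canonical, "CCG")
  expect_equal(canonicalFamily("GGC")$alias, "GGC")
  expect_equal(canonicalFamily("AT")$canonical, "AT")  # self-revcomp set
  # TGA and ATG are one family under rotation + reverse complement
  expect_equal(canonicalFamily("TGA")$canonical, "ATC")
  expect_equal(canonicalFamily("TGA")$alias, "TGA")
  expect_equal(canonicalFamily("ATG")$canonical, "ATC")
  # invariance and idempotence
  set.seed(2)
  for (m in c("AG", "ACC", "AAGT", "ACGTC", "AACGTC")) {
    fam <- canonicalFamily(m)$canonical
    p <- nchar(m)
    rot <- paste0(substr(m, 3, p), substr(m, 1, 2))
    expect_equal(canonicalFamily(rot)$canonical, fam)
    expect_equal(canonicalFamily(oracleRevcomp(m))$canonical, fam)
    expect_equal(canonicalFamily(fam)$canonical, fam)
  }
  expect_error(canonicalFamily("ATAT"), "primitive")
  expect_error(canonicalFamily("ANT"), "ACGT")
})

test_that("perfect-SSR scan finds maximal runs with exact counts", {
  s <- paste0("GATTACAGT", strrep("AG", 11), "TTTCCGATCAGT")
  loci <- findPerfectSSRs(s)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$period, 2L)
  expect_equal(loci$motif, "AG")
  expect_equal(loci$repeat_count, 11L)
  expect_equal(loci$length_bp, 22L)
  expect_equal(loci$canonical_family, "AG")
  expect_equal(substr(s, loci$start, loci$end), strrep("AG", 11))

  # exactly at the Class-I trinucleotide minimum
  s2 <- paste0("TGCATGATGGT", strrep("ACC", 7), "TTGAGATCAGTC")
  l2 <- findPerfectSSRs(s2)
  expect_equal(l2$repeat_count, 7L)
  expect_equal(l2$canonical_family, "ACC")

  # below the dinucleotide threshold: nothing
  expect_equal(nrow(findPerfectSSRs(paste0("CCTGA", strrep("AT", 9), "GGACT"))),
               0)

  # (ATAT)x5 is a dinucleotide run, never a tetranucleotide
  l4 <- findPerfectSSRs(paste0("CCTGA", strrep("ATAT", 5), "GGACT"))
  expect_equal(l4$period, 2L)
  expect_equal(l4$repeat_count, 10L)

  # runs break at ambiguity codes
  l5 <- findPerfectSSRs(paste0("CC", strrep("AG", 6), "N", strrep("AG", 6),
                               "TT"))
  expect_equal(nrow(l5), 0)
})

test_that("Class-I thresholds follow the per-period minima", {
  expect_true(isClassI(2, 10))
  expect_false(isClassI(2, 9))
  expect_true(isClassI(3, 7))
  expect_true(isClassI(4, 5))   # exactly 20 bp
  expect_true(isClassI(6, 4))   # 24 bp
  expect_error(isClassI(7, 4), "period")
  relaxed <- MiningParams(relaxed = TRUE)
  expect_true(isClassI(2, 4, relaxed))
  # Class-I loci always span >= 20 bp
  params <- MiningParams()
  for (p in 2:6)
    expect_gte(p * params@minRepeats[as.character(p)], 20)
})

test_that("mining is strand-symmetric and loci never overlap", {
  set.seed(31)
  for (i in 1:20) {
    s <- paste0(randomSeq(150), strrep(c("AG", "ACC", "AAGT")[i %% 3 + 1],
                                       12), randomSeq(150))
    a <- as.data.frame(findPerfectSSRs(s))
    b <- as.data.frame(findPerfectSSRs(oracleRevcomp(s)))
    expect_equal(
      sort(paste(a$canonical_family, a$period, a$repeat_count)),
      sort(paste(b$canonical_family, b$period, b$repeat_count)))
    if (nrow(a) > 1) {
      o <- order(a$start)
      expect_true(all(a$start[o][-1] > a$end[o][-nrow(a)]))
    }
  }
})

test_that("relaxed profile finds at least the Class-I loci plus short runs", {
  set.seed(7)
  s <- paste0(randomSeq(100), strrep("AT", 5), randomSeq(100),
              strrep("AG", 11), randomSeq(100))
  classI <- findPerfectSSRs(s)
  relaxed <- findPerfectSSRs(s, MiningParams(relaxed = TRUE))
  expect_gte(nrow(relaxed), nrow(classI))
  expect_true("AT" %in% relaxed$canonical_family)
  expect_false("AT" %in% classI$canonical_family)
})

test_that("genus mining concatenates per-sequence results with labels", {
  set.seed(8)
  seqs <- c(u1 = paste0(randomSeq(120), strrep("AG", 10), randomSeq(120)),
            u2 = paste0(randomSeq(120), strrep("CT", 12), randomSeq(120)),
            u3 = randomSeq(200))
  x <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(x)$genus <- rep("Testus", 3)
  loci <- mineGenus(x)
  expect_equal(sort(unique(loci$seq_id)), c("u1", "u2"))
  expect_equal(unique(loci$genus), "Testus")
  expect_true(all(loci$canonical_family == "AG"))
  expect_equal(nrow(mineGenus(x[0])), 0)
})
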