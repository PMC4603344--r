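test_that("GC fraction is a plain letter count", {
  expect_equal(gcFraction("ACGT"), 0.5)
  expect_equal(gcFraction("AAAA"), 0)
  # a published forward primer: 11 G/C over 21 nt
  expect_equal(gcFraction("CAACCAGTGGTGTGAGTAGGA"), 11 / 21, tolerance = 1e-12)
  expect_error(gcFraction("ACGN"), "ACGT")
})

test_that("gc_linear melting temperatures match the closed form", {
  # 20-mer, 10 G/C: 64.9 + 41 (10 - 16.4) / 20
  s <- paste0(strrep("A", 10), strrep("G", 10))
  expect_equal(as.numeric(meltingTemperature(s, "gc_linear")), 51.78,
               tolerance = 1e-9)
  expect_equal(as.numeric(meltingTemperature(strrep("A", 20), "gc_linear")),
               64.9 + 41 * (-16.4) / 20, tolerance = 1e-9)
  expect_error(meltingTemperature("ACGTACGTACGT", "gc_linear"), "14")
})

test_that("nearest-neighbor Tm reproduces reference duplex estimates", {
  # frozen from an independent SantaLucia-1998 implementation
  # (50 mM Na+, 500 nM oligo, entropic salt correction)
  ref <- c(ACGTACGTACGTACGTACGT = 56.1458,
           CAACCAGTGGTGTGAGTAGGA = 56.4763,
           GACGTTGGTGGAGAGGTTGAG = 57.8289,
           ACAACCCATTTGCCTCAAAG = 54.1605)
  got <- meltingTemperature(names(ref))
  expect_equal(as.numeric(got), unname(ref), tolerance = 1e-3)
  # strand symmetry of the nearest-neighbor table
  set.seed(41)
  for (i in 1:5) {
    s <- randomSeq(20)
    expect_equal(as.numeric(meltingTemperature(s)),
                 as.numeric(meltingTemperature(oracleRevcomp(s))),
                 tolerance = 1e-9)
  }
})

test_that("self-complementarity screens agree between forms", {
  set.seed(42)
  seqs <- vapply(1:100, function(i) randomSeq(sample(18:23, 1)), character(1))
  slow <- vapply(seqs, SSRmine:::selfCompExceeds, logical(1), maxLen = 8L)
  fast <- SSRmine:::selfCompViolates(seqs, 8L)
  expect_equal(unname(slow), fast)
  hairpin <- paste0("GGGGCCCC", randomSeq(10), "GGGGCCCC")  # 8-mer palindrome
  expect_true(SSRmine:::selfCompExceeds(hairpin, 7L))
})

test_that("designed pairs satisfy every hard constraint by re-measurement", {
  set.seed(43)
  found <- 0
  for (i in 1:10) {
    tpl <- paste0(randomSeq(280, gc = 0.55), strrep("AG", 12),
                  randomSeq(280, gc = 0.55))
    pp <- designPrimers(tpl, 281, 304, PrimerParams())
    if (nrow(pp) == 0) next
    found <- found + 1
    expect_true(all(nchar(pp$forward_seq) %in% 18:23))
    expect_true(all(nchar(pp$reverse_seq) %in% 18:23))
    expect_true(all(pp$gc_f >= 0.3 & pp$gc_f <= 0.7))
    expect_true(all(pp$gc_r >= 0.3 & pp$gc_r <= 0.7))
    expect_true(all(pp$tm_f >= 55 & pp$tm_f <= 65))
    expect_true(all(pp$tm_r >= 55 & pp$tm_r <= 65))
    expect_true(all(abs(pp$tm_f - pp$tm_r) <= 3))
    expect_true(all(pp$product_size >= 90 & pp$product_size <= 320))
    expect_true(all(pp$product_size == pp$r_end - pp$f_start + 1))
    # primers flank, never overlap, the repeat run
    expect_true(all(pp$f_end < 281))
    expect_true(all(pp$r_start > 304))
    # sequences re-derive from the template
    expect_equal(substring(tpl, pp$f_start[1], pp$f_end[1]),
                 pp$forward_seq[1])
    expect_equal(oracleRevcomp(substring(tpl, pp$r_start[1], pp$r_end[1])),
                 pp$reverse_seq[1])
    # re-measured Tm and GC match the reported values
    expect_equal(pp$gc_f[1], gcFraction(pp$forward_seq[1]))
    expect_equal(as.numeric(meltingTemperature(pp$forward_seq[1])),
                 pp$tm_f[1])
  }
  expect_gt(found, 3)
})

test_that("no room for a forward primer means an undesignable locus", {
  set.seed(44)
  tpl <- paste0(randomSeq(10), strrep("AG", 12), randomSeq(300))
  expect_equal(nrow(designPrimers(tpl, 11, 34)), 0)
})

test_that("penalty is zero only at the joint optimum", {
  p <- PrimerParams()
  w <- p@weights
  pen <- function(lf, lr, tf, tr, gf, gr)
    w["len"] * (abs(lf - 20) + abs(lr - 20)) +
    w["tm"] * (abs(tf - 60) + abs(tr - 60)) +
    w["gc"] * (abs(gf - 0.5) + abs(gr - 0.5)) * 100 + w["pair"] * abs(tf - tr)
  expect_equal(unname(pen(20, 20, 60, 60, 0.5, 0.5)), 0)
  expect_gt(pen(21, 20, 60, 60, 0.5, 0.5), 0)
  expect_gt(pen(20, 20, 61, 60, 0.5, 0.5), 0)
})

test_that("relaxing a hard constraint never loses designable loci", {
  set.seed(45)
  tight <- PrimerParams()
  loose <- PrimerParams(gcRange = c(0.25, 0.75), tmRange = c(50, 70),
                        productRange = c(80L, 400L))
  n_tight <- 0; n_loose <- 0
  for (i in 1:8) {
    tpl <- paste0(randomSeq(250, gc = 0.5), strrep("ACC", 8),
                  randomSeq(250, gc = 0.5))
    n_tight <- n_tight + (nrow(designPrimers(tpl, 251, 274, tight,
                                             best = TRUE)) > 0)
    n_loose <- n_loose + (nrow(designPrimers(tpl, 251, 274, loose,
                                             best = TRUE)) > 0)
  }
  expect_gte(n_loose, n_tight)
})

test_that("catalog keeps exactly the designable loci with their best pair", {
  set.seed(46)
  good <- paste0(randomSeq(260, gc = 0.55), strrep("AG", 11),
                 randomSeq(260, gc = 0.55))
  cramped <- paste0(randomSeq(5), strrep("AG", 11), randomSeq(5))
  nrich <- paste0(strrep("N", 150), strrep("AG", 11), strrep("N", 150))
  seqs <- Biostrings::DNAStringSet(c(u1 = good, u2 = cramped, u3 = nrich))
  S4Vectors::mcols(seqs)$genus <- rep("Testus", 3)
  loci <- mineGenus(seqs)
  expect_equal(sort(unique(loci$seq_id)), c("u1", "u2", "u3"))
  cat3 <- catalogWithPrimers(loci, seqs)
  expect_true(all(cat3$seq_id == "u1"))
  if (nrow(cat3) == 1)
    expect_equal(cat3$penalty,
                 designPrimers(good, 261, 282, best = TRUE)$penalty)
})
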