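mkSet <- function(seqs, genus = "Testus") {
  x <- Biostrings::DNAStringSet(seqs)
  S4Vectors::mcols(x)$genus <- rep(genus, length(x))
  x
}

test_that("identical sequences collapse to one contig", {
  set.seed(21)
  s <- randomSeq(200)
  u <- reduceRedundancy(mkSet(c(a = s, b = s)))
  expect_length(u, 1)
  expect_equal(S4Vectors::mcols(u)$kind, "contig")
  expect_setequal(S4Vectors::mcols(u)$members[[1]], c("a", "b"))
  expect_equal(as.character(u[[1]]), s)
})

test_that("sequences below the identity threshold stay separate", {
  set.seed(22)
  s <- randomSeq(200)
  v <- strsplit(s, "")[[1]]
  idx <- sample(200, 24)  # 12% substitutions
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  s2 <- paste(v, collapse = "")
  u <- reduceRedundancy(mkSet(c(a = s, b = s2)))
  expect_length(u, 2)
  expect_true(all(S4Vectors::mcols(u)$kind == "singleton"))
})

test_that("near-identical pair merges, unrelated sequence stays out", {
  set.seed(23)
  s <- randomSeq(200)
  v <- strsplit(s, "")[[1]]
  for (i in sample(200, 2)) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  s2 <- paste(v, collapse = "")
  b <- randomSeq(200)
  u <- reduceRedundancy(mkSet(c(x = s, y = s2, z = b)))
  expect_length(u, 2)
  kinds <- sort(S4Vectors::mcols(u)$kind)
  expect_equal(kinds, c("contig", "singleton"))
  contig <- which(S4Vectors::mcols(u)$kind == "contig")
  expect_setequal(S4Vectors::mcols(u)$members[[contig]], c("x", "y"))
})

test_that("reverse-complement copies join and are re-oriented", {
  set.seed(24)
  s <- randomSeq(300)
  u <- reduceRedundancy(mkSet(c(fw = s, rc = oracleRevcomp(s))))
  expect_length(u, 1)
  expect_equal(as.character(u[[1]]), s)
  expect_setequal(S4Vectors::mcols(u)$members[[1]], c("fw", "rc"))
})

test_that("membership conserves every input record exactly once", {
  set.seed(25)
  base <- vapply(1:6, function(i) randomSeq(250), character(1))
  seqs <- c(base, base[1:3], vapply(1:4, function(i) randomSeq(150),
                                    character(1)))
  names(seqs) <- sprintf("r%02d", seq_along(seqs))
  u <- reduceRedundancy(mkSet(seqs))
  members <- unlist(S4Vectors::mcols(u)$members)
  expect_setequal(members, names(seqs))
  expect_equal(length(members), length(seqs))
})

test_that("clustering is order-independent", {
  set.seed(26)
  base <- randomSeq(300)
  seqs <- c(a = base, b = substr(base, 20, 300), c = randomSeq(220),
            d = oracleRevcomp(base))
  u1 <- reduceRedundancy(mkSet(seqs))
  u2 <- reduceRedundancy(mkSet(seqs[c(3, 1, 4, 2)]))
  key <- function(u) {
    m <- lapply(S4Vectors::mcols(u)$members, sort)
    m[order(vapply(m, paste, character(1), collapse = ","))]
  }
  expect_equal(key(u1), key(u2))
})

test_that("contig consensus takes the per-column majority", {
  set.seed(27)
  s <- randomSeq(200)
  v <- strsplit(s, "")[[1]]
  pos <- 57
  alt <- setdiff(c("A", "C", "G", "T"), v[pos])[1]
  v2 <- v; v2[pos] <- alt
  s2 <- paste(v2, collapse = "")
  # two copies of the variant against one representative-length original:
  # equal-length processing order is id-ascending, so "a" is representative
  u <- reduceRedundancy(mkSet(c(a = s, b = s2, c = s2)))
  expect_length(u, 1)
  expect_equal(substr(as.character(u[[1]]), pos, pos), alt)
})

test_that("length filter keeps only sequences strictly longer than cutoff", {
  set.seed(28)
  x <- Biostrings::DNAStringSet(c(a = randomSeq(100), b = randomSeq(101),
                                  c = randomSeq(250)))
  kept <- filterMinLength(x, 100L)
  expect_equal(names(kept), c("b", "c"))
  expect_length(filterMinLength(x[0]), 0)
  expect_length(filterMinLength(x, 50L), 3)
})
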