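mkGenes <- function(df) {
  g <- GenomicRanges::GRanges(df$seqnames,
                              IRanges::IRanges(df$start, df$end),
                              strand = "+")
  g$type <- df$type
  g$transcript_id <- df$transcript_id
  g$gene_id <- sub("^t", "g", df$transcript_id)
  g
}

mkHit <- function(qid, blocks, strand = "+", pident = 1, evalue = NA_real_) {
  h <- S4Vectors::DataFrame(query_id = qid, subject_id = "chr1",
                            strand = strand, pident = pident,
                            aligned_length = sum(blocks$q_end -
                                                   blocks$q_start + 1L),
                            evalue = evalue)
  h$blocks <- list(blocks)
  SSRmine:::AlignmentHits(h)
}

mkLocus <- function(qid, start, end, period = 2L) {
  SSRmine:::SSRCatalog(S4Vectors::DataFrame(
    seq_id = qid, genus = "Testus", start = start, end = end,
    period = period, motif = strrep("AG", period / 2),
    repeat_count = as.integer((end - start + 1) / period),
    length_bp = end - start + 1L,
    canonical_family = "AG", display_alias = "AG"))
}

genesDf <- data.frame(
  seqnames = "chr1",
  start = c(1001, 1101, 1301, 1501, 1701),
  end = c(1100, 1300, 1500, 1700, 1800),
  type = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR"),
  transcript_id = "t1")

test_that("wholly exonic, UTR and intergenic projections classify correctly", {
  genes <- mkGenes(genesDf)
  # query aligned 1..900 onto subject 1001..1900
  blocks <- data.frame(q_start = 1, q_end = 900, s_start = 1001, s_end = 1900)
  # SSR q 151..190 -> s 1151..1190, inside CDS
  call <- classifyContext(mkLocus("q", 151, 190)[1, ], mkHit("q", blocks),
                          genes)
  expect_equal(call$category, "exon")
  expect_equal(c(call$s_start, call$s_end), c(1151, 1190))
  expect_equal(call$frac_exon, 1)
  # SSR q 21..50 -> 5' UTR
  expect_equal(classifyContext(mkLocus("q", 21, 50)[1, ], mkHit("q", blocks),
                               genes)$category, "UTR")
  # SSR q 851..880 -> s 1851..1880, past every feature: genomic
  expect_equal(classifyContext(mkLocus("q", 851, 880)[1, ], mkHit("q", blocks),
                               genes)$category, "genomic")
})

test_that("majority overlap decides, priority breaks ties", {
  genes <- mkGenes(genesDf)
  blocks <- data.frame(q_start = 1, q_end = 900, s_start = 1001, s_end = 1900)
  # 60% in 3' UTR (1701..), 40% in CDS: s 1689..1718 -> q 689..718
  call <- classifyContext(mkLocus("q", 689, 718)[1, ], mkHit("q", blocks),
                          genes)
  expect_equal(call$category, "UTR")
  expect_equal(call$frac_UTR, 0.6)
  expect_equal(call$frac_exon, 0.4)
  # exact 50/50 across CDS|intron boundary: priority exon > intron
  call2 <- classifyContext(mkLocus("q", 291, 310)[1, ], mkHit("q", blocks),
                           genes)
  expect_equal(call2$frac_exon, 0.5)
  expect_equal(call2$frac_intron, 0.5)
  expect_equal(call2$category, "exon")
})

test_that("no significant hit gives no_hit; thresholds are honored", {
  genes <- mkGenes(genesDf)
  blocks <- data.frame(q_start = 1, q_end = 40, s_start = 1001, s_end = 1040)
  weak <- mkHit("q", blocks, pident = 0.8)       # below identity threshold
  expect_equal(classifyContext(mkLocus("q", 5, 24)[1, ], weak,
                               genes)$category, "no_hit")
  short <- mkHit("q", blocks, pident = 1)        # aligned length 40 < 50
  expect_equal(classifyContext(mkLocus("q", 5, 24)[1, ], short,
                               genes)$category, "no_hit")
  none <- mkHit("other", blocks)
  expect_equal(classifyContext(mkLocus("q", 5, 24)[1, ], none,
                               genes)$category, "no_hit")
  # E-value mode honors supplied E-values
  ev <- mkHit("q", data.frame(q_start = 1, q_end = 200, s_start = 1001,
                              s_end = 1200), evalue = 1e-3)
  expect_equal(classifyContext(mkLocus("q", 151, 190)[1, ], ev, genes,
                               SignificanceParams(mode = "evalue"))$category,
               "no_hit")
  ev2 <- mkHit("q", data.frame(q_start = 1, q_end = 200, s_start = 1001,
                               s_end = 1200), evalue = 1e-8)
  expect_equal(classifyContext(mkLocus("q", 151, 190)[1, ], ev2, genes,
                               SignificanceParams(mode = "evalue"))$category,
               "exon")
})

test_that("classification is invariant under the mirrored minus-strand hit", {
  genes <- mkGenes(genesDf)
  qlen <- 900
  plus <- mkHit("q", data.frame(q_start = 1, q_end = 900,
                                s_start = 1001, s_end = 1900))
  # the same alignment seen from the reverse-complemented query
  minus <- mkHit("q", data.frame(q_start = 1, q_end = 900,
                                 s_start = 1001, s_end = 1900),
                 strand = "-")
  a <- classifyContext(mkLocus("q", 151, 190)[1, ], plus, genes)
  b <- classifyContext(mkLocus("q", qlen - 190 + 1, qlen - 151 + 1)[1, ],
                       minus, genes)
  expect_equal(a$category, b$category)
  expect_equal(c(a$s_start, a$s_end), c(b$s_start, b$s_end))
})

test_that("context table cross-tabulates and reports the exclusion fraction", {
  genes <- mkGenes(genesDf)
  blocks <- data.frame(q_start = 1, q_end = 900, s_start = 1001, s_end = 1900)
  loci <- do.call(rbind, list(mkLocus("q", 151, 190), mkLocus("q", 21, 50),
                              mkLocus("nohit", 21, 50)))
  hits <- mkHit("q", blocks)
  calls <- classifyContexts(SSRmine:::SSRCatalog(loci), hits, genes)
  tab <- contextTable(calls)
  d <- as.data.frame(tab)
  expect_equal(sum(d$count), 2)
  expect_equal(d$count[d$period == 2 & d$category == "exon"], 1)
  expect_equal(d$count[d$period == 2 & d$category == "UTR"], 1)
  expect_equal(S4Vectors::metadata(tab)$exclusion_fraction, 1 / 3)
  # all no_hit: empty table, exclusion 1
  calls2 <- classifyContexts(mkLocus("nohit", 21, 50), hits, genes)
  tab2 <- contextTable(calls2)
  expect_equal(sum(as.data.frame(tab2)$count), 0)
  expect_equal(S4Vectors::metadata(tab2)$exclusion_fraction, 1)
})

test_that("fixture counts survive a round trip through the table type", {
  t1 <- loadPaperFixture("table1")
  d <- as.data.frame(t1)
  expect_equal(sum(d$count[d$genus == "Oryza"]), 397)
  expect_equal(sum(d$count[d$genus == "Arabidopsis"]), 139)
})
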