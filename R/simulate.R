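#' Parameters for the synthetic EST study generator
#'
#' Defines the simulated study conditions: gene architecture, background
#' base composition, where and how often microsatellites are planted, the
#' motif-family mix per genomic context (trinucleotide families enriched
#' in coding sequence, dinucleotide families in untranslated regions,
#' mirroring the compositional structure seen in plant ESTs), and the EST
#' sampling process (coverage, fragment lengths, substitution errors,
#' intron retention, genomic contamination, sub-100-bp fragments and
#' exact duplicates).
#'
#' @slot seed integer RNG seed.
#' @slot nGenes number of genes.
#' @slot exonCountRange,exonLenRange,intronLenRange,utrLenRange integer
#'   ranges (bp) for gene architecture.
#' @slot gcBackground background GC fraction.
#' @slot ssrPlantRate per-transcript probability of planting one SSR.
#' @slot contextMix named probabilities over CDS/UTR/intron/intergenic.
#' @slot familyFreqs named list (per context) of named probability
#'   vectors over canonical families.
#' @slot repeatCountRange named list (per period "2".."6") of integer
#'   ranges for planted repeat counts.
#' @slot coveragePerTranscript mean of the per-transcript Poisson
#'   fragment count.
#' @slot fragmentLenRange sampled fragment length range (bp), truncated
#'   at the source length.
#' @slot errorRate per-base substitution probability.
#' @slot intronRetentionRate fraction of transcript fragments drawn from
#'   unspliced pre-mRNA.
#' @slot genomicFragmentRate fraction of fragments drawn from intergenic
#'   genome.
#' @slot shortFragmentRate fraction of fragments truncated below 100 bp
#'   (exercises the length filter).
#' @slot duplicateRate probability that a fragment is emitted twice.
#' @export
setClass("SimParams", representation(
  seed = "integer", nGenes = "integer",
  exonCountRange = "integer", exonLenRange = "integer",
  intronLenRange = "integer", utrLenRange = "integer",
  gcBackground = "numeric", ssrPlantRate = "numeric",
  contextMix = "numeric", familyFreqs = "list",
  repeatCountRange = "list", coveragePerTranscript = "numeric",
  fragmentLenRange = "integer", errorRate = "numeric",
  intronRetentionRate = "numeric", genomicFragmentRate = "numeric",
  shortFragmentRate = "numeric", duplicateRate = "numeric"))

setValidity("SimParams", function(object) {
  msg <- NULL
  probs <- c(object@ssrPlantRate, object@errorRate,
             object@intronRetentionRate, object@genomicFragmentRate,
             object@shortFragmentRate, object@duplicateRate,
             object@gcBackground)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0,1]")
  if (abs(sum(object@contextMix) - 1) > 1e-9)
    msg <- c(msg, "contextMix must sum to 1")
  if (!all(names(object@contextMix) == c("CDS", "UTR", "intron", "intergenic")))
    msg <- c(msg, "contextMix must be named CDS/UTR/intron/intergenic")
  for (ctx in names(object@familyFreqs)) {
    if (abs(sum(object@familyFreqs[[ctx]]) - 1) > 1e-9)
      msg <- c(msg, sprintf("familyFreqs[%s] must sum to 1", ctx))
  }
  if (is.null(msg)) TRUE else msg
})

#' @param seed,nGenes,exonCountRange,exonLenRange,intronLenRange,utrLenRange
#'   see slots.
#' @param gcBackground,ssrPlantRate,contextMix,familyFreqs,repeatCountRange
#'   see slots.
#' @param coveragePerTranscript,fragmentLenRange,errorRate see slots.
#' @param intronRetentionRate,genomicFragmentRate,shortFragmentRate see
#'   slots.
#' @param duplicateRate see slots.
#' @return A `SimParams` object.
#' @rdname SimParams-class
#' @export
SimParams <- function(seed = 1L, nGenes = 200L,
                      exonCountRange = c(2L, 4L),
                      exonLenRange = c(150L, 400L),
                      intronLenRange = c(80L, 250L),
                      utrLenRange = c(80L, 250L),
                      gcBackground = 0.42,
                      ssrPlantRate = 1.0,
                      contextMix = c(CDS = 0.45, UTR = 0.33,
                                     intron = 0.12, intergenic = 0.10),
                      familyFreqs = defaultFamilyFreqs(),
                      repeatCountRange = list(`2` = c(10L, 15L), `3` = c(7L, 11L),
                                              `4` = c(5L, 7L), `5` = c(4L, 6L),
                                              `6` = c(4L, 5L)),
                      coveragePerTranscript = 3,
                      fragmentLenRange = c(1500L, 2500L),
                      errorRate = 0.002,
                      intronRetentionRate = 0.10,
                      genomicFragmentRate = 0.05,
                      shortFragmentRate = 0.05,
                      duplicateRate = 0.20) {
  new("SimParams", seed = as.integer(seed), nGenes = as.integer(nGenes),
      exonCountRange = as.integer(exonCountRange),
      exonLenRange = as.integer(exonLenRange),
      intronLenRange = as.integer(intronLenRange),
      utrLenRange = as.integer(utrLenRange),
      gcBackground = gcBackground, ssrPlantRate = ssrPlantRate,
      contextMix = contextMix, familyFreqs = familyFreqs,
      repeatCountRange = repeatCountRange,
      coveragePerTranscript = coveragePerTranscript,
      fragmentLenRange = as.integer(fragmentLenRange),
      errorRate = errorRate, intronRetentionRate = intronRetentionRate,
      genomicFragmentRate = genomicFragmentRate,
      shortFragmentRate = shortFragmentRate, duplicateRate = duplicateRate)
}

#' Default context-conditional motif-family frequencies
#'
#' Trinucleotide families dominate in coding sequence, dinucleotide
#' families (mostly AG) in UTRs and other non-coding contexts.
#'
#' @return Named list of named probability vectors (canonical family
#'   names).
#' @export
defaultFamilyFreqs <- function() {
  canon <- function(x) canonicalFamily(x)$canonical
  list(
    CDS = stats::setNames(
      c(0.22, 0.16, 0.14, 0.12, 0.12, 0.06, 0.10, 0.08),
      canon(c("AAG", "ACC", "AGG", "AGC", "CCG", "ACG", "AAGCAG", "AATCGG"))),
    UTR = stats::setNames(
      c(0.45, 0.15, 0.10, 0.10, 0.05, 0.05, 0.05, 0.05),
      canon(c("AG", "AC", "AT", "AAG", "ACC", "AAT", "ACCT", "AATCC"))),
    intron = stats::setNames(
      c(0.30, 0.25, 0.15, 0.15, 0.10, 0.05),
      canon(c("AG", "AT", "AC", "AAT", "AGT", "AAAT"))),
    intergenic = stats::setNames(
      c(0.25, 0.30, 0.15, 0.10, 0.10, 0.10),
      canon(c("AG", "AT", "AC", "AAT", "AAAT", "AATAT"))))
}

randomDNA <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# pick a concrete motif occurrence for a canonical family (any rotation
# of the family's two strand forms)
motifFromFamily <- function(family) {
  forms <- unique(c(rotationsOf(family), rotationsOf(revcompChar(family))))
  sample(forms, 1)
}

# insert an SSR string into a background piece, fixing the junction bases
# so the planted run stays maximal and exactly repeat_count units long
insertSSR <- function(piece, ssr, motif) {
  n <- nchar(piece)
  p <- nchar(motif)
  pos <- if (n <= 2) 1L else sample(seq_len(n - 1L), 1) + 1L  # insert before pos
  left <- substr(piece, 1, pos - 1L)
  right <- substr(piece, pos, n)
  lastc <- substr(motif, p, p)
  firstc <- substr(motif, 1, 1)
  if (nchar(left) > 0 && substr(left, nchar(left), nchar(left)) == lastc) {
    alt <- setdiff(c("A", "C", "G", "T"), lastc)
    substr(left, nchar(left), nchar(left)) <- sample(alt, 1)
  }
  if (nchar(right) > 0 && substr(right, 1, 1) == firstc) {
    alt <- setdiff(c("A", "C", "G", "T"), firstc)
    substr(right, 1, 1) <- sample(alt, 1)
  }
  list(seq = paste0(left, ssr, right), offset = nchar(left))
}

#' Simulate an annotated toy genome with planted microsatellites
#'
#' Builds one chromosome of `nGenes` genes (5'UTR - exons/introns -
#' 3'UTR, plus strand) separated by intergenic spacers, on an i.i.d.
#' background of the given GC fraction. Per transcript, with probability
#' `ssrPlantRate`, one SSR is planted: its context is drawn from
#' `contextMix`, its canonical family from `familyFreqs[[context]]`, its
#' concrete motif uniformly from the family's rotations and
#' reverse-complement rotations, and its repeat count uniformly from
#' `repeatCountRange`. SSRs are inserted (flanks displaced, junction
#' bases adjusted), so ground-truth repeat counts are exact. Spontaneous
#' Class-I repeats already present in the background are recorded
#' separately by running the miner on each pre-insertion transcript.
#' Identical parameters and seed give byte-identical output.
#'
#' @param params a [SimParams] object.
#' @return A list with elements `genome` (one-sequence
#'   [Biostrings::DNAStringSet], "chr1"), `genes` (feature
#'   [GenomicRanges::GRanges] as from [readGff3Genes()]), `mrna` and
#'   `premrna` (named [Biostrings::DNAStringSet] of spliced and unspliced
#'   transcripts), `intergenic` (named [Biostrings::DNAStringSet] of
#'   spacers with their chromosome offsets in
#'   `metadata`), `truth` (a data.frame per planted SSR: id, context,
#'   motif, period, repeat count, canonical family, chromosome and
#'   transcript coordinates) and `spontaneous` (a data.frame of
#'   background repeats per transcript).
#' @export
simulateGenome <- function(params = SimParams()) {
  set.seed(params@seed)
  gc <- params@gcBackground
  genesList <- list()
  truth <- list()
  spont <- list()
  chromParts <- character(0)
  chromLen <- 0L
  mrna <- character(0); premrna <- character(0)
  intergenic <- character(0); intergenicOff <- integer(0)

  addSpacer <- function(withSSR, fam) {
    len <- sample(400:800, 1)
    s <- randomDNA(len, gc)
    off <- 0L
    ssrRow <- NULL
    if (withSSR) {
      motif <- motifFromFamily(fam)
      p <- nchar(motif)
      k <- sample(seq(params@repeatCountRange[[as.character(p)]][1],
                      params@repeatCountRange[[as.character(p)]][2]), 1)
      ins <- insertSSR(s, strrep(motif, k), motif)
      s <- ins$seq
      ssrRow <- list(motif = motif, period = p, repeat_count = k,
                     offset = ins$offset)
    }
    list(seq = s, ssr = ssrRow)
  }

  mixNames <- names(params@contextMix)
  for (g in seq_len(params@nGenes)) {
    txid <- sprintf("tx%04d", g)
    gid <- sprintf("g%04d", g)
    plant <- stats::runif(1) < params@ssrPlantRate
    ctx <- if (plant) sample(mixNames, 1, prob = params@contextMix) else NA
    fam <- if (plant) {
      ff <- params@familyFreqs[[ctx]]
      sample(names(ff), 1, prob = ff)
    } else NA

    # intergenic spacer before the gene (carries the SSR when intergenic)
    sp <- addSpacer(plant && ctx == "intergenic", fam)
    spOff <- chromLen
    chromParts <- c(chromParts, sp$seq)
    intergenic <- c(intergenic, sp$seq)
    intergenicOff <- c(intergenicOff, spOff)
    if (!is.null(sp$ssr)) {
      truth[[length(truth) + 1L]] <- data.frame(
        ssr_id = sprintf("ssr%04d", length(truth) + 1L),
        context = "intergenic", motif = sp$ssr$motif,
        period = sp$ssr$period, repeat_count = sp$ssr$repeat_count,
        chrom_start = spOff + sp$ssr$offset + 1L,
        chrom_end = spOff + sp$ssr$offset + sp$ssr$period * sp$ssr$repeat_count,
        transcript_id = NA_character_,
        mrna_start = NA_integer_, mrna_end = NA_integer_,
        premrna_start = NA_integer_, premrna_end = NA_integer_)
    }
    chromLen <- chromLen + nchar(sp$seq)

    nex <- sample(seq(params@exonCountRange[1], params@exonCountRange[2]), 1)
    if (plant && ctx == "intron" && nex < 2) nex <- 2L
    exLens <- sample(seq(params@exonLenRange[1], params@exonLenRange[2]),
                     nex, replace = TRUE)
    inLens <- if (nex > 1)
      sample(seq(params@intronLenRange[1], params@intronLenRange[2]),
             nex - 1, replace = TRUE) else integer(0)
    utr5 <- randomDNA(sample(seq(params@utrLenRange[1],
                                 params@utrLenRange[2]), 1), gc)
    utr3 <- randomDNA(sample(seq(params@utrLenRange[1],
                                 params@utrLenRange[2]), 1), gc)
    exons <- vapply(exLens, randomDNA, character(1), gc = gc)
    introns <- vapply(inLens, randomDNA, character(1), gc = gc)

    # pre-insertion spliced background, mined for spontaneous repeats
    bg <- paste0(utr5, paste(exons, collapse = ""), utr3)

    ssrInfo <- NULL
    if (plant && ctx != "intergenic") {
      motif <- motifFromFamily(fam)
      p <- nchar(motif)
      k <- sample(seq(params@repeatCountRange[[as.character(p)]][1],
                      params@repeatCountRange[[as.character(p)]][2]), 1)
      ssrStr <- strrep(motif, k)
      if (ctx == "CDS") {
        ei <- sample(seq_len(nex), 1)
        ins <- insertSSR(exons[ei], ssrStr, motif)
        exons[ei] <- ins$seq
        ssrInfo <- list(kind = "CDS", idx = ei, offset = ins$offset)
      } else if (ctx == "UTR") {
        side <- sample(c(5L, 3L), 1)
        if (side == 5L) {
          ins <- insertSSR(utr5, ssrStr, motif)
          utr5 <- ins$seq
        } else {
          ins <- insertSSR(utr3, ssrStr, motif)
          utr3 <- ins$seq
        }
        ssrInfo <- list(kind = "UTR", idx = side, offset = ins$offset)
      } else {
        ii <- sample(seq_len(nex - 1L), 1)
        ins <- insertSSR(introns[ii], ssrStr, motif)
        introns[ii] <- ins$seq
        ssrInfo <- list(kind = "intron", idx = ii, offset = ins$offset)
      }
      ssrInfo$motif <- motif; ssrInfo$period <- p; ssrInfo$repeat_count <- k
    }

    # assemble gene on the chromosome; record features
    geneStart <- chromLen + 1L
    pieces <- c(list(c("five_prime_UTR", utr5)))
    for (i in seq_len(nex)) {
      pieces <- c(pieces, list(c("CDS", exons[i])))
      if (i < nex) pieces <- c(pieces, list(c("intron", introns[i])))
    }
    pieces <- c(pieces, list(c("three_prime_UTR", utr3)))
    feat <- list(); pos <- geneStart
    for (pc in pieces) {
      w <- nchar(pc[2])
      feat[[length(feat) + 1L]] <- data.frame(type = pc[1], start = pos,
                                              end = pos + w - 1L)
      pos <- pos + w
    }
    feat <- do.call(rbind, feat)
    chromParts <- c(chromParts, vapply(pieces, `[`, character(1), 2))
    chromLen <- pos - 1L

    genesList[[length(genesList) + 1L]] <-
      GenomicRanges::GRanges("chr1",
                             IRanges::IRanges(feat$start, feat$end),
                             strand = "+", type = feat$type,
                             transcript_id = txid, gene_id = gid)

    mrnaSeq <- paste0(utr5, paste(exons, collapse = ""), utr3)
    pre <- paste0(utr5, paste(vapply(seq_len(nex), function(i) {
      if (i < nex) paste0(exons[i], introns[i]) else exons[i]
    }, character(1)), collapse = ""), utr3)
    mrna[txid] <- mrnaSeq
    premrna[txid] <- pre

    # coordinates of the planted SSR in all frames
    if (!is.null(ssrInfo)) {
      p <- ssrInfo$period; k <- ssrInfo$repeat_count
      len <- p * k
      u5 <- nchar(utr5)
      exCum <- cumsum(c(0L, nchar(exons)))
      inCum <- cumsum(c(0L, nchar(introns)))
      if (ssrInfo$kind == "CDS") {
        ei <- ssrInfo$idx
        m_start <- u5 + exCum[ei] + ssrInfo$offset + 1L
        pm_start <- u5 + exCum[ei] + (if (ei > 1) inCum[ei] else 0L) +
          ssrInfo$offset + 1L
        ctxName <- "CDS"
      } else if (ssrInfo$kind == "UTR") {
        if (ssrInfo$idx == 5L) {
          m_start <- ssrInfo$offset + 1L
          pm_start <- m_start
        } else {
          m_start <- u5 + exCum[nex + 1L] + ssrInfo$offset + 1L
          pm_start <- u5 + exCum[nex + 1L] + inCum[nex] + ssrInfo$offset + 1L
        }
        ctxName <- "UTR"
      } else {
        ii <- ssrInfo$idx
        m_start <- NA_integer_
        pm_start <- u5 + exCum[ii + 1L] + (if (ii > 1) inCum[ii] else 0L) +
          ssrInfo$offset + 1L
        ctxName <- "intron"
      }
      chromStart <- geneStart + pm_start - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        ssr_id = sprintf("ssr%04d", length(truth) + 1L),
        context = ctxName, motif = ssrInfo$motif, period = p,
        repeat_count = k,
        chrom_start = chromStart, chrom_end = chromStart + len - 1L,
        transcript_id = txid,
        mrna_start = m_start,
        mrna_end = if (is.na(m_start)) NA_integer_ else m_start + len - 1L,
        premrna_start = pm_start, premrna_end = pm_start + len - 1L)
    }

    spLoci <- findPerfectSSRs(bg, MiningParams(), seqId = txid)
    if (nrow(spLoci) > 0)
      spont[[length(spont) + 1L]] <-
        as.data.frame(spLoci)[, c("seq_id", "period", "motif",
                                  "repeat_count", "canonical_family")]
  }
  # trailing spacer
  sp <- addSpacer(FALSE, NA)
  intergenic <- c(intergenic, sp$seq)
  intergenicOff <- c(intergenicOff, chromLen)
  chromParts <- c(chromParts, sp$seq)

  genome <- Biostrings::DNAStringSet(paste(chromParts, collapse = ""))
  names(genome) <- "chr1"
  genes <- BiocGenerics::sort(do.call(c, genesList))
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(ssr_id = character(), context = character(),
               motif = character(), period = integer(),
               repeat_count = integer(), chrom_start = integer(),
               chrom_end = integer(), transcript_id = character(),
               mrna_start = integer(), mrna_end = integer(),
               premrna_start = integer(), premrna_end = integer())
  fam <- if (nrow(truthDf)) canonicalFamily(truthDf$motif) else NULL
  truthDf$canonical_family <- if (is.null(fam)) character(0) else fam$canonical
  spontDf <- if (length(spont)) do.call(rbind, spont) else
    data.frame(seq_id = character(), period = integer(), motif = character(),
               repeat_count = integer(), canonical_family = character())
  ig <- Biostrings::DNAStringSet(intergenic)
  names(ig) <- sprintf("ig%04d", seq_along(intergenic))
  S4Vectors::mcols(ig)$chrom_offset <- intergenicOff
  mset <- Biostrings::DNAStringSet(mrna)
  pset <- Biostrings::DNAStringSet(premrna)
  list(genome = genome, genes = genes, mrna = mset, premrna = pset,
       intergenic = ig, truth = truthDf, spontaneous = spontDf,
       params = params)
}

#' Simulate a redundant, error-bearing EST set from a toy genome
#'
#' Draws Poisson(`coveragePerTranscript`) fragments per transcript;
#' fragments come from the spliced mRNA, from unspliced pre-mRNA
#' (probability `intronRetentionRate`) or from intergenic genome
#' (probability `genomicFragmentRate`); a fraction `shortFragmentRate`
#' is truncated below 100 bp; fragments are duplicated with probability
#' `duplicateRate`; each emitted copy gets an independent random strand
#' and independent per-base substitutions at `errorRate`.
#'
#' @param sim output of [simulateGenome()].
#' @param params the same [SimParams]; the EST stream is seeded with
#'   `seed + 1` so either stage can be rerun reproducibly on its own.
#' @param genus genus label for the generated records.
#' @return A list with `ests` (named [Biostrings::DNAStringSet]) and
#'   `fragments` (a data.frame per emitted record: id, source type,
#'   source id, interval, strand, error count, duplicate group, and the
#'   comma-separated ids of planted SSRs fully contained -- with one
#'   motif-length of margin -- in the fragment).
#' @export
simulateEsts <- function(sim, params = sim$params, genus = "Synthetica") {
  set.seed(params@seed + 1L)
  truth <- sim$truth
  ests <- character(0)
  rows <- list()
  serial <- 0L
  dupGroup <- 0L

  emit <- function(seq, srcType, srcId, lo, hi, grp, covers) {
    serial <<- serial + 1L
    strand <- sample(c("+", "-"), 1)
    nerr <- stats::rbinom(1, nchar(seq), params@errorRate)
    if (nerr > 0) {
      posns <- sample(nchar(seq), nerr)
      v <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (p in posns) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      seq <- paste(v, collapse = "")
    }
    if (strand == "-") seq <- revcompChar(seq)
    id <- sprintf("%s_e%05d", genus, serial)
    ests[id] <<- seq
    rows[[length(rows) + 1L]] <<- data.frame(
      est_id = id, source_type = srcType, source_id = srcId,
      src_start = lo, src_end = hi, strand = strand, n_errors = nerr,
      dup_group = grp, covers = covers)
  }

  fragment <- function(srcSeq, srcType, srcId, ssrTab) {
    n <- nchar(srcSeq)
    short <- stats::runif(1) < params@shortFragmentRate
    len <- if (short) sample(40:99, 1) else
      sample(seq(params@fragmentLenRange[1], params@fragmentLenRange[2]), 1)
    len <- min(len, n)
    lo <- if (len >= n) 1L else sample(seq_len(n - len + 1L), 1)
    hi <- lo + len - 1L
    covers <- ""
    if (nrow(ssrTab) > 0) {
      ok <- ssrTab$s1 - ssrTab$period >= lo & ssrTab$s2 + ssrTab$period <= hi
      covers <- paste(ssrTab$ssr_id[ok], collapse = ",")
    }
    frag <- substr(srcSeq, lo, hi)
    dupGroup <<- dupGroup + 1L
    ncopy <- if (stats::runif(1) < params@duplicateRate) 2L else 1L
    for (i in seq_len(ncopy))
      emit(frag, srcType, srcId, lo, hi, dupGroup, covers)
  }

  igOff <- S4Vectors::mcols(sim$intergenic)$chrom_offset
  igTab <- lapply(seq_along(sim$intergenic), function(i) {
    w <- truth[truth$context == "intergenic" &
                 truth$chrom_start > igOff[i] &
                 truth$chrom_end <= igOff[i] + Biostrings::width(sim$intergenic)[i], ,
               drop = FALSE]
    if (nrow(w) == 0)
      return(data.frame(ssr_id = character(), s1 = integer(), s2 = integer(),
                        period = integer()))
    data.frame(ssr_id = w$ssr_id, s1 = w$chrom_start - igOff[i],
               s2 = w$chrom_end - igOff[i], period = w$period)
  })

  for (ti in seq_along(sim$mrna)) {
    tx <- names(sim$mrna)[ti]
    nf <- stats::rpois(1, params@coveragePerTranscript)
    if (nf == 0) next
    tt <- truth[!is.na(truth$transcript_id) & truth$transcript_id == tx, ,
                drop = FALSE]
    for (f in seq_len(nf)) {
      u <- stats::runif(1)
      if (u < params@genomicFragmentRate) {
        ii <- sample(length(sim$intergenic), 1)
        fragment(as.character(sim$intergenic[[ii]]), "intergenic",
                 names(sim$intergenic)[ii], igTab[[ii]])
      } else if (u < params@genomicFragmentRate + params@intronRetentionRate) {
        ssrTab <- data.frame(ssr_id = tt$ssr_id, s1 = tt$premrna_start,
                             s2 = tt$premrna_end, period = tt$period)
        ssrTab <- ssrTab[!is.na(ssrTab$s1), , drop = FALSE]
        fragment(as.character(sim$premrna[[tx]]), "premrna", tx, ssrTab)
      } else {
        ssrTab <- data.frame(ssr_id = tt$ssr_id, s1 = tt$mrna_start,
                             s2 = tt$mrna_end, period = tt$period)
        ssrTab <- ssrTab[!is.na(ssrTab$s1), , drop = FALSE]
        fragment(as.character(sim$mrna[[tx]]), "mrna", tx, ssrTab)
      }
    }
  }
  out <- Biostrings::DNAStringSet(ests)
  S4Vectors::mcols(out)$genus <- rep(genus, length(out))
  frags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(est_id = character(), source_type = character(),
               source_id = character(), src_start = integer(),
               src_end = integer(), strand = character(),
               n_errors = integer(), dup_group = integer(),
               covers = character())
  list(ests = out, fragments = frags)
}

#' Write simulated genome annotation as GFF3
#'
#' Emits gene, mRNA, exon, CDS and UTR rows (1-based inclusive); exon
#' rows are the union of CDS and UTR intervals with adjacent pieces
#' merged, so introns re-derive as exon gaps on re-import.
#'
#' @param genes feature [GenomicRanges::GRanges] (`type`,
#'   `transcript_id`, `gene_id` metadata columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  txs <- unique(genes$transcript_id)
  for (tx in txs) {
    f <- genes[genes$transcript_id == tx]
    gid <- f$gene_id[1]
    chr <- as.character(GenomeInfoDb::seqnames(f))[1]
    strand <- as.character(BiocGenerics::strand(f))[1]
    lo <- min(BiocGenerics::start(f)); hi <- max(BiocGenerics::end(f))
    line <- function(type, s, e, id = NULL, parent = NULL) {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      sprintf("%s\tSSRmine\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chr, type, s, e, strand, paste(attrs, collapse = ";"))
    }
    writeLines(line("gene", lo, hi, id = gid), con)
    writeLines(line("mRNA", lo, hi, id = tx, parent = gid), con)
    typ <- as.character(f$type)
    exonic <- IRanges::reduce(IRanges::ranges(f[typ != "intron"]))
    for (i in seq_along(exonic))
      writeLines(line("exon", IRanges::start(exonic)[i],
                      IRanges::end(exonic)[i], parent = tx), con)
    for (i in which(typ %in% c("CDS", "five_prime_UTR", "three_prime_UTR")))
      writeLines(line(typ[i], BiocGenerics::start(f)[i],
                      BiocGenerics::end(f)[i], parent = tx), con)
  }
  invisible(path)
}
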