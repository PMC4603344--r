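#' Classify the genomic context of an SSR locus
#'
#' If no alignment of the SSR's source sequence passes the significance
#' thresholds, the call is `no_hit` (such loci are excluded from context
#' tables and reported as an exclusion fraction). Otherwise the best hit
#' (lowest E-value when available, ties and E-value-free hits by highest
#' identity x aligned length) is used to project the repeat interval onto
#' the reference, and the projected interval is intersected with the
#' annotated gene features: CDS overlap counts as `exon`, five/three
#' prime UTRs as `UTR`, introns as `intron`. The category is the
#' majority-overlap feature type, ties broken by the priority
#' exon > UTR > intron; a projection overlapping no gene feature (or an
#' unprojectable interval) is `genomic`.
#'
#' @param ssr one row of an [SSRCatalog].
#' @param hits [AlignmentHits] of the SSR's source sequence.
#' @param genes gene-model features as returned by [readGff3Genes()].
#' @param params a [SignificanceParams] object.
#' @return A one-row [ContextCalls] object.
#' @export
classifyContext <- function(ssr, hits, genes, params = SignificanceParams()) {
  row <- function(category, sid = NA_character_, s1 = NA_integer_,
                  s2 = NA_integer_, fe = 0, fu = 0, fi = 0) {
    ContextCalls(DataFrame(seq_id = ssr$seq_id, start = ssr$start,
                           end = ssr$end, period = ssr$period,
                           category = category, subject_id = sid,
                           s_start = s1, s_end = s2,
                           frac_exon = fe, frac_UTR = fu, frac_intron = fi))
  }
  hits <- hits[hits$query_id == ssr$seq_id, , drop = FALSE]
  if (nrow(hits) > 0) {
    sig <- if (params@mode == "evalue" && !all(is.na(hits$evalue)))
      !is.na(hits$evalue) & hits$evalue <= params@evalueMax
    else hits$pident >= params@minIdentity &
         hits$aligned_length >= params@minAlignedLength
    hits <- hits[sig, , drop = FALSE]
  }
  if (nrow(hits) == 0) return(row("no_hit"))
  ev <- hits$evalue
  score <- hits$pident * hits$aligned_length
  best <- if (!all(is.na(ev))) {
    ev[is.na(ev)] <- Inf
    order(ev, -score)[1]
  } else order(-score)[1]
  hit <- hits[best, , drop = FALSE]
  proj <- projectInterval(hit, ssr$start, ssr$end)
  if (is.null(proj))
    return(row("genomic", hit$subject_id))
  plen <- proj$s_end - proj$s_start + 1L
  pr <- GenomicRanges::GRanges(hit$subject_id,
                               IRanges::IRanges(proj$s_start, proj$s_end))
  ft <- as.character(genes$type)
  ovl <- function(types) {
    g <- genes[ft %in% types]
    if (length(g) == 0) return(0L)
    ints <- IRanges::intersect(IRanges::reduce(IRanges::ranges(
      g[as.character(GenomeInfoDb::seqnames(g)) == hit$subject_id])),
      IRanges::ranges(pr))
    sum(IRanges::width(ints))
  }
  bpExon <- ovl("CDS")
  bpUTR <- ovl(c("five_prime_UTR", "three_prime_UTR"))
  bpIntron <- ovl("intron")
  fe <- bpExon / plen; fu <- bpUTR / plen; fi <- bpIntron / plen
  if (bpExon + bpUTR + bpIntron == 0L)
    return(row("genomic", hit$subject_id, proj$s_start, proj$s_end))
  cats <- c(exon = bpExon, UTR = bpUTR, intron = bpIntron)
  topv <- max(cats)
  # names() preserves the exon > UTR > intron priority order on ties
  category <- names(cats)[cats == topv][1]
  row(category, hit$subject_id, proj$s_start, proj$s_end, fe, fu, fi)
}

#' Classify every locus of a catalog
#'
#' @param loci an [SSRCatalog].
#' @param hits [AlignmentHits] for the loci's source sequences.
#' @param genes gene-model features ([readGff3Genes()]).
#' @param params a [SignificanceParams] object.
#' @return A [ContextCalls] object, one row per locus.
#' @export
classifyContexts <- function(loci, hits, genes, params = SignificanceParams()) {
  # plain-list split of hits by query avoids repeated S4 subsetting
  hd <- as.data.frame(hits[, setdiff(colnames(hits), "blocks")])
  hd$blocks <- hits$blocks
  hsplit <- split(hd, hd$query_id)
  emptyHits <- hd[0, , drop = FALSE]
  calls <- lapply(seq_len(nrow(loci)), function(i) {
    h <- hsplit[[loci$seq_id[i]]]
    if (is.null(h)) h <- emptyHits
    classifyContext(loci[i, , drop = FALSE], h, genes, params)
  })
  if (length(calls) == 0)
    return(ContextCalls(DataFrame(seq_id = character(), start = integer(),
                                  end = integer(), period = integer(),
                                  category = character(),
                                  subject_id = character(),
                                  s_start = integer(), s_end = integer(),
                                  frac_exon = numeric(), frac_UTR = numeric(),
                                  frac_intron = numeric())))
  ContextCalls(do.call(rbind, calls))
}

#' Cross-tabulate context calls by period and category
#'
#' `no_hit` calls are excluded from the table and reported as an
#' exclusion fraction in `metadata(x)$exclusion_fraction`.
#'
#' @param calls a [ContextCalls] object.
#' @return A [CountTable] over `period x category` (categories
#'   genomic/intron/UTR/exon).
#' @export
contextTable <- function(calls) {
  n <- nrow(calls)
  excl <- if (n == 0) 0 else sum(calls$category == "no_hit") / n
  kept <- calls[calls$category != "no_hit", , drop = FALSE]
  grid <- expand.grid(period = 2:6, category = CONTEXT_CATEGORIES,
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(p, cc)
    sum(kept$period == p & kept$category == cc), grid$period, grid$category)
  grid <- grid[order(grid$period, grid$category), ]
  rownames(grid) <- NULL
  ct <- CountTable(grid, axes = c("period", "category"))
  metadata(ct)$exclusion_fraction <- excl
  ct
}
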