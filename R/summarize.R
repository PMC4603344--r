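#' Cross-tabulate an SSR catalog by taxonomic group, period and family
#'
#' @param loci an [SSRCatalog].
#' @param taxa a genus-to-group mapping from [taxonMap()].
#' @return A [CountTable] over
#'   `taxonomic_group x genus x period x canonical_family`; genera absent
#'   from `taxa` are kept under group `"unmapped"` and listed in
#'   `metadata(x)$unmapped_genera` (never silently dropped).
#' @export
composeCounts <- function(loci, taxa = taxonMap()) {
  df <- as.data.frame(loci)
  if (nrow(df) == 0) {
    ct <- CountTable(data.frame(taxonomic_group = character(),
                                genus = character(), period = integer(),
                                canonical_family = character(),
                                count = integer()),
                     axes = c("taxonomic_group", "genus", "period",
                              "canonical_family"))
    metadata(ct)$unmapped_genera <- character(0)
    return(ct)
  }
  df$taxonomic_group <- unname(taxa[df$genus])
  unmapped <- sort(unique(df$genus[is.na(df$taxonomic_group)]))
  df$taxonomic_group[is.na(df$taxonomic_group)] <- "unmapped"
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = list(taxonomic_group = df$taxonomic_group,
                                    genus = df$genus, period = df$period,
                                    canonical_family = df$canonical_family),
                          FUN = sum)
  agg <- agg[order(agg$taxonomic_group, agg$genus, agg$period,
                   agg$canonical_family), ]
  rownames(agg) <- NULL
  ct <- CountTable(agg, axes = c("taxonomic_group", "genus", "period",
                                 "canonical_family"))
  metadata(ct)$unmapped_genera <- unmapped
  ct
}

#' Percentage shares within a slice of a count table
#'
#' Computes `100 * cell / slice total`, rounded half away from zero to
#' two decimals (the convention of the printed tables this package
#' reproduces).
#'
#' @param table a [CountTable].
#' @param by axis column(s) whose levels define the reported cells
#'   (cells sharing a `by` level are pooled).
#' @param within optional axis column(s) defining separate slices, each
#'   summing to 100.
#' @return A data.frame with the `within` columns (if any), the `by`
#'   columns, `count` and `percent`.
#' @examples
#' t1 <- loadPaperFixture("table1")
#' percentOfTotal(t1, by = "period", within = "genus")
#' @export
percentOfTotal <- function(table, by, within = NULL) {
  df <- as.data.frame(table)
  stopifnot(all(c(by, within) %in% colnames(df)))
  agg <- stats::aggregate(df["count"],
                          by = df[, c(within, by), drop = FALSE], FUN = sum)
  if (is.null(within)) {
    tot <- sum(agg$count)
    if (tot == 0) stop("slice total is zero")
    agg$percent <- roundHalfAway(100 * agg$count / tot, 2)
  } else {
    key <- interaction(agg[, within, drop = FALSE], drop = TRUE)
    tots <- tapply(agg$count, key, sum)
    if (any(tots == 0)) stop("slice total is zero")
    agg$percent <- roundHalfAway(100 * agg$count / as.numeric(tots[key]), 2)
  }
  ord <- do.call(order, agg[, c(within, by), drop = FALSE])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Location distribution of SSRs across genomic contexts
#'
#' From a `period x category` context table (optionally also split by
#' genus), computes each category's share of the total and, per period,
#' the conditional share of each category within that period (e.g. the
#' fraction of dinucleotide repeats falling in UTRs).
#'
#' @param table a [CountTable] containing `period` and `category` axes
#'   (categories restricted to genomic/intron/UTR/exon).
#' @return A list with `by_category` and `by_period_within_category`
#'   data.frames (percentages at two decimals).
#' @export
locationDistribution <- function(table) {
  ax <- countAxes(table)
  stopifnot(all(c("period", "category") %in% ax))
  extra <- setdiff(ax, c("period", "category"))
  stopifnot(all(unique(as.data.frame(table)$category) %in% CONTEXT_CATEGORIES))
  list(
    by_category = percentOfTotal(table, by = "category",
                                 within = if (length(extra)) extra else NULL),
    by_period_within_category =
      percentOfTotal(table, by = "category",
                     within = c(extra, "period")))
}

#' Amplification-rate summary of empirically tested loci
#'
#' A locus counts as amplified when any tested species shows a PCR
#' product, including stutter-peak profiles (a stutter profile is an
#' amplification, even though it is unusable for scoring alleles). Rates
#' are reported at one decimal.
#'
#' @param records PCR test records (e.g. `loadPaperFixture("table3")`),
#'   with columns `locus`, `genus`, `outcome`.
#' @return A list with `overall` (a one-row data.frame: tested,
#'   amplified, rate) and `by_genus`.
#' @export
summarizeAmplification <- function(records) {
  df <- as.data.frame(records)
  amp <- tapply(df$outcome %in% c("product", "stutter"), df$locus, any)
  genus <- tapply(df$genus, df$locus, function(g) g[1])
  one <- function(idx) {
    n <- length(idx); a <- sum(amp[idx])
    data.frame(tested = n, amplified = a,
               rate = roundHalfAway(100 * a / n, 1))
  }
  by_genus <- do.call(rbind, lapply(split(seq_along(amp), genus), one))
  by_genus <- cbind(genus = rownames(by_genus), by_genus)
  rownames(by_genus) <- NULL
  list(overall = one(seq_along(amp)), by_genus = by_genus)
}

#' Cross-species transferability summary
#'
#' A marker transfers when it is functional (a PCR product in both
#' congeneric species tested) and polymorphic (two or more alleles in the
#' union across the genus). Loci with stutter profiles are discarded from
#' the denominator entirely. When both species show a single allele, the
#' locus is polymorphic only if the two allele sizes differ.
#'
#' @param records per-locus-per-species test records
#'   (e.g. `loadPaperFixture("table4")`), with columns `locus`, `genus`,
#'   `species`, `outcome`, `n_alleles`, `size_min`, `size_max`.
#' @return A list with `per_locus` (locus, genus, retained, transferable)
#'   and `overall` (retained, transferable, rate in percent at one
#'   decimal).
#' @export
summarizeTransferability <- function(records) {
  df <- as.data.frame(records)
  per <- lapply(split(df, df$locus), function(d) {
    stut <- any(d$outcome == "stutter")
    functional <- !stut && all(d$outcome == "product")
    poly <- FALSE
    if (functional) {
      if (any(d$n_alleles >= 2, na.rm = TRUE)) poly <- TRUE
      else {
        sizes <- unique(stats::na.omit(c(d$size_min, d$size_max)))
        poly <- length(sizes) >= 2
      }
    }
    data.frame(locus = d$locus[1], genus = d$genus[1],
               retained = !stut, transferable = functional && poly)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  retained <- sum(per$retained)
  transferable <- sum(per$transferable)
  list(per_locus = per,
       overall = data.frame(retained = retained, transferable = transferable,
                            rate = roundHalfAway(100 * transferable /
                                                   max(retained, 1), 1)))
}

#' Write a count table as TSV
#'
#' @param table a [CountTable].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
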