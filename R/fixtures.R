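#' Load a packaged reference table
#'
#' The package ships TSV transcriptions of four printed reference tables
#' used by the summary operations and their tests:
#' \describe{
#'   \item{table1}{SSR counts for the two control genera by repeat period
#'     and genomic context (genomic / intron / UTR / exon). Returned as a
#'     [CountTable] over `genus x period x category`.}
#'   \item{table2}{SSR counts for the eight taxonomic groups by repeat
#'     period, plus genus and EST counts. Returned as a [CountTable] over
#'     `taxonomic_group x period`, with the genus/EST columns in
#'     `metadata(x)$groups`.}
#'   \item{table3}{The 24 empirically tested loci (primer sequences,
#'     motifs, expected and observed product sizes, amplification
#'     outcome). Returned as a `DFrame` of PCR test records.}
#'   \item{table4}{Cross-species transferability records: one row per
#'     locus per congeneric species with allele counts and size ranges.
#'     Returned as a `DFrame`.}
#' }
#'
#' Every table is validated on load: stored totals must equal the sum of
#' their parts (see Details), and record-level invariants (allele counts
#' only for amplified loci, size ranges ordered) must hold.
#'
#' @details For `table2` the repeat-type counts of every row sum to the
#' stored row total and the per-type column sums match the stored grand
#' totals, as do the genus columns. The EST-count column of the printed
#' source does not sum to its printed grand total; that column is stored
#' as printed and excluded from validation (`metadata(x)$n_est_consistent`
#' is `FALSE`).
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`, `"table4"`.
#' @return See description.
#' @examples
#' t1 <- loadPaperFixture("table1")
#' grandTotal(t1)  # 536 classified loci over both genera
#' @export
loadPaperFixture <- function(name = c("table1", "table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", switch(name,
    table1 = "table1_context_counts.tsv",
    table2 = "table2_group_counts.tsv",
    table3 = "table3_empirical.tsv",
    table4 = "table4_transferability.tsv"), package = "SSRmine")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA")
  switch(name,
         table1 = .loadTable1(tab),
         table2 = .loadTable2(tab),
         table3 = .loadTable3(tab),
         table4 = .loadTable4(tab))
}

.loadTable1 <- function(tab) {
  cats <- c("genomic", "intron", "utr", "exon")
  sums <- rowSums(tab[, cats])
  bad <- which(sums != tab$total)
  if (length(bad))
    stop("table1 rows whose categories do not sum to their total: ",
         paste(paste(tab$genus[bad], tab$period[bad]), collapse = ", "))
  long <- do.call(rbind, lapply(cats, function(cc) {
    data.frame(genus = tab$genus, period = tab$period,
               category = ifelse(cc == "utr", "UTR", cc),
               count = tab[[cc]])
  }))
  long <- long[order(long$genus, long$period, long$category), ]
  rownames(long) <- NULL
  CountTable(long, axes = c("genus", "period", "category"))
}

.loadTable2 <- function(tab) {
  types <- c("di", "tri", "tetra", "penta", "hexa")
  tot <- tab[tab$group == "Total", ]
  body <- tab[tab$group != "Total", ]
  bad <- which(rowSums(body[, types]) != body$total)
  if (length(bad))
    stop("table2 rows whose type counts do not sum to their total: ",
         paste(body$group[bad], collapse = ", "))
  colBad <- c(types, "total", "n_genera", "n_genera_ssr")[
    vapply(c(types, "total", "n_genera", "n_genera_ssr"),
           function(cc) sum(body[[cc]]) != tot[[cc]], logical(1))]
  if (length(colBad))
    stop("table2 column sums disagree with stored totals: ",
         paste(colBad, collapse = ", "))
  long <- do.call(rbind, lapply(seq_along(types), function(i) {
    data.frame(taxonomic_group = body$group, period = i + 1L,
               count = body[[types[i]]])
  }))
  long <- long[order(long$taxonomic_group, long$period), ]
  rownames(long) <- NULL
  ct <- CountTable(long, axes = c("taxonomic_group", "period"))
  metadata(ct)$groups <- body[, c("group", "n_genera", "n_genera_ssr",
                                  "n_est", "commonest_motifs")]
  metadata(ct)$n_est_consistent <- sum(body$n_est) == tot$n_est
  ct
}

.loadTable3 <- function(tab) {
  if (nrow(tab) != 24)
    stop("table3 must have 24 locus records")
  bad <- which(!is.na(tab$n_alleles) & tab$outcome != "product")
  if (length(bad))
    stop("table3 rows with allele counts but no product: ",
         paste(tab$locus[bad], collapse = ", "))
  bad <- which(!is.na(tab$n_alleles) & tab$n_alleles < 1)
  if (length(bad))
    stop("table3 rows with n_alleles < 1: ",
         paste(tab$locus[bad], collapse = ", "))
  bad <- which(tab$expected_min > tab$expected_max |
                 (!is.na(tab$size_min) & tab$size_min > tab$size_max))
  if (length(bad))
    stop("table3 rows with inverted size ranges: ",
         paste(tab$locus[bad], collapse = ", "))
  DataFrame(tab)
}

.loadTable4 <- function(tab) {
  bad <- which(!is.na(tab$n_alleles) & tab$outcome != "product")
  if (length(bad))
    stop("table4 rows with allele counts but no product: ",
         paste(tab$locus[bad], collapse = ", "))
  cnt <- table(tab$locus)
  if (any(cnt < 2))
    stop("table4 loci with fewer than two congeneric species: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  DataFrame(tab)
}
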