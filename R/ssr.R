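#' Canonical motif family of a microsatellite motif
#'
#' Two motifs describe the same repeat family if one can be obtained from
#' the other by cyclic rotation and/or reverse complementation (a repeat
#' read from the other strand or with a shifted register is the same
#' locus). The canonical name is the lexicographic minimum over all
#' rotations of the motif and of its reverse complement. A small fixed
#' lookup supplies the conventional display alias used in the plant
#' EST-SSR literature where it differs from the minimum (e.g. the family
#' containing CCG is conventionally written "GGC", the family containing
#' ATC is written "TGA", ACT is written "AGT", and the CG dinucleotide
#' family is written "GC").
#'
#' @param motif character vector of primitive ACGT motifs (length 2-6).
#' @return A data.frame with columns `motif`, `canonical`, `alias`.
#' @examples
#' canonicalFamily("TC")    # canonical "AG"
#' canonicalFamily("GGC")   # canonical "CCG", alias "GGC"
#' @export
canonicalFamily <- function(motif) {
  motif <- toupper(motif)
  if (any(!isACGT(motif)))
    stop("motif must be ACGT-only")
  if (any(nchar(motif) < 2 | nchar(motif) > 6))
    stop("motif length must be 2..6")
  if (any(!vapply(motif, isPrimitiveMotif, logical(1))))
    stop("motif must be primitive (not a power of a shorter string)")
  canon <- vapply(motif, function(m) {
    min(c(rotationsOf(m), rotationsOf(revcompChar(m))))
  }, character(1), USE.NAMES = FALSE)
  alias <- MOTIF_ALIASES[canon]
  alias[is.na(alias)] <- canon[is.na(alias)]
  data.frame(motif = motif, canonical = canon, alias = unname(alias),
             stringsAsFactors = FALSE)
}

# display aliases: canonical name -> conventional literature name
MOTIF_ALIASES <- c(CG = "GC", CCG = "GGC", ATC = "TGA", ACT = "AGT")

rotationsOf <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n) - 1L, function(k)
    paste0(substr(m, k + 1L, n), substr(m, 1L, k)), character(1))
}

isPrimitiveMotif <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 &&
        m == paste(rep(substr(m, 1, d), n / d), collapse = ""))
      return(FALSE)
  }
  TRUE
}

#' Class-I test for a repeat run
#'
#' A run qualifies under the active profile when its repeat count reaches
#' the per-period minimum (Class-I defaults: 10/7/5/4/4 units for periods
#' 2-6, i.e. at least 20 bp).
#'
#' @param period motif length, 2-6.
#' @param repeatCount number of complete repeat units.
#' @param params a [MiningParams] object.
#' @return Logical vector.
#' @export
isClassI <- function(period, repeatCount, params = MiningParams()) {
  if (any(!period %in% params@periods))
    stop("period outside ", min(params@periods), "..", max(params@periods))
  repeatCount >= params@minRepeats[as.character(period)]
}

#' Find all maximal perfect tandem repeats in one sequence
#'
#' Scans every position and period 2-6 for maximal perfect runs of a
#' primitive motif meeting the per-period repeat-count minimum. Runs are
#' broken at non-ACGT characters. When candidate runs of different
#' periods occupy overlapping intervals the longer run wins; ties go to
#' the smaller period. Output is sorted by start and never overlaps.
#'
#' @param sequence a single uppercase DNA string.
#' @param params a [MiningParams] object.
#' @param seqId,genus labels copied to the output.
#' @return An [SSRCatalog] (possibly with zero rows).
#' @examples
#' findPerfectSSRs(paste0("GATTACAGT", strrep("AG", 11), "CCTTTGATCAGT"))
#' @export
findPerfectSSRs <- function(sequence, params = MiningParams(),
                            seqId = NA_character_, genus = NA_character_) {
  stopifnot(length(sequence) == 1)
  df <- .scanSSRs(toupper(sequence), params)
  .asCatalog(df, seqId, genus)
}

# core scanner: plain data.frame of maximal perfect runs, sorted by start
.scanSSRs <- function(sequence, params) {
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(), period = integer(),
                      motif = character(), repeat_count = integer(),
                      length_bp = integer())
  if (n < 8) return(empty)
  v <- strsplit(sequence, "", fixed = TRUE)[[1]]
  okbase <- v %in% c("A", "C", "G", "T")
  cand <- list()
  for (p in sort(params@periods)) {
    if (n < 2 * p) next
    eq <- v[seq_len(n - p)] == v[seq_len(n - p) + p]
    eq <- eq & okbase[seq_len(n - p)] & okbase[seq_len(n - p) + p]
    # maximal runs of TRUE: a run of length L starting at i means
    # positions i .. i+L+p-1 are periodic with period p
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= p)) {
      span <- r$lengths[j] + p
      k <- span %/% p
      if (k < params@minRepeats[as.character(p)]) next
      i <- starts[j]
      motif <- substr(sequence, i, i + p - 1L)
      if (!isPrimitiveMotif(motif)) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = i, end = i + k * p - 1L, period = p,
                   motif = motif, repeat_count = k, length_bp = k * p)
    }
  }
  if (length(cand) == 0) return(empty)
  df <- do.call(rbind, cand)
  # overlap resolution: longer run wins, tie -> smaller period, then start
  df <- df[order(-df$length_bp, df$period, df$start), ]
  keep <- logical(nrow(df))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] <= occ_end & df$end[i] >= occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, df$start[i])
      occ_end <- c(occ_end, df$end[i])
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.asCatalog <- function(df, seqId, genus) {
  if (nrow(df) == 0)
    return(SSRCatalog(DataFrame(seq_id = character(), genus = character(),
                                start = integer(), end = integer(),
                                period = integer(), motif = character(),
                                repeat_count = integer(),
                                length_bp = integer(),
                                canonical_family = character(),
                                display_alias = character())))
  fam <- canonicalFamily(df$motif)
  SSRCatalog(DataFrame(seq_id = rep(seqId, length.out = nrow(df)),
                       genus = rep(genus, length.out = nrow(df)),
                       start = as.integer(df$start), end = as.integer(df$end),
                       period = as.integer(df$period), motif = df$motif,
                       repeat_count = as.integer(df$repeat_count),
                       length_bp = as.integer(df$length_bp),
                       canonical_family = fam$canonical,
                       display_alias = fam$alias))
}

#' Mine a genus's unique sequences for perfect SSRs
#'
#' Applies [findPerfectSSRs()] to every unique sequence and concatenates
#' the results, tagging each locus with its source id and genus. A genus
#' yielding zero loci is a valid outcome under conservative thresholds.
#'
#' @param uniques a named [Biostrings::DNAStringSet], typically the
#'   length-filtered output of [reduceRedundancy()]; a `genus` metadata
#'   column is propagated when present.
#' @param params a [MiningParams] object.
#' @return An [SSRCatalog].
#' @export
mineGenus <- function(uniques, params = MiningParams()) {
  genus <- S4Vectors::mcols(uniques)$genus
  if (is.null(genus)) genus <- rep(NA_character_, length(uniques))
  seqs <- as.character(uniques)
  res <- lapply(seq_along(seqs), function(i) {
    df <- .scanSSRs(seqs[i], params)
    if (nrow(df) == 0) return(NULL)
    df$seq_id <- names(seqs)[i]
    df$genus <- genus[i]
    df
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) return(.asCatalog(.scanSSRs("", params), NA, NA))
  all <- do.call(rbind, res)
  .asCatalog(all[, c("start", "end", "period", "motif", "repeat_count",
                     "length_bp")], all$seq_id, all$genus)
}

#' Write an SSR catalog as TSV
#'
#' @param catalog an [SSRCatalog].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSSRCatalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
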