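#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- SimpleList
#' @importFrom data.table data.table .SD
#' @importClassesFrom S4Vectors DFrame
NULL

VALID_GROUPS <- c("Florideophyceae", "Charophyceae", "Monilophyta",
                  "Lycopodiophyta", "Acrogymnospermae", "Magnoliidae",
                  "Monocotyledoneae", "Eudicotyledoneae")

CONTEXT_CATEGORIES <- c("genomic", "intron", "UTR", "exon")

#' Mining parameters for perfect-SSR detection
#'
#' Holds the per-period minimum repeat counts and the set of motif periods
#' searched. The Class-I profile requires 10 di-, 7 tri-, 5 tetra- and 4
#' penta-/hexanucleotide repeat units, i.e. every emitted locus spans at
#' least 20 bp. The relaxed profile requires 4 units for every period.
#'
#' @slot minRepeats named integer vector, names "2".."6".
#' @slot periods integer vector of motif periods searched.
#' @export
setClass("MiningParams", representation(minRepeats = "integer",
                                        periods = "integer"))

setValidity("MiningParams", function(object) {
  msg <- NULL
  if (!all(object@periods %in% 2:6))
    msg <- c(msg, "periods must lie in 2..6")
  if (!all(as.character(object@periods) %in% names(object@minRepeats)))
    msg <- c(msg, "minRepeats must cover every period")
  if (any(object@minRepeats < 2L))
    msg <- c(msg, "every minRepeats value must be >= 2")
  if (is.null(msg)) TRUE else msg
})

#' @param relaxed if `TRUE`, use the relaxed profile (at least four repeat
#'   units for every period) instead of the Class-I profile.
#' @param minRepeats optional named integer vector overriding individual
#'   per-period minima, e.g. `c("2" = 8)`.
#' @return A `MiningParams` object.
#' @examples
#' MiningParams()              # Class I
#' MiningParams(relaxed = TRUE)
#' @rdname MiningParams-class
#' @export
MiningParams <- function(relaxed = FALSE, minRepeats = NULL) {
  base <- if (relaxed) c("2" = 4L, "3" = 4L, "4" = 4L, "5" = 4L, "6" = 4L)
          else c("2" = 10L, "3" = 7L, "4" = 5L, "5" = 4L, "6" = 4L)
  if (!is.null(minRepeats))
    base[names(minRepeats)] <- as.integer(minRepeats)
  new("MiningParams", minRepeats = base, periods = 2:6)
}

#' Clustering parameters for redundancy reduction
#'
#' @slot minIdentity minimum pairwise identity over the aligned overlap for
#'   a sequence to join a cluster.
#' @slot minOverlapFraction minimum aligned fraction of the shorter
#'   sequence.
#' @slot kmerSize exact k-mer size used for candidate pairing.
#' @slot revComp whether a sequence may join a cluster via its reverse
#'   complement.
#' @export
setClass("ClusterParams", representation(minIdentity = "numeric",
                                         minOverlapFraction = "numeric",
                                         kmerSize = "integer",
                                         revComp = "logical"))

setValidity("ClusterParams", function(object) {
  ok <- object@minIdentity > 0 && object@minIdentity <= 1 &&
    object@minOverlapFraction > 0 && object@minOverlapFraction <= 1 &&
    object@kmerSize >= 4L
  if (ok) TRUE else "invalid clustering thresholds"
})

#' @param minIdentity,minOverlapFraction,kmerSize,revComp see slots.
#' @return A `ClusterParams` object.
#' @rdname ClusterParams-class
#' @export
ClusterParams <- function(minIdentity = 0.95, minOverlapFraction = 0.80,
                          kmerSize = 12L, revComp = TRUE) {
  new("ClusterParams", minIdentity = minIdentity,
      minOverlapFraction = minOverlapFraction,
      kmerSize = as.integer(kmerSize), revComp = revComp)
}

#' Primer design parameters
#'
#' Hard constraint windows and penalty weights for flanking-primer
#' selection: primer length 18-23 nt (optimum 20), melting temperature
#' 55-65 degC (optimum 60), GC content 30-70 % (optimum 50), product size
#' 90-320 bp. The pair penalty is
#' `w_len (|len_f-20| + |len_r-20|) + w_tm (|Tm_f-60| + |Tm_r-60|) +
#'  w_gc (|GC_f-50| + |GC_r-50|) + w_pair |Tm_f-Tm_r|` with GC in
#' percentage points.
#'
#' @slot lenRange,lenOpt primer length window (nt) and optimum.
#' @slot tmRange,tmOpt melting temperature window (degC) and optimum.
#' @slot gcRange,gcOpt GC fraction window and optimum.
#' @slot productRange PCR product size window (bp).
#' @slot maxTmDiff maximum |Tm_f - Tm_r| (degC).
#' @slot maxSelfComp longest tolerated self-complementary stretch (nt).
#' @slot tmModel "nearest_neighbor" or "gc_linear".
#' @slot weights penalty weights (len, tm, gc, pair).
#' @export
setClass("PrimerParams", representation(lenRange = "integer", lenOpt = "integer",
                                        tmRange = "numeric", tmOpt = "numeric",
                                        gcRange = "numeric", gcOpt = "numeric",
                                        productRange = "integer",
                                        maxTmDiff = "numeric",
                                        maxSelfComp = "integer",
                                        tmModel = "character",
                                        weights = "numeric"))

setValidity("PrimerParams", function(object) {
  msg <- NULL
  inwin <- function(r, o) r[1] <= o && o <= r[2]
  if (!inwin(object@lenRange, object@lenOpt)) msg <- c(msg, "lenOpt outside lenRange")
  if (!inwin(object@tmRange, object@tmOpt)) msg <- c(msg, "tmOpt outside tmRange")
  if (!inwin(object@gcRange, object@gcOpt)) msg <- c(msg, "gcOpt outside gcRange")
  if (diff(object@productRange) < 0) msg <- c(msg, "empty product size range")
  if (!object@tmModel %in% c("nearest_neighbor", "gc_linear"))
    msg <- c(msg, "unknown tmModel")
  if (is.null(msg)) TRUE else msg
})

#' @param lenRange,lenOpt,tmRange,tmOpt,gcRange,gcOpt,productRange,maxTmDiff
#'   see slots.
#' @param maxSelfComp,tmModel,weights see slots.
#' @return A `PrimerParams` object.
#' @rdname PrimerParams-class
#' @export
PrimerParams <- function(lenRange = c(18L, 23L), lenOpt = 20L,
                         tmRange = c(55, 65), tmOpt = 60,
                         gcRange = c(0.30, 0.70), gcOpt = 0.50,
                         productRange = c(90L, 320L),
                         maxTmDiff = 3.0, maxSelfComp = 8L,
                         tmModel = "nearest_neighbor",
                         weights = c(len = 1.0, tm = 1.0, gc = 0.5, pair = 1.0)) {
  new("PrimerParams", lenRange = as.integer(lenRange), lenOpt = as.integer(lenOpt),
      tmRange = tmRange, tmOpt = tmOpt, gcRange = gcRange, gcOpt = gcOpt,
      productRange = as.integer(productRange), maxTmDiff = maxTmDiff,
      maxSelfComp = as.integer(maxSelfComp), tmModel = tmModel,
      weights = weights)
}

#' Significance thresholds for alignment hits
#'
#' In `evalue` mode a hit is significant when its E-value (supplied by an
#' external aligner) is at most `evalueMax`. In `identity_length` mode --
#' used for the internal toy aligner, which has no E-value model -- a hit
#' is significant when its identity and aligned length both reach their
#' thresholds.
#'
#' @slot mode "evalue" or "identity_length".
#' @slot evalueMax maximum E-value.
#' @slot minIdentity,minAlignedLength identity fraction and aligned bp
#'   thresholds.
#' @export
setClass("SignificanceParams", representation(mode = "character",
                                              evalueMax = "numeric",
                                              minIdentity = "numeric",
                                              minAlignedLength = "integer"))

setValidity("SignificanceParams", function(object) {
  if (!object@mode %in% c("evalue", "identity_length")) return("unknown mode")
  if (object@evalueMax <= 0 || object@minIdentity <= 0 ||
      object@minAlignedLength <= 0) return("thresholds must be positive")
  TRUE
})

#' @param mode,evalueMax,minIdentity,minAlignedLength see slots.
#' @return A `SignificanceParams` object.
#' @rdname SignificanceParams-class
#' @export
SignificanceParams <- function(mode = "identity_length", evalueMax = 1e-5,
                               minIdentity = 0.90, minAlignedLength = 50L) {
  new("SignificanceParams", mode = mode, evalueMax = evalueMax,
      minIdentity = minIdentity, minAlignedLength = as.integer(minAlignedLength))
}

#' Catalog of perfect SSR loci
#'
#' A `DFrame` subclass with one row per maximal perfect tandem repeat.
#' Columns: `seq_id`, `genus`, `start`, `end` (1-based inclusive on the
#' unique sequence), `period`, `motif` (as it occurs at `start`),
#' `repeat_count`, `length_bp`, `canonical_family`, `display_alias`.
#' @export
setClass("SSRCatalog", contains = "DFrame")

setValidity("SSRCatalog", function(object) {
  need <- c("seq_id", "genus", "start", "end", "period", "motif",
            "repeat_count", "length_bp", "canonical_family", "display_alias")
  if (!all(need %in% colnames(object)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) > 0) {
    if (any(object$length_bp != object$period * object$repeat_count))
      return("length_bp must equal period * repeat_count")
    if (any(object$end - object$start + 1L != object$length_bp))
      return("end - start + 1 must equal length_bp")
  }
  TRUE
})

SSRCatalog <- function(df) {
  if (is.data.frame(df)) df <- DataFrame(df)
  new("SSRCatalog", df)
}

setMethod("show", "SSRCatalog", function(object) {
  cat(sprintf("SSRCatalog with %d loci on %d sequences (%d gener%s)\n",
              nrow(object), length(unique(object$seq_id)),
              length(unique(object$genus)),
              if (length(unique(object$genus)) == 1) "us" else "a"))
  callNextMethod()
})

#' Catalog of designed primer pairs
#'
#' A `DFrame` subclass with one row per primer pair. Reverse primers are
#' given 5'->3' on the minus strand. `f_start`/`r_end` are 1-based
#' template coordinates of the outermost primer bases; `product_size`
#' equals `r_end - f_start + 1`.
#' @export
setClass("PrimerCatalog", contains = "DFrame")

setValidity("PrimerCatalog", function(object) {
  need <- c("seq_id", "forward_seq", "reverse_seq", "f_start", "r_end",
            "tm_f", "tm_r", "gc_f", "gc_r", "product_size", "penalty")
  if (!all(need %in% colnames(object)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) > 0 && any(object$penalty < 0))
    return("penalty must be non-negative")
  TRUE
})

PrimerCatalog <- function(df) {
  if (is.data.frame(df)) df <- DataFrame(df)
  new("PrimerCatalog", df)
}

#' Genomic-context calls for SSR loci
#'
#' A `DFrame` subclass, one row per SSR locus, with `category` in
#' `{exon, UTR, intron, genomic, no_hit}`, the projected subject interval
#' (`subject_id`, `s_start`, `s_end`; `NA` when unprojected) and
#' per-feature-type overlap fractions of the projected repeat bases.
#' @export
setClass("ContextCalls", contains = "DFrame")

setValidity("ContextCalls", function(object) {
  need <- c("seq_id", "start", "end", "period", "category",
            "subject_id", "s_start", "s_end",
            "frac_exon", "frac_UTR", "frac_intron")
  if (!all(need %in% colnames(object)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) > 0) {
    if (!all(object$category %in% c(CONTEXT_CATEGORIES, "no_hit")))
      return("invalid category")
    fr <- object$frac_exon + object$frac_UTR + object$frac_intron
    if (any(fr > 1 + 1e-9, na.rm = TRUE))
      return("overlap fractions must sum to <= 1")
  }
  TRUE
})

ContextCalls <- function(df) {
  if (is.data.frame(df)) df <- DataFrame(df)
  new("ContextCalls", df)
}

#' Cross-tabulated SSR counts
#'
#' A `DFrame` subclass in long format: one or more axis columns (an
#' ordered subset of `taxonomic_group`, `genus`, `period`,
#' `canonical_family`, `category`) plus a `count` column. The axis names
#' are kept in `metadata(x)$axes`; derived margins are recomputed, never
#' stored.
#' @export
setClass("CountTable", contains = "DFrame")

setValidity("CountTable", function(object) {
  if (!"count" %in% colnames(object)) return("missing count column")
  ax <- metadata(object)$axes
  if (is.null(ax) || !all(ax %in% colnames(object)))
    return("metadata(x)$axes must name axis columns")
  if (nrow(object) > 0 && any(object$count < 0)) return("negative count")
  TRUE
})

CountTable <- function(df, axes) {
  if (is.data.frame(df)) df <- DataFrame(df)
  metadata(df)$axes <- axes
  new("CountTable", df)
}

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable over {%s}: %d cells, grand total %d\n",
              paste(metadata(object)$axes, collapse = ", "),
              nrow(object), sum(object$count)))
  callNextMethod()
})

#' Gapped alignment hits
#'
#' A `DFrame` subclass with one row per hit: `query_id`, `subject_id`,
#' `strand` ("+"/"-"), `pident` (identity fraction in \[0,1\]),
#' `aligned_length` (bp of gapless aligned blocks), `evalue` (`NA` unless
#' supplied by an external aligner) and a `blocks` list column holding,
#' per hit, a data.frame of gapless segment pairs (`q_start`, `q_end`,
#' `s_start`, `s_end`; 1-based inclusive, subject coordinates always on
#' the plus strand, blocks ordered by increasing query coordinate).
#' @export
setClass("AlignmentHits", contains = "DFrame")

setValidity("AlignmentHits", function(object) {
  need <- c("query_id", "subject_id", "strand", "pident", "aligned_length",
            "evalue", "blocks")
  if (!all(need %in% colnames(object)))
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  if (nrow(object) > 0) {
    if (!all(object$strand %in% c("+", "-"))) return("invalid strand")
    for (b in object$blocks) {
      if (any(b$q_end - b$q_start != abs(b$s_end - b$s_start)))
        return("block query and subject spans differ")
      if (is.unsorted(b$q_start, strictly = TRUE) && nrow(b) > 1)
        return("blocks must be strictly increasing in query coordinates")
    }
  }
  TRUE
})

AlignmentHits <- function(df) {
  if (is.data.frame(df)) df <- DataFrame(df)
  new("AlignmentHits", df)
}

setMethod("show", "AlignmentHits", function(object) {
  cat(sprintf("AlignmentHits: %d hits, %d queries, %d subjects\n",
              nrow(object), length(unique(object$query_id)),
              length(unique(object$subject_id))))
  callNextMethod()
})

#' @describeIn CountTable-class axis column names.
#' @param x a `CountTable`.
#' @export
countAxes <- function(x) metadata(x)$axes

#' @describeIn CountTable-class grand total of the counts.
#' @export
grandTotal <- function(x) sum(x$count)
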