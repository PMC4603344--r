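#' GC fraction of a DNA string
#'
#' @param seq character vector of ACGT-only sequences.
#' @return Numeric vector of (#G + #C) / length.
#' @examples
#' gcFraction("ACGT")  # 0.5
#' @export
gcFraction <- function(seq) {
  seq <- toupper(seq)
  if (any(!isACGT(seq)))
    stop("gcFraction requires ACGT-only sequences")
  nchar(gsub("[^GC]", "", seq)) / nchar(seq)
}

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH kcal/mol, dS cal/(mol K), 5'->3' dinucleotide stacks
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Oligonucleotide melting temperature
#'
#' Two models are provided. `"gc_linear"` is the closed-form
#' `64.9 + 41 (nGC - 16.4) / L` (degC), convenient for hand-checkable
#' arithmetic. `"nearest_neighbor"` (the default used in primer design)
#' is the standard two-state duplex estimate from summed nearest-neighbor
#' enthalpies and entropies (SantaLucia 1998 unified set) with terminal
#' initiation terms, the entropic salt correction
#' `dS + 0.368 (L-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15` for a non-self-complementary
#' duplex at oligo concentration `C`.
#'
#' @param seq character vector of ACGT-only sequences, length >= 14 nt
#'   (below that the formulas leave their validity range).
#' @param model `"nearest_neighbor"` or `"gc_linear"`.
#' @param na monovalent salt concentration, mol/L.
#' @param oligo oligo concentration, mol/L.
#' @return Numeric vector of melting temperatures in degC, with the model
#'   and conditions attached as attributes `model`, `na`, `oligo`.
#' @examples
#' meltingTemperature(strrep("AG", 10), model = "gc_linear")  # 51.78
#' @export
meltingTemperature <- function(seq, model = c("nearest_neighbor", "gc_linear"),
                               na = 0.05, oligo = 5e-7) {
  model <- match.arg(model)
  seq <- toupper(seq)
  if (any(!isACGT(seq)))
    stop("meltingTemperature requires ACGT-only sequences")
  L <- nchar(seq)
  if (any(L < 14))
    stop("sequences shorter than 14 nt are outside the formulas' validity range")
  tm <- if (model == "gc_linear") {
    ngc <- nchar(gsub("[^GC]", "", seq))
    64.9 + 41 * (ngc - 16.4) / L
  } else {
    vapply(seq, function(s) {
      n <- nchar(s)
      stacks <- substring(s, 1:(n - 1), 2:n)
      dh <- sum(NN_DH[stacks])
      ds <- sum(NN_DS[stacks])
      ends <- c(substr(s, 1, 1), substr(s, n, n))
      dh <- dh + sum(ifelse(ends %in% c("G", "C"), 0.1, 2.3))
      ds <- ds + sum(ifelse(ends %in% c("G", "C"), -2.8, 4.1))
      ds <- ds + 0.368 * (n - 1) * log(na)
      1000 * dh / (ds + 1.98722 * log(oligo / 4)) - 273.15
    }, numeric(1), USE.NAMES = FALSE)
  }
  structure(tm, model = model, na = na, oligo = oligo)
}

# longest self-complementary stretch: the largest k such that some
# k-substring's reverse complement is also a substring of the primer
longestSelfComp <- function(seq) {
  n <- nchar(seq)
  for (k in seq(min(n, 20L), 1L)) {
    subs <- unique(substring(seq, 1:(n - k + 1), k:n))
    if (any(revcompChar(subs) %in% subs)) return(k)
  }
  0L
}

# violation-only screen: TRUE when a (maxLen+1)-mer and its reverse
# complement both occur in the primer
selfCompExceeds <- function(seq, maxLen) {
  k <- maxLen + 1L
  n <- nchar(seq)
  if (n < k) return(FALSE)
  subs <- substring(seq, 1:(n - k + 1), k:n)
  any(revcompChar(subs) %in% subs)
}

# vectorized form over many candidate primers
selfCompViolates <- function(seqs, maxLen) {
  k <- maxLen + 1L
  L <- nchar(seqs)
  if (max(L) < k) return(rep(FALSE, length(seqs)))
  ids <- integer(0); subs <- character(0)
  for (j in 1:(max(L) - k + 1L)) {
    ok <- L >= j + k - 1L
    if (!any(ok)) break
    ids <- c(ids, which(ok))
    subs <- c(subs, substring(seqs[ok], j, j + k - 1L))
  }
  rc <- chartr("ACGT", "TGCA", subs)
  rcr <- do.call(paste0, lapply(k:1, function(i) substring(rc, i, i)))
  key <- paste0(ids, "_", subs)
  hit <- paste0(ids, "_", rcr) %in% key
  seq_along(seqs) %in% unique(ids[hit])
}

revcompBulk <- function(seqs) {
  if (length(seqs) == 0) return(seqs)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Design flanking primer pairs for one SSR locus
#'
#' Enumerates every candidate forward window ending before the repeat run
#' and reverse window starting after it, within allowable product sizes;
#' discards candidates violating any hard constraint (primer length, Tm
#' window, GC window, ambiguity-free sequence, self-complementary
#' stretch, pair Tm difference, product size); scores remaining pairs by
#' the penalty described in [PrimerParams()]; ties are broken by smaller
#' product size, then leftmost forward start. Primers never overlap the
#' repeat run itself (a primer inside the repeat cannot size alleles).
#'
#' @param template the unique sequence (character or
#'   [Biostrings::DNAString]) carrying the SSR.
#' @param ssrStart,ssrEnd 1-based inclusive repeat-run coordinates on the
#'   template.
#' @param params a [PrimerParams] object.
#' @param seqId label copied to the output.
#' @param best if `TRUE`, return only the best pair.
#' @return A [PrimerCatalog], best penalty first; zero rows when the SSR
#'   is undesignable.
#' @export
designPrimers <- function(template, ssrStart, ssrEnd,
                          params = PrimerParams(), seqId = NA_character_,
                          best = FALSE) {
  template <- toupper(as.character(template))
  n <- nchar(template)
  stopifnot(ssrStart >= 1, ssrEnd <= n, ssrStart <= ssrEnd)
  empty <- PrimerCatalog(DataFrame(seq_id = character(),
                                   forward_seq = character(),
                                   reverse_seq = character(),
                                   f_start = integer(), f_end = integer(),
                                   r_start = integer(), r_end = integer(),
                                   tm_f = numeric(), tm_r = numeric(),
                                   gc_f = numeric(), gc_r = numeric(),
                                   product_size = integer(),
                                   penalty = numeric(),
                                   tm_model = character()))
  lens <- seq(params@lenRange[1], params@lenRange[2])
  maxProd <- params@productRange[2]

  candidates <- function(reverse) {
    if (!reverse) {
      ends <- seq_len(ssrStart - 1L)
      ends <- ends[ends >= params@lenRange[1]]
      # forward primers must sit within maxProd of the run's right flank
      ends <- ends[ends >= ssrEnd + 1L + params@lenRange[1] - maxProd]
      grid <- expand.grid(end = ends, len = lens)
      grid$start <- grid$end - grid$len + 1L
      grid <- grid[grid$start >= 1L, ]
    } else {
      starts <- seq(ssrEnd + 1L, n)
      starts <- starts[starts + params@lenRange[1] - 1L <= n]
      starts <- starts[starts <= ssrStart - 1L - params@lenRange[1] + maxProd]
      grid <- expand.grid(start = starts, len = lens)
      grid$end <- grid$start + grid$len - 1L
      grid <- grid[grid$end <= n, ]
    }
    if (nrow(grid) == 0) return(grid[, c()])
    seqs <- substring(template, grid$start, grid$end)
    ok <- isACGT(seqs)
    grid <- grid[ok, , drop = FALSE]; seqs <- seqs[ok]
    if (nrow(grid) == 0) return(grid)
    if (reverse) seqs <- revcompBulk(seqs)
    gc <- gcFraction(seqs)
    ok <- gc >= params@gcRange[1] & gc <= params@gcRange[2]
    grid <- grid[ok, , drop = FALSE]; seqs <- seqs[ok]; gc <- gc[ok]
    if (nrow(grid) == 0) return(grid)
    tm <- as.numeric(meltingTemperature(seqs, model = params@tmModel))
    ok <- tm >= params@tmRange[1] & tm <= params@tmRange[2]
    grid <- grid[ok, , drop = FALSE]; seqs <- seqs[ok]; gc <- gc[ok]; tm <- tm[ok]
    if (nrow(grid) == 0) return(grid)
    ok <- !selfCompViolates(seqs, params@maxSelfComp)
    grid <- grid[ok, , drop = FALSE]
    grid$seq <- seqs[ok]; grid$gc <- gc[ok]; grid$tm <- tm[ok]
    grid
  }

  fwd <- candidates(reverse = FALSE)
  if (NROW(fwd) == 0) return(empty)
  rev <- candidates(reverse = TRUE)
  if (NROW(rev) == 0) return(empty)
  w <- params@weights

  if (best) {
    # best-only search: scan forward candidates in single-side penalty
    # order with a lower-bound cutoff instead of materializing all pairs
    pf <- w["len"] * abs(fwd$len - params@lenOpt) +
      w["tm"] * abs(fwd$tm - params@tmOpt) +
      w["gc"] * abs(fwd$gc - params@gcOpt) * 100
    pr <- w["len"] * abs(rev$len - params@lenOpt) +
      w["tm"] * abs(rev$tm - params@tmOpt) +
      w["gc"] * abs(rev$gc - params@gcOpt) * 100
    ordF <- order(pf)
    bestPen <- Inf; bestRow <- NULL
    for (i in ordF) {
      if (pf[i] + min(pr) > bestPen + 1e-9) break
      prod <- rev$end - fwd$start[i] + 1L
      dtm <- abs(fwd$tm[i] - rev$tm)
      ok <- prod >= params@productRange[1] & prod <= params@productRange[2] &
        dtm <= params@maxTmDiff
      if (!any(ok)) next
      pen <- pf[i] + pr[ok] + w["pair"] * dtm[ok]
      cands <- which(ok)
      # ties: smaller product size, then leftmost forward start (the
      # forward scan order already fixes f_start ties)
      o <- order(pen, prod[ok])
      jbest <- cands[o[1]]
      if (pen[o[1]] < bestPen - 1e-12 ||
          (abs(pen[o[1]] - bestPen) <= 1e-12 && !is.null(bestRow) &&
           (prod[jbest] < bestRow$product_size ||
            (prod[jbest] == bestRow$product_size &&
             fwd$start[i] < bestRow$start_f)))) {
        bestPen <- pen[o[1]]
        bestRow <- data.frame(
          start_f = fwd$start[i], end_f = fwd$end[i], len_f = fwd$len[i],
          seq_f = fwd$seq[i], gc_f = fwd$gc[i], tm_f = fwd$tm[i],
          start_r = rev$start[jbest], end_r = rev$end[jbest],
          len_r = rev$len[jbest], seq_r = rev$seq[jbest],
          gc_r = rev$gc[jbest], tm_r = rev$tm[jbest],
          product_size = prod[jbest], penalty = pen[o[1]])
      }
    }
    if (is.null(bestRow)) return(empty)
    pairs <- bestRow
    return(PrimerCatalog(DataFrame(
      seq_id = seqId, forward_seq = pairs$seq_f, reverse_seq = pairs$seq_r,
      f_start = as.integer(pairs$start_f), f_end = as.integer(pairs$end_f),
      r_start = as.integer(pairs$start_r), r_end = as.integer(pairs$end_r),
      tm_f = pairs$tm_f, tm_r = pairs$tm_r,
      gc_f = pairs$gc_f, gc_r = pairs$gc_r,
      product_size = as.integer(pairs$product_size),
      penalty = pairs$penalty, tm_model = params@tmModel)))
  }

  pairs <- merge(cbind(fwd, dummy = 1), cbind(rev, dummy = 1), by = "dummy",
                 suffixes = c("_f", "_r"))
  pairs$product_size <- pairs$end_r - pairs$start_f + 1L
  pairs <- pairs[pairs$product_size >= params@productRange[1] &
                   pairs$product_size <= params@productRange[2], ]
  if (nrow(pairs) == 0) return(empty)
  pairs <- pairs[abs(pairs$tm_f - pairs$tm_r) <= params@maxTmDiff, ]
  if (nrow(pairs) == 0) return(empty)
  w <- params@weights
  pairs$penalty <-
    w["len"] * (abs(pairs$len_f - params@lenOpt) + abs(pairs$len_r - params@lenOpt)) +
    w["tm"] * (abs(pairs$tm_f - params@tmOpt) + abs(pairs$tm_r - params@tmOpt)) +
    w["gc"] * (abs(pairs$gc_f - params@gcOpt) + abs(pairs$gc_r - params@gcOpt)) * 100 +
    w["pair"] * abs(pairs$tm_f - pairs$tm_r)
  pairs <- pairs[order(pairs$penalty, pairs$product_size, pairs$start_f), ]
  if (best) pairs <- pairs[1, , drop = FALSE]
  PrimerCatalog(DataFrame(seq_id = rep(seqId, nrow(pairs)),
                          forward_seq = pairs$seq_f,
                          reverse_seq = pairs$seq_r,
                          f_start = as.integer(pairs$start_f),
                          f_end = as.integer(pairs$end_f),
                          r_start = as.integer(pairs$start_r),
                          r_end = as.integer(pairs$end_r),
                          tm_f = pairs$tm_f, tm_r = pairs$tm_r,
                          gc_f = pairs$gc_f, gc_r = pairs$gc_r,
                          product_size = as.integer(pairs$product_size),
                          penalty = pairs$penalty,
                          tm_model = rep(params@tmModel, nrow(pairs))))
}

#' Pair every designable SSR locus with its best primer pair
#'
#' Retains exactly the loci for which [designPrimers()] returns at least
#' one compliant pair; each retained locus is paired with its
#' best-penalty pair. This is the "catalog" filter: an SSR without a
#' usable primer pair never enters the marker catalog.
#'
#' @param loci an [SSRCatalog].
#' @param templates a named [Biostrings::DNAStringSet] containing every
#'   `seq_id` in `loci`.
#' @param params a [PrimerParams] object.
#' @return A `DFrame` joining the locus columns with the chosen pair's
#'   columns (prefix `primer_`-free; see [PrimerCatalog]).
#' @export
catalogWithPrimers <- function(loci, templates, params = PrimerParams()) {
  rows <- list()
  ldf <- as.data.frame(loci)
  tpls <- as.character(templates)
  for (i in seq_len(nrow(ldf))) {
    tpl <- tpls[[ldf$seq_id[i]]]
    pp <- designPrimers(tpl, ldf$start[i], ldf$end[i], params,
                        seqId = ldf$seq_id[i], best = TRUE)
    if (nrow(pp) == 0) next
    pair <- as.data.frame(pp)[, setdiff(colnames(pp), "seq_id")]
    rows[[length(rows) + 1L]] <- cbind(ldf[i, , drop = FALSE], pair)
  }
  if (length(rows) == 0) {
    skeleton <- cbind(as.data.frame(loci[0, , drop = FALSE]),
                      as.data.frame(designPrimers("ACGTACGTACGTACGTACGTACGT",
                                                  12, 13))[, -1, drop = FALSE][0, ])
    return(DataFrame(skeleton))
  }
  DataFrame(do.call(rbind, rows))
}

#' Write a primer catalog as TSV
#'
#' Mirrors the published catalog columns: locus id, motif as
#' `(MOTIF)_n`, primer sequences, expected product size, melting
#' temperatures and penalty.
#'
#' @param catalog output of [catalogWithPrimers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePrimerCatalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  if (nrow(df) > 0) {
    df$motif_repeat <- sprintf("(%s)_%d", df$motif, df$repeat_count)
  } else df$motif_repeat <- character(0)
  keep <- c("seq_id", "genus", "start", "end", "motif_repeat",
            "canonical_family", "display_alias", "forward_seq", "reverse_seq",
            "product_size", "tm_f", "tm_r", "penalty")
  utils::write.table(df[, intersect(keep, colnames(df))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
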