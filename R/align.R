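#' Toy seed-and-extend local aligner
#'
#' A stand-in for a full local-alignment search engine at toy reference
#' scale: exact k-mer seeds (default k = 11) are collected on both
#' strands, merged along diagonals into gapless segments, extended
#' base-by-base with an X-drop rule (match +1, mismatch -2, drop 6), and
#' chained colinearly so that subject gaps (introns) separate blocks.
#' Each chain becomes one [AlignmentHits] row whose `pident` is matches
#' over aligned block columns. No E-value model is attached
#' (significance for these hits uses identity-and-length thresholds; see
#' [SignificanceParams()]).
#'
#' @param queries a named [Biostrings::DNAStringSet] (or named character
#'   vector) of query sequences.
#' @param reference a named [Biostrings::DNAStringSet] (or named
#'   character vector) of reference sequences.
#' @param k seed length.
#' @param minSeeds minimum seeded matches for a chain to be reported.
#' @param params a [SignificanceParams] object; chains below the
#'   identity/length thresholds are dropped.
#' @return An [AlignmentHits] object.
#' @export
alignLocal <- function(queries, reference, k = 11L,
                       minSeeds = 1L, params = SignificanceParams()) {
  qseq <- toupper(as.character(queries))
  if (is.null(names(qseq))) names(qseq) <- paste0("q", seq_along(qseq))
  rseq <- toupper(as.character(reference))
  if (is.null(names(rseq))) names(rseq) <- paste0("s", seq_along(rseq))

  # low-complexity k-mers (periodic, period <= 6: the repeats themselves)
  # are excluded from seeding -- they match every same-motif repeat in the
  # reference; flanking sequence provides ample unique seeds
  dropPeriodic <- function(km) {
    periodic <- rep(FALSE, length(km))
    for (p in 1:6)
      periodic <- periodic |
        substring(km, 1L, k - p) == substring(km, p + 1L, k)
    periodic
  }
  refIdx <- lapply(rseq, function(s) {
    n <- nchar(s)
    if (n < k) return(NULL)
    dt <- data.table::data.table(kmer = substring(s, 1:(n - k + 1), k:n),
                                 spos = 1:(n - k + 1))
    dt <- dt[!dropPeriodic(dt$kmer), ]
    data.table::setkey(dt, kmer)
    dt
  })
  refChars <- lapply(rseq, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  hits <- list()
  for (qi in seq_along(qseq)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qseq[qi] else revcompChar(qseq[qi])
      nq <- nchar(q)
      if (nq < k) next
      qdt <- data.table::data.table(kmer = substring(q, 1:(nq - k + 1), k:nq),
                                    qpos = 1:(nq - k + 1))
      for (si in seq_along(rseq)) {
        idx <- refIdx[[si]]
        if (is.null(idx)) next
        seeds <- idx[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
        if (nrow(seeds) == 0) next
        segs <- .mergeSeeds(seeds, k, q, refChars[[si]])
        if (is.null(segs) || nrow(segs) < minSeeds) next
        chains <- .chainSegments(segs)
        for (ch in chains) {
          alen <- sum(ch$q_end - ch$q_start + 1L)
          pid <- sum(ch$matches) / alen
          sig <- pid >= params@minIdentity && alen >= params@minAlignedLength
          if (!sig) next
          blocks <- ch[, c("q_start", "q_end", "s_start", "s_end")]
          if (strand == "-") {
            # report blocks in original query coordinates
            b <- blocks
            blocks$q_start <- nq - b$q_end + 1L
            blocks$q_end <- nq - b$q_start + 1L
            blocks <- blocks[order(blocks$q_start), , drop = FALSE]
          }
          rownames(blocks) <- NULL
          hits[[length(hits) + 1L]] <- DataFrame(
            query_id = names(qseq)[qi], subject_id = names(rseq)[si],
            strand = strand, pident = pid, aligned_length = alen,
            evalue = NA_real_, blocks = I(list(blocks)))
        }
      }
    }
  }
  if (length(hits) == 0)
    return(AlignmentHits(DataFrame(query_id = character(),
                                   subject_id = character(),
                                   strand = character(), pident = numeric(),
                                   aligned_length = integer(),
                                   evalue = numeric(), blocks = I(list()))))
  out <- do.call(rbind, hits)
  # best hits first
  out <- out[order(-(out$pident * out$aligned_length)), ]
  AlignmentHits(out)
}

# merge seeds on one diagonal into gapless segments, then extend with
# X-drop; returns a data.frame of segments with match counts
.mergeSeeds <- function(seeds, k, q, sv) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  nq <- length(qv); ns <- length(sv)
  dt <- seeds
  dt$diag <- dt$spos - dt$qpos
  dt <- dt[order(dt$diag, dt$qpos), ]
  segs <- list()
  d0 <- NULL; lo <- hi <- NULL
  flush <- function() {
    if (is.null(d0)) return()
    segs[[length(segs) + 1L]] <<- c(diag = d0, q_start = lo, q_end = hi + k - 1L)
  }
  for (i in seq_len(nrow(dt))) {
    d <- dt$diag[i]; qp <- dt$qpos[i]
    if (is.null(d0) || d != d0 || qp > hi + k + 30L) {
      flush(); d0 <- d; lo <- hi <- qp
    } else hi <- max(hi, qp)
  }
  flush()
  if (length(segs) == 0) return(NULL)
  out <- as.data.frame(do.call(rbind, segs))
  # extend each segment with X-drop (match +1, mismatch -2, drop 6)
  res <- lapply(seq_len(nrow(out)), function(i) {
    d <- out$diag[i]; qs <- out$q_start[i]; qe <- out$q_end[i]
    # left
    best <- 0; sc <- 0; bq <- qs
    j <- qs - 1L
    while (j >= 1L && j + d >= 1L && sc > best - 6) {
      sc <- sc + if (qv[j] == sv[j + d] && qv[j] %in% c("A","C","G","T")) 1 else -2
      if (sc > best) { best <- sc; bq <- j }
      j <- j - 1L
    }
    qs <- bq
    best <- 0; sc <- 0; bq <- qe
    j <- qe + 1L
    while (j <= nq && j + d <= ns && sc > best - 6) {
      sc <- sc + if (qv[j] == sv[j + d] && qv[j] %in% c("A","C","G","T")) 1 else -2
      if (sc > best) { best <- sc; bq <- j }
      j <- j + 1L
    }
    qe <- bq
    m <- sum(qv[qs:qe] == sv[(qs:qe) + d])
    data.frame(q_start = qs, q_end = qe, s_start = qs + d, s_end = qe + d,
               matches = m)
  })
  out <- do.call(rbind, res)
  unique(out)
}

# colinear chaining by dynamic programming (weighted chains with gap
# penalties): segments are chained so that query and subject coordinates
# both increase, query gaps stay small (spliced transcripts), subject
# gaps stay at intron scale, and small overlaps -- micro-homology at
# splice junctions makes neighbouring X-drop extensions overrun by a few
# bases -- are tolerated and trimmed. The gap penalty keeps scattered
# random seed matches from attaching to a true chain. Chains are peeled
# off best-first until no segments remain.
.chainSegments <- function(segs, maxOverlap = 20L, maxQGap = 60L,
                           maxSGap = 20000L, minSeg = 15L) {
  segs <- segs[segs$matches >= minSeg, , drop = FALSE]
  if (nrow(segs) == 0) return(list())
  if (nrow(segs) > 200) {
    segs <- segs[order(-segs$matches), , drop = FALSE][1:200, , drop = FALSE]
  }
  chains <- list()
  remaining <- segs
  while (nrow(remaining) > 0) {
    s <- remaining[order(remaining$q_start, remaining$s_start), ,
                   drop = FALSE]
    m <- nrow(s)
    dp <- as.numeric(s$matches)
    prev <- integer(m)
    if (m > 1) {
      for (i in 2:m) {
        for (j in 1:(i - 1)) {
          qgap <- s$q_start[i] - s$q_end[j] - 1L
          sgap <- s$s_start[i] - s$s_end[j] - 1L
          if (qgap < -maxOverlap || qgap > maxQGap) next
          if (sgap < -maxOverlap || sgap > maxSGap) next
          cand <- dp[j] + s$matches[i] -
            0.001 * max(sgap, 0L) - 0.01 * max(qgap, 0L)
          if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
        }
      }
    }
    idx <- which.max(dp)
    while (prev[idx[1]] > 0) idx <- c(prev[idx[1]], idx)
    chain <- s[idx, , drop = FALSE]
    # trim residual overlaps so blocks are disjoint and q-increasing
    if (nrow(chain) > 1) {
      for (r in 2:nrow(chain)) {
        d <- chain$q_end[r - 1] - chain$q_start[r] + 1L
        if (d > 0) {
          chain$q_start[r] <- chain$q_start[r] + d
          chain$s_start[r] <- chain$s_start[r] + d
          chain$matches[r] <- max(chain$matches[r] - d, 0L)
        }
      }
      chain <- chain[chain$q_end >= chain$q_start, , drop = FALSE]
    }
    rownames(chain) <- NULL
    chains[[length(chains) + 1L]] <- chain
    remaining <- s[-idx, , drop = FALSE]
  }
  chains
}

#' Project a query interval through an alignment onto the subject
#'
#' Maps the first and last aligned base of the interval through the hit's
#' block list; minus-strand hits are reflected so the returned interval
#' is always in plus-strand subject coordinates. The projection is
#' reported absent (`NULL`) when fewer than half of the interval's bases
#' are covered by aligned blocks.
#'
#' @param hit one row of an [AlignmentHits] object.
#' @param qStart,qEnd 1-based inclusive query interval.
#' @return A list with `s_start`, `s_end`, `covered` (aligned bases of the
#'   interval), or `NULL` when unprojected.
#' @export
projectInterval <- function(hit, qStart, qEnd) {
  b <- hit$blocks[[1]]
  strand <- hit$strand[1]
  qlen <- max(b$q_end)
  if (qStart < 1 || qStart > qEnd)
    stop("invalid query interval")
  covered <- 0L
  s_lo <- Inf; s_hi <- -Inf
  for (i in seq_len(nrow(b))) {
    lo <- max(qStart, b$q_start[i]); hi <- min(qEnd, b$q_end[i])
    if (lo > hi) next
    covered <- covered + (hi - lo + 1L)
    if (strand == "+") {
      ss <- b$s_start[i] + (lo - b$q_start[i])
      se <- b$s_start[i] + (hi - b$q_start[i])
    } else {
      # minus strand: increasing query maps to decreasing subject
      se <- b$s_end[i] - (lo - b$q_start[i])
      ss <- b$s_end[i] - (hi - b$q_start[i])
    }
    s_lo <- min(s_lo, ss); s_hi <- max(s_hi, se)
  }
  if (covered < (qEnd - qStart + 1L) / 2) return(NULL)
  list(s_start = as.integer(s_lo), s_end = as.integer(s_hi),
       covered = as.integer(covered))
}
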