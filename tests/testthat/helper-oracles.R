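# Independent oracles used by the property and acceptance tests. These
# deliberately re-derive results with plain loops and base R, separate
# from the package's vectorized implementations.

randomSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracleRevcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# brute force scan: every position and period checked for primitivity,
# left-maximality and repeat count by direct substring comparison
oracleSSRs <- function(seq, minRep = c(`2` = 10, `3` = 7, `4` = 5,
                                       `5` = 4, `6` = 4)) {
  n <- nchar(seq)
  out <- list()
  for (p in 2:6) {
    if (n < 2 * p) next
    for (i in 1:(n - 2 * p + 1)) {
      motif <- substr(seq, i, i + p - 1)
      if (grepl("[^ACGT]", motif)) next
      prim <- TRUE
      for (d in 1:(p - 1))
        if (p %% d == 0 && motif == strrep(substr(motif, 1, d), p / d))
          prim <- FALSE
      if (!prim) next
      if (i > p && substr(seq, i - p, i - 1) == motif) next  # not leftmost
      k <- 1
      while (i + (k + 1) * p - 1 <= n &&
             substr(seq, i + k * p, i + (k + 1) * p - 1) == motif)
        k <- k + 1
      if (k < minRep[as.character(p)]) next
      out[[length(out) + 1]] <- data.frame(
        start = i, end = i + k * p - 1, period = p, motif = motif,
        repeat_count = k)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      motif = character(), repeat_count = integer()))
  df <- do.call(rbind, out)
  # the declared overlap rule: longer run wins, tie -> smaller period
  df <- df[order(-(df$end - df$start + 1), df$period, df$start), ]
  keep <- rep(FALSE, nrow(df))
  occ <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(df))) {
    if (nrow(occ) == 0 ||
        !any(df$start[r] <= occ[, 2] & df$end[r] >= occ[, 1])) {
      keep[r] <- TRUE
      occ <- rbind(occ, c(df$start[r], df$end[r]))
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# motif-family oracle: union-find closure over single-rotation and
# reverse-complement edges among all motifs of one period
oracleFamilies <- function(period) {
  alph <- c("A", "C", "G", "T")
  motifs <- do.call(paste0, expand.grid(rep(list(alph), period),
                                        stringsAsFactors = FALSE))
  idx <- stats::setNames(seq_along(motifs), motifs)
  parent <- seq_along(motifs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (m in motifs) {
    rot <- paste0(substr(m, 2, period), substr(m, 1, 1))
    union(idx[[m]], idx[[rot]])
    union(idx[[m]], idx[[oracleRevcomp(m)]])
  }
  roots <- vapply(seq_along(motifs), find, integer(1))
  classMin <- vapply(split(motifs, roots), min, character(1))
  stats::setNames(unname(classMin[as.character(roots)]), motifs)
}

# exhaustive primer-pair search with its own constraint arithmetic;
# gc_linear melting model so expected values stay closed-form
oraclePrimers <- function(template, ssrStart, ssrEnd,
                          lenRange = 18:23, tmRange = c(55, 65),
                          gcRange = c(0.30, 0.70), prodRange = c(90, 320),
                          maxTmDiff = 3, maxSelfComp = 8,
                          weights = c(len = 1, tm = 1, gc = 0.5, pair = 1)) {
  n <- nchar(template)
  oTm <- function(s) 64.9 + 41 * (lengths(regmatches(s, gregexpr("[GC]", s))) - 16.4) / nchar(s)
  oGc <- function(s) lengths(regmatches(s, gregexpr("[GC]", s))) / nchar(s)
  # violation check at the 9-mer level: equivalent to "longest
  # self-complementary stretch <= 8"
  oSelf <- function(s) {
    L <- nchar(s)
    k <- maxSelfComp + 1
    if (L < k) return(0)
    subs <- substring(s, 1:(L - k + 1), k:L)
    rc <- vapply(subs, oracleRevcomp, character(1))
    if (any(rc %in% subs)) k else 0
  }
  cand <- function(reverse) {
    rows <- list()
    for (L in lenRange) {
      if (!reverse) {
        for (e in seq_len(ssrStart - 1)) {
          s <- e - L + 1
          if (s < 1) next
          rows[[length(rows) + 1]] <- c(s, e, L)
        }
      } else {
        for (s in (ssrEnd + 1):n) {
          e <- s + L - 1
          if (e > n) next
          rows[[length(rows) + 1]] <- c(s, e, L)
        }
      }
    }
    if (length(rows) == 0) return(NULL)
    g <- as.data.frame(do.call(rbind, rows))
    names(g) <- c("start", "end", "len")
    g$seq <- substring(template, g$start, g$end)
    if (reverse) g$seq <- vapply(g$seq, oracleRevcomp, character(1))
    g <- g[!grepl("[^ACGT]", g$seq), , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    g$gc <- oGc(g$seq); g$tm <- oTm(g$seq)
    g <- g[g$gc >= gcRange[1] & g$gc <= gcRange[2] &
             g$tm >= tmRange[1] & g$tm <= tmRange[2], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    g <- g[vapply(g$seq, oSelf, numeric(1)) <= maxSelfComp, , drop = FALSE]
    if (nrow(g) == 0) NULL else g
  }
  fwd <- cand(FALSE); rev <- cand(TRUE)
  if (is.null(fwd) || is.null(rev)) return(NULL)
  pf <- weights["len"] * abs(fwd$len - 20) + weights["tm"] * abs(fwd$tm - 60) +
    weights["gc"] * abs(fwd$gc - 0.5) * 100
  pr <- weights["len"] * abs(rev$len - 20) + weights["tm"] * abs(rev$tm - 60) +
    weights["gc"] * abs(rev$gc - 0.5) * 100
  prod <- outer(fwd$start, rev$end, function(a, b) b - a + 1)
  dtm <- abs(outer(fwd$tm, rev$tm, "-"))
  pen <- outer(pf, pr, "+") + weights["pair"] * dtm
  bad <- prod < prodRange[1] | prod > prodRange[2] | dtm > maxTmDiff
  pen[bad] <- Inf
  if (!any(is.finite(pen))) return(NULL)
  best <- which(pen <= min(pen) + 1e-12, arr.ind = TRUE)
  # tie-break: smaller product size, then leftmost forward start
  o <- order(prod[best], fwd$start[best[, 1]])
  bi <- best[o[1], ]
  list(forward = fwd$seq[bi[1]], reverse = rev$seq[bi[2]],
       f_start = fwd$start[bi[1]], r_end = rev$end[bi[2]],
       product = prod[bi[1], bi[2]], penalty = pen[bi[1], bi[2]])
}

# plain-arithmetic context classifier: projection and overlap with loops
oracleContext <- function(ssrStart, ssrEnd, blocks, strand, genesDf,
                          subjectId) {
  s_lo <- Inf; s_hi <- -Inf; covered <- 0
  for (b in seq_len(nrow(blocks))) {
    lo <- max(ssrStart, blocks$q_start[b]); hi <- min(ssrEnd, blocks$q_end[b])
    if (lo > hi) next
    covered <- covered + hi - lo + 1
    if (strand == "+") {
      ss <- blocks$s_start[b] + lo - blocks$q_start[b]
      se <- blocks$s_start[b] + hi - blocks$q_start[b]
    } else {
      se <- blocks$s_end[b] - (lo - blocks$q_start[b])
      ss <- blocks$s_end[b] - (hi - blocks$q_start[b])
    }
    s_lo <- min(s_lo, ss); s_hi <- max(s_hi, se)
  }
  if (covered < (ssrEnd - ssrStart + 1) / 2) return("genomic")
  g <- genesDf[genesDf$seqnames == subjectId, , drop = FALSE]
  bp <- c(exon = 0, UTR = 0, intron = 0)
  lab <- c(CDS = "exon", five_prime_UTR = "UTR", three_prime_UTR = "UTR",
           intron = "intron")
  for (r in seq_len(nrow(g))) {
    ov <- min(s_hi, g$end[r]) - max(s_lo, g$start[r]) + 1
    if (ov > 0 && g$type[r] %in% names(lab))
      bp[lab[[g$type[r]]]] <- bp[[lab[[g$type[r]]]]] + ov
  }
  if (sum(bp) == 0) return("genomic")
  names(bp)[bp == max(bp)][1]
}
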