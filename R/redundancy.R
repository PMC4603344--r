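#' Collapse an EST set into non-redundant unique sequences
#'
#' Greedy representative-based clustering: records are processed in
#' (length descending, id ascending) order; each sequence joins the first
#' existing cluster whose representative shares at least one exact k-mer
#' and aligns at `minIdentity` identity over at least
#' `minOverlapFraction` of the shorter sequence, otherwise it founds a new
#' cluster. A sequence may join via its reverse complement (EST libraries
#' mix orientations) and is then stored re-oriented to the
#' representative. Clusters with two or more members become contigs whose
#' consensus is the per-column majority over the star alignment to the
#' representative (ties keep the representative's base); single-member
#' clusters are singletons.
#'
#' @param records a named [Biostrings::DNAStringSet] of ESTs from one
#'   genus (a `genus` metadata column is propagated).
#' @param params a [ClusterParams] object.
#' @return A named [Biostrings::DNAStringSet] of unique sequences with
#'   ids `<genus>_u<serial>` and metadata columns `kind`
#'   ("contig"/"singleton"), `genus` and `members` (a
#'   [S4Vectors::SimpleList] of contributing record ids).
#' @export
reduceRedundancy <- function(records, params = ClusterParams()) {
  genus <- S4Vectors::mcols(records)$genus
  genus <- if (is.null(genus) || length(genus) == 0) NA_character_ else genus[1]
  gtag <- if (is.na(genus)) "unknown" else genus
  if (length(records) == 0) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- DataFrame(kind = character(), genus = character(),
                                       members = I(list()))
    return(out)
  }
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stop("records must carry unique names")
  ord <- order(-Biostrings::width(records), ids)
  seqs <- as.character(records)[ord]
  ids <- ids[ord]
  k <- params@kmerSize

  # candidate-pairing k-mers; low-complexity k-mers (periodic with period
  # <= 6, i.e. k-mers inside SSR runs) are excluded so that unrelated
  # sequences sharing a repeat motif are not paired
  kmersOf <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- unique(substring(s, 1:(n - k + 1), k:n))
    periodic <- rep(FALSE, length(km))
    for (p in 1:6)
      periodic <- periodic |
        substring(km, 1L, k - p) == substring(km, p + 1L, k)
    km[!periodic]
  }

  kmerIndex <- new.env(hash = TRUE, parent = emptyenv())
  reps <- character(0)           # representative sequences
  members <- list()              # per cluster: member ids
  memberSeqs <- list()           # per cluster: member seqs oriented to rep

  # containment with substitutions only: fast C-level scan
  containedIn <- function(s, rep) {
    mm <- floor((1 - params@minIdentity) * nchar(s))
    Biostrings::countPattern(s, rep, max.mismatch = mm) > 0
  }

  alnOK <- function(s, rep) {
    # identity over aligned columns and overlap fraction of the shorter
    # sequence, from an ends-free alignment (partial overlaps, indels)
    aln <- Biostrings::pairwiseAlignment(
      s, rep, type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    m <- Biostrings::nmatch(aln)
    cols <- Biostrings::nchar(aln)   # alignment length incl. indel columns
    if (cols == 0) return(FALSE)
    ident <- m / cols
    pspan <- BiocGenerics::width(Biostrings::pattern(aln))
    sspan <- BiocGenerics::width(Biostrings::subject(aln))
    overlap <- if (nchar(s) <= nchar(rep)) pspan / nchar(s)
               else sspan / nchar(rep)
    ident >= params@minIdentity && overlap >= params@minOverlapFraction
  }

  for (i in seq_along(seqs)) {
    s <- seqs[i]
    km <- kmersOf(s)
    hits <- unlist(mget(km, envir = kmerIndex, ifnotfound = list(NULL)),
                   use.names = FALSE)
    joined <- FALSE
    oriented <- s
    if (length(hits)) {
      # prefilter: a true >=95 %-identity overlap shares many exact
      # k-mers; candidates sharing only a handful are skipped unaligned
      shared <- tabulate(hits)
      cand <- which(shared >= max(3, 0.2 * length(km)))
      rc <- if (params@revComp) revcompChar(s) else NULL
      for (ci in sort(cand)) {
        # containment fast paths (substitution-only redundancy) before
        # the full ends-free alignment
        if (containedIn(s, reps[ci])) {
          joined <- TRUE; oriented <- s
        } else if (params@revComp && containedIn(rc, reps[ci])) {
          joined <- TRUE; oriented <- rc
        } else if (alnOK(s, reps[ci])) {
          joined <- TRUE; oriented <- s
        } else if (params@revComp && alnOK(rc, reps[ci])) {
          joined <- TRUE; oriented <- rc
        }
        if (joined) {
          members[[ci]] <- c(members[[ci]], ids[i])
          memberSeqs[[ci]] <- c(memberSeqs[[ci]], oriented)
          break
        }
      }
    }
    if (!joined) {
      ci <- length(reps) + 1L
      reps[ci] <- s
      members[[ci]] <- ids[i]
      memberSeqs[[ci]] <- s
      for (x in km) kmerIndex[[x]] <- c(kmerIndex[[x]], ci)
      if (params@revComp)
        for (x in kmersOf(revcompChar(s)))
          kmerIndex[[x]] <- unique(c(kmerIndex[[x]], ci))
    }
  }

  consensus <- vapply(seq_along(reps), function(ci) {
    if (length(memberSeqs[[ci]]) == 1) return(reps[ci])
    starConsensus(reps[ci], memberSeqs[[ci]][-1])
  }, character(1))

  out <- Biostrings::DNAStringSet(consensus)
  names(out) <- sprintf("%s_u%d", gtag, seq_along(reps))
  S4Vectors::mcols(out) <- DataFrame(
    kind = ifelse(lengths(members) >= 2, "contig", "singleton"),
    genus = rep(genus, length(reps)),
    members = I(members))
  out
}

# per-column majority vote over representative coordinates; the
# representative votes too and wins ties. Members that sit in the
# representative as a substitution-only match are voted in directly; the
# (rare) gapped members go through an ends-free alignment.
starConsensus <- function(rep, others, maxMismatchFrac = 0.10) {
  n <- nchar(rep)
  repv <- strsplit(rep, "", fixed = TRUE)[[1]]
  votes <- matrix("", nrow = length(others) + 1L, ncol = n)
  votes[1, ] <- repv
  for (j in seq_along(others)) {
    s <- others[j]
    mm <- floor(maxMismatchFrac * nchar(s))
    hit <- Biostrings::matchPattern(s, rep, max.mismatch = mm)
    # edge matches can hang off the representative; keep in-bounds ones
    hit <- hit[BiocGenerics::start(hit) >= 1L &
                 BiocGenerics::end(hit) <= n]
    if (length(hit) >= 1) {
      off <- BiocGenerics::start(hit)[1] - 1L
      votes[j + 1L, off + seq_len(nchar(s))] <-
        strsplit(s, "", fixed = TRUE)[[1]]
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      s, rep, type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    rpos <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
    for (col in seq_along(sub)) {
      if (sub[col] != "-") {
        rpos <- rpos + 1L
        if (pat[col] != "-") votes[j + 1L, rpos] <- pat[col]
      }
    }
  }
  out <- repv
  # columns where every vote equals the representative (the common case)
  # need no tally
  disagree <- which(colSums(votes != "" & votes != rep(repv, each = nrow(votes))) > 0)
  for (p in disagree) {
    v <- votes[, p]
    v <- v[v != ""]
    tb <- sort(table(v), decreasing = TRUE)
    top <- names(tb)[tb == tb[1]]
    out[p] <- if (repv[p] %in% top) repv[p] else top[1]
  }
  paste(out, collapse = "")
}

#' Drop unique sequences at or below a minimum length
#'
#' Retains sequences whose length is strictly greater than `minLen`
#' (a "larger than 100 bp" rule, read literally).
#'
#' @param uniques a [Biostrings::DNAStringSet].
#' @param minLen length threshold in bp.
#' @return The filtered [Biostrings::DNAStringSet].
#' @export
filterMinLength <- function(uniques, minLen = 100L) {
  stopifnot(minLen >= 1)
  uniques[Biostrings::width(uniques) > minLen]
}

#' Write the unique-sequence membership table
#'
#' @param uniques output of [reduceRedundancy()].
#' @param path output TSV (columns unique_id, kind, member_id).
#' @return `path`, invisibly.
#' @export
writeMembershipTable <- function(uniques, path) {
  mc <- S4Vectors::mcols(uniques)
  rows <- do.call(rbind, lapply(seq_along(uniques), function(i)
    data.frame(unique_id = names(uniques)[i], kind = mc$kind[i],
               member_id = mc$members[[i]])))
  if (is.null(rows))
    rows <- data.frame(unique_id = character(), kind = character(),
                       member_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
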