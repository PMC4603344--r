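#' Read an EST set from FASTA
#'
#' Sequences are uppercased and the pre-whitespace header token becomes the
#' record id. Duplicated ids are an error because ids key every downstream
#' table.
#'
#' @param path FASTA file.
#' @param genus genus label attached to every record.
#' @return A [Biostrings::DNAStringSet] with record ids as names and a
#'   `genus` metadata column.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt", ">b", "NNAC"), f)
#' readEstFasta(f, genus = "Oryza")
#' @export
readEstFasta <- function(path, genus = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicated FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad)) {
    # report the file line of the first offending record
    hdr <- grep("^>", readLines(path))
    stop(sprintf("illegal sequence characters in record '%s' (header line %d)",
                 ids[which(bad)[1]], hdr[which(bad)[1]]))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$genus <- rep(genus, length(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or character vector).
#' @param path output file.
#' @param width line-wrapping width.
#' @return `path`, invisibly.
#' @export
writeEstFasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(seqs)
    seqs <- x
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read 12-column tabular alignments
#'
#' Ingests the standard 12-column tab-separated alignment convention
#' (query, subject, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore). Coordinates in the file are 1-based
#' inclusive; `sstart > send` denotes a minus-strand hit and is flipped to
#' the plus-strand representation with `strand = "-"`. Each row becomes a
#' single-block hit; `pident` is rescaled from percent to a fraction.
#'
#' @param path tabular alignment file (no header).
#' @return An [AlignmentHits] object.
#' @export
readAlignmentsTabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          rep("character", 10)))
  if (nrow(tab) == 0) {
    return(AlignmentHits(DataFrame(query_id = character(), subject_id = character(),
                                   strand = character(), pident = numeric(),
                                   aligned_length = integer(), evalue = numeric(),
                                   blocks = I(list()))))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value in column '%s', row %d",
                   col, which(is.na(v))[1]))
    v
  }
  pident <- num("pident"); alen <- as.integer(num("length"))
  qs <- as.integer(num("qstart")); qe <- as.integer(num("qend"))
  ss <- as.integer(num("sstart")); se <- as.integer(num("send"))
  ev <- num("evalue")
  minus <- ss > se
  blocks <- lapply(seq_len(nrow(tab)), function(i) {
    data.frame(q_start = qs[i], q_end = qe[i],
               s_start = if (minus[i]) se[i] else ss[i],
               s_end = if (minus[i]) ss[i] else se[i])
  })
  AlignmentHits(DataFrame(query_id = tab$query, subject_id = tab$subject,
                          strand = ifelse(minus, "-", "+"),
                          pident = pident / 100, aligned_length = alen,
                          evalue = ev, blocks = I(blocks)))
}

#' Write alignment hits back to the 12-column tabular convention
#'
#' Single-block hits are written with file-convention coordinates (1-based
#' inclusive; minus-strand hits get `sstart > send`), so
#' `readAlignmentsTabular(writeAlignmentsTabular(x))` is the identity on
#' coordinates. Multi-block hits are written one row per block.
#'
#' @param hits an [AlignmentHits] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignmentsTabular <- function(hits, path) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    b <- hits$blocks[[i]]
    minus <- hits$strand[i] == "-"
    data.frame(query = hits$query_id[i], subject = hits$subject_id[i],
               pident = sprintf("%.2f", 100 * hits$pident[i]),
               length = b$q_end - b$q_start + 1L, mismatch = 0L, gapopen = 0L,
               qstart = b$q_start, qend = b$q_end,
               sstart = if (minus) b$s_end else b$s_start,
               send = if (minus) b$s_start else b$s_end,
               evalue = ifelse(is.na(hits$evalue[i]), 0, hits$evalue[i]),
               bitscore = 0)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Returns one feature set per mRNA: CDS and UTR rows are kept (UTRs are
#' derived as exon minus CDS when not given explicitly) and intron
#' intervals are synthesized as the gaps between consecutive exons.
#'
#' @param path GFF3 file.
#' @return A [GenomicRanges::GRanges] of features with metadata columns
#'   `transcript_id`, `gene_id` and `type` (one of `five_prime_UTR`,
#'   `CDS`, `intron`, `three_prime_UTR`).
#' @export
readGff3Genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  getParent <- function(x) {
    p <- x$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  tx_ids <- mrna$ID
  tx_gene <- getParent(mrna)
  names(tx_gene) <- tx_ids
  keep <- typ %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  feats <- gr[keep]
  parent <- getParent(feats)
  res <- list()
  for (tx in tx_ids) {
    f <- feats[!is.na(parent) & parent == tx]
    ftyp <- as.character(f$type)
    ex <- f[ftyp == "exon"]
    cds <- f[ftyp == "CDS"]
    utr5 <- f[ftyp == "five_prime_UTR"]
    utr3 <- f[ftyp == "three_prime_UTR"]
    if (length(ex) > 0 && length(cds) > 0) {
      outside <- IRanges::setdiff(IRanges::reduce(IRanges::ranges(cds)),
                                  IRanges::reduce(IRanges::ranges(ex)))
      if (length(outside) > 0)
        stop(sprintf("CDS of %s extends outside its exons", tx))
    }
    pieces <- GenomicRanges::GRanges()
    addPiece <- function(pieces, g, type) {
      if (length(g) == 0) return(pieces)
      g2 <- GenomicRanges::granges(g)
      g2$type <- type
      c(pieces, g2)
    }
    pieces <- addPiece(pieces, cds, "CDS")
    if (length(utr5) || length(utr3)) {
      pieces <- addPiece(pieces, utr5, "five_prime_UTR")
      pieces <- addPiece(pieces, utr3, "three_prime_UTR")
    } else if (length(ex) && length(cds)) {
      # derive UTRs: exonic minus CDS; 5' side is upstream of the CDS on +
      exr <- IRanges::reduce(IRanges::ranges(ex))
      utr <- IRanges::setdiff(exr, IRanges::reduce(IRanges::ranges(cds)))
      if (length(utr)) {
        plus <- as.character(BiocGenerics::strand(ex))[1] != "-"
        cds_lo <- min(IRanges::start(IRanges::ranges(cds)))
        cds_hi <- max(IRanges::end(IRanges::ranges(cds)))
        side5 <- if (plus) IRanges::end(utr) < cds_lo else IRanges::start(utr) > cds_hi
        g <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex)[1], utr,
                                    strand = BiocGenerics::strand(ex)[1])
        g$type <- ifelse(side5, "five_prime_UTR", "three_prime_UTR")
        pieces <- c(pieces, g)
      }
    }
    if (length(ex) > 1) {
      exr <- BiocGenerics::sort(IRanges::reduce(IRanges::ranges(ex)))
      gaps <- IRanges::gaps(exr, start = min(IRanges::start(exr)),
                            end = max(IRanges::end(exr)))
      if (length(gaps)) {
        g <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex)[1], gaps,
                                    strand = BiocGenerics::strand(ex)[1])
        g$type <- "intron"
        pieces <- c(pieces, g)
      }
    }
    if (length(pieces)) {
      pieces$transcript_id <- tx
      pieces$gene_id <- unname(tx_gene[tx])
      res[[tx]] <- pieces
    }
  }
  if (length(res) == 0)
    return(GenomicRanges::GRanges(type = character(),
                                  transcript_id = character(),
                                  gene_id = character()))
  out <- BiocGenerics::sort(do.call(c, unname(res)))
  out
}

#' Genus-to-taxonomic-group mapping
#'
#' Loads the packaged genus-to-group table (the eight groups used for
#' compositional summaries) optionally extended with user rows.
#'
#' @param extra optional data.frame with columns `genus` and `group`.
#' @return Named character vector: names are genera, values group labels.
#' @export
taxonMap <- function(extra = NULL) {
  f <- system.file("extdata", "genus_groups.tsv", package = "SSRmine")
  tab <- utils::read.table(f, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("genus", "group") %in% names(extra)))
    tab <- rbind(tab, extra[, c("genus", "group")])
    tab <- tab[!duplicated(tab$genus, fromLast = TRUE), ]
  }
  if (!all(tab$group %in% VALID_GROUPS))
    stop("unknown taxonomic group: ",
         paste(setdiff(tab$group, VALID_GROUPS), collapse = ", "))
  stats::setNames(tab$group, tab$genus)
}
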