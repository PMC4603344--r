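# shared small helpers: none exported

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

revcompChar <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# rounding half away from zero at the printed precision
roundHalfAway <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertDNA <- function(seq, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seq)
  if (any(bad))
    stop(sprintf("%s contains non-IUPAC characters", what), call. = FALSE)
  invisible(seq)
}

isACGT <- function(seq) !grepl("[^ACGT]", seq)

md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f)
  unname(tools::md5sum(f))
}
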