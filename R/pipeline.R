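#' Pipeline configuration
#'
#' Bundles every stage's parameters, the input/output locations and the
#' seed into one validated list. Stages read their inputs from
#' `outDir` (or from the user-supplied `input`/`reference`/`annotation`/
#' `alignments` paths) and write their outputs plus a manifest line
#' there.
#'
#' @param outDir output directory (created if missing).
#' @param seed integer seed; forwarded into [SimParams] unless `sim` is
#'   given.
#' @param genus genus label used for synthetic data.
#' @param input optional path to a real EST FASTA (skips the simulate
#'   stage).
#' @param reference,annotation optional reference FASTA and GFF3 for the
#'   context stage (default: the simulated ones).
#' @param alignments optional pre-computed 12-column tabular alignment
#'   file used instead of the internal aligner.
#' @param sim a [SimParams] object.
#' @param cluster a [ClusterParams] object.
#' @param mining a [MiningParams] object.
#' @param primer a [PrimerParams] object.
#' @param significance a [SignificanceParams] object.
#' @param minLen unique-sequence length filter (strictly greater than).
#' @return A named list of class `"ssrmine_config"`.
#' @export
pipelineConfig <- function(outDir, seed = 1L, genus = "Synthetica",
                           input = NULL, reference = NULL, annotation = NULL,
                           alignments = NULL,
                           sim = SimParams(seed = seed),
                           cluster = ClusterParams(),
                           mining = MiningParams(),
                           primer = PrimerParams(),
                           significance = SignificanceParams(),
                           minLen = 100L) {
  stopifnot(is.character(outDir), length(outDir) == 1)
  for (p in c(input, reference, annotation, alignments))
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p)
  cfg <- list(outDir = outDir, seed = as.integer(seed), genus = genus,
              input = input, reference = reference, annotation = annotation,
              alignments = alignments, sim = sim, cluster = cluster,
              mining = mining, primer = primer, significance = significance,
              minLen = as.integer(minLen))
  class(cfg) <- "ssrmine_config"
  cfg
}

STAGES <- c("simulate", "reduce", "mine", "primers", "context", "summarize")

stageOutputs <- function(name) {
  switch(name,
         simulate = c("genome.fasta", "genes.gff3", "ests.fasta",
                      "truth_ssrs.tsv", "truth_fragments.tsv"),
         reduce = c("uniques.fasta", "uniques_filtered.fasta",
                    "membership.tsv"),
         mine = "ssr_loci.tsv",
         primers = "primer_catalog.tsv",
         context = c("context_calls.tsv", "context_table.tsv"),
         summarize = c("summary_counts.tsv", "summary_period_percent.tsv",
                       "funnel.tsv"))
}

stageDeps <- function(name, config) {
  switch(name,
         simulate = character(),
         reduce = if (is.null(config$input)) "ests.fasta" else character(),
         mine = "uniques_filtered.fasta",
         primers = c("uniques_filtered.fasta", "ssr_loci.tsv"),
         context = c("uniques_filtered.fasta", "ssr_loci.tsv"),
         summarize = "ssr_loci.tsv")
}

appendManifest <- function(config, name, outputs) {
  digest <- md5OfObject(config[setdiff(names(config), "outDir")])
  sums <- tools::md5sum(file.path(config$outDir, outputs))
  rows <- data.frame(stage = name, params_digest = digest,
                     file = outputs, md5 = unname(sums))
  mf <- file.path(config$outDir, "manifest.tsv")
  utils::write.table(rows, mf, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(mf), append = file.exists(mf))
}

readLociTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character",
                                         genus = "character",
                                         motif = "character",
                                         canonical_family = "character",
                                         display_alias = "character"))
  SSRCatalog(DataFrame(df))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (toy genome + EST set), `reduce` (redundancy
#' reduction + length filter), `mine` (perfect-SSR detection), `primers`
#' (flanking primer design; catalog keeps only primer-bearing loci),
#' `context` (alignment + exon/UTR/intron/genomic classification),
#' `summarize` (count tables and the stage-by-stage funnel). Each stage
#' writes its outputs under `config$outDir` and appends a manifest line
#' (stage, parameter digest, output checksums). Missing upstream outputs
#' raise an error naming the missing stage.
#'
#' @param name stage name.
#' @param config a [pipelineConfig()].
#' @return The stage's main in-memory result, invisibly.
#' @export
runStage <- function(name, config) {
  name <- match.arg(name, STAGES)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  deps <- stageDeps(name, config)
  missing <- deps[!file.exists(file.path(config$outDir, deps))]
  if (length(missing)) {
    owner <- vapply(missing, function(m)
      STAGES[vapply(STAGES, function(s) m %in% stageOutputs(s), logical(1))][1],
      character(1))
    stop(sprintf("stage '%s' needs outputs of stage '%s' (missing: %s)",
                 name, paste(unique(owner), collapse = ", "),
                 paste(missing, collapse = ", ")))
  }
  out <- file.path(config$outDir, stageOutputs(name))
  res <- switch(name,
    simulate = {
      sim <- simulateGenome(config$sim)
      est <- simulateEsts(sim, config$sim, genus = config$genus)
      writeEstFasta(sim$genome, out[1])
      writeGff3(sim$genes, out[2])
      writeEstFasta(est$ests, out[3])
      utils::write.table(sim$truth, out[4], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(est$fragments, out[5], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      list(sim = sim, est = est)
    },
    reduce = {
      src <- config$input %||% file.path(config$outDir, "ests.fasta")
      ests <- readEstFasta(src, genus = config$genus)
      uniques <- reduceRedundancy(ests, config$cluster)
      writeEstFasta(uniques, out[1])
      filtered <- filterMinLength(uniques, config$minLen)
      writeEstFasta(filtered, out[2])
      writeMembershipTable(uniques, out[3])
      filtered
    },
    mine = {
      uniques <- readEstFasta(file.path(config$outDir, "uniques_filtered.fasta"),
                              genus = config$genus)
      loci <- mineGenus(uniques, config$mining)
      writeSSRCatalog(loci, out[1])
      loci
    },
    primers = {
      uniques <- readEstFasta(file.path(config$outDir, "uniques_filtered.fasta"),
                              genus = config$genus)
      loci <- readLociTsv(file.path(config$outDir, "ssr_loci.tsv"))
      catalog <- catalogWithPrimers(loci, uniques, config$primer)
      utils::write.table(as.data.frame(catalog), out[1], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      catalog
    },
    context = {
      ref <- config$reference %||% file.path(config$outDir, "genome.fasta")
      ann <- config$annotation %||% file.path(config$outDir, "genes.gff3")
      if (!file.exists(ref) || !file.exists(ann))
        stop("stage 'context' needs a reference and annotation ",
             "(run 'simulate' or supply reference=/annotation=)")
      uniques <- readEstFasta(file.path(config$outDir, "uniques_filtered.fasta"),
                              genus = config$genus)
      loci <- readLociTsv(file.path(config$outDir, "ssr_loci.tsv"))
      genes <- readGff3Genes(ann)
      withSSR <- unique(loci$seq_id)
      hits <- if (!is.null(config$alignments))
        readAlignmentsTabular(config$alignments)
      else alignLocal(uniques[names(uniques) %in% withSSR],
                      readEstFasta(ref), params = config$significance)
      calls <- classifyContexts(loci, hits, genes, config$significance)
      utils::write.table(as.data.frame(calls), out[1], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ct <- contextTable(calls)
      utils::write.table(as.data.frame(ct), out[2], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      calls
    },
    summarize = {
      loci <- readLociTsv(file.path(config$outDir, "ssr_loci.tsv"))
      counts <- composeCounts(loci)
      writeCountTable(counts, out[1])
      pct <- if (nrow(loci) > 0)
        percentOfTotal(counts, by = "period") else
        data.frame(period = integer(), count = integer(), percent = numeric())
      utils::write.table(pct, out[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      funnel <- pipelineFunnel(config)
      utils::write.table(funnel, out[3], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      counts
    })
  appendManifest(config, name, stageOutputs(name))
  invisible(res)
}

countFasta <- function(path) {
  if (!file.exists(path)) return(NA_integer_)
  length(Biostrings::fasta.seqlengths(path))
}

pipelineFunnel <- function(config) {
  od <- config$outDir
  nEst <- countFasta(config$input %||% file.path(od, "ests.fasta"))
  nUnique <- countFasta(file.path(od, "uniques.fasta"))
  nFiltered <- countFasta(file.path(od, "uniques_filtered.fasta"))
  lociPath <- file.path(od, "ssr_loci.tsv")
  nSsrSeq <- if (file.exists(lociPath))
    length(unique(utils::read.table(lociPath, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)$seq_id))
  else NA_integer_
  primPath <- file.path(od, "primer_catalog.tsv")
  nPrimSeq <- if (file.exists(primPath)) {
    pc <- utils::read.table(primPath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    length(unique(pc$seq_id))
  } else NA_integer_
  data.frame(step = c("est_records", "unique_sequences", "length_filtered",
                      "ssr_bearing_sequences", "primer_bearing_sequences"),
             count = c(nEst, nUnique, nFiltered, nSsrSeq, nPrimSeq))
}

#' Run the whole pipeline
#'
#' Executes simulate (skipped when `config$input` points at a real EST
#' FASTA) -> reduce -> mine -> primers -> context (when a reference and
#' annotation are available) -> summarize, and returns the funnel of
#' counts through the stages (records downloaded/generated, unique
#' sequences, length-filtered uniques, SSR-bearing and primer-bearing
#' sequences).
#'
#' @param config a [pipelineConfig()].
#' @return A list with `funnel` (data.frame) and `outputs` (paths of all
#'   written files).
#' @export
runAll <- function(config) {
  stages <- STAGES
  if (!is.null(config$input)) stages <- setdiff(stages, "simulate")
  haveRef <- !is.null(config$reference) || is.null(config$input)
  if (!haveRef) stages <- setdiff(stages, "context")
  for (s in stages) {
    message("running stage: ", s)
    runStage(s, config)
  }
  funnel <- pipelineFunnel(config)
  outputs <- file.path(config$outDir,
                       unlist(lapply(stages, stageOutputs), use.names = FALSE))
  message(paste(sprintf("%s: %s", funnel$step, funnel$count), collapse = "; "))
  list(funnel = funnel, outputs = outputs)
}
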