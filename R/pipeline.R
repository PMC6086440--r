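# Report assembly and the programmatic front end behind the command
# line interface: monophyly reports in the layout of published
# posterior-odds tables, divergence tables, haplotype tables and the
# synthetic-data entry point. All randomness is behind the config seed;
# machine outputs are plain TSV/JSON/NEXUS.

# "1.1 x 10-4" style scientific notation at `sig` significant figures.
formatSci <- function(x, sig = 2L) {
  s <- sprintf(paste0("%.", sig - 1L, "e"), x)
  parts <- strsplit(s, "e", fixed = TRUE)[[1]]
  expo <- as.integer(parts[2])
  paste0(parts[1], " x 10", expo)
}

#' Format the posterior-probability cell of a monophyly result
#'
#' Exact values print to three decimals ("0.096"); ESS-based bounds
#' print with a "<"/">" and two significant figures, tagged by basis:
#' "< 1.1 x 10-4 (P)".
#'
#' @param result a \linkS4class{MonophylyResult}.
#' @param config a \linkS4class{PipelineConfig} carrying the rounding
#'   rules.
#' @return character vector (one cell, or one per ESS basis for bounds).
#' @export
formatProbabilityCell <- function(result, config = pipelineConfig()) {
  .formatCell(result@probability, result@bound, config)
}

#' Format the posterior-odds cell of a monophyly result
#' @inheritParams formatProbabilityCell
#' @return character vector, as \code{\link{formatProbabilityCell}}.
#' @export
formatOddsCell <- function(result, config = pipelineConfig()) {
  .formatCell(result@odds, result@bound, config)
}

.formatCell <- function(vals, bound, config) {
  if (bound == "none")
    return(sprintf(paste0("%.", config@oddsDigits, "f"), vals))
  op <- if (bound == "upper") "<" else ">"
  ok <- !is.na(vals)
  unname(vapply(which(ok), function(i) {
    sprintf("%s %s (%s)", op,
            formatSci(vals[i], config@boundSigFigs), names(vals)[i])
  }, ""))
}

#' Read a monophyly hypothesis file
#'
#' Two formats: a JSON array of objects \code{{"name": ..., "taxa":
#' [...]}} (any file ending in .json), or plain text with one
#' hypothesis per line, \code{"name: taxonA taxonB ..."} (comma or
#' whitespace separated; lines starting with "#" ignored).
#'
#' @param path hypothesis file.
#' @return named list of taxon sets.
#' @export
readHypotheses <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(x)) stopInput("empty hypotheses file: %s", path)
    out <- setNames(
      lapply(x, function(h) as.character(unlist(h$taxa))),
      vapply(x, function(h) as.character(h$name), ""))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stopInput("empty hypotheses file: %s", path)
    parts <- strsplit(lines, ":", fixed = TRUE)
    out <- setNames(
      lapply(parts, function(p) {
        if (length(p) != 2) stopInput("malformed hypothesis line")
        strsplit(trimws(p[2]), "[,[:space:]]+")[[1]]
      }),
      vapply(parts, function(p) trimws(p[1]), ""))
  }
  bad <- names(out)[lengths(out) < 2]
  if (length(bad))
    stopInput("hypotheses with fewer than 2 taxa: %s",
              paste(bad, collapse = ", "))
  out
}

# Provenance block: input digests, seed, config hash, package version.
.provenance <- function(files, config) {
  files <- files[file.exists(files)]
  cfgTxt <- paste(utils::capture.output(utils::str(attributes(config))),
                  collapse = "\n")
  tmp <- tempfile()
  writeLines(cfgTxt, tmp)
  on.exit(unlink(tmp))
  list(
    inputs = as.list(tools::md5sum(files)),
    seed = config@seed,
    configHash = unname(tools::md5sum(tmp)),
    version = as.character(utils::packageVersion("PosteriorTrees"))
  )
}

#' Run monophyly tests over one or more tree traces
#'
#' For every trace an \linkS4class{ESSReport} is computed, then every
#' hypothesis is tested. With multiple traces (independent MCMC chains)
#' each chain is tested separately and a pooled trace is added — pooling
#' is never implicit elsewhere. Hypotheses whose taxa are absent from a
#' trace are skipped for that trace with a warning (taxon sets can
#' differ across loci).
#'
#' @param traces a \linkS4class{TreeTrace}, or a named list of them.
#' @param hypotheses named list of taxon sets (see
#'   \code{\link{readHypotheses}}).
#' @param config a \linkS4class{PipelineConfig}.
#' @param scalarTraces optional named list of parameter traces for the
#'   scalar ESS section (applied to every chain).
#' @return list with one element per trace: \code{ess} (ESSReport),
#'   \code{results} (list of MonophylyResult) and \code{report} (a
#'   formatted data.frame with hypothesis, basis, P and odds columns);
#'   plus \code{provenance}.
#' @export
runMonophyly <- function(traces, hypotheses, config = pipelineConfig(),
                         scalarTraces = list()) {
  if (is(traces, "TreeTrace")) traces <- list(trace = traces)
  if (is.null(names(traces)))
    names(traces) <- paste0("chain", seq_along(traces))
  if (!length(hypotheses)) stopInput("no hypotheses supplied")
  if (length(traces) > 1) traces$pooled <- poolTraces(unname(traces))
  out <- list()
  for (nm in names(traces)) {
    trace <- traces[[nm]]
    ess <- essReport(trace, scalarTraces = scalarTraces, config = config)
    results <- list()
    for (h in names(hypotheses)) {
      taxa <- hypotheses[[h]]
      if (!all(taxa %in% trace@taxa)) {
        warning(sprintf(
          "trace '%s': hypothesis '%s' skipped (taxa absent: %s)", nm, h,
          paste(setdiff(taxa, trace@taxa), collapse = ", ")),
          call. = FALSE)
        next
      }
      results[[h]] <- monophylyTest(trace, taxa, ess, name = h)
    }
    out[[nm]] <- list(ess = ess, results = results,
                      report = formatMonophylyReport(results, config))
  }
  out$provenance <- .provenance(character(), config)
  out
}

#' Assemble a posterior-odds report table
#'
#' One row per hypothesis for exact results; bounded results get one
#' row per ESS basis ("P" then "A"), mirroring the two-line layout of
#' published posterior-odds tables.
#'
#' @param results list of \linkS4class{MonophylyResult}.
#' @param config rounding rules.
#' @return data.frame with columns hypothesis, basis, P, odds.
#' @export
formatMonophylyReport <- function(results,
                                  config = pipelineConfig()) {
  rows <- lapply(results, function(r) {
    pcell <- formatProbabilityCell(r, config)
    ocell <- formatOddsCell(r, config)
    basis <- if (r@bound == "none") "" else names(r@probability)
    data.frame(hypothesis = r@hypothesis,
               basis = basis[seq_along(pcell)],
               P = pcell, odds = ocell, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(hypothesis = character(), basis = character(),
                      P = character(), odds = character())
  out
}

#' Summarize a tree trace: MCC tree, ages and divergence rows
#'
#' @param trace an ultrametric \linkS4class{TreeTrace}.
#' @param namedPairs named list of taxon sets for divergence reporting
#'   (may be empty).
#' @param config a \linkS4class{PipelineConfig} (HPD level).
#' @param outPrefix optional path prefix; when given, writes
#'   \code{<prefix>.mcc.nex} (annotated NEXUS) and
#'   \code{<prefix>.divergence.tsv}.
#' @param interval "hpd" or "central".
#' @return list with \code{mcc} (annotated tree), \code{divergence}
#'   (data.frame or NULL) and \code{files}.
#' @export
runSummarize <- function(trace, namedPairs = list(),
                         config = pipelineConfig(), outPrefix = NULL,
                         interval = "hpd") {
  mcc <- mccTree(trace)
  mcc <- annotateAges(mcc, trace, level = config@hpdLevel,
                      interval = interval)
  div <- if (length(namedPairs)) divergenceTable(mcc, namedPairs)
         else NULL
  files <- character()
  if (!is.null(outPrefix)) {
    nex <- paste0(outPrefix, ".mcc.nex")
    writeMccNexus(mcc, nex)
    files <- nex
    if (!is.null(div)) {
      tsv <- paste0(outPrefix, ".divergence.tsv")
      dd <- div
      for (cc in c("median", "lower", "upper"))
        dd[[cc]] <- sprintf("%.2f", dd[[cc]])
      dd$support <- sprintf("%.2f", dd$support)
      utils::write.table(dd, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, tsv)
    }
  }
  list(mcc = mcc, divergence = div, files = files)
}

#' Tabulate haplotypes from a FASTA alignment
#'
#' @param fasta path to an aligned FASTA file, or sequences directly.
#' @param groups id-to-group mapping: a two-column TSV path, a named
#'   character vector, or NULL to parse groups from id suffixes
#'   (\code{"GY018_borb"} style).
#' @param lengths optional named integer vector (group -> diagnostic
#'   fragment length in bp) to append species calls via the length
#'   classifier.
#' @param classifier a \linkS4class{LengthClassifier} (default: the
#'   shipped ITS1 diagnostic) used when \code{lengths} is given.
#' @param outFile optional TSV output path.
#' @return list with \code{table} (a \linkS4class{HaplotypeTable}) and
#'   \code{report} (data.frame in a per-group table layout).
#' @export
runHaplotypes <- function(fasta, groups = NULL, lengths = NULL,
                          classifier = NULL, outFile = NULL) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 &&
              file.exists(fasta)) readAlignedFasta(fasta) else fasta
  seqs <- .asSequences(seqs)
  if (is.null(groups)) {
    groups <- parseGroupsFromIds(names(seqs))
  } else if (is.character(groups) && length(groups) == 1 &&
             file.exists(groups)) {
    df <- utils::read.table(groups, header = FALSE, sep = "\t",
                            col.names = c("id", "group"),
                            stringsAsFactors = FALSE)
    groups <- setNames(df$group, df$id)
  }
  tab <- haplotypeTable(seqs, groups)
  report <- tab@table
  if (!is.null(lengths)) {
    if (is.null(classifier)) classifier <- its1Classifier(quiet = TRUE)
    report$fragmentBp <- as.integer(lengths[report$group])
    report$species <- ifelse(
      is.na(report$fragmentBp), "unknown",
      classifyByLength(report$fragmentBp, classifier))
  }
  if (!is.null(outFile))
    utils::write.table(report, outFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(table = tab, report = report)
}

#' Generate synthetic inputs (sticky tree trace or dated phylogeny)
#'
#' Dispatches to the synthetic module and writes files plus a JSON
#' ground-truth sidecar; fully deterministic under the config seeds.
#'
#' @param mode "sticky" (autocorrelated topology trace) or "phylo"
#'   (birth-death tree, relaxed-clock rates, GTR+G+I alignment).
#' @param config a \linkS4class{StickyChainConfig} (sticky) or
#'   \linkS4class{SeqSimConfig} (phylo).
#' @param outPrefix path prefix for outputs.
#' @return list of generated objects and file paths.
#' @export
runSimulate <- function(mode = c("sticky", "phylo"), config,
                        outPrefix = tempfile("sim")) {
  mode <- match.arg(mode)
  if (mode == "sticky") {
    if (!is(config, "StickyChainConfig"))
      stopInput("sticky mode needs a StickyChainConfig")
    out <- sampleStickyChain(config)
    treesFile <- paste0(outPrefix, ".trees.nex")
    writeNexusTrace(out$trace, treesFile)
    truthFile <- paste0(outPrefix, ".truth.json")
    writeSimTruth(out$truth, truthFile)
    c(out, list(files = c(trees = treesFile, truth = truthFile)))
  } else {
    if (!is(config, "SeqSimConfig"))
      stopInput("phylo mode needs a SeqSimConfig")
    tree <- simulateBDTree(config)
    rates <- assignRelaxedRates(tree, config@ucldMean, config@ucldStdev,
                                seed = deriveSeed(config@seed, "rates"))
    aln <- simulateAlignment(tree, rates, config)
    treeFile <- paste0(outPrefix, ".true.nwk")
    writeLines(writeNewick(tree), treeFile)
    fastaFile <- paste0(outPrefix, ".fasta")
    Biostrings::writeXStringSet(aln, fastaFile)
    truth <- new("SimTruth", trueTree = tree, branchRates = rates,
                 taxa = sort(tree$tip.label))
    truthFile <- paste0(outPrefix, ".truth.json")
    writeSimTruth(truth, truthFile)
    list(tree = tree, rates = rates, alignment = aln,
         truth = truth,
         files = c(tree = treeFile, fasta = fastaFile,
                   truth = truthFile))
  }
}
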