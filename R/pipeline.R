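## High-level pipeline entry points. These back the command-line wrapper
## shipped under inst/cli/gliadin.R; each is a thin orchestration of the
## seqio / classifier / census functions with per-protein error isolation.

.resolveCatalog <- function(catalog) {
  if (is(catalog, "EpitopeCatalog")) return(catalog)
  if (is.character(catalog)) return(readEpitopeCatalog(catalog))
  stop("catalog must be an EpitopeCatalog or a file path")
}

.resolvePanel <- function(panel) {
  if (is.null(panel) || is(panel, "ReferencePanel")) return(panel)
  if (is.character(panel)) return(readReferencePanel(panel))
  stop("panel must be a ReferencePanel, a file path, or NULL")
}

#' Profile a FASTA of proteins into a census report
#'
#' Reads the sequences, runs [buildCensus()] and writes the census TSV.
#' Records whose sequence contains residues outside the accepted alphabet
#' are logged as failures and the rest of the batch proceeds.
#'
#' @param fasta path to the input FASTA.
#' @param out path for the census TSV.
#' @param catalog an [EpitopeCatalog-class] or path to a catalog TSV.
#' @param panel optional [ReferencePanel-class] or path to a panel FASTA.
#' @param config a [profilerConfig()] list.
#' @param quiet suppress progress messages.
#' @return the [GliadinCensus-class], invisibly; failures are available
#'   via [censusFailures()].
#' @export
runProfile <- function(fasta, out, catalog = defaultEpitopeCatalog(),
                       panel = NULL, config = profilerConfig(),
                       quiet = FALSE) {
  catalog <- .resolveCatalog(catalog)
  panel <- .resolvePanel(panel)
  raw <- .readFastaRaw(fasta)
  ok <- vapply(raw$seqs, function(s) nzchar(s) && .validAASequence(s),
               logical(1))
  preFail <- data.frame(
    protein_id = raw$ids[!ok],
    error = rep("sequence contains residues outside the accepted alphabet",
                sum(!ok)),
    stringsAsFactors = FALSE)
  mat <- vapply(raw$desc, .parseHeaderKey, character(1), key = "maturity")
  mat[is.na(mat) | !mat %in% .MATURITY_LEVELS] <- "unknown"
  proteins <- ProteinSet(setNames(raw$seqs[ok], raw$ids[ok]),
                         maturity = mat[ok],
                         description = raw$desc[ok])
  census <- buildCensus(proteins, catalog = catalog, panel = panel,
                        config = config)
  census@failures <- rbind(preFail, census@failures)
  writeCensusReport(census, out)
  if (!quiet) {
    message(sprintf("profiled %d/%d protein(s); census written to %s",
                    length(census), length(raw$ids), out))
    if (nrow(censusFailures(census)))
      message("failed: ",
              paste(censusFailures(census)$protein_id, collapse = ", "))
  }
  invisible(census)
}

#' Summarize a 2-DE spot table
#'
#' @param spots a [SpotTable-class] or path to a spot TSV.
#' @param out optional path for the summary TSV.
#' @return the [CompositionSummary-class], invisibly.
#' @export
runSummarize <- function(spots, out = NULL) {
  if (is.character(spots)) spots <- readSpotTable(spots)
  summary <- summarizeSpots(spots)
  if (!is.null(out)) writeCompositionSummary(summary, out)
  invisible(summary)
}

#' Assign genomes of origin for a FASTA of gliadins
#'
#' Matures and classifies each sequence, then applies the motif rule with
#' nearest-reference fallback against the panel.
#'
#' @param fasta path to the input FASTA.
#' @param panel a [ReferencePanel-class] or path to a panel FASTA.
#' @param out optional path for the genome-call TSV.
#' @param config a [profilerConfig()] list.
#' @return data.frame with columns protein_id, family, subtype, genome,
#'   method, best_reference, identity; invisibly when `out` is given.
#' @export
runAssign <- function(fasta, panel, out = NULL,
                      config = profilerConfig()) {
  panel <- .resolvePanel(panel)
  proteins <- suppressWarnings(
    matureProteins(readProteinFasta(fasta),
                   signatures = config$signatureSet,
                   maxOffset = config$maxSignatureOffset))
  seqs <- proteinSequences(proteins)
  rows <- lapply(seq_along(seqs), function(i) {
    cls <- classifyGliadin(seqs[[i]], config)
    gen <- tryCatch(
      assignGenome(seqs[[i]], cls$family, cls$subtype, panel, config),
      error = function(e) list(genome = "unknown", method = "none",
                               evidence = NA_character_))
    data.frame(protein_id = names(seqs)[i], family = cls$family,
               subtype = cls$subtype, genome = gen$genome,
               method = gen$method,
               best_reference = if (is.list(gen$evidence))
                 gen$evidence$best_reference_id else NA_character_,
               identity = if (is.list(gen$evidence))
                 gen$evidence$identity else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Generate a reproducible synthetic fixture set
#'
#' Writes a FASTA of synthetic gliadin precursors, a ground-truth TSV
#' (planted family, subtype, cysteines, chain-terminator flag, 33-mer
#' flag, per-epitope planted counts) and a synthetic spot table with its
#' exact summary. Rerunning with the same seed reproduces the files
#' byte-identically.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed.
#' @param nProteins number of synthetic proteins.
#' @param nSpots number of synthetic 2-DE spots.
#' @param quiet suppress progress messages.
#' @return invisible list of the written paths.
#' @export
runSimulate <- function(outDir, seed = 1L, nProteins = 10L, nSpots = 98L,
                        quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  catalog <- defaultEpitopeCatalog()
  sims <- lapply(seq_len(nProteins), function(i)
    generateProtein(sampleGliadinSpec(seed * 1000L + i), catalog))
  seqs <- unlist(lapply(sims, function(s) proteinSequences(s$protein)))
  proteins <- ProteinSet(seqs, maturity = "precursor")
  fastaPath <- file.path(outDir, "synthetic_proteins.fasta")
  writeProteinFasta(proteins, fastaPath)
  truthTab <- do.call(rbind, lapply(sims, function(s) {
    tr <- s$truth
    cbind(data.frame(protein_id = proteinIds(s$protein),
                     family = tr$family, subtype = tr$subtype,
                     cys_count = tr$cys_count,
                     chain_terminator = tr$chain_terminator,
                     has_33mer = tr$has_33mer,
                     genome_by_motif = tr$genome_by_motif,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(tr$epitope_counts),
                        check.names = FALSE))
  }))
  truthPath <- file.path(outDir, "synthetic_truth.tsv")
  write.table(truthTab, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  spotSim <- generateSpotTable(nSpots, seed = seed)
  spotPath <- file.path(outDir, "synthetic_spots.tsv")
  writeSpotTable(spotSim$spots, spotPath)
  sumPath <- file.path(outDir, "synthetic_spot_summary.tsv")
  writeCompositionSummary(spotSim$truth, sumPath)
  if (!quiet)
    message(sprintf("wrote %d synthetic proteins and %d spots to %s",
                    nProteins, nSpots, outDir))
  invisible(list(fasta = fastaPath, truth = truthPath, spots = spotPath,
                 summary = sumPath))
}
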