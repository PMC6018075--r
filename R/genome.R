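## Genome-of-origin assignment (A/B/D): diagnostic motif rules first, then
## nearest labeled reference under global-alignment percent identity. The
## nearest-reference step replaces tree building: the decision content of a
## labeled phylogeny is which labeled cluster a query is nearest to, which
## highest pairwise identity against the labeled panel reproduces.

.identityMatrix <- function(match = 1, mismatch = 0) {
  letters <- Biostrings::AA_ALPHABET
  m <- matrix(mismatch, nrow = length(letters), ncol = length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global-alignment percent identity between two sequences
#'
#' Needleman-Wunsch global alignment under identity scoring (match
#' `alignMatch`, mismatch `alignMismatch`, linear gap penalty `alignGap`
#' per gapped position), with identity = matches / alignment length x 100.
#'
#' @param seqA,seqB non-empty amino-acid sequences (character or
#'   `AAString`).
#' @param config a [profilerConfig()] list supplying the scoring
#'   parameters.
#' @return numeric percent identity in `[0, 100]`.
#' @examples
#' pairwiseIdentity("AAAA", "AAAA")  # 100
#' pairwiseIdentity("AAAA", "AATA")  # 75
#' @export
pairwiseIdentity <- function(seqA, seqB, config = profilerConfig()) {
  a <- .asSequence(seqA)
  b <- .asSequence(seqB)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- pairwiseAlignment(
    AAString(a), AAString(b), type = "global",
    substitutionMatrix = .identityMatrix(config$alignMatch,
                                         config$alignMismatch),
    gapOpening = 0, gapExtension = config$alignGap)
  alenStr <- as.character(alignedPattern(aln))
  nmatch(aln) / nchar(alenStr) * 100
}

#' Assign genome of origin by diagnostic motif
#'
#' Hard rules: omega-1,2 sequences starting ARE- are D-genome, those
#' starting ARQ- or KEL- are A-genome; omega-5 sequences starting SRL- or
#' GRL- are B-genome; alpha-gliadins containing the CSTT motif are
#' B-genome. Anything else is `unknown` (defer to the reference method).
#'
#' @param family gliadin family (`alpha`, `gamma`, `omega`, ...).
#' @param subtype omega subtype (`omega_1_2`, `omega_5` or `none`).
#' @param sequence mature amino-acid sequence.
#' @return list with `genome` (`A`/`B`/`D`/`unknown`), `method = "motif"`
#'   and `evidence` (the motif that fired, or NA).
#' @examples
#' assignGenomeByMotif("omega", "omega_1_2", "ARELNPSNK")$genome  # "D"
#' @export
assignGenomeByMotif <- function(family, subtype, sequence) {
  s <- .asSequence(sequence)
  genome <- "unknown"
  evidence <- NA_character_
  if (family == "omega" && subtype == "omega_1_2") {
    if (startsWith(s, "ARE")) { genome <- "D"; evidence <- "ARE-" }
    else if (startsWith(s, "ARQ")) { genome <- "A"; evidence <- "ARQ-" }
    else if (startsWith(s, "KEL")) { genome <- "A"; evidence <- "KEL-" }
  } else if (family == "omega" && subtype == "omega_5") {
    if (startsWith(s, "SRL")) { genome <- "B"; evidence <- "SRL-" }
    else if (startsWith(s, "GRL")) { genome <- "B"; evidence <- "GRL-" }
  } else if (family == "alpha") {
    if (countOccurrences(s, "CSTT")$count > 0) {
      genome <- "B"; evidence <- "CSTT"
    }
  }
  list(genome = genome, method = "motif", evidence = evidence)
}

#' Assign genome of origin by nearest labeled reference
#'
#' Computes [pairwiseIdentity()] of the query against every panel entry of
#' the same family and returns the genome of the best-matching reference.
#' If the top two references belong to different genomes and their
#' identities are within `tieMargin` identity points, the call is
#' `unknown`.
#'
#' @param sequence mature amino-acid query sequence.
#' @param family gliadin family of the query; the panel is filtered to it.
#' @param panel a [ReferencePanel-class].
#' @param config a [profilerConfig()] list (`tieMargin`, alignment scoring).
#' @return list with `genome`, `method = "reference"` and `evidence` (list:
#'   best_reference_id, identity, runner-up id/identity).
#' @export
assignGenomeByReference <- function(sequence, family, panel,
                                    config = profilerConfig()) {
  stopifnot(is(panel, "ReferencePanel"))
  s <- .asSequence(sequence)
  tab <- panelEntries(panel)
  tab <- tab[tab$family == family, , drop = FALSE]
  if (nrow(tab) == 0)
    stop("reference panel has no entries for family '", family, "'")
  ids <- vapply(tab$sequence, function(r) pairwiseIdentity(s, r, config),
                numeric(1))
  o <- order(-ids)
  best <- o[1]
  genome <- tab$genome[best]
  runner <- NA_integer_
  if (length(o) > 1) {
    other <- o[tab$genome[o] != genome]
    if (length(other)) {
      runner <- other[1]
      if (ids[best] - ids[runner] < config$tieMargin)
        genome <- "unknown"
    }
  }
  list(genome = genome, method = "reference",
       evidence = list(best_reference_id = tab$protein_id[best],
                       identity = unname(ids[best]),
                       runner_up_id = if (is.na(runner)) NA_character_
                                      else tab$protein_id[runner],
                       runner_up_identity = if (is.na(runner)) NA_real_
                                            else unname(ids[runner])))
}

#' Assign genome of origin (motif rule first, panel fallback)
#'
#' Applies [assignGenomeByMotif()] and, when that yields `unknown` and a
#' panel is supplied with entries for the query's family, falls back to
#' [assignGenomeByReference()].
#'
#' @inheritParams assignGenomeByReference
#' @param subtype omega subtype of the query.
#' @return list with `genome`, `method` (`motif`, `reference` or `none`)
#'   and `evidence`.
#' @export
assignGenome <- function(sequence, family, subtype = "none", panel = NULL,
                         config = profilerConfig()) {
  call <- assignGenomeByMotif(family, subtype, sequence)
  if (call$genome != "unknown") return(call)
  if (!is.null(panel) &&
      any(panelEntries(panel)$family == family))
    return(assignGenomeByReference(sequence, family, panel, config))
  list(genome = "unknown", method = "none", evidence = NA_character_)
}
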