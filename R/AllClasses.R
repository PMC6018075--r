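#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment nmatch alignedPattern AAString letterFrequency
#' @importFrom IRanges IRanges
#' @importFrom stats rgamma runif setNames
#' @importFrom utils read.delim write.table modifyList
NULL

## Amino-acid alphabet accepted throughout: the 20 canonical residues plus X
## (unknown). Anything else is a hard error.
.AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","X")

.MATURITY_LEVELS <- c("precursor", "mature", "unknown")
.SPOT_CATEGORIES <- c("alpha", "gamma", "omega", "lmw_gs", "non_gluten",
                      "unknown")
.FAMILY_LEVELS <- c("alpha", "gamma", "omega", "unclassified")
.SUBTYPE_LEVELS <- c("omega_1_2", "omega_5", "none")
.GENOMES <- c("A", "B", "D")

.validAASequence <- function(x) {
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% .AA_LETTERS)
}

#' ProteinSet: a collection of gliadin (or other) protein sequences
#'
#' Thin wrapper around an [Biostrings::AAStringSet] that additionally tracks
#' the maturity state of every entry (`precursor`, `mature` or `unknown`).
#' Sequences are uppercase and restricted to the 20 canonical amino acids
#' plus `X`; identifiers must be unique.
#'
#' @slot sequences An `AAStringSet`, named by protein identifier.
#' @slot maturity Character vector parallel to `sequences`.
#' @slot description Free-text header remainder, parallel to `sequences`.
#' @exportClass ProteinSet
setClass("ProteinSet",
  representation(sequences = "AAStringSet",
                 maturity = "character",
                 description = "character"))

setValidity("ProteinSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || anyNA(ids) || any(!nzchar(ids))))
    msgs <- c(msgs, "every sequence must be named by a protein id")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate protein ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@maturity) != n || length(object@description) != n)
    msgs <- c(msgs, "maturity and description must parallel sequences")
  if (!all(object@maturity %in% .MATURITY_LEVELS))
    msgs <- c(msgs, "maturity must be one of precursor/mature/unknown")
  if (n > 0) {
    seqs <- as.character(object@sequences)
    if (any(!nzchar(seqs)))
      msgs <- c(msgs, "empty sequences are not allowed")
    bad <- !vapply(seqs, .validAASequence, logical(1))
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "sequence(s) with non-canonical residues: %s",
        paste(ids[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' EpitopeCatalog: named CD/WDEIA epitope core sequences
#'
#' Each entry has a native core, an optional deamidated core (equal length,
#' differing from the native core only at Q positions, as Q->E), the disease
#' it is relevant for (`CD` or `WDEIA`), the gliadin family it derives from,
#' and a `verified` flag marking cores whose sequence is fixed by in-package
#' evidence (the 33-mer decomposition) rather than taken from the external
#' epitope nomenclature.
#'
#' @slot table data.frame with columns name, core_native, core_deamidated
#'   (NA when absent), disease, source_family, verified.
#' @exportClass EpitopeCatalog
setClass("EpitopeCatalog", representation(table = "data.frame"))

setValidity("EpitopeCatalog", function(object) {
  tab <- object@table
  need <- c("name", "core_native", "core_deamidated", "disease",
            "source_family", "verified")
  if (!all(need %in% names(tab)))
    return(sprintf("catalog table must have columns: %s",
                   paste(need, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(tab$name))
    msgs <- c(msgs, sprintf("duplicate epitope names: %s",
                            paste(unique(tab$name[duplicated(tab$name)]),
                                  collapse = ", ")))
  if (any(!nzchar(tab$core_native)) || anyNA(tab$core_native))
    msgs <- c(msgs, "core_native must be non-empty")
  if (!all(tab$disease %in% c("CD", "WDEIA")))
    msgs <- c(msgs, "disease must be CD or WDEIA")
  if (!all(tab$source_family %in% c("alpha", "gamma", "omega", "any")))
    msgs <- c(msgs, "source_family must be alpha/gamma/omega/any")
  for (i in seq_len(nrow(tab))) {
    nat <- tab$core_native[i]
    dea <- tab$core_deamidated[i]
    if (!.validAASequence(nat))
      msgs <- c(msgs, sprintf("%s: invalid residues in native core",
                              tab$name[i]))
    if (!is.na(dea) && nzchar(dea)) {
      if (nchar(dea) != nchar(nat)) {
        msgs <- c(msgs, sprintf(
          "%s: deamidated core length %d != native length %d",
          tab$name[i], nchar(dea), nchar(nat)))
      } else {
        a <- strsplit(nat, "")[[1]]
        b <- strsplit(dea, "")[[1]]
        diff <- which(a != b)
        if (length(diff) == 0L) {
          msgs <- c(msgs, sprintf(
            "%s: deamidated core identical to native core", tab$name[i]))
        } else if (!all(a[diff] == "Q" & b[diff] == "E")) {
          msgs <- c(msgs, sprintf(
            "%s: deamidated core differs from native at a non-Q position or not as Q->E",
            tab$name[i]))
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SpotTable: listings of 2-DE spots and their identified proteins
#'
#' One row per (spot, protein) listing. A spot may carry several listings,
#' but at most one of them may be non-minor (the predominant protein);
#' gel-image quantification assigns each spot a single normalized volume
#' (percent of total gel volume), so all listings of a spot share the same
#' `volume_norm`.
#'
#' @slot listings data.frame with columns spot_id, volume_norm, protein_id,
#'   category, minor_flag.
#' @exportClass SpotTable
setClass("SpotTable", representation(listings = "data.frame"))

setValidity("SpotTable", function(object) {
  tab <- object@listings
  need <- c("spot_id", "volume_norm", "protein_id", "category", "minor_flag")
  if (!all(need %in% names(tab)))
    return(sprintf("spot table must have columns: %s",
                   paste(need, collapse = ", ")))
  msgs <- character()
  if (any(tab$volume_norm < 0) || anyNA(tab$volume_norm))
    msgs <- c(msgs, "volume_norm must be >= 0 and non-missing")
  if (!all(tab$category %in% .SPOT_CATEGORIES))
    msgs <- c(msgs, sprintf(
      "unknown category label(s): %s",
      paste(setdiff(unique(tab$category), .SPOT_CATEGORIES), collapse = ", ")))
  if (!is.logical(tab$minor_flag) || anyNA(tab$minor_flag))
    msgs <- c(msgs, "minor_flag must be logical and non-missing")
  pred <- tab$spot_id[!tab$minor_flag]
  if (anyDuplicated(pred))
    msgs <- c(msgs, sprintf(
      "spot(s) with more than one non-minor (predominant) listing: %s",
      paste(unique(pred[duplicated(pred)]), collapse = ", ")))
  vol <- tapply(tab$volume_norm, tab$spot_id,
                function(v) diff(range(v)) > 1e-9)
  if (any(vol))
    msgs <- c(msgs, "listings of the same spot must share volume_norm")
  if (length(msgs)) msgs else TRUE
})

#' ReferencePanel: genome-labeled reference gliadin sequences
#'
#' @slot entries data.frame with columns protein_id, genome (A/B/D), family
#'   (alpha/gamma/omega) and sequence (mature amino-acid sequence).
#' @exportClass ReferencePanel
setClass("ReferencePanel", representation(entries = "data.frame"))

setValidity("ReferencePanel", function(object) {
  tab <- object@entries
  need <- c("protein_id", "genome", "family", "sequence")
  if (!all(need %in% names(tab)))
    return(sprintf("panel must have columns: %s", paste(need, collapse = ", ")))
  msgs <- character()
  if (!all(tab$genome %in% .GENOMES))
    msgs <- c(msgs, "genome labels must be A, B or D")
  if (!all(tab$family %in% c("alpha", "gamma", "omega")))
    msgs <- c(msgs, "family must be alpha/gamma/omega")
  if (anyDuplicated(tab$protein_id))
    msgs <- c(msgs, "duplicate reference ids")
  if (nrow(tab) > 0 && !all(vapply(tab$sequence, .validAASequence, logical(1))))
    msgs <- c(msgs, "invalid residues in reference sequence(s)")
  if (length(msgs)) msgs else TRUE
})

#' GliadinCensus: per-protein structural and epitope characterization
#'
#' The tabular part (one row per successfully profiled protein) mirrors the
#' census layout of proteomic gliadin surveys: family, subtype, genome call,
#' cysteine count, chain-terminator flag, 33-mer presence, and one count per
#' catalog epitope. Per-protein details (domain segmentation, motif counts,
#' individual epitope hits) are kept alongside; proteins that failed are
#' recorded with their error message.
#'
#' @slot table data.frame of per-protein summary fields.
#' @slot epitopeCounts integer matrix, proteins x catalog epitopes.
#' @slot details named list (by protein id) of lists with elements
#'   `segmentation`, `motifCounts`, `hits`.
#' @slot failures data.frame with columns protein_id, error.
#' @exportClass GliadinCensus
setClass("GliadinCensus",
  representation(table = "data.frame",
                 epitopeCounts = "matrix",
                 details = "list",
                 failures = "data.frame"))

setValidity("GliadinCensus", function(object) {
  msgs <- character()
  if (nrow(object@table) != nrow(object@epitopeCounts))
    msgs <- c(msgs, "epitopeCounts must have one row per census row")
  if (nrow(object@table) > 0) {
    if (!all(object@table$family %in% .FAMILY_LEVELS))
      msgs <- c(msgs, "invalid family value")
    if (!all(object@table$subtype %in% .SUBTYPE_LEVELS))
      msgs <- c(msgs, "invalid subtype value")
    bad <- object@table$subtype != "none" & object@table$family != "omega"
    if (any(bad))
      msgs <- c(msgs, "subtype may differ from none only for omega family")
    ct <- object@table$chain_terminator
    cys <- object@table$cys_count
    if (!all(ct == (cys %% 2L == 1L & cys > 0L)))
      msgs <- c(msgs, "chain_terminator must equal (cys_count odd and > 0)")
  }
  if (length(msgs)) msgs else TRUE
})

#' CompositionSummary: per-category spot counts and volume percentages
#'
#' Aggregation of a [SpotTable] in the shape of a gel-composition summary:
#' one row per protein category with the number of predominant spots and
#' the summed normalized volume (percent of total gel volume), plus totals.
#'
#' @slot rows data.frame with columns category, n_spots, volume_pct.
#' @slot totalSpots integer.
#' @slot totalPct numeric.
#' @exportClass CompositionSummary
setClass("CompositionSummary",
  representation(rows = "data.frame",
                 totalSpots = "integer",
                 totalPct = "numeric"))

setValidity("CompositionSummary", function(object) {
  tab <- object@rows
  msgs <- character()
  if (!all(c("category", "n_spots", "volume_pct") %in% names(tab)))
    return("rows must have columns category, n_spots, volume_pct")
  if (any(tab$volume_pct < 0))
    msgs <- c(msgs, "volume_pct must be >= 0")
  if (nrow(tab) > 0) {
    if (sum(tab$n_spots) != object@totalSpots)
      msgs <- c(msgs, "n_spots must sum to totalSpots")
    if (abs(sum(tab$volume_pct) - object@totalPct) > 1e-9)
      msgs <- c(msgs, "volume_pct must sum to totalPct")
  }
  if (length(msgs)) msgs else TRUE
})
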