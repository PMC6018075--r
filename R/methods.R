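## Accessors, constructors and show() methods for the core containers.

#' Construct a ProteinSet
#'
#' @param sequences named character vector or `AAStringSet` of amino-acid
#'   sequences (uppercased on input).
#' @param maturity character vector (recycled if length 1) with values
#'   `precursor`, `mature` or `unknown`.
#' @param description optional free-text descriptions.
#' @return a [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(p1 = "LQLQPFPQPQLPYPQ"), maturity = "mature")
#' proteinIds(ps)
#' @export
ProteinSet <- function(sequences = character(), maturity = "unknown",
                       description = NULL) {
  if (is(sequences, "AAStringSet")) {
    seqs <- toupper(as.character(sequences))
  } else {
    seqs <- toupper(as.character(sequences))
    names(seqs) <- names(sequences)
  }
  n <- length(seqs)
  maturity <- rep_len(as.character(maturity), n)
  if (is.null(description)) description <- rep_len("", n)
  description <- rep_len(as.character(description), n)
  new("ProteinSet", sequences = AAStringSet(seqs), maturity = maturity,
      description = description)
}

#' @rdname ProteinSet-class
#' @export
setMethod("proteinIds", "ProteinSet", function(x) names(x@sequences))

#' @rdname ProteinSet-class
#' @export
setMethod("proteinSequences", "ProteinSet",
          function(x) setNames(as.character(x@sequences), names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("maturity", "ProteinSet",
          function(x) setNames(x@maturity, names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet-class
#' @param i index (numeric, logical or protein id)
#' @param j,drop,... ignored
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ProteinSet", sequences = x@sequences[i], maturity = x@maturity[i],
      description = x@description[i])
})

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet with %d sequence(s)\n", length(object)))
  n <- min(length(object), 5L)
  for (i in seq_len(n)) {
    s <- as.character(object@sequences[[i]])
    cat(sprintf("  %s [%s, %d aa] %s%s\n", names(object@sequences)[i],
                object@maturity[i], nchar(s),
                substr(s, 1, 30), if (nchar(s) > 30) "..." else ""))
  }
  if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                      length(object) - n))
})

#' Construct an EpitopeCatalog
#'
#' @param table data.frame with columns name, core_native, core_deamidated,
#'   disease, source_family and optionally verified (default FALSE).
#' @return an [EpitopeCatalog-class] object.
#' @export
EpitopeCatalog <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$verified)) table$verified <- logical(nrow(table))
  if (is.null(table$core_deamidated))
    table$core_deamidated <- rep(NA_character_, nrow(table))
  table$core_deamidated[!is.na(table$core_deamidated) &
                        table$core_deamidated %in% c("", "-")] <- NA_character_
  table$core_native <- toupper(table$core_native)
  table$core_deamidated <- toupper(table$core_deamidated)
  rownames(table) <- NULL
  new("EpitopeCatalog", table = table)
}

#' @rdname EpitopeCatalog-class
#' @export
setMethod("catalogTable", "EpitopeCatalog", function(x) x@table)

#' @rdname EpitopeCatalog-class
#' @export
setMethod("epitopeNames", "EpitopeCatalog", function(x) x@table$name)

#' @rdname EpitopeCatalog-class
#' @export
setMethod("length", "EpitopeCatalog", function(x) nrow(x@table))

setMethod("show", "EpitopeCatalog", function(object) {
  tab <- object@table
  cat(sprintf("EpitopeCatalog with %d entries (%d CD, %d WDEIA; %d verified)\n",
              nrow(tab), sum(tab$disease == "CD"),
              sum(tab$disease == "WDEIA"), sum(tab$verified)))
})

#' Construct a SpotTable
#'
#' @param listings data.frame with columns spot_id, volume_norm, protein_id,
#'   category, minor_flag.
#' @return a [SpotTable-class] object.
#' @export
SpotTable <- function(listings) {
  listings <- as.data.frame(listings, stringsAsFactors = FALSE)
  listings$spot_id <- as.character(listings$spot_id)
  listings$protein_id <- as.character(listings$protein_id)
  listings$minor_flag <- as.logical(listings$minor_flag)
  rownames(listings) <- NULL
  new("SpotTable", listings = listings)
}

#' @rdname SpotTable-class
#' @export
setMethod("spotListings", "SpotTable", function(x) x@listings)

#' @rdname SpotTable-class
#' @export
setMethod("length", "SpotTable",
          function(x) length(unique(x@listings$spot_id)))

setMethod("show", "SpotTable", function(object) {
  tab <- object@listings
  cat(sprintf("SpotTable: %d listings over %d spots, total volume %.2f\n",
              nrow(tab), length(unique(tab$spot_id)),
              sum(tab$volume_norm[!duplicated(tab$spot_id)])))
})

#' Construct a ReferencePanel
#'
#' @param entries data.frame with columns protein_id, genome, family,
#'   sequence.
#' @return a [ReferencePanel-class] object.
#' @export
ReferencePanel <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$sequence <- toupper(entries$sequence)
  rownames(entries) <- NULL
  new("ReferencePanel", entries = entries)
}

#' @rdname ReferencePanel-class
#' @export
setMethod("panelEntries", "ReferencePanel", function(x) x@entries)

#' @rdname ReferencePanel-class
#' @export
setMethod("length", "ReferencePanel", function(x) nrow(x@entries))

setMethod("show", "ReferencePanel", function(object) {
  tab <- object@entries
  cat(sprintf("ReferencePanel: %d entries (%s)\n", nrow(tab),
              paste(sprintf("%s:%d", names(table(tab$genome)),
                            as.integer(table(tab$genome))), collapse = " ")))
})

#' @rdname GliadinCensus-class
#' @export
setMethod("censusTable", "GliadinCensus", function(x) {
  cbind(x@table, as.data.frame(x@epitopeCounts, check.names = FALSE))
})

#' @rdname GliadinCensus-class
#' @export
setMethod("epitopeCounts", "GliadinCensus", function(x) x@epitopeCounts)

#' @rdname GliadinCensus-class
#' @export
setMethod("censusFailures", "GliadinCensus", function(x) x@failures)

#' @rdname GliadinCensus-class
#' @export
setMethod("censusDetails", "GliadinCensus", function(x, id) {
  if (!id %in% names(x@details))
    stop("no census details for protein '", id, "'")
  x@details[[id]]
})

#' @rdname GliadinCensus-class
#' @export
setMethod("length", "GliadinCensus", function(x) nrow(x@table))

setMethod("show", "GliadinCensus", function(object) {
  tab <- object@table
  cat(sprintf("GliadinCensus: %d profiled, %d failed\n", nrow(tab),
              nrow(object@failures)))
  if (nrow(tab) > 0) {
    fam <- table(factor(tab$family, levels = .FAMILY_LEVELS))
    cat("  families: ",
        paste(sprintf("%s=%d", names(fam), as.integer(fam)), collapse = " "),
        "\n", sep = "")
    cat(sprintf("  chain terminators (odd Cys): %d; 33-mer carriers: %d\n",
                sum(tab$chain_terminator), sum(tab$has_33mer)))
  }
})

#' @rdname CompositionSummary-class
#' @export
setMethod("summaryRows", "CompositionSummary", function(x) x@rows)

setMethod("show", "CompositionSummary", function(object) {
  cat("CompositionSummary\n")
  tab <- object@rows
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-12s %4d spots  %7.2f%%\n", tab$category[i],
                tab$n_spots[i], tab$volume_pct[i]))
  cat(sprintf("  %-12s %4d spots  %7.2f%%\n", "total", object@totalSpots,
              object@totalPct))
})
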