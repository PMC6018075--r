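## Readers and writers for every external artifact: FASTA sequences and
## reference panels, the epitope catalog, 2-DE spot tables, and the census
## and composition-summary reports. FASTA goes through Biostrings; tables
## are plain TSV.

.parseHeaderKey <- function(description, key) {
  m <- regmatches(description,
                  regexpr(sprintf("\\b%s=[^[:space:]]+", key), description))
  if (length(m) && nzchar(m)) sub(sprintf("^%s=", key), "", m)
  else NA_character_
}

.readFastaRaw <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(readAAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  list(ids = ids, desc = desc, seqs = toupper(as.character(set)))
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; maturity is taken from an optional
#' `maturity=` key in the header (e.g. `>p1 maturity=mature ...`), and is
#' `unknown` otherwise. Duplicate ids and residues outside the 20 canonical
#' amino acids plus X are errors.
#'
#' @param path path to a FASTA file.
#' @return a [ProteinSet-class].
#' @export
readProteinFasta <- function(path) {
  raw <- .readFastaRaw(path)
  mat <- vapply(raw$desc, .parseHeaderKey, character(1), key = "maturity")
  mat[is.na(mat)] <- "unknown"
  if (!all(mat %in% .MATURITY_LEVELS))
    stop("invalid maturity value(s) in FASTA headers: ",
         paste(setdiff(unique(mat), .MATURITY_LEVELS), collapse = ", "))
  ProteinSet(setNames(raw$seqs, raw$ids), maturity = mat,
             description = raw$desc)
}

#' Write a ProteinSet to FASTA
#'
#' The maturity state is carried in the header as a `maturity=` key so the
#' file round-trips through [readProteinFasta()].
#'
#' @param x a [ProteinSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  stopifnot(is(x, "ProteinSet"))
  set <- x@sequences
  names(set) <- sprintf("%s maturity=%s", names(set), x@maturity)
  writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read an epitope catalog
#'
#' TSV with columns name, core_native, core_deamidated (empty or `-` when
#' absent), disease, source_family and optionally verified. Validated
#' against the catalog invariants (unique names; deamidated cores equal in
#' length to the native core and differing only as Q to E).
#'
#' @param path path to a TSV file.
#' @return an [EpitopeCatalog-class].
#' @seealso [defaultEpitopeCatalog()]
#' @export
readEpitopeCatalog <- function(path) {
  if (!file.exists(path)) stop("epitope catalog not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!is.null(tab$verified)) tab$verified <- as.logical(tab$verified)
  EpitopeCatalog(tab)
}

#' Write an epitope catalog
#' @param x an [EpitopeCatalog-class].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
writeEpitopeCatalog <- function(x, path) {
  stopifnot(is(x, "EpitopeCatalog"))
  tab <- catalogTable(x)
  tab$core_deamidated[is.na(tab$core_deamidated)] <- "-"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The shipped CD/WDEIA epitope catalog
#'
#' Default catalog of celiac-disease and WDEIA epitope cores for the
#' alpha-, gamma- and omega-gliadin families. The alpha1a and alpha2 cores
#' are fixed by their overlapping occurrence counts within the 33-mer
#' peptide, and WD-1/WD-2 are the dominant omega-5 WDEIA cores QQIPQQQ and
#' QQFPQQQ; these carry `verified = TRUE`. The remaining cores are
#' configuration taken from the published CD-epitope nomenclature and the
#' WDEIA literature and are flagged `verified = FALSE`; replace them via
#' [readEpitopeCatalog()] if a different catalog is preferred.
#'
#' @return an [EpitopeCatalog-class].
#' @examples
#' defaultEpitopeCatalog()
#' @export
defaultEpitopeCatalog <- function() {
  path <- system.file("extdata", "cd_wdeia_epitopes.tsv",
                      package = "gliadinCensus", mustWork = TRUE)
  readEpitopeCatalog(path)
}

#' Read a 2-DE spot table
#'
#' TSV with header spot_id, volume_norm, protein_id, category, minor_flag.
#' Volumes are decimal percentages of total gel volume (0-100 scale);
#' negative volumes and unknown category labels are errors.
#'
#' @param path path to a TSV file.
#' @return a [SpotTable-class].
#' @export
readSpotTable <- function(path) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(spot_id = "character",
                                   protein_id = "character"))
  need <- c("spot_id", "volume_norm", "protein_id", "category", "minor_flag")
  if (!all(need %in% names(tab)))
    stop("spot table must have columns: ", paste(need, collapse = ", "))
  tab$volume_norm <- as.numeric(tab$volume_norm)
  if (anyNA(tab$volume_norm)) stop("non-numeric volume_norm in ", path)
  tab$protein_id[is.na(tab$protein_id)] <- ""
  SpotTable(tab[need])
}

#' Write a 2-DE spot table
#' @param x a [SpotTable-class].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
writeSpotTable <- function(x, path) {
  stopifnot(is(x, "SpotTable"))
  write.table(spotListings(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a census report
#'
#' TSV mirroring the per-protein census layout of gliadin proteomic
#' surveys: protein_id, family, subtype, genome, genome_method, cys_count,
#' chain_terminator, has_33mer, followed by one integer column per catalog
#' epitope. Round-trips through [readCensusReport()].
#'
#' @param census a [GliadinCensus-class].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
writeCensusReport <- function(census, path) {
  stopifnot(is(census, "GliadinCensus"))
  write.table(censusTable(census), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read back a census report
#' @param path path to a TSV written by [writeCensusReport()].
#' @return data.frame in the layout of [censusTable()].
#' @export
readCensusReport <- function(path) {
  if (!file.exists(path)) stop("census report not found: ", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = c(protein_id = "character"))
}

#' Write a composition summary
#'
#' TSV in gel-summary layout (category, n_spots, volume_pct) with a final
#' `total` row; percentages are printed with 2 decimals.
#'
#' @param x a [CompositionSummary-class].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
writeCompositionSummary <- function(x, path) {
  stopifnot(is(x, "CompositionSummary"))
  tab <- summaryRows(x)
  out <- data.frame(category = c(tab$category, "total"),
                    n_spots = c(tab$n_spots, x@totalSpots),
                    volume_pct = sprintf("%.2f", c(tab$volume_pct,
                                                   x@totalPct)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a composition summary
#' @param path path to a TSV written by [writeCompositionSummary()].
#' @return a [CompositionSummary-class] (percentages at the written 2-decimal
#'   precision).
#' @export
readCompositionSummary <- function(path) {
  if (!file.exists(path)) stop("summary not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tot <- tab[tab$category == "total", , drop = FALSE]
  tab <- tab[tab$category != "total", , drop = FALSE]
  rownames(tab) <- NULL
  tab$volume_pct <- as.numeric(tab$volume_pct)
  new("CompositionSummary", rows = tab,
      totalSpots = as.integer(sum(tab$n_spots)),
      totalPct = sum(tab$volume_pct))
}

#' Read a genome-labeled reference panel from FASTA
#'
#' Headers must carry `genome=` (A, B or D) and `family=` (alpha, gamma or
#' omega) keys, e.g. `>ref1 genome=D family=alpha`. Sequences are taken as
#' mature.
#'
#' @param path path to a FASTA file.
#' @return a [ReferencePanel-class].
#' @export
readReferencePanel <- function(path) {
  raw <- .readFastaRaw(path)
  genome <- vapply(raw$desc, .parseHeaderKey, character(1), key = "genome")
  family <- vapply(raw$desc, .parseHeaderKey, character(1), key = "family")
  if (anyNA(genome) || anyNA(family))
    stop("reference panel headers must carry genome= and family= keys")
  ReferencePanel(data.frame(protein_id = raw$ids, genome = genome,
                            family = family, sequence = raw$seqs,
                            stringsAsFactors = FALSE))
}

#' Write a reference panel to FASTA
#' @param x a [ReferencePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReferencePanel <- function(x, path) {
  stopifnot(is(x, "ReferencePanel"))
  tab <- panelEntries(x)
  set <- AAStringSet(setNames(tab$sequence,
                              sprintf("%s genome=%s family=%s",
                                      tab$protein_id, tab$genome,
                                      tab$family)))
  writeXStringSet(set, filepath = path)
  invisible(path)
}

#' The shipped Keumkang 2-DE spot assignment table
#'
#' Spot/protein assignments (98 gel spots; predominant and minor listings)
#' transcribed from the published Keumkang gliadin survey. Per-spot
#' normalized volumes were not published individually, so the volumes in
#' this fixture are synthetic: the published per-category totals split
#' randomly (fixed seed) across each category's spots. Spot counts per
#' category and minor flags are faithful to the survey.
#'
#' @return a [SpotTable-class] with 98 distinct spots.
#' @export
keumkangSpotTable <- function() {
  path <- system.file("extdata", "keumkang_spots_synthetic_volumes.tsv",
                      package = "gliadinCensus", mustWork = TRUE)
  readSpotTable(path)
}
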