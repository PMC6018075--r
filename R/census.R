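## Census assembly (per-protein characterization table) and spot-table
## aggregation into composition summaries.

#' Build a per-protein gliadin census
#'
#' For each input protein: signal-peptide maturation, family/subtype
#' classification, domain segmentation, exhaustive epitope scan, cysteine
#' census with chain-terminator flag, 33-mer detection, and genome
#' assignment (motif rule, with nearest-reference fallback when a panel is
#' supplied). A protein that fails any step is recorded in the failure log
#' and the batch continues.
#'
#' @param proteins a [ProteinSet-class].
#' @param catalog an [EpitopeCatalog-class] (default: shipped catalog).
#' @param panel optional [ReferencePanel-class] for reference-based genome
#'   calls.
#' @param config a [profilerConfig()] list.
#' @return a [GliadinCensus-class].
#' @examples
#' sim <- generateProtein(gliadinSpec("alpha", include33mer = TRUE, seed = 1))
#' censusTable(buildCensus(sim$protein))
#' @export
buildCensus <- function(proteins, catalog = defaultEpitopeCatalog(),
                        panel = NULL, config = profilerConfig()) {
  stopifnot(is(proteins, "ProteinSet"), is(catalog, "EpitopeCatalog"))
  epi <- epitopeNames(catalog)
  rows <- vector("list", length(proteins))
  counts <- matrix(0L, nrow = length(proteins), ncol = length(epi),
                   dimnames = list(proteinIds(proteins), epi))
  details <- list()
  failures <- data.frame(protein_id = character(), error = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(length(proteins))) {
    pid <- proteinIds(proteins)[i]
    res <- tryCatch({
      p <- suppressWarnings(
        matureProteins(proteins[i], signatures = config$signatureSet,
                       maxOffset = config$maxSignatureOffset))
      s <- proteinSequences(p)[[1]]
      cls <- classifyGliadin(s, config)
      seg <- if (cls$family %in% c("alpha", "gamma", "omega"))
        segmentDomains(s, cls$family, config, catalog) else NULL
      hits <- scanEpitopes(s, catalog,
                           deamidationMode = config$deamidationMode,
                           id = pid)
      cnt <- table(factor(hits$epitope_name, levels = epi))
      cys <- cls$evidence$cys_count
      gen <- if (cls$family %in% c("alpha", "gamma", "omega"))
        assignGenome(s, cls$family, cls$subtype, panel, config)
      else list(genome = "unknown", method = "none",
                evidence = NA_character_)
      motifs <- unique(c(config$omegaMotifs, config$alphaMotifs))
      mc <- data.frame(
        motif = c(motifs, "gamma_repeat"),
        count = c(vapply(motifs,
                         function(m) countOccurrences(s, m)$count,
                         integer(1)),
                  countGammaRepeat(s)$count),
        stringsAsFactors = FALSE)
      list(row = data.frame(
             protein_id = pid, family = cls$family, subtype = cls$subtype,
             genome = gen$genome, genome_method = gen$method,
             cys_count = cys,
             chain_terminator = flagChainTerminator(cys),
             has_33mer = cls$evidence$has_33mer,
             nterm_signature = cls$evidence$nterm,
             mature_length = nchar(s),
             stringsAsFactors = FALSE),
           counts = as.integer(cnt),
           detail = list(sequence = s, segmentation = seg,
                         motifCounts = mc, hits = hits,
                         classification = cls, genome = gen))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(protein_id = pid,
                                   error = conditionMessage(res),
                                   stringsAsFactors = FALSE))
    } else {
      rows[[i]] <- res$row
      counts[pid, ] <- res$counts
      details[[pid]] <- res$detail
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  tab <- if (any(ok)) do.call(rbind, rows[ok])
  else data.frame(protein_id = character(), family = character(),
                  subtype = character(), genome = character(),
                  genome_method = character(), cys_count = integer(),
                  chain_terminator = logical(), has_33mer = logical(),
                  nterm_signature = character(), mature_length = integer(),
                  stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("GliadinCensus", table = tab,
      epitopeCounts = counts[ok, , drop = FALSE],
      details = details, failures = failures)
}

## Collapse a SpotTable to one row per distinct spot: the category of the
## non-minor (predominant) listing, or "unknown" when every listing is
## minor; the spot's single volume.
.distinctSpots <- function(spots) {
  tab <- spotListings(spots)
  ids <- unique(tab$spot_id)
  cat <- vapply(ids, function(id) {
    sub <- tab[tab$spot_id == id, , drop = FALSE]
    pred <- sub[!sub$minor_flag, , drop = FALSE]
    if (nrow(pred)) pred$category[1] else "unknown"
  }, character(1))
  prot <- vapply(ids, function(id) {
    sub <- tab[tab$spot_id == id & !tab$minor_flag, , drop = FALSE]
    if (nrow(sub)) sub$protein_id[1] else ""
  }, character(1))
  vol <- tab$volume_norm[match(ids, tab$spot_id)]
  data.frame(spot_id = ids, volume_norm = vol, protein_id = prot,
             category = cat, stringsAsFactors = FALSE)
}

#' Summarize a spot table into a gel-composition summary
#'
#' Groups distinct spots by category (a spot's category is that of its
#' predominant, i.e. non-minor, protein listing; spots with only minor
#' listings count as `unknown`), counting spots and summing normalized
#' volumes, with a total row. Volume is conserved exactly.
#'
#' @param spots a [SpotTable-class].
#' @return a [CompositionSummary-class].
#' @export
summarizeSpots <- function(spots) {
  stopifnot(is(spots, "SpotTable"))
  d <- .distinctSpots(spots)
  cats <- .SPOT_CATEGORIES[.SPOT_CATEGORIES %in% d$category]
  rows <- data.frame(
    category = cats,
    n_spots = vapply(cats, function(cc) sum(d$category == cc), integer(1)),
    volume_pct = vapply(cats, function(cc)
      sum(d$volume_norm[d$category == cc]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  new("CompositionSummary", rows = rows,
      totalSpots = as.integer(nrow(d)), totalPct = sum(rows$volume_pct))
}

#' Count spots whose predominant protein belongs to a category
#'
#' Minor-component listings (marked with an asterisk in published spot
#' tables) are excluded: only the distinct spots in which a protein of the
#' category is the predominant identification are counted.
#'
#' @param spots a [SpotTable-class].
#' @param category one of alpha, gamma, omega, lmw_gs, non_gluten, unknown.
#' @return integer spot count.
#' @examples
#' countPredominantSpots(keumkangSpotTable(), "alpha")  # 31
#' @export
countPredominantSpots <- function(spots, category) {
  stopifnot(is(spots, "SpotTable"),
            category %in% .SPOT_CATEGORIES)
  tab <- spotListings(spots)
  length(unique(tab$spot_id[!tab$minor_flag & tab$category == category]))
}

#' Per-genome volume shares within a gliadin family
#'
#' Sums the normalized volumes of the distinct spots whose predominant
#' protein is profiled in `census` (optionally restricted to one family),
#' grouped by the census genome call; proteins without a genome call
#' accumulate under `unknown`. Minor listings are excluded.
#'
#' @param spots a [SpotTable-class].
#' @param census a [GliadinCensus-class] providing genome calls per
#'   protein id.
#' @param family optional family filter (`alpha`, `gamma`, `omega`).
#' @return named numeric vector over A, B, D, unknown.
#' @export
genomeShare <- function(spots, census, family = NULL) {
  stopifnot(is(spots, "SpotTable"), is(census, "GliadinCensus"))
  d <- .distinctSpots(spots)
  ct <- census@table
  d <- d[d$protein_id %in% ct$protein_id, , drop = FALSE]
  idx <- match(d$protein_id, ct$protein_id)
  d$genome <- ct$genome[idx]
  d$family <- ct$family[idx]
  if (!is.null(family)) d <- d[d$family == family, , drop = FALSE]
  out <- setNames(numeric(4), c(.GENOMES, "unknown"))
  for (g in names(out)) out[g] <- sum(d$volume_norm[d$genome == g])
  out
}
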