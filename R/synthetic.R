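## Seeded generators of gliadin-like proteins and 2-DE spot tables with
## exactly known ground truth. The generator's guarantee is that every
## planted quantity is recovered verbatim by the census: repeat units,
## planted epitope copies and polyglutamine runs are joined by short
## spacers drawn from residues that cannot extend any Q/P-rich motif, so
## planted counts equal scanned counts.

## Spacer alphabet: no 3 consecutive positions of any catalog core or
## repeat unit lie within this set, so a full spacer can never complete a
## spurious match.
.SPACER_ALPHABET <- c("A", "S", "T", "N", "G", "V")

## Cysteine-free signal-peptide template shared by all synthetic
## precursors, so precursor and mature cysteine counts agree (as for real
## gliadin signal peptides). Contains no mature-start signature.
.SIGNAL_PEPTIDE <- "MKTFLILALLAIVATTA"

## Repeat units the generator may use, per family/subtype.
.FAMILY_UNITS <- list(
  alpha = c("PQPQLPY", "PFPQPQ"),
  gamma = c("PFPQPQQ"),
  omega_1_2 = c("PQQPFP"),
  omega_5 = c("FPQQQ", "QQIPQQ"))

## Epitope content of the literal 33-mer (overlapping occurrences),
## verified by hand against the printed peptide: one alpha1a copy, two
## alpha1b copies, three alpha2 copies.
.MER33_CONTENT <- c("DQ2.5-glia-alpha1a" = 1L,
                    "DQ2.5-glia-alpha1b" = 2L,
                    "DQ2.5-glia-alpha2" = 3L)

.DEFAULT_SIGNATURES <- c(alpha = "VRVPVPQ", gamma = "NMQVDPS",
                         omega_1_2 = "AREL", omega_5 = "SRLL")

## Evaluate expr under a private RNG stream seeded by `seed`, restoring
## the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    saved <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", saved, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic gliadin
#'
#' Describes the architecture of one synthetic protein: family (and omega
#' subtype), number of repeat units per motif, planted epitope copies,
#' cysteine count, polyglutamine run lengths, whether the 33-mer is
#' embedded, the mature N-terminal signature and the seed. Family defaults
#' reflect typical gliadin architecture: alpha with two polyglutamine
#' domains and 6 cysteines; gamma with one polyglutamine domain and 8
#' cysteines; omega with essentially no cysteines and a repeat-dominated
#' body (omega-1,2: PQQPFP; omega-5: FPQQQ + QQIPQQ).
#'
#' @param family `"alpha"`, `"gamma"` or `"omega"`.
#' @param subtype for omega only: `"omega_1_2"` or `"omega_5"`.
#' @param nRepeatUnits named integer vector of repeat units per motif;
#'   motifs must be admissible for the family (alpha: PQPQLPY, PFPQPQ;
#'   gamma: PFPQPQQ; omega-1,2: PQQPFP; omega-5: FPQQQ, QQIPQQ).
#' @param plantedEpitopes named integer vector of copies per catalog
#'   epitope name.
#' @param cysCount number of cysteines placed in the non-repetitive
#'   domains.
#' @param polyQLengths lengths of the planted polyglutamine runs.
#' @param include33mer embed one literal 33-mer (alpha only); its epitope
#'   content (1x alpha1a, 2x alpha1b, 3x alpha2) is added to the ground
#'   truth.
#' @param signature mature N-terminal signature string.
#' @param id protein identifier; default derived from family and seed.
#' @param seed integer seed; the same spec is byte-identical across calls.
#' @return a list of class `gliadinSpec`.
#' @examples
#' gliadinSpec("omega", subtype = "omega_5",
#'             nRepeatUnits = c(FPQQQ = 28, QQIPQQ = 10), cysCount = 0)
#' @export
gliadinSpec <- function(family = c("alpha", "gamma", "omega"),
                        subtype = NULL, nRepeatUnits = NULL,
                        plantedEpitopes = NULL, cysCount = NULL,
                        polyQLengths = NULL, include33mer = FALSE,
                        signature = NULL, id = NULL, seed = 1L) {
  family <- match.arg(family)
  if (family == "omega") {
    if (is.null(subtype)) subtype <- "omega_1_2"
    if (!subtype %in% c("omega_1_2", "omega_5"))
      stop("omega subtype must be omega_1_2 or omega_5")
  } else {
    if (!is.null(subtype) && subtype != "none")
      stop("subtype is only meaningful for omega specs")
    subtype <- "none"
  }
  key <- if (family == "omega") subtype else family
  if (is.null(nRepeatUnits)) {
    nRepeatUnits <- switch(key,
      alpha = c(PQPQLPY = 10L, PFPQPQ = 6L),
      gamma = c(PFPQPQQ = 12L),
      omega_1_2 = c(PQQPFP = 15L),
      omega_5 = c(FPQQQ = 28L, QQIPQQ = 10L))
  }
  allowed <- .FAMILY_UNITS[[key]]
  if (is.null(names(nRepeatUnits)) ||
      !all(names(nRepeatUnits) %in% allowed))
    stop("inadmissible repeat unit(s) for ", key, " spec: ",
         paste(setdiff(names(nRepeatUnits), allowed), collapse = ", "))
  if (any(nRepeatUnits < 0)) stop("repeat unit counts must be >= 0")
  if (is.null(plantedEpitopes)) plantedEpitopes <- integer(0)
  if (length(plantedEpitopes) &&
      (is.null(names(plantedEpitopes)) || any(plantedEpitopes < 0)))
    stop("plantedEpitopes must be a named vector of counts >= 0")
  if (is.null(cysCount))
    cysCount <- switch(key, alpha = 6L, gamma = 8L, 0L)
  if (cysCount < 0) stop("cysCount must be >= 0")
  if (include33mer && family != "alpha")
    stop("the 33-mer can only be embedded in an alpha spec")
  if (is.null(polyQLengths))
    polyQLengths <- switch(key, alpha = c(14L, 9L), gamma = 12L,
                           integer(0))
  if (is.null(signature)) signature <- .DEFAULT_SIGNATURES[[key]]
  if (is.null(id)) id <- sprintf("syn-%s-%d", key, as.integer(seed))
  structure(list(family = family, subtype = subtype,
                 nRepeatUnits = nRepeatUnits,
                 plantedEpitopes = plantedEpitopes,
                 cysCount = as.integer(cysCount),
                 polyQLengths = as.integer(polyQLengths),
                 include33mer = include33mer, signature = signature,
                 id = id, seed = as.integer(seed)),
            class = "gliadinSpec")
}

.randomSpacer <- function(len = 3L) {
  paste(sample(.SPACER_ALPHABET, len, replace = TRUE), collapse = "")
}

.nonRepetitiveBlock <- function(len, nCys) {
  res <- sample(.SPACER_ALPHABET, len, replace = TRUE)
  if (nCys > 0) {
    pos <- sample.int(len, nCys)
    res[pos] <- "C"
  }
  paste(res, collapse = "")
}

#' Generate one synthetic gliadin precursor with ground truth
#'
#' Assembles signal peptide + mature N-terminal signature + a repetitive
#' block (repeat units and planted epitope copies in seeded random order,
#' joined by 3-residue spacers) + polyglutamine runs + non-repetitive
#' blocks carrying exactly the requested cysteines. Deterministic under
#' the spec's seed.
#'
#' @param spec a [gliadinSpec()].
#' @param catalog the [EpitopeCatalog-class] providing planted cores
#'   (default: shipped catalog).
#' @return list with `protein` (a one-entry [ProteinSet-class], maturity
#'   `precursor`) and `truth`, a list recording the planted family,
#'   subtype, cysteine count, chain-terminator flag, epitope counts
#'   (incl. the 33-mer's content), repeat-unit counts, polyglutamine run
#'   count, 33-mer flag, mature start offset and mature sequence.
#' @examples
#' sim <- generateProtein(gliadinSpec("alpha", seed = 7))
#' sim$truth$cys_count
#' @export
generateProtein <- function(spec, catalog = defaultEpitopeCatalog()) {
  stopifnot(inherits(spec, "gliadinSpec"))
  tab <- catalogTable(catalog)
  if (length(spec$plantedEpitopes)) {
    missing <- setdiff(names(spec$plantedEpitopes), tab$name)
    if (length(missing))
      stop("planted epitope(s) not in catalog: ",
           paste(missing, collapse = ", "))
  }
  .withSeed(spec$seed, {
    ## repetitive block: units + planted epitopes, epitopes kept interior
    units <- rep(names(spec$nRepeatUnits), times = spec$nRepeatUnits)
    epis <- rep(names(spec$plantedEpitopes),
                times = spec$plantedEpitopes)
    pieces <- sample(units)
    inserts <- c(epis, if (spec$include33mer) ".33mer")
    if (length(inserts)) {
      if (length(pieces) < 2)
        stop("spec needs at least 2 repeat units to host planted inserts")
      at <- sort(sample(seq_len(length(pieces) - 1L), length(inserts),
                        replace = TRUE))
      out <- character(0)
      for (i in seq_along(pieces)) {
        out <- c(out, pieces[i])
        here <- inserts[at == i]
        out <- c(out, here)
      }
      pieces <- out
    }
    literal <- vapply(pieces, function(p) {
      if (p == ".33mer") GLIADIN_33MER
      else if (p %in% tab$name) tab$core_native[match(p, tab$name)]
      else p
    }, character(1))
    repBlock <- if (length(literal) == 0L) "" else {
      sp <- vapply(seq_len(length(literal) - 1L),
                   function(i) .randomSpacer(), character(1))
      paste0(paste0(literal[-length(literal)], sp, collapse = ""),
             literal[length(literal)])
    }
    ## polyglutamine + non-repetitive architecture per family
    polyQ <- vapply(spec$polyQLengths,
                    function(l) strrep("Q", l), character(1))
    nBlocks <- if (spec$family == "omega") 1L else 2L
    cysSplit <- if (nBlocks == 2L) {
      k <- sample.int(spec$cysCount + 1L, 1L) - 1L
      c(k, spec$cysCount - k)
    } else spec$cysCount
    nonrep <- vapply(seq_len(nBlocks), function(i)
      .nonRepetitiveBlock(sample(15:25, 1L), cysSplit[i]), character(1))
    blocks <- switch(spec$family,
      alpha = c(spec$signature, repBlock,
                if (length(polyQ) >= 1) polyQ[1], nonrep[1],
                if (length(polyQ) >= 2) polyQ[2], nonrep[2],
                if (length(polyQ) > 2) polyQ[-(1:2)]),
      gamma = c(spec$signature, repBlock, nonrep[1], polyQ, nonrep[2]),
      omega = c(spec$signature, repBlock, polyQ, nonrep[1]))
    blocks <- blocks[nzchar(blocks)]
    spBlk <- vapply(seq_len(length(blocks) - 1L),
                    function(i) .randomSpacer(), character(1))
    matureSeq <- paste0(paste0(blocks[-length(blocks)], spBlk,
                               collapse = ""),
                        blocks[length(blocks)])
    precursor <- paste0(.SIGNAL_PEPTIDE, matureSeq)
    ## ground truth epitope counts: planted copies + the 33-mer's content
    epiCounts <- setNames(rep(0L, nrow(tab)), tab$name)
    if (length(spec$plantedEpitopes))
      epiCounts[names(spec$plantedEpitopes)] <-
        epiCounts[names(spec$plantedEpitopes)] + spec$plantedEpitopes
    if (spec$include33mer)
      epiCounts[names(.MER33_CONTENT)] <-
        epiCounts[names(.MER33_CONTENT)] + .MER33_CONTENT
    truth <- list(
      family = spec$family, subtype = spec$subtype,
      cys_count = spec$cysCount,
      chain_terminator = unname(flagChainTerminator(spec$cysCount)),
      epitope_counts = epiCounts,
      unit_counts = spec$nRepeatUnits,
      n_polyq = length(spec$polyQLengths),
      has_33mer = spec$include33mer,
      mature_start = nchar(.SIGNAL_PEPTIDE) + 1L,
      mature_sequence = matureSeq,
      genome_by_motif = assignGenomeByMotif(spec$family, spec$subtype,
                                            matureSeq)$genome,
      seed = spec$seed)
    list(protein = ProteinSet(setNames(precursor, spec$id),
                              maturity = "precursor"),
         truth = truth)
  })
}

#' Sample a random but internally consistent gliadin spec
#'
#' Draws a family (or uses the given one) and realistic parameter ranges:
#' alpha with 5-7 cysteines, gamma with 7-9, omega with 0-1; repeat-unit
#' numbers and planted epitope copies in the ranges seen across gliadin
#' families. Used for randomized round-trip validation.
#'
#' @param seed integer seed.
#' @param family optional fixed family.
#' @return a [gliadinSpec()].
#' @export
sampleGliadinSpec <- function(seed, family = NULL) {
  .withSeed(seed, {
    if (is.null(family))
      family <- sample(c("alpha", "gamma", "omega"), 1L)
    subtype <- NULL
    if (family == "omega")
      subtype <- sample(c("omega_1_2", "omega_5"), 1L)
    key <- if (family == "omega") subtype else family
    units <- switch(key,
      alpha = c(PQPQLPY = sample(8:14, 1L), PFPQPQ = sample(4:8, 1L)),
      gamma = c(PFPQPQQ = sample(8:18, 1L)),
      omega_1_2 = c(PQQPFP = sample(12:20, 1L)),
      omega_5 = c(FPQQQ = sample(20:30, 1L), QQIPQQ = sample(8:12, 1L)))
    cys <- switch(key, alpha = sample(5:7, 1L), gamma = sample(7:9, 1L),
                  sample(0:1, 1L))
    pool <- switch(key,
      alpha = c("DQ2.5-glia-alpha1a", "DQ2.5-glia-alpha2",
                "DQ2.5-glia-alpha3", "DQ8-glia-alpha1"),
      gamma = c("DQ2.5-glia-gamma1", "DQ2.5-glia-gamma2",
                "DQ2.5-glia-gamma4c", "DQ2.5-glia-gamma5"),
      omega_1_2 = c("DQ2.5-glia-omega1", "DQ2.5-glia-omega2",
                    "DQ2.5-glia-gamma4c", "DQ2.5-glia-gamma5"),
      omega_5 = c("WD-1", "WD-2", "WD-3", "WD-4"))
    chosen <- pool[runif(length(pool)) < 0.6]
    planted <- if (length(chosen))
      setNames(sample(1:3, length(chosen), replace = TRUE), chosen)
    else NULL
    include33 <- family == "alpha" && runif(1) < 0.3
    gliadinSpec(family = family, subtype = subtype,
                nRepeatUnits = units, plantedEpitopes = planted,
                cysCount = cys, include33mer = include33, seed = seed)
  })
}

#' Generate a synthetic 2-DE spot table with ground truth
#'
#' Categories are sampled by weight; volumes are Dirichlet-style (gamma
#' variates normalized to a 100% total). Ground truth is the exact
#' per-category group sum.
#'
#' @param nSpots number of spots (> 0).
#' @param categoryWeights named non-negative weights over the spot
#'   categories; default approximates the composition of a wheat gliadin
#'   2-DE gel (about a third alpha spots, a third gamma, some LMW-GS,
#'   non-gluten and unidentified, a rare omega spot).
#' @param seed integer seed.
#' @return list with `spots` (a [SpotTable-class]) and `truth` (a
#'   [CompositionSummary-class] with the exact group sums).
#' @examples
#' sim <- generateSpotTable(98, seed = 1)
#' summarizeSpots(sim$spots)
#' @export
generateSpotTable <- function(nSpots,
                              categoryWeights = c(alpha = 31, gamma = 28,
                                                  omega = 1, lmw_gs = 11,
                                                  non_gluten = 7,
                                                  unknown = 20),
                              seed = 1L) {
  if (nSpots <= 0) stop("nSpots must be > 0")
  if (is.null(names(categoryWeights)) ||
      !all(names(categoryWeights) %in% .SPOT_CATEGORIES))
    stop("categoryWeights must be named by spot categories")
  if (any(categoryWeights < 0) || sum(categoryWeights) <= 0)
    stop("categoryWeights must be non-negative with a positive sum")
  .withSeed(seed, {
    cats <- sample(names(categoryWeights), nSpots, replace = TRUE,
                   prob = categoryWeights)
    vols <- rgamma(nSpots, shape = 2)
    vols <- vols / sum(vols) * 100
    tab <- data.frame(
      spot_id = sprintf("S%03d", seq_len(nSpots)),
      volume_norm = vols,
      protein_id = sprintf("P%03d", seq_len(nSpots)),
      category = cats, minor_flag = FALSE, stringsAsFactors = FALSE)
    present <- .SPOT_CATEGORIES[.SPOT_CATEGORIES %in% cats]
    rows <- data.frame(
      category = present,
      n_spots = vapply(present, function(cc) sum(cats == cc), integer(1)),
      volume_pct = vapply(present, function(cc) sum(vols[cats == cc]),
                          numeric(1)),
      stringsAsFactors = FALSE)
    rownames(rows) <- NULL
    truth <- new("CompositionSummary", rows = rows,
                 totalSpots = as.integer(nSpots),
                 totalPct = sum(rows$volume_pct))
    list(spots = SpotTable(tab), truth = truth)
  })
}
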