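## Per-protein structural characterization: maturation, family/subtype
## classification, cysteine census, chain-terminator flagging and domain
## segmentation.

#' Trim precursors to the mature sequence by N-terminal signature
#'
#' Records already marked `mature` are returned unchanged. For the rest,
#' the earliest occurrence of any configured mature-start signature within
#' the first `maxSignatureOffset` residues marks the mature start and
#' everything before it (the signal peptide) is removed. If no signature is
#' found the record is returned unchanged with maturity `unknown` and a
#' warning.
#'
#' @param x a [ProteinSet-class].
#' @param signatures character vector of mature-start signatures; default
#'   from [profilerConfig()].
#' @param maxOffset search window from the N-terminus, in residues.
#' @return a [ProteinSet-class] with trimmed sequences and updated maturity.
#' @examples
#' p <- ProteinSet(c(w = "MKTFLILALLAIVATTAARQLNPSNKELQSP"),
#'                 maturity = "precursor")
#' proteinSequences(matureProteins(p))  # starts "ARQL"
#' @export
matureProteins <- function(x, signatures = profilerConfig()$signatureSet,
                           maxOffset = profilerConfig()$maxSignatureOffset) {
  stopifnot(is(x, "ProteinSet"))
  seqs <- proteinSequences(x)
  mat <- maturity(x)
  notFound <- character(0)
  for (i in seq_along(seqs)) {
    if (mat[i] == "mature") next
    window <- substr(seqs[i], 1L, maxOffset + max(nchar(signatures)) - 1L)
    starts <- vapply(signatures,
                     function(sg) {
                       s <- .motifStarts(window, sg)
                       s <- s[s <= maxOffset]
                       if (length(s)) s[1] else NA_integer_
                     }, integer(1))
    if (all(is.na(starts))) {
      mat[i] <- "unknown"
      notFound <- c(notFound, names(seqs)[i])
    } else {
      cut <- min(starts, na.rm = TRUE)
      seqs[i] <- substr(seqs[i], cut, nchar(seqs[i]))
      mat[i] <- "mature"
    }
  }
  if (length(notFound))
    warning("no mature-start signature found for: ",
            paste(notFound, collapse = ", "))
  ProteinSet(seqs, maturity = mat, description = x@description)
}

#' Count cysteine residues
#'
#' @param sequence amino-acid sequence (character or `AAString`).
#' @return integer count of C residues.
#' @examples
#' countCysteines("CACAC")  # 3
#' @export
countCysteines <- function(sequence) {
  countOccurrences(sequence, "C")$count
}

#' Flag glutenin chain terminators by cysteine parity
#'
#' A gliadin with an odd number of cysteines carries one unpaired cysteine
#' that can form a single intermolecular disulfide bond, linking the protein
#' into the glutenin polymer where it caps (terminates) polymer growth. Even
#' counts (including zero) pair up intramolecularly.
#'
#' @param cysCount non-negative integer vector.
#' @return logical vector: TRUE iff the count is odd and positive.
#' @examples
#' flagChainTerminator(c(0, 1, 6, 7, 8))  # FALSE TRUE FALSE TRUE FALSE
#' @export
flagChainTerminator <- function(cysCount) {
  stopifnot(all(cysCount >= 0))
  cysCount %% 2 == 1 & cysCount > 0
}

#' Classify a mature gliadin sequence into family and subtype
#'
#' Deterministic rule cascade over repeat-motif content and cysteine count:
#' \enumerate{
#'   \item omega: at most `omegaMaxCys` cysteines and at least
#'     `omegaDensityThreshold` of the sequence covered by omega repeat
#'     motifs. The omega subtype follows the dominant repeat content --
#'     omega-5 when FPQQQ + QQIPQQ copies outnumber PQQPFP copies, else
#'     omega-1,2 -- rather than the N-terminal signature, because SRLL-
#'     starting sequences dominated by the PQQPFP repeat are omega-1,2.
#'   \item gamma: at least `gammaMinRepeats` degenerate gamma repeats and a
#'     cysteine count of 8 +/- `cysTol`.
#'   \item alpha: alpha repeat content (the 33-mer, or at least
#'     `alphaMinRepeats` alpha repeat motifs) or an alpha mature-start
#'     signature, and a cysteine count of 6 +/- `cysTol`.
#'   \item otherwise unclassified (subtype `none`). LMW-GS and non-gluten
#'     sequences land here by design.
#' }
#'
#' @param sequence mature amino-acid sequence (character or `AAString`).
#' @param config a [profilerConfig()] list.
#' @return list with elements `family`, `subtype` and `evidence` (named
#'   list: cys_count, omega_density, gamma_repeats, alpha_repeats,
#'   omega5_motifs, omega12_motifs, has_33mer, nterm).
#' @export
classifyGliadin <- function(sequence, config = profilerConfig()) {
  s <- .asSequence(sequence)
  cys <- countCysteines(s)
  omegaCov <- mean(.motifCoverage(s, config$omegaMotifs))
  gammaN <- countGammaRepeat(s)$count
  alphaN <- sum(vapply(config$alphaMotifs,
                       function(m) countOccurrences(s, m)$count, integer(1)))
  has33 <- length(detect33mer(s)) > 0
  n5 <- countOccurrences(s, "FPQQQ")$count + countOccurrences(s, "QQIPQQ")$count
  n12 <- countOccurrences(s, "PQQPFP")$count
  nterm <- substr(s, 1, 4)
  family <- "unclassified"
  subtype <- "none"
  if (cys <= config$omegaMaxCys && omegaCov >= config$omegaDensityThreshold) {
    family <- "omega"
    subtype <- if (n5 > n12) "omega_5" else "omega_1_2"
  } else if (gammaN >= config$gammaMinRepeats &&
             abs(cys - config$gammaCys) <= config$cysTol) {
    family <- "gamma"
  } else if ((has33 || alphaN >= config$alphaMinRepeats ||
              any(vapply(config$alphaSignatures,
                         function(sg) startsWith(s, sg), logical(1)))) &&
             abs(cys - config$alphaCys) <= config$cysTol) {
    family <- "alpha"
  }
  list(family = family, subtype = subtype,
       evidence = list(cys_count = cys, omega_density = omegaCov,
                       gamma_repeats = gammaN, alpha_repeats = alphaN,
                       omega5_motifs = n5, omega12_motifs = n12,
                       has_33mer = has33, nterm = nterm))
}

## Family-specific motif sets used for repetitive-domain coverage.
.familyCoverage <- function(sequence, family, config, catalog = NULL) {
  motifs <- switch(family,
    alpha = c(config$alphaMotifs, GLIADIN_33MER),
    omega = config$omegaMotifs,
    gamma = character(0))
  if (!is.null(catalog)) {
    tab <- catalogTable(catalog)
    motifs <- c(motifs,
                tab$core_native[tab$source_family %in% c(family, "any")])
  }
  .motifCoverage(sequence, motifs, gammaRepeat = (family == "gamma"))
}

.runsFromLogical <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Segment a mature gliadin into structural domains
#'
#' Repetitive domains are maximal spans of family repeat-motif occurrences,
#' bridging spacer gaps up to `segMaxGap` residues and requiring at least
#' `segMinRepLen` residues. Polyglutamine domains are polyQ runs (at least
#' `polyQMinLen` Q) outside the repetitive spans. A short prefix (up to
#' `maxSigPrefix` residues) before the first repetitive domain is labeled
#' as the N-terminal signature; everything else is non-repetitive. The
#' returned segments are contiguous, non-overlapping and cover the mature
#' sequence exactly.
#'
#' @param sequence mature amino-acid sequence (character or `AAString`).
#' @param family `"alpha"`, `"gamma"` or `"omega"` (an unclassified family
#'   is an error).
#' @param config a [profilerConfig()] list.
#' @param catalog optional [EpitopeCatalog-class]; its family-matched native
#'   cores then also count as repetitive content (planted or natural
#'   epitopes inside a repeat domain do not interrupt it).
#' @return data.frame with columns label (one of nterm_signature,
#'   repetitive, polyglutamine, nonrepetitive), start, end (1-based,
#'   inclusive).
#' @export
segmentDomains <- function(sequence, family, config = profilerConfig(),
                           catalog = NULL) {
  if (!family %in% c("alpha", "gamma", "omega"))
    stop("cannot segment a sequence of family '", family, "'")
  s <- .asSequence(sequence)
  n <- nchar(s)
  covered <- .familyCoverage(s, family, config, catalog)
  ## bridge spacer gaps up to segMaxGap between covered spans
  runs <- .runsFromLogical(covered)
  rep_spans <- NULL
  if (nrow(runs) > 0) {
    merged <- runs[1, , drop = FALSE]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1L <= config$segMaxGap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    rep_spans <- merged[merged$end - merged$start + 1L >= config$segMinRepLen,
                        , drop = FALSE]
  }
  label <- rep("nonrepetitive", n)
  if (!is.null(rep_spans))
    for (i in seq_len(nrow(rep_spans)))
      label[rep_spans$start[i]:rep_spans$end[i]] <- "repetitive"
  ## polyglutamine runs outside repetitive spans
  pq <- findPolyQRuns(s, config$polyQMinLen)
  for (i in seq_along(pq)) {
    idx <- IRanges::start(pq)[i]:IRanges::end(pq)[i]
    idx <- idx[label[idx] == "nonrepetitive"]
    if (length(idx) >= config$polyQMinLen) {
      ## keep only contiguous remainders long enough
      sub <- .runsFromLogical(seq_len(n) %in% idx)
      for (j in seq_len(nrow(sub)))
        if (sub$end[j] - sub$start[j] + 1L >= config$polyQMinLen)
          label[sub$start[j]:sub$end[j]] <- "polyglutamine"
    }
  }
  ## N-terminal signature prefix
  firstRep <- which(label == "repetitive")[1]
  if (!is.na(firstRep) && firstRep > 1L &&
      firstRep - 1L <= config$maxSigPrefix &&
      all(label[1:(firstRep - 1L)] == "nonrepetitive"))
    label[1:(firstRep - 1L)] <- "nterm_signature"
  r <- rle(label)
  ends <- cumsum(r$lengths)
  out <- data.frame(label = r$values,
                    start = ends - r$lengths + 1L,
                    end = ends, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
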