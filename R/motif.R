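## Motif engine: exhaustive overlapping/non-overlapping motif counting,
## epitope scanning with deamidation handling, the degenerate gamma-repeat,
## polyglutamine runs and 33-mer detection. All coordinates are 1-based and
## inclusive, the R/Bioconductor convention.

#' The protease-resistant alpha-gliadin 33-mer peptide
#'
#' The 33-residue peptide from D-genome alpha-gliadins that resists
#' gastrointestinal proteolysis and carries multiple overlapping CD
#' epitopes (one DQ2.5-glia-alpha1a copy and three overlapping
#' DQ2.5-glia-alpha2 copies).
#' @export
GLIADIN_33MER <- "LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"

.asSequence <- function(x) {
  if (is(x, "AAString") || is(x, "AAStringSet")) x <- as.character(x)
  x <- toupper(as.character(x))
  stopifnot(length(x) == 1L)
  x
}

## All start positions of an exact motif, overlapping allowed. O(n*m) via a
## vectorized sliding window; the deliberately naive loop oracle used in the
## tests is independent of this.
.motifStarts <- function(sequence, motif) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (m == 0L || m > n) return(integer(0))
  idx <- seq_len(n - m + 1L)
  unname(which(substring(sequence, idx, idx + m - 1L) == motif))
}

#' Count motif occurrences in a protein sequence
#'
#' Overlapping mode reports every start position at which the motif matches;
#' non-overlapping mode consumes matches greedily from the left (a match may
#' not start before the previous one ends). Repeat-motif copy numbers quoted
#' for gliadins (e.g. 28 copies of FPQQQ in an omega-5 sequence) follow the
#' overlapping convention, which coincides with the non-overlapping one when
#' copies are spacer-separated.
#'
#' @param sequence amino-acid sequence (character or `AAString`).
#' @param motif non-empty motif string.
#' @param mode `"overlapping"` (default) or `"non_overlapping"`.
#' @return list with elements `motif`, `mode`, `count` and `positions`
#'   (sorted 1-based start positions).
#' @examples
#' countOccurrences("AAAA", "AA")$count                      # 3
#' countOccurrences("AAAA", "AA", "non_overlapping")$count   # 2
#' countOccurrences(GLIADIN_33MER, "PQPQLPYPQ")$positions    # 7 14 21
#' @export
countOccurrences <- function(sequence, motif,
                             mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  sequence <- .asSequence(sequence)
  motif <- toupper(as.character(motif))
  if (!nzchar(motif)) stop("motif must be non-empty")
  starts <- .motifStarts(sequence, motif)
  if (mode == "non_overlapping" && length(starts) > 1L) {
    keep <- integer(0)
    nextFree <- 1L
    for (s in starts) {
      if (s >= nextFree) {
        keep <- c(keep, s)
        nextFree <- s + nchar(motif)
      }
    }
    starts <- keep
  }
  list(motif = motif, mode = mode, count = length(starts),
       positions = as.integer(starts))
}

#' Scan a protein for catalog epitopes
#'
#' Reports every overlapping occurrence of each catalog epitope's native
#' core and, with `deamidationMode = "both"`, of its deamidated core as
#' well. Hits are deduplicated per (epitope, start); when the native and the
#' deamidated core match at the same position the native form is reported.
#' The default is native-only because deposited gliadin sequences are native
#' (deamidation happens enzymatically in the gut, not in the genome).
#'
#' @param x a [ProteinSet-class], or a single sequence (character or
#'   `AAString`); for a bare sequence `id` names the protein in the output.
#' @param catalog an [EpitopeCatalog-class]; defaults to the shipped
#'   CD/WDEIA catalog.
#' @param deamidationMode `"native_only"` (default) or `"both"`.
#' @param id protein id used when `x` is a bare sequence.
#' @return data.frame with columns protein_id, epitope_name, start, end
#'   (1-based inclusive), matched_text and form (`native`/`deamidated`).
#' @examples
#' hits <- scanEpitopes(GLIADIN_33MER, id = "33mer")
#' table(hits$epitope_name)
#' @export
scanEpitopes <- function(x, catalog = defaultEpitopeCatalog(),
                         deamidationMode = c("native_only", "both"),
                         id = "protein") {
  deamidationMode <- match.arg(deamidationMode)
  stopifnot(is(catalog, "EpitopeCatalog"))
  if (is(x, "ProteinSet")) {
    if (any(maturity(x) == "precursor"))
      warning("scanning precursor sequence(s); epitope positions refer to ",
              "the unmatured sequence")
    seqs <- proteinSequences(x)
  } else {
    seqs <- setNames(.asSequence(x), id)
  }
  tab <- catalogTable(catalog)
  out <- vector("list", 0L)
  for (p in seq_along(seqs)) {
    s <- seqs[[p]]
    pid <- names(seqs)[p]
    for (i in seq_len(nrow(tab))) {
      forms <- c(native = tab$core_native[i])
      if (deamidationMode == "both" && !is.na(tab$core_deamidated[i]))
        forms <- c(forms, deamidated = tab$core_deamidated[i])
      hits <- NULL
      for (f in names(forms)) {
        starts <- .motifStarts(s, forms[[f]])
        if (length(starts))
          hits <- rbind(hits, data.frame(
            protein_id = pid, epitope_name = tab$name[i],
            start = starts, end = starts + nchar(forms[[f]]) - 1L,
            matched_text = substring(s, starts,
                                     starts + nchar(forms[[f]]) - 1L),
            form = f, stringsAsFactors = FALSE))
      }
      if (!is.null(hits)) {
        ## dedupe per start; rbind order puts native first
        hits <- hits[!duplicated(hits$start), , drop = FALSE]
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out))
    return(data.frame(protein_id = character(), epitope_name = character(),
                      start = integer(), end = integer(),
                      matched_text = character(), form = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(match(res$protein_id, names(seqs)), res$epitope_name,
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Literal expansions of the degenerate gamma repeat PFP Q{1,2} (PQQ){1,2},
## longest first so that the longest expansion wins at each start.
.GAMMA_EXPANSIONS <- local({
  e <- c(outer(c("Q", "QQ"), c("PQQ", "PQQPQQ"),
               function(q, r) paste0("PFP", q, r)))
  e[order(-nchar(e))]
})

#' Count the degenerate gamma-gliadin repeat motif
#'
#' The gamma-gliadin repetitive domain is built from the degenerate unit
#' PFP Q(1-2) (PQQ)(1-2). Matches are sought at every start position
#' (overlapping); at each start the longest of the four literal expansions
#' that matches is taken, and at most one hit is recorded per start, which
#' prevents double-counting nested expansions.
#'
#' @param sequence amino-acid sequence (character or `AAString`).
#' @return list with `pattern`, `count`, `positions` (1-based starts) and
#'   `widths` (length of the winning expansion at each start).
#' @examples
#' countGammaRepeat("PFPQPQQ")$count        # 1
#' countGammaRepeat("PFPQQPQQPQQ")$widths   # 11: PFP+QQ+PQQPQQ
#' @export
countGammaRepeat <- function(sequence) {
  sequence <- .asSequence(sequence)
  positions <- integer(0)
  widths <- integer(0)
  n <- nchar(sequence)
  for (exp in .GAMMA_EXPANSIONS) {
    starts <- .motifStarts(sequence, exp)
    newS <- setdiff(starts, positions)
    positions <- c(positions, newS)
    widths <- c(widths, rep.int(nchar(exp), length(newS)))
  }
  o <- order(positions)
  list(pattern = "PFPQ{1,2}(PQQ){1,2}", count = length(positions),
       positions = as.integer(positions[o]), widths = as.integer(widths[o]))
}

#' Find polyglutamine runs
#'
#' Maximal runs of consecutive Q residues of at least `minLen`; maximality
#' makes the runs non-overlapping by construction.
#'
#' @param sequence amino-acid sequence (character or `AAString`).
#' @param minLen minimum run length (>= 2).
#' @return an [IRanges::IRanges] of runs (1-based, inclusive).
#' @examples
#' findPolyQRuns("PPQQQQQQPP", minLen = 6)
#' @export
findPolyQRuns <- function(sequence, minLen = 6L) {
  stopifnot(minLen >= 2L)
  sequence <- .asSequence(sequence)
  m <- gregexpr(sprintf("Q{%d,}", as.integer(minLen)), sequence)[[1]]
  if (m[1] == -1L) return(IRanges())
  IRanges(start = as.integer(m),
          width = as.integer(attr(m, "match.length")))
}

#' Detect the alpha-gliadin 33-mer
#'
#' All overlapping occurrences of the literal 33-mer peptide
#' [GLIADIN_33MER] in a sequence.
#'
#' @param sequence amino-acid sequence (character or `AAString`).
#' @return integer vector of 1-based start positions (possibly empty).
#' @examples
#' detect33mer(GLIADIN_33MER)  # 1
#' @export
detect33mer <- function(sequence) {
  .motifStarts(.asSequence(sequence), GLIADIN_33MER)
}

## Positions of `sequence` covered by at least one occurrence of any of
## `motifs` (used by the classifier density rule and the segmenter).
.motifCoverage <- function(sequence, motifs, gammaRepeat = FALSE) {
  n <- nchar(sequence)
  covered <- logical(n)
  for (mo in motifs) {
    starts <- .motifStarts(sequence, mo)
    for (s in starts) covered[s:(s + nchar(mo) - 1L)] <- TRUE
  }
  if (gammaRepeat) {
    g <- countGammaRepeat(sequence)
    for (i in seq_along(g$positions))
      covered[g$positions[i]:(g$positions[i] + g$widths[i] - 1L)] <- TRUE
  }
  covered
}
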