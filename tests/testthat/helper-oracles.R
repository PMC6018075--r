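## Independent oracles and small generators used across the suite. These
## are deliberately naive and share no code with the package internals.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

randomAAString <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## position-by-position loop oracle for overlapping motif counts
naiveCountOverlapping <- function(s, motif) {
  n <- nchar(s); m <- nchar(motif)
  starts <- integer(0)
  i <- 1L
  while (i + m - 1L <= n) {
    if (substr(s, i, i + m - 1L) == motif) starts <- c(starts, i)
    i <- i + 1L
  }
  starts
}

## greedy left-to-right oracle for non-overlapping counts
naiveCountNonOverlapping <- function(s, motif) {
  n <- nchar(s); m <- nchar(motif)
  starts <- integer(0)
  i <- 1L
  while (i + m - 1L <= n) {
    if (substr(s, i, i + m - 1L) == motif) {
      starts <- c(starts, i)
      i <- i + m
    } else i <- i + 1L
  }
  starts
}

## oracle for the degenerate gamma repeat: try the four literal expansions
## at every start, longest first
gammaExpansions <- {
  e <- c(outer(c("Q","QQ"), c("PQQ","PQQPQQ"), function(q, r) paste0("PFP", q, r)))
  e[order(-nchar(e))]
}
naiveGammaRepeat <- function(s) {
  hits <- NULL
  for (i in seq_len(nchar(s))) {
    for (exp in gammaExpansions) {
      if (i + nchar(exp) - 1L <= nchar(s) &&
          substr(s, i, i + nchar(exp) - 1L) == exp) {
        hits <- rbind(hits, data.frame(start = i, width = nchar(exp)))
        break
      }
    }
  }
  if (is.null(hits)) data.frame(start = integer(0), width = integer(0))
  else hits
}

## exhaustive global-alignment enumeration (match/mismatch/linear gap).
## Returns the maximal score and the set of identities (matches/alen*100)
## achieved by the co-optimal alignments.
bruteAlignIdentities <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  combos <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > length(va) && j > length(vb)) {
      matrix(0, 1, 3, dimnames = list(NULL, c("score","matches","alen")))
    } else {
      out <- NULL
      if (i <= length(va) && j <= length(vb)) {
        sub <- combos(i + 1L, j + 1L)
        hit <- va[i] == vb[j]
        out <- rbind(out, sub + rep(c(if (hit) match else mismatch,
                                      as.numeric(hit), 1),
                                    each = nrow(sub)))
      }
      if (i <= length(va)) {
        sub <- combos(i + 1L, j)
        out <- rbind(out, sub + rep(c(-gap, 0, 1), each = nrow(sub)))
      }
      if (j <= length(vb)) {
        sub <- combos(i, j + 1L)
        out <- rbind(out, sub + rep(c(-gap, 0, 1), each = nrow(sub)))
      }
      unique(out)
    }
    memo[[key]] <- res
    res
  }
  all <- combos(1L, 1L)
  best <- max(all[, "score"])
  opt <- all[all[, "score"] == best, , drop = FALSE]
  list(score = best,
       identities = sort(unique(opt[, "matches"] / opt[, "alen"] * 100)))
}

## substitute ceiling(rate * n) random positions with a different residue
mutateSequence <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  k <- max(1L, ceiling(rate * length(v)))
  pos <- sample(seq_along(v), k)
  for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
  paste(v, collapse = "")
}

## brute-force group-and-sum oracle for spot summaries
naiveSpotSummary <- function(listings) {
  ids <- unique(listings$spot_id)
  cat <- vapply(ids, function(id) {
    sub <- listings[listings$spot_id == id & !listings$minor_flag, , drop = FALSE]
    if (nrow(sub)) sub$category[1] else "unknown"
  }, character(1))
  vol <- listings$volume_norm[match(ids, listings$spot_id)]
  out <- aggregate(list(volume = vol), by = list(category = cat), FUN = sum)
  out$n <- as.integer(table(cat)[out$category])
  out
}

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
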