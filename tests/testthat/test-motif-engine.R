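test_that("overlapping and non-overlapping counts match hand-derived cases", {
  ## the three overlapping alpha2 copies inside the 33-mer
  res <- countOccurrences(GLIADIN_33MER, "PQPQLPYPQ")
  expect_equal(res$count, 3L)
  expect_equal(res$positions, c(7L, 14L, 21L))

  expect_equal(countOccurrences("AAAA", "AA")$count, 3L)
  expect_equal(countOccurrences("AAAA", "AA", "non_overlapping")$count, 2L)

  res2 <- countOccurrences("PQQPFPQQPFP", "PQQPFP")
  expect_equal(res2$positions, c(1L, 6L))

  expect_error(countOccurrences("AAAA", ""), "non-empty")
})

test_that("motif counts agree with a naive sliding-window oracle", {
  set.seed(101)
  for (i in 1:400) {
    s <- randomAAString(sample(5:80, 1), alphabet = c("P", "Q", "F", "A"))
    m <- randomAAString(sample(1:5, 1), alphabet = c("P", "Q", "F"))
    ov <- countOccurrences(s, m, "overlapping")
    no <- countOccurrences(s, m, "non_overlapping")
    expect_identical(ov$positions, naiveCountOverlapping(s, m))
    expect_identical(no$positions, naiveCountNonOverlapping(s, m))
    expect_gte(ov$count, no$count)
    expect_equal(ov$count, length(ov$positions))
    expect_true(all(diff(ov$positions) > 0))
  }
})

test_that("epitope scanning locates cores at exact positions", {
  cat <- EpitopeCatalog(data.frame(
    name = c("a1a", "a2"),
    core_native = c("PFPQPQLPY", "PQPQLPYPQ"),
    core_deamidated = NA_character_, disease = "CD",
    source_family = "alpha"))
  hits <- scanEpitopes(GLIADIN_33MER, cat, id = "m33")
  expect_equal(hits$start[hits$epitope_name == "a1a"], 5L)
  expect_equal(hits$start[hits$epitope_name == "a2"], c(7L, 14L, 21L))
  ## every hit satisfies matched_text == substr(sequence, start, end)
  expect_true(all(hits$matched_text ==
                  substring(GLIADIN_33MER, hits$start, hits$end)))
  expect_true(all(hits$end - hits$start + 1L == nchar(hits$matched_text)))

  emptyCat <- EpitopeCatalog(data.frame(
    name = character(), core_native = character(),
    core_deamidated = character(), disease = character(),
    source_family = character()))
  expect_equal(nrow(scanEpitopes(GLIADIN_33MER, emptyCat)), 0L)
})

test_that("planted non-overlapping copies are each found exactly once", {
  cat <- defaultEpitopeCatalog()
  set.seed(7)
  for (k in c(1, 3, 5)) {
    spacers <- replicate(k + 1, randomAAString(4, c("A", "S", "T", "G")))
    s <- paste0(paste0(spacers[seq_len(k)], "PQPQLPYPQ", collapse = ""),
                spacers[k + 1])
    hits <- scanEpitopes(s, cat, id = "p")
    expect_equal(sum(hits$epitope_name == "DQ2.5-glia-alpha2"), k)
  }
})

test_that("deamidated cores are matched in mode 'both' at the native positions", {
  cat <- defaultEpitopeCatalog()
  tab <- catalogTable(cat)
  native <- tab$core_native[tab$name == "DQ2.5-glia-alpha2"]
  deam <- tab$core_deamidated[tab$name == "DQ2.5-glia-alpha2"]
  s_nat <- paste0("AAAT", native, "TSSA", native, "GGGG")
  s_dea <- gsub(native, deam, s_nat, fixed = TRUE)

  ## native-only mode sees nothing in the deamidated copy
  h0 <- scanEpitopes(s_dea, cat, deamidationMode = "native_only")
  expect_equal(sum(h0$epitope_name == "DQ2.5-glia-alpha2"), 0L)

  ## in mode both, the hit multiset per epitope is preserved under the
  ## native -> deamidated substitution
  hn <- scanEpitopes(s_nat, cat, deamidationMode = "both")
  hd <- scanEpitopes(s_dea, cat, deamidationMode = "both")
  key <- function(h) sort(paste(h$epitope_name, h$start))
  expect_equal(key(hd), key(hn))
  expect_setequal(hd$form[hd$epitope_name == "DQ2.5-glia-alpha2"],
                  "deamidated")
})

test_that("the degenerate gamma repeat takes the longest expansion per start", {
  r1 <- countGammaRepeat("PFPQPQQ")
  expect_equal(r1$count, 1L)
  expect_equal(r1$positions, 1L)
  expect_equal(r1$widths, 7L)

  expect_equal(countGammaRepeat("AAAA")$count, 0L)

  ## longest-match rule: PFP + QQ + PQQPQQ consumes the whole string
  r3 <- countGammaRepeat("PFPQQPQQPQQ")
  expect_equal(r3$count, 1L)
  expect_equal(r3$widths, 11L)

  set.seed(31)
  for (i in 1:200) {
    s <- randomAAString(sample(6:60, 1), alphabet = c("P", "Q", "F"))
    got <- countGammaRepeat(s)
    want <- naiveGammaRepeat(s)
    expect_equal(got$positions, want$start)
    expect_equal(got$widths, want$width)
  }
})

test_that("polyglutamine runs are maximal, half-open-free and thresholded", {
  r <- findPolyQRuns("PPQQQQQQPP", minLen = 6)
  expect_equal(IRanges::start(r), 3L)
  expect_equal(IRanges::end(r), 8L)

  expect_equal(length(findPolyQRuns("QPQPQP", minLen = 2)), 0L)

  r2 <- findPolyQRuns(strrep("Q", 10), minLen = 6)
  expect_equal(IRanges::start(r2), 1L)
  expect_equal(IRanges::end(r2), 10L)

  expect_error(findPolyQRuns("QQQ", minLen = 1), "minLen")

  ## runs are non-overlapping by construction
  r3 <- findPolyQRuns("QQQAQQQQAQQ", minLen = 2)
  expect_equal(IRanges::start(r3), c(1L, 5L, 10L))
  expect_equal(IRanges::width(r3), c(3L, 4L, 2L))
})

test_that("33-mer detection reports all literal occurrences", {
  expect_equal(detect33mer(GLIADIN_33MER), 1L)
  expect_equal(length(detect33mer("AAAA")), 0L)
  set.seed(5)
  prefix <- randomAAString(57, c("A", "S", "T", "G", "V"))
  s <- paste0(prefix, GLIADIN_33MER, "AAAA")
  expect_equal(detect33mer(s), 58L)
})
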