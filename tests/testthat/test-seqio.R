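test_that("FASTA reading normalizes case, parses maturity and validates ids", {
  f <- writeTempFasta(c(">p1 maturity=mature some alpha-gliadin", "lqlq",
                        ">p2", "PQPQLPYPQ"))
  ps <- readProteinFasta(f)
  expect_s4_class(ps, "ProteinSet")
  expect_equal(length(ps), 2L)
  expect_equal(unname(proteinSequences(ps)["p1"]), "LQLQ")
  expect_equal(unname(maturity(ps)), c("mature", "unknown"))

  empty <- writeTempFasta(character(0))
  expect_equal(length(readProteinFasta(empty)), 0L)

  dup <- writeTempFasta(c(">p1", "LQLQ", ">p1", "PPPP"))
  expect_error(readProteinFasta(dup), "duplicate")

  bad <- writeTempFasta(c("LQLQ", ">p1", "LQLQ"))
  expect_error(readProteinFasta(bad), "FASTA")

  inv <- writeTempFasta(c(">p1", "LQZQ"))
  expect_error(readProteinFasta(inv), "residues")
})

test_that("FASTA writing round-trips sequences and maturity", {
  ps <- ProteinSet(c(a = "LQLQPFPQ", b = "QQIPQQQAAA"),
                   maturity = c("mature", "precursor"))
  f <- tempfile(fileext = ".fasta")
  writeProteinFasta(ps, f)
  back <- readProteinFasta(f)
  expect_equal(proteinSequences(back), proteinSequences(ps))
  expect_equal(maturity(back), maturity(ps))
})

test_that("epitope catalog validation enforces the deamidation rule", {
  good <- EpitopeCatalog(data.frame(
    name = "DQ2.5-glia-alpha2", core_native = "PQPQLPYPQ",
    core_deamidated = "PQPELPYPQ", disease = "CD",
    source_family = "alpha"))
  expect_s4_class(good, "EpitopeCatalog")

  wd <- EpitopeCatalog(data.frame(
    name = "WD-1", core_native = "QQIPQQQ", core_deamidated = "-",
    disease = "WDEIA", source_family = "omega"))
  expect_true(is.na(catalogTable(wd)$core_deamidated))

  expect_error(EpitopeCatalog(data.frame(
    name = c("e", "e"), core_native = c("PQPQ", "PQPQ"),
    core_deamidated = NA, disease = "CD", source_family = "alpha")),
    "duplicate")

  ## length mismatch
  expect_error(EpitopeCatalog(data.frame(
    name = "e", core_native = "PQPQLPYPQ", core_deamidated = "PQPE",
    disease = "CD", source_family = "alpha")), "length")

  ## substitution at a non-Q position
  expect_error(EpitopeCatalog(data.frame(
    name = "e", core_native = "PQPQLPYPQ", core_deamidated = "PQPQLPEPQ",
    disease = "CD", source_family = "alpha")), "non-Q")

  ## non Q->E substitution at a Q position
  expect_error(EpitopeCatalog(data.frame(
    name = "e", core_native = "PQPQLPYPQ", core_deamidated = "PQPALPYPQ",
    disease = "CD", source_family = "alpha")), "non-Q")
})

test_that("the shipped catalog is valid and flags unverified cores", {
  cat <- defaultEpitopeCatalog()
  tab <- catalogTable(cat)
  expect_true(all(c("DQ2.5-glia-alpha1a", "DQ2.5-glia-alpha2",
                    "WD-1", "WD-2") %in% tab$name))
  expect_equal(tab$core_native[tab$name == "WD-1"], "QQIPQQQ")
  expect_equal(tab$core_native[tab$name == "WD-2"], "QQFPQQQ")
  ## only the 33-mer-anchored and in-text cores are marked verified
  expect_setequal(tab$name[tab$verified],
                  c("DQ2.5-glia-alpha1a", "DQ2.5-glia-alpha2",
                    "WD-1", "WD-2"))
  f <- tempfile(fileext = ".tsv")
  writeEpitopeCatalog(cat, f)
  expect_equal(catalogTable(readEpitopeCatalog(f)), tab)
})

test_that("spot tables are parsed, validated and round-tripped", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("spot_id\tvolume_norm\tprotein_id\tcategory\tminor_flag",
               "1\t40.5\tP1\talpha\tFALSE",
               "2\t30.5\tP2\tgamma\tFALSE",
               "3\t29.0\t\tunknown\tFALSE"), f)
  st <- readSpotTable(f)
  expect_equal(nrow(spotListings(st)), 3L)

  writeLines(c("spot_id\tvolume_norm\tprotein_id\tcategory\tminor_flag",
               "1\t-1\tP1\talpha\tFALSE"), f)
  expect_error(readSpotTable(f), "volume")

  writeLines(c("spot_id\tvolume_norm\tprotein_id\tcategory\tminor_flag",
               "1\t10\tP1\tdelta\tFALSE"), f)
  expect_error(readSpotTable(f), "category")

  out <- tempfile(fileext = ".tsv")
  writeSpotTable(st, out)
  expect_equal(spotListings(readSpotTable(out)), spotListings(st))
})

test_that("the Keumkang fixture has 98 spots in the published layout", {
  ks <- keumkangSpotTable()
  expect_equal(length(ks), 98L)
  tab <- spotListings(ks)
  ## spot 43: predominant alpha listing plus minor alpha and gamma listings
  s43 <- tab[tab$spot_id == "43", ]
  expect_equal(nrow(s43), 3L)
  expect_equal(sum(!s43$minor_flag), 1L)
  expect_equal(s43$category[!s43$minor_flag], "alpha")
})

test_that("census reports round-trip and an empty census gives a header-only file", {
  sim <- generateProtein(gliadinSpec("gamma", seed = 11))
  cen <- buildCensus(sim$protein)
  f <- tempfile(fileext = ".tsv")
  writeCensusReport(cen, f)
  back <- readCensusReport(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$family, "gamma")
  expect_equal(back[["DQ2.5-glia-gamma1"]],
               unname(epitopeCounts(cen)[1, "DQ2.5-glia-gamma1"]))
  ## identity under a second write/read cycle
  f2 <- tempfile(fileext = ".tsv")
  write.table(back, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readCensusReport(f2), back)

  emptyCen <- buildCensus(ProteinSet())
  fe <- tempfile(fileext = ".tsv")
  writeCensusReport(emptyCen, fe)
  expect_equal(nrow(readCensusReport(fe)), 0L)
  expect_gt(length(readLines(fe)), 0L)
})

test_that("composition summaries print 2-decimal percentages and round-trip", {
  st <- SpotTable(data.frame(
    spot_id = c("1", "2"), volume_norm = c(60.125, 39.875),
    protein_id = c("a", "b"), category = c("alpha", "gamma"),
    minor_flag = FALSE))
  sm <- summarizeSpots(st)
  f <- tempfile(fileext = ".tsv")
  writeCompositionSummary(sm, f)
  lines <- readLines(f)
  expect_match(lines[2], "60\\.12|60\\.13")  # 2 decimals
  back <- readCompositionSummary(f)
  expect_equal(summaryRows(back)$category, summaryRows(sm)$category)
  expect_equal(summaryRows(back)$volume_pct,
               round(summaryRows(sm)$volume_pct, 2))
  ## written form is a fixed point of write -> read -> write
  f2 <- tempfile(fileext = ".tsv")
  writeCompositionSummary(back, f2)
  expect_equal(readLines(f2), lines)
})

test_that("reference panels read from FASTA with genome/family header keys", {
  f <- writeTempFasta(c(">r1 genome=D family=alpha", "PQPQLPYPQAAA",
                        ">r2 genome=B family=alpha", "PQPQLPYPQCSTT"))
  panel <- readReferencePanel(f)
  expect_equal(panelEntries(panel)$genome, c("D", "B"))
  out <- tempfile(fileext = ".fasta")
  writeReferencePanel(panel, out)
  expect_equal(panelEntries(readReferencePanel(out)), panelEntries(panel))
  bad <- writeTempFasta(c(">r1 genome=D", "PQPQ"))
  expect_error(readReferencePanel(bad), "family")
})
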