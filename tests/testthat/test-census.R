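test_that("census recovers planted epitope counts and cysteines", {
  sim <- generateProtein(gliadinSpec(
    "alpha", plantedEpitopes = c("DQ2.5-glia-alpha1a" = 1,
                                 "DQ2.5-glia-alpha2" = 3),
    cysCount = 6, seed = 81))
  cen <- buildCensus(sim$protein)
  tab <- censusTable(cen)
  expect_equal(tab$family, "alpha")
  expect_equal(tab[["DQ2.5-glia-alpha1a"]], 1L)
  expect_equal(tab[["DQ2.5-glia-alpha2"]], 3L)
  expect_equal(tab$cys_count, 6L)
  expect_false(tab$chain_terminator)

  ## omega-5 with WDEIA epitopes planted in the repeat body
  sim2 <- generateProtein(gliadinSpec(
    "omega", subtype = "omega_5",
    plantedEpitopes = c("WD-1" = 4, "WD-2" = 12), cysCount = 1,
    seed = 82))
  cen2 <- buildCensus(sim2$protein)
  tab2 <- censusTable(cen2)
  expect_equal(tab2[["WD-1"]], 4L)
  expect_equal(tab2[["WD-2"]], 12L)
  expect_equal(tab2$subtype, "omega_5")
  expect_true(tab2$chain_terminator)  # single cysteine, like the GRLL- omega-5

  expect_equal(length(buildCensus(ProteinSet())), 0L)
})

test_that("census details expose segmentation, motif counts and hits", {
  sim <- generateProtein(gliadinSpec("omega", subtype = "omega_1_2",
                                     seed = 83))
  cen <- buildCensus(sim$protein)
  d <- censusDetails(cen, proteinIds(sim$protein))
  expect_equal(d$motifCounts$count[d$motifCounts$motif == "PQQPFP"],
               unname(sim$truth$unit_counts["PQQPFP"]))
  expect_true(all(c("segmentation", "hits", "classification") %in% names(d)))
  expect_error(censusDetails(cen, "nope"), "no census details")
})

test_that("spot summaries conserve volume and match a group-sum oracle", {
  ks <- keumkangSpotTable()
  sm <- summarizeSpots(ks)
  rows <- summaryRows(sm)
  expect_equal(sm@totalSpots, 98L)
  expect_equal(sm@totalPct, 100, tolerance = 1e-9)
  ## per-category bookkeeping of the fixture (volumes planted to the
  ## published category totals)
  expect_equal(rows$n_spots[rows$category == "alpha"], 31L)
  expect_equal(rows$volume_pct[rows$category == "alpha"], 41.99,
               tolerance = 1e-9)
  expect_equal(rows$volume_pct[rows$category == "gamma"], 24.84,
               tolerance = 1e-9)

  ## single spot
  one <- SpotTable(data.frame(spot_id = "1", volume_norm = 100,
                              protein_id = "p", category = "alpha",
                              minor_flag = FALSE))
  so <- summarizeSpots(one)
  expect_equal(summaryRows(so)$volume_pct, 100)
  expect_equal(so@totalSpots, 1L)

  ## random tables against the oracle, conservation to 1e-9
  for (i in 1:10) {
    sim <- generateSpotTable(sample(5:60, 1), seed = 900 + i)
    sm2 <- summarizeSpots(sim$spots)
    lst <- spotListings(sim$spots)
    oracle <- naiveSpotSummary(lst)
    r2 <- summaryRows(sm2)
    expect_equal(sum(r2$volume_pct), sum(lst$volume_norm),
                 tolerance = 1e-9)
    for (j in seq_len(nrow(oracle))) {
      expect_equal(r2$volume_pct[r2$category == oracle$category[j]],
                   oracle$volume[j], tolerance = 1e-9)
      expect_equal(r2$n_spots[r2$category == oracle$category[j]],
                   oracle$n[j])
    }
  }

  ## two non-minor listings for one spot are rejected
  expect_error(SpotTable(data.frame(
    spot_id = c("1", "1"), volume_norm = 10,
    protein_id = c("a", "b"), category = c("alpha", "gamma"),
    minor_flag = FALSE)), "non-minor")
})

test_that("predominant-spot counting excludes minor listings", {
  ks <- keumkangSpotTable()
  expect_equal(countPredominantSpots(ks, "alpha"), 31L)
  expect_equal(countPredominantSpots(ks, "gamma"), 28L)
  expect_equal(countPredominantSpots(ks, "omega"), 1L)
  expect_equal(countPredominantSpots(ks, "lmw_gs"), 11L)

  ## summed over categories = number of non-minor spots
  cats <- c("alpha", "gamma", "omega", "lmw_gs", "non_gluten", "unknown")
  tot <- sum(vapply(cats, function(cc) countPredominantSpots(ks, cc),
                    integer(1)))
  lst <- spotListings(ks)
  expect_equal(tot, length(unique(lst$spot_id[!lst$minor_flag])))

  empty <- SpotTable(data.frame(spot_id = character(),
                                volume_norm = numeric(),
                                protein_id = character(),
                                category = character(),
                                minor_flag = logical()))
  expect_equal(countPredominantSpots(empty, "alpha"), 0L)

  allMinor <- SpotTable(data.frame(
    spot_id = c("1", "2"), volume_norm = c(1, 2),
    protein_id = c("a", "b"), category = "alpha", minor_flag = TRUE))
  expect_equal(countPredominantSpots(allMinor, "alpha"), 0L)
})

test_that("genome shares sum spot volumes by census genome call", {
  sims <- list(
    D = generateProtein(gliadinSpec("omega", subtype = "omega_1_2",
                                    signature = "AREL", seed = 91)),
    A = generateProtein(gliadinSpec("omega", subtype = "omega_1_2",
                                    signature = "ARQL", seed = 92)),
    B = generateProtein(gliadinSpec("omega", subtype = "omega_5",
                                    signature = "SRLL", seed = 93)))
  seqs <- unlist(lapply(sims, function(s) proteinSequences(s$protein)))
  names(seqs) <- c("pD", "pA", "pB")
  cen <- buildCensus(ProteinSet(seqs, maturity = "precursor"))
  spots <- SpotTable(data.frame(
    spot_id = c("1", "2", "3"), volume_norm = c(40, 30, 30),
    protein_id = c("pD", "pA", "pB"), category = "omega",
    minor_flag = FALSE))
  sh <- genomeShare(spots, cen, family = "omega")
  expect_equal(unname(sh["D"]), 40)
  expect_equal(unname(sh["A"]), 30)
  expect_equal(unname(sh["B"]), 30)
  expect_equal(unname(sh["unknown"]), 0)

  ## all spots from one genome
  single <- SpotTable(data.frame(
    spot_id = c("1", "2"), volume_norm = c(70, 30), protein_id = "pD",
    category = "omega", minor_flag = FALSE))
  expect_equal(unname(genomeShare(single, cen)["D"]), 100)

  ## a protein without a genome call lands in the unknown bucket
  g <- generateProtein(gliadinSpec("gamma", seed = 94))
  seqs2 <- setNames(proteinSequences(g$protein), "pG")
  cen2 <- buildCensus(ProteinSet(seqs2, maturity = "precursor"))
  spots2 <- SpotTable(data.frame(
    spot_id = "1", volume_norm = 12.5, protein_id = "pG",
    category = "gamma", minor_flag = FALSE))
  expect_equal(unname(genomeShare(spots2, cen2)["unknown"]), 12.5)
})
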