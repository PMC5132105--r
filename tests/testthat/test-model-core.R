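# Core data model: validation, formulas, GPR rules, media application.

test_that("well-formed fixture models validate cleanly", {
  expect_length(validateModel(fx_ph), 0)
  expect_length(validateModel(fx_het), 0)
  expect_length(validateModel(chainModel()), 0)
})

test_that("validateModel names each offending entity", {
  m <- chainModel()
  # bound violation
  bad <- m; bad@reactions$lb[bad@reactions$id == "R_AB"] <- 5
  bad@reactions$ub[bad@reactions$id == "R_AB"] <- -5
  v <- validateModel(bad)
  expect_length(v, 1)
  expect_match(v, "R_AB")
  # undeclared compartment
  bad2 <- m; bad2@metabolites$compartment[1] <- "x9"
  expect_match(validateModel(bad2), "x9", all = FALSE)
  # missing biomass
  bad3 <- m; bad3@biomassIds <- "BIO_MISSING"
  expect_match(validateModel(bad3), "BIO_MISSING", all = FALSE)
  # two extracellular compartments
  bad4 <- m
  bad4@compartments <- rbind(bad4@compartments,
    data.frame(id = "e1", label = "extracellular", species_index = 0L))
  expect_match(validateModel(bad4), "extracellular", all = FALSE)
  # exchange tag on a reaction touching the cytosol
  bad5 <- m; bad5@reactions$source_tag[bad5@reactions$id == "R_AB"] <- "exchange"
  expect_match(validateModel(bad5), "R_AB", all = FALSE)
})

test_that("constructor rejects stoichiometry over unknown metabolites", {
  m <- chainModel()
  expect_error(
    CommFBA:::addReactionsToModel(m, data.frame(id = "RX"),
      data.frame(reaction = "RX", metabolite = "X_c1", coef = -1)),
    "X_c1")
})

test_that("zero coefficients are dropped at construction", {
  cmp <- data.frame(id = c("c1", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(1L, 0L))
  mets <- data.frame(id = c("A_c1", "B_c1"), compartment = "c1")
  rxns <- data.frame(id = "R1", lb = 0, ub = 10)
  st <- data.frame(reaction = c("R1", "R1"), metabolite = c("A_c1", "B_c1"),
                   coef = c(-1, 0))
  m <- MetabolicModel("z", cmp, mets, rxns, st, biomassIds = "R1")
  expect_equal(Matrix::nnzero(stoichiometry(m)), 1)
})

test_that("formula parsing handles counts, implicit ones and massless species", {
  expect_equal(parseFormula("C6H12O6"), c(C = 6L, H = 12L, O = 6L),
               ignore_attr = TRUE)
  expect_equal(parseFormula("HNO3"), c(H = 1L, N = 1L, O = 3L),
               ignore_attr = TRUE)
  expect_length(parseFormula(""), 0)
  expect_error(parseFormula("C6H12-"), "malformed")
  expect_error(parseFormula(NA_character_), "missing")
})

test_that("elemental balance: balanced, unbalanced and exempt reactions", {
  cmp <- data.frame(id = c("c1", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(1L, 0L))
  mets <- data.frame(id = c("A_c1", "B_c1", "A_e0"),
                     compartment = c("c1", "c1", "e0"),
                     formula = c("C6H12O6", "C3H6O3", "C6H12O6"))
  rxns <- data.frame(id = c("SPLIT", "HALF", "EX_A"),
                     lb = 0, ub = 10,
                     source_tag = c("draft", "draft", "exchange"))
  st <- data.frame(reaction = c("SPLIT", "SPLIT", "HALF", "HALF", "EX_A"),
                   metabolite = c("A_c1", "B_c1", "A_c1", "B_c1", "A_e0"),
                   coef = c(-1, 2, -1, 1, -1))
  m <- MetabolicModel("bal", cmp, mets, rxns, st, biomassIds = "SPLIT")
  expect_true(all(elementalBalance(m, "SPLIT") == 0))
  expect_equal(elementalBalance(m, "HALF"),
               c(C = -3, H = -6, O = -3), ignore_attr = TRUE)
  ex <- elementalBalance(m, "EX_A")
  expect_length(ex, 0)
  expect_true(attr(ex, "exempt"))
  # missing formula errors with the metabolite named
  m2 <- m; m2@metabolites$formula[2] <- NA_character_
  expect_error(elementalBalance(m2, "SPLIT"), "B_c1")
})

test_that("all non-exchange, non-biomass fixture reactions are balanced", {
  for (m in list(fx_ph, fx_het)) {
    rx <- reactions(m)
    for (r in rx$id[!rx$source_tag %in% c("exchange", "biomass")]) {
      bal <- elementalBalance(m, r)
      expect_true(length(bal) == 0 || all(abs(bal) < 1e-9),
                  label = paste(modelId(m), r, "balanced"))
    }
  }
})

test_that("GPR parsing and three-valued evaluation", {
  calls <- c(g1 = "on", g2 = "off", g3 = "on")
  expect_equal(CommFBA:::evalGPR("g1 or g2", calls), "on")
  expect_equal(CommFBA:::evalGPR("g1 and g2", calls), "off")
  expect_equal(CommFBA:::evalGPR("g1 and gX", calls), "unknown")
  expect_equal(CommFBA:::evalGPR("g2 or gX", calls), "unknown")
  expect_equal(CommFBA:::evalGPR("(g1 and g2) or g3", calls), "on")
  expect_true(is.na(CommFBA:::evalGPR("", calls)))
  expect_setequal(CommFBA:::gprGenes("(g1 and g2) or (g1 and g3)"),
                  c("g1", "g2", "g3"))
  expect_error(parseGPR("g1 and (g2"), "parenthes")
  expect_error(parseGPR("and g1"), "malformed")
})

test_that("applyMedia sets exchange bounds and is idempotent", {
  m <- chainModel()
  med <- MediaCondition("m", "A", max_uptake = 3, max_excretion = 50)
  m1 <- applyMedia(m, med)
  rx <- reactions(m1)
  expect_equal(unlist(rx[rx$id == "EX_A", c("lb", "ub")]), c(lb = -3, ub = 50))
  m2 <- applyMedia(m1, med)
  expect_identical(reactions(m1), reactions(m2))
  expect_identical(stoichiometry(m1), stoichiometry(m2))
  # non-exchange reactions untouched
  expect_identical(rx[rx$id != "EX_A", ],
                   reactions(m)[reactions(m)$id != "EX_A", ])
})

test_that("empty media closes all uptake", {
  m <- applyMedia(fx_ph, MediaCondition("none", character(0)))
  rx <- reactions(m)
  expect_true(all(rx$lb[rx$source_tag == "exchange"] == 0))
  expect_false(predictGrowth(fx_ph, MediaCondition("none", character(0)))$growth)
})

test_that("media naming an unknown compound errors with the compound name", {
  expect_error(applyMedia(chainModel(), MediaCondition("bad", "unobtainium")),
               "unobtainium")
})

test_that("media TSV round trip preserves entries", {
  path <- tempfile(fileext = ".tsv")
  writeMedia(richMedia(), path)
  back <- readMedia(path, name = "rich")
  expect_equal(back@entries, richMedia()@entries, ignore_attr = TRUE)
})
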