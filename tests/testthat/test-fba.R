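# FBA, parsimonious FBA, growth, auxotrophy and interaction extraction.

test_that("FBA on a linear chain is bound-limited", {
  m <- chainModel()
  med <- MediaCondition("mA", "A", max_uptake = 10)
  sol <- runFBA(m, med)
  expect_equal(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 10, tolerance = 1e-9)
  expect_equal(unname(fluxes(sol)[["EX_A"]]), -10, tolerance = 1e-9)
})

test_that("media without any carbon yields zero objective", {
  sol <- runFBA(chainModel(), MediaCondition("empty", character(0)))
  expect_lt(abs(objectiveValue(sol)), 1e-9)
})

test_that("every optimal solution satisfies S v = 0 and its bounds", {
  cases <- list(
    list(fx_ph, autotrophicMedia()),
    list(fx_het, richMedia()),
    list(fx_ph, richMedia())
  )
  for (cs in cases) {
    for (pars in c(FALSE, TRUE)) {
      m <- applyMedia(cs[[1]], cs[[2]])
      sol <- runFBA(m, objective = biomassIds(m)[1], parsimonious = pars)
      expect_equal(solverStatus(sol), "optimal")
      v <- fluxes(sol)[colnames(stoichiometry(m))]
      resid <- as.vector(stoichiometry(m) %*% v)
      expect_lt(max(abs(resid)), 1e-9)
      rx <- reactions(m)
      expect_true(all(v >= rx$lb - 1e-9 & v <= rx$ub + 1e-9))
    }
  }
})

test_that("pFBA keeps the FBA optimum and minimizes total flux (oracle)", {
  # chain with a parallel wasteful cycle: B <-> C both directions open
  cmp <- data.frame(id = c("c1", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(1L, 0L))
  mets <- data.frame(id = c("A_c1", "B_c1", "C_c1", "A_e0"),
                     compartment = c("c1", "c1", "c1", "e0"))
  rxns <- data.frame(id = c("EX_A", "T_A", "R_AB", "CYC1", "CYC2", "BIO"),
                     lb = c(-10, 0, 0, -100, -100, 0), ub = 100,
                     source_tag = c("exchange", "transport", "draft",
                                    "draft", "draft", "biomass"))
  st <- data.frame(
    reaction = c("EX_A", "T_A", "T_A", "R_AB", "R_AB",
                 "CYC1", "CYC1", "CYC2", "CYC2", "BIO"),
    metabolite = c("A_e0", "A_e0", "A_c1", "A_c1", "B_c1",
                   "B_c1", "C_c1", "C_c1", "B_c1", "B_c1"),
    coef = c(-1, -1, 1, -1, 1, -1, 1, -1, 1, -1))
  m <- MetabolicModel("cyc", cmp, mets, rxns, st, biomassIds = "BIO")
  med <- MediaCondition("mA", "A", max_uptake = 10)
  plain <- runFBA(m, med)
  pfba <- runFBA(m, med, parsimonious = TRUE)
  expect_equal(objectiveValue(pfba), objectiveValue(plain), tolerance = 1e-9)
  # the wasteful cycle carries no flux after the parsimony stage
  expect_lt(abs(fluxes(pfba)[["CYC1"]]), 1e-9)
  expect_lt(abs(fluxes(pfba)[["CYC2"]]), 1e-9)
  # total |v| matches the brute-force vertex-enumeration minimum
  want <- bruteMinTotalFlux(m, med, "BIO", objectiveValue(plain))
  expect_equal(sum(abs(fluxes(pfba))), want, tolerance = 1e-7)
})

test_that("pFBA matches vertex enumeration on the fixture phototroph", {
  sol <- runFBA(fx_ph, autotrophicMedia())
  want <- bruteFBA(fx_ph, autotrophicMedia(), "BIO")
  expect_equal(objectiveValue(sol), want$objective, tolerance = 1e-7)
})

test_that("growth calls are monotone in the threshold", {
  g <- predictGrowth(fx_ph, autotrophicMedia())
  expect_true(g$growth)
  expect_false(predictGrowth(fx_ph, autotrophicMedia(),
                             threshold = g$objective * 1.01)$growth)
})

test_that("auxotrophy prediction flags required compounds only", {
  # heterotroph: carbon source, amino acid, vitamin and O2 are essential
  aux <- predictAuxotrophies(fx_het, richMedia())
  expect_setequal(aux, c("ac", "ala", "vit", "o2"))
  # interchangeable N sources: neither nitrate nor ammonia is reported for
  # the phototroph (either rescues the other)
  aux_p <- predictAuxotrophies(fx_ph, richMedia())
  expect_false("no3" %in% aux_p)
  expect_false("nh3" %in% aux_p)
  # on a minimal media every component of the phototroph's regime is
  # essential (no alternatives to rescue a dropout)
  expect_setequal(predictAuxotrophies(fx_ph, autotrophicMedia()),
                  c("photon", "co2", "no3", "h2o"))
  # on rich media only light remains essential for the phototroph
  expect_equal(aux_p, "photon")
  # error when the model does not grow at all
  expect_error(predictAuxotrophies(fx_het, autotrophicMedia()), "does not grow")
})

test_that("interaction extraction finds the obligate cross-feeding pattern", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  gf <- communityGapfill(cm, fx_db, autotrophicMedia())
  ints <- identifyInteractions(gf@model, autotrophicMedia())
  key <- paste(ints$compound, ints$producer, ints$consumer)
  # organic carbon and organic (fixed) nitrogen flow phototroph -> heterotroph
  expect_true("glc phototroph heterotroph" %in% key)
  expect_true("ala phototroph heterotroph" %in% key)
  # O2 evolved by the phototroph sustains the aerobic heterotroph
  expect_true("o2 phototroph heterotroph" %in% key)
  expect_true(all(ints$flux > 1e-6))
  expect_true(all(ints$producer != ints$consumer))
})

test_that("two independent prototrophs exchange nothing", {
  # two phototroph copies: each grows alone on autotrophic media
  ph2 <- fx_ph
  ph2@id <- "phototroph2"
  cm <- buildCompartmentalized(list(fx_ph, ph2))$model
  ints <- identifyInteractions(cm, autotrophicMedia())
  expect_equal(nrow(ints), 0L)
})

test_that("interactions are invariant under member permutation", {
  g1 <- communityGapfill(buildCompartmentalized(list(fx_ph, fx_het))$model,
                         fx_db, autotrophicMedia())
  g2 <- communityGapfill(buildCompartmentalized(list(fx_het, fx_ph))$model,
                         fx_db, autotrophicMedia())
  i1 <- identifyInteractions(g1@model, autotrophicMedia())
  i2 <- identifyInteractions(g2@model, autotrophicMedia())
  expect_identical(i1[c("compound", "producer", "consumer")],
                   i2[c("compound", "producer", "consumer")])
  expect_equal(i1$flux, i2$flux, tolerance = 1e-6)
})

test_that("interaction extraction refuses non-growing communities", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  expect_error(identifyInteractions(cm, autotrophicMedia()), "does not grow")
})

test_that("FVA mode reports at least the pFBA interactions", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  gf <- communityGapfill(cm, fx_db, autotrophicMedia())
  pf <- identifyInteractions(gf@model, autotrophicMedia())
  fva <- identifyInteractions(gf@model, autotrophicMedia(), mode = "fva")
  key <- function(d) paste(d$compound, d$producer, d$consumer)
  expect_true(all(key(pf) %in% key(fva)))
  expect_true(all(fva$status %in% c("obligatory", "possible")))
})
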