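# Gapfilling: exact parsimony search, brute-force oracle agreement,
# community-level delegation and the three construction strategies.

test_that("an already-growing model needs no additions", {
  res <- gapfill(fx_ph, fx_db, autotrophicMedia())
  expect_equal(nrow(addedReactions(res)), 0L)
  expect_equal(totalCost(res), 0)
  res2 <- communityGapfill(buildCompartmentalized(list(fx_ph, fx_ph))$model,
                           fx_db, autotrophicMedia())
  expect_equal(totalCost(res2), 0)
})

test_that("a single missing internal step is repaired at cost 1", {
  broken <- dropReactions(fx_ph, "NAR")
  db <- dbSubset(fx_db, c("NAR", "LDH", "DST1", "DST2"))
  res <- gapfill(broken, db, autotrophicMedia())
  expect_equal(totalCost(res), 1)
  expect_equal(addedReactions(res)$id, "NAR")
  # the repaired model reaches the target on re-simulation
  expect_gte(res@objectiveValue, 0.01)
  expect_true(predictGrowth(res@model, autotrophicMedia())$growth)
  # oracle agreement, including uniqueness of the minimal solution
  bf <- bruteForceGapfill(broken, db, autotrophicMedia())
  expect_length(bf, 1)
  expect_equal(bf[[1]], "NAR")
})

test_that("a one-reaction route is preferred over a two-reaction route", {
  # vitamin synthesis (VS1+VS2, cost 2) vs a direct vitamin importer with
  # vitamin in the media (TPT_vit, cost 1)
  broken <- dropReactions(fx_ph, c("VS1", "VS2"))
  med <- MediaCondition("auto_vit", c("photon", "co2", "no3", "h2o", "vit"),
                        max_uptake = c(100, 20, 10, 100, 1))
  db <- dbSubset(fx_db, c("VS1", "VS2", "LDH"), transporters = "vit")
  res <- gapfill(broken, db, med)
  expect_equal(totalCost(res), 1)
  expect_equal(addedReactions(res)$id, "TPT_vit")
  bf <- bruteForceGapfill(broken, db, med)
  expect_equal(sort(unique(vapply(bf, paste, "", collapse = "+"))), "TPT_vit")
})

test_that("gapfill cost matches the brute-force minimum on varied instances", {
  # phototroph lesions on autotrophic media, full fixture database
  lesions <- list("NAR", "ALS2", "VS2", "PSII", "CBB", "T_no3",
                  c("NAR", "VS2"), c("ALS1", "ALS2"), c("VS1", "VS2"),
                  c("PSII", "NAR"), c("T_no3", "NAR"))
  for (les in lesions) {
    broken <- dropReactions(fx_ph, les)
    res <- gapfill(broken, fx_db, autotrophicMedia())
    bf <- bruteForceGapfill(broken, fx_db, autotrophicMedia(), max_size = 3)
    expect_gt(length(bf), 0)
    expect_equal(totalCost(res), length(bf[[1]]),
                 label = paste("lesion", paste(les, collapse = "+")))
    # the exact search picks one of the enumerated minimal solutions
    expect_true(paste(sort(addedReactions(res)$id), collapse = "+") %in%
                  vapply(bf, function(s) paste(s, collapse = "+"), ""),
                label = paste("solution for", paste(les, collapse = "+")))
  }
})

test_that("distractor reactions never appear in any minimal solution", {
  lesions <- list("NAR", c("VS1", "VS2"), c("ALS1", "ALS2"))
  for (les in lesions) {
    bf <- bruteForceGapfill(dropReactions(fx_ph, les), fx_db,
                            autotrophicMedia(), max_size = 3)
    sel <- unique(unlist(bf))
    expect_false(any(c("LDH", "DST1", "DST2") %in% sel))
  }
})

test_that("unreachable targets error (gapfill) / return empty (oracle)", {
  broken <- dropReactions(fx_het, "T_ac")   # no carbon importer left at all
  db <- dbSubset(fx_db, c("LDH", "DST1", "DST2"))
  expect_error(gapfill(broken, db, acetateMinimalMedia()), "no gapfill solution")
  expect_length(bruteForceGapfill(broken, db, acetateMinimalMedia(),
                                  max_size = 3), 0)
})

test_that("media monotonicity: richer media never needs a costlier repair", {
  variants <- list(c("T_glc"), c("T_glc", "ALS1", "ALS2"),
                   c("T_glc", "VS1", "VS2"))
  for (dels in variants) {
    het <- makeToyHeterotroph(fixtureSpec(hetDeletions = dels))
    on_min <- gapfill(het, fx_db, glucoseMinimalMedia())
    on_rich <- gapfill(het, fx_db, richMedia())
    expect_lte(totalCost(on_rich), totalCost(on_min))
  }
})

test_that("community gapfilling delegates to the partner (cross-feeding)", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  res <- communityGapfill(cm, fx_db, autotrophicMedia())
  adds <- addedReactions(res)
  # the repair is pure cross-feeding: three transporters, no biosynthesis
  expect_equal(totalCost(res), 3)
  expect_setequal(adds$id, c("TPT_glc", "TPT_ala", "TPT_vit"))
  # exporters sit in the phototroph compartment, the importer in the
  # heterotroph compartment
  expect_equal(sort(adds$compartment), c("c1", "c1", "c2"))
  # strictly cheaper than making the heterotroph self-sufficient
  solo <- gapfill(fx_het, fx_db, autotrophicMedia())
  expect_equal(totalCost(solo), 9)
  expect_lt(totalCost(res), totalCost(solo))
  # community cost <= sum of individual costs on the same media
  solo_ph <- gapfill(fx_ph, fx_db, autotrophicMedia())
  expect_lte(totalCost(res), totalCost(solo) + totalCost(solo_ph))
  # and strictly between the cheapest member repair and the sum
  expect_gt(totalCost(res), min(totalCost(solo), totalCost(solo_ph)))
  expect_lt(totalCost(res), totalCost(solo) + totalCost(solo_ph))
})

test_that("mixed-bag community needs fewer gapfilled reactions", {
  mb <- buildMixedBag(list(fx_ph, fx_het))$model
  res_mb <- communityGapfill(mb, fx_db, autotrophicMedia())
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  res_cm <- communityGapfill(cm, fx_db, autotrophicMedia())
  expect_lt(totalCost(res_mb), totalCost(res_cm))
  # pooled enzymes make the merged drafts autotrophic outright
  expect_equal(totalCost(res_mb), 0)
})

test_that("iterative gapfilling accumulates repairs across media", {
  out <- gapfillIterative(fx_het, fx_db,
                          list(glucoseMinimalMedia(), autotrophicMedia()))
  expect_length(out, 2)
  final <- out[[2]]@model
  expect_true(predictGrowth(final, glucoseMinimalMedia())$growth)
  expect_true(predictGrowth(final, autotrophicMedia())$growth)
  # a second round on already-covered media adds nothing
  again <- gapfill(final, fx_db, glucoseMinimalMedia())
  expect_equal(totalCost(again), 0)
  # single media behaves exactly like plain gapfill
  one <- gapfillIterative(fx_het, fx_db, list(glucoseMinimalMedia()))
  direct <- gapfill(fx_het, fx_db, glucoseMinimalMedia())
  expect_equal(sort(addedReactions(one[[1]])$reaction_id),
               sort(addedReactions(direct)$reaction_id))
})

test_that("added reactions are tagged gapfilled and carry direction", {
  res <- communityGapfill(buildCompartmentalized(list(fx_ph, fx_het))$model,
                          fx_db, autotrophicMedia())
  adds <- addedReactions(res)
  expect_true(all(adds$direction %in% c("fwd", "rev")))
  rx <- reactions(res@model)
  expect_true(all(rx$source_tag[rx$id %in% adds$reaction_id] == "gapfilled"))
})

test_that("strategy A fails loudly when a member cannot be repaired alone", {
  # no database entries can give the heterotroph a carbon source on
  # autotrophic media if even the photon transporter template is withheld
  db <- dbSubset(fx_db, c("LDH", "DST1", "DST2"))
  expect_error(
    runStrategy(list(fx_ph, fx_het), db,
                memberMedia = list(autotrophicMedia(), glucoseMinimalMedia()),
                communityMedia = autotrophicMedia(), strategy = "A"),
    "pre-gapfilling")
})

test_that("strategies A, B, C reproduce the interaction-count ordering", {
  A <- runStrategy(list(fx_ph, fx_het), fx_db,
                   memberMedia = list(autotrophicMedia(), glucoseMinimalMedia()),
                   communityMedia = autotrophicMedia(), strategy = "A")
  B <- runStrategy(list(fx_ph, fx_het), fx_db,
                   communityMedia = autotrophicMedia(), strategy = "B")
  C <- runStrategy(list(fx_ph, fx_het), fx_db, memberMedia = richMedia(),
                   communityMedia = autotrophicMedia(), strategy = "C")
  # all three models grow as communities
  for (s in list(A, B, C))
    expect_true(predictGrowth(s$model, autotrophicMedia())$growth)
  nA <- nrow(identifyInteractions(A$model, autotrophicMedia()))
  nB <- nrow(identifyInteractions(B$model, autotrophicMedia()))
  nC <- nrow(identifyInteractions(C$model, autotrophicMedia()))
  # more community-level gapfilling => at least as many predicted exchanges
  expect_lte(nA, nB)
  expect_lte(nB, nC)
  # pre-gapfilling alone predicts strictly fewer exchanges here
  expect_lt(nA, nB)
  # strategy B's community repair is the cross-feeding solution
  expect_setequal(addedReactions(B$results$cgf_compartments)$id,
                  c("TPT_glc", "TPT_ala", "TPT_vit"))
  # strategy provenance labels
  expect_equal(B$results$cgf_compartments@strategy, "cgf")
  expect_equal(C$results$cgf_compartments@strategy, "igf+cgf")
  expect_equal(A$results$igf_heterotroph@strategy, "igf")
})

test_that("brute-force guard rejects oversized databases", {
  big <- fx_db
  # inflate by relabeling entries until past the guard
  extra <- big@reactions
  extra$id <- paste0(extra$id, "_x")
  st2 <- big@stoich; st2$reaction <- paste0(st2$reaction, "_x")
  inflated <- ReactionDatabase(rbind(big@reactions, extra),
                               rbind(big@stoich, st2), big@compounds,
                               big@transporterCompounds)
  expect_error(bruteForceGapfill(fx_het, inflated, glucoseMinimalMedia()),
               "guard")
})
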