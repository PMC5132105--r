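# Merging member models into mixed-bag and compartmentalized communities.

test_that("mergeBiomass sums and rescales coefficients", {
  out <- mergeBiomass(list(c(X = -1, ATP = -2, bio = 1),
                           c(X = -1, Y = -3, bio = 1)), n = 2)
  expect_equal(out[sort(names(out))],
               c(ATP = -1, bio = 1, X = -1, Y = -1.5)[sort(c("ATP", "bio", "X", "Y"))])
  # single member is the identity
  one <- c(A = -2, bio = 1)
  expect_equal(mergeBiomass(list(one), 1), one)
  # two identical biomasses halve back to the original
  expect_equal(mergeBiomass(list(one, one), 2), one)
  expect_error(mergeBiomass(list(one), 0), "n must be")
})

test_that("merging a model with itself leaves the reaction count unchanged", {
  mb <- buildMixedBag(list(fx_ph, fx_ph))
  # every non-biomass reaction collapses onto its duplicate
  expect_equal(nrow(reactions(mb$model)), nrow(reactions(fx_ph)))
  # self-duplicate GPRs are OR-merged without bloat ("g" or "g" stays "g")
  gpr_orig <- setNames(reactions(fx_ph)$gpr, reactions(fx_ph)$id)
  gpr_merged <- setNames(reactions(mb$model)$gpr, reactions(mb$model)$id)
  shared <- intersect(names(gpr_orig), names(gpr_merged))
  expect_identical(gpr_merged[setdiff(shared, "BIO")],
                   gpr_orig[setdiff(shared, "BIO")])
})

test_that("mixed-bag duplicate collapse, bound union and gene preservation", {
  mb <- buildMixedBag(list(fx_ph, fx_het))
  m <- mb$model
  n_members <- nrow(reactions(fx_ph)) + nrow(reactions(fx_het))
  # duplicate count identity: members - merged (biomasses merge 2 -> 1)
  expect_equal(nrow(reactions(m)), n_members - mb$report$duplicates - 1L)
  expect_lte(nrow(reactions(m)), n_members)
  # genes are preserved: community gene set = union of member gene sets
  expect_setequal(genes(m), union(genes(fx_ph), genes(fx_het)))
  # the shared CO2 uniport merged with union-interval bounds:
  # both members are reversible here, and the merged copy must be too
  rx <- reactions(m)
  expect_equal(unname(unlist(rx[rx$id == "T_co2", c("lb", "ub")])),
               c(-100, 100))
  # GPRs of merged duplicates are OR-unions
  expect_match(rx$gpr[rx$id == "T_nh3"], "gP05")
  expect_match(rx$gpr[rx$id == "T_nh3"], "gH02")
  # single community biomass, the default objective
  expect_equal(m@communityBiomassId, "bio_community")
  expect_equal(biomassIds(m), "bio_community")
})

test_that("mixed-bag merge of disjoint models equals the sum of counts", {
  # two disjoint chains cannot share any canonical reaction
  a <- chainModel()
  b <- chainModel()
  b@id <- "chain2"
  b@reactions$id <- paste0(b@reactions$id, "2")
  b@metabolites$id <- sub("^A", "C", sub("^B", "D", b@metabolites$id))
  rownames(b@S) <- b@metabolites$id
  colnames(b@S) <- b@reactions$id
  b@biomassIds <- "BIO2"
  mb <- buildMixedBag(list(a, b))
  expect_equal(mb$report$duplicates, 0L)
  expect_equal(nrow(reactions(mb$model)),
               nrow(reactions(a)) + nrow(reactions(b)) - 1L)  # merged biomass
})

test_that("compartmentalized build wires species compartments and coupling", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))
  m <- cm$model
  expect_s4_class(m, "CommunityModel")
  expect_equal(m@nMembers, 2L)
  expect_setequal(compartments(m)$id, c("c1", "c2", "e0"))
  expect_equal(sum(compartments(m)$label == "extracellular"), 1L)
  # shared exchanges collapse; species transporters stay distinct
  rx <- reactions(m)
  expect_equal(sum(rx$id == "EX_glc"), 1L)
  expect_true(all(c("T_nh3_sp1", "T_nh3_sp2") %in% rx$id))
  # community biomass drains 1/N of each member pseudo-biomass
  st <- CommFBA:::reactionStoich(m, "bio_community")
  expect_equal(sort(names(st)), c("biomass_sp1_c1", "biomass_sp2_c2"))
  expect_equal(unname(st), c(-0.5, -0.5))
  # the drafts cannot grow together on autotrophic media (heterotroph
  # lacks any carbon importer), so 1/N coupling zeroes community biomass
  g <- predictGrowth(m, autotrophicMedia())
  expect_false(g$growth)
  expect_lt(abs(g$objective), 1e-9)
  # but the phototroph alone grows on the same media
  expect_true(predictGrowth(fx_ph, autotrophicMedia())$growth)
})

test_that("member extraction round-trips the compartmentalized merge", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  for (member in list(fx_ph, fx_het)) {
    back <- extractMember(cm, modelId(member))
    r0 <- reactions(member); r1 <- reactions(back)
    expect_setequal(r1$id, r0$id)
    r1 <- r1[match(r0$id, r1$id), ]
    expect_equal(r1$lb, r0$lb)
    expect_equal(r1$ub, r0$ub)
    expect_equal(r1$gpr, r0$gpr)
    # identical stoichiometry for every reaction
    for (rid in r0$id) {
      s0 <- CommFBA:::reactionStoich(member, rid)
      s1 <- CommFBA:::reactionStoich(back, rid)
      expect_equal(s1[sort(names(s1))], s0[sort(names(s0))],
                   label = paste("stoich of", rid))
    }
    expect_equal(biomassIds(back), biomassIds(member))
  }
})

test_that("compartmentalized merge needs at least two members", {
  expect_error(buildCompartmentalized(list(fx_ph)), "two member")
  expect_error(buildMixedBag(list()), "at least one")
})

test_that("community model JSON round trip preserves the community block", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  path <- tempfile(fileext = ".json")
  writeModelJSON(cm, path)
  back <- readModelJSON(path)
  expect_s4_class(back, "CommunityModel")
  expect_equal(back@nMembers, cm@nMembers)
  expect_equal(back@speciesIndex, cm@speciesIndex)
  expect_equal(back@memberBiomassIds, cm@memberBiomassIds)
  expect_equal(sort(reactions(back)$id), sort(reactions(cm)$id))
})
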