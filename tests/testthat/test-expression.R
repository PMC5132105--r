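# Expression integration: threshold calls, reaction activity, flux fitting
# and consistency reporting.

test_that("threshold is the stated percentile of universal-role values", {
  # all universal genes at 100: threshold 100; ties are called on
  vals <- c(u1 = 100, u2 = 100, u3 = 100, low = 5, high = 200, tie = 100)
  prof <- callGeneActivity(vals, c("u1", "u2", "u3"))
  expect_equal(activityThreshold(prof), 100)
  expect_equal(unname(activityCalls(prof)[c("low", "high", "tie")]),
               c("off", "on", "on"))

  # universal values 1..80: the 10th percentile interpolates to 8.9
  vals2 <- setNames(1:80, sprintf("u%02d", 1:80))
  vals2 <- c(vals2, g_below = 8, g_above = 9)
  prof2 <- callGeneActivity(vals2, sprintf("u%02d", 1:80))
  # oracle: the interpolation formula computed independently
  k <- 0.10 * (80 - 1) + 1
  want <- floor(k) + (k - floor(k)) * 1   # sorted values are 1..80
  expect_equal(activityThreshold(prof2), want)
  expect_equal(activityThreshold(prof2), 8.9)
  expect_equal(unname(activityCalls(prof2)[c("g_below", "g_above")]),
               c("off", "on"))
})

test_that("fewer than two universal genes with values is an error", {
  expect_error(callGeneActivity(c(a = 1, b = 2), c("a", "zz")),
               "at least two universal")
})

test_that("reaction activity: OR, AND, decisive unknown, empty GPR", {
  m <- chainModel()
  m@reactions$gpr <- c("", "g1 or g2", "g1 and g2", "g1 and g3")
  calls <- c(g1 = "on", g2 = "off")     # g3 unprofiled -> unknown
  act <- reactionActivity(m, calls)
  expect_equal(unname(act), c("unknown", "active", "inactive", "unknown"))
})

test_that("genes absent from the profile are unknown", {
  prof <- callGeneActivity(c(u1 = 10, u2 = 20, g = 30), c("u1", "u2"))
  act <- reactionActivity(
    {
      m <- chainModel(); m@reactions$gpr <- c("", "", "gAbsent", "g"); m
    }, prof)
  expect_equal(unname(act[3]), "unknown")
  expect_equal(unname(act[4]), "active")
})

test_that("transcriptomic FBA attains full agreement when calls are flux-consistent", {
  ep <- makeExpressionProfile(fx_ph, fixtureSpec(seed = 11, noise = 0),
                              autotrophicMedia())
  prof <- callGeneActivity(ep$values, ep$universal)
  act <- reactionActivity(fx_ph, prof)
  fit <- transcriptomicFBA(fx_ph, autotrophicMedia(), act)
  expect_equal(fit$nAgree, fit$nClassified)
  expect_gte(fit$solution@objective, 0.01)
})

test_that("an inactive reaction that is the sole route still carries flux", {
  # call the phototroph's only nitrogen route inactive: biomass needs it,
  # so the fit sacrifices exactly that one agreement
  ep <- makeExpressionProfile(fx_ph, fixtureSpec(seed = 11, noise = 0),
                              autotrophicMedia())
  prof <- callGeneActivity(ep$values, ep$universal)
  act <- reactionActivity(fx_ph, prof)
  act["NAR"] <- "inactive"
  fit <- transcriptomicFBA(fx_ph, autotrophicMedia(), act)
  expect_equal(fit$nAgree, fit$nClassified - 1L)
  expect_false(fit$agreement[["NAR"]])
  expect_gt(abs(fit$solution@fluxes[["NAR"]]), 1e-6)
  expect_gte(fit$solution@objective, 0.01)
})

test_that("epsilon = 0 makes the biomass constraint vacuous: everything
           called inactive is silenced", {
  # limit case: every GPR-bearing reaction called inactive; without a
  # biomass floor nothing forces flux, so the fit shuts the network down
  act <- reactionActivity(fx_ph, character(0))
  act[act == "unknown" & nzchar(reactions(fx_ph)$gpr)] <- "inactive"
  fit <- transcriptomicFBA(fx_ph, autotrophicMedia(), act, epsilon = 0)
  inact <- names(act)[act == "inactive"]
  expect_true(all(abs(fit$solution@fluxes[inact]) < 1e-9))
  expect_equal(fit$nAgree, fit$nClassified)
  # the same calls with a biomass floor cannot all be honored
  fit2 <- transcriptomicFBA(fx_ph, autotrophicMedia(), act, epsilon = 0.01)
  expect_lt(fit2$nAgree, fit2$nClassified)
  expect_gte(fit2$solution@objective, 0.01)
})

test_that("fitting never reduces agreement below plain pFBA", {
  ep <- makeExpressionProfile(fx_ph, fixtureSpec(seed = 3, noise = 1),
                              autotrophicMedia())
  prof <- callGeneActivity(ep$values, ep$universal)
  act <- reactionActivity(fx_ph, prof)
  fit <- transcriptomicFBA(fx_ph, autotrophicMedia(), act)
  pfba <- runFBA(fx_ph, autotrophicMedia(), parsimonious = TRUE)
  rep_fit <- consistencyReport(fit$solution, act, fx_ph)
  rep_pfba <- consistencyReport(pfba, act, fx_ph)
  agree <- function(r) r@counts[["+F+E"]] + r@counts[["-F-E"]]
  expect_gte(agree(rep_fit), agree(rep_pfba))
})

test_that("consistency report categories sum to 100 and accuracies follow", {
  ep <- makeExpressionProfile(fx_ph, fixtureSpec(seed = 5, noise = 1),
                              autotrophicMedia())
  prof <- callGeneActivity(ep$values, ep$universal)
  act <- reactionActivity(fx_ph, prof)
  fit <- transcriptomicFBA(fx_ph, autotrophicMedia(), act)
  rep <- consistencyReport(fit$solution, act, fx_ph)
  p <- categoryPercentages(rep)
  expect_equal(sum(p), 100, tolerance = 0.2)
  a <- accuracies(rep)
  expect_equal(a[["overall"]], p[["+F+E"]] + p[["-F-E"]], tolerance = 0.2)
  cnt <- rep@counts
  expect_equal(a[["active"]],
               100 * cnt[["+F+E"]] / (cnt[["+F+E"]] + cnt[["-F+E"]]))
  expect_equal(a[["inactive"]],
               100 * cnt[["-F-E"]] / (cnt[["-F-E"]] + cnt[["+F-E"]]))
})

test_that("degenerate denominators give NA accuracies, not errors", {
  a <- accuracyFromCategories(100, 0, 0, 0)
  expect_equal(a[["active"]], 100)
  expect_true(is.na(a[["inactive"]]))
  expect_equal(a[["overall"]], 100)
})

test_that("per-pathway breakdown counts active gapfilled reactions", {
  cm <- buildCompartmentalized(list(fx_ph, fx_het))$model
  gf <- communityGapfill(cm, fx_db, autotrophicMedia())
  model <- gf@model
  ep <- makeExpressionProfile(fx_ph, fixtureSpec(seed = 11, noise = 0),
                              autotrophicMedia())
  prof <- callGeneActivity(ep$values, ep$universal)
  act <- reactionActivity(model, prof)
  sol <- runFBA(model, autotrophicMedia(), parsimonious = TRUE)
  rep <- consistencyReport(sol, act, model)
  pw <- pathwayBreakdown(rep)
  # the three gapfilled transporters all carry flux (obligate cross-feeding)
  expect_equal(sum(pw$gapfilled_active), 3)
  expect_true("transport" %in% pw$pathway)
})

test_that("expression TSV written by the fixtures reads back identically", {
  dir <- tempfile(); dir.create(dir)
  write.table(makeExpressionProfile(fx_ph, fixtureSpec(seed = 2))$table,
              file.path(dir, "e.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tab <- read.delim(file.path(dir, "e.tsv"))
  vals <- setNames(tab$value, tab$gene)
  ref <- makeExpressionProfile(fx_ph, fixtureSpec(seed = 2))$values
  expect_equal(vals[names(ref)], ref, tolerance = 1e-9)
})
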