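# Synthetic phototroph-heterotroph consortium fixtures.
#
# A compact, fully balanced toy consortium emulating a thermophilic
# cyanobacterium feeding an obligate aerobic heterotroph: the phototroph
# fixes CO2 and nitrate photosynthetically and can secrete sugar, ammonia
# and O2; the heterotroph catabolizes sugars aerobically but lacks the
# nitrate pathway, its sugar importer, and amino-acid/vitamin synthesis,
# so on autotrophic media it can only grow through phototroph-derived
# organic carbon, fixed nitrogen, vitamins and O2. Energy and redox
# carriers use single-letter pseudo-elements (ATP = "AP", ADP = "A",
# Pi = "P"; NADP(H) = "Q"/"QH2"; NAD(H) = "R"/"RH2") so that every
# non-exchange, non-biomass reaction is elementally balanced.

FIXTURE_COMPOUNDS <- data.frame(
  id      = c("photon", "co2", "o2", "h2o", "no3", "nh3", "glc", "pyr",
              "ac", "ala", "ima", "pvit", "vit", "lac", "dsta", "dstb",
              "atp", "adp", "pi", "nadp", "nadph", "nad", "nadh"),
  name    = c("photon", "carbon dioxide", "oxygen", "water", "nitrate",
              "ammonia", "glucose", "pyruvate", "acetate", "alanine",
              "alanine imine precursor", "provitamin", "vitamin B-like cofactor",
              "lactate", "distractor A", "distractor B",
              "ATP", "ADP", "phosphate", "NADP", "NADPH", "NAD", "NADH"),
  formula = c("", "CO2", "O2", "H2O", "HNO3", "H3N", "C6H12O6", "C3H4O3",
              "C2H4O2", "C3H7NO2", "C3H5NO2", "C6H12N2O3", "C6H14N2O4",
              "C3H6O3", "C4H8O4", "C4H8O4",
              "AP", "A", "P", "Q", "QH2", "R", "RH2"),
  stringsAsFactors = FALSE
)

EXTRACELLULAR_COMPOUNDS <- c("photon", "co2", "o2", "h2o", "no3", "nh3",
                             "glc", "ala", "vit", "ac")

#' Fixture generation parameters
#'
#' @param seed random seed; the same seed yields byte-identical fixtures.
#' @param noise log-scale standard deviation of the expression bands
#'   (0.3 separates active/inactive cleanly; around 1.0 the bands overlap
#'   by roughly 10 percent).
#' @param hetDeletions reaction ids absent from the heterotroph draft (its
#'   annotation gaps); defaults to the sugar importer, amino-acid synthesis
#'   and vitamin synthesis.
#' @param photoSecretion compounds the phototroph draft can exchange with
#'   the environment through reversible transporters.
#' @return a list of class "FixtureSpec".
#' @export
fixtureSpec <- function(seed = 1L, noise = 0.3,
                        hetDeletions = c("T_glc", "ALS1", "ALS2", "VS1", "VS2"),
                        photoSecretion = c("glc", "nh3", "o2")) {
  structure(list(seed = as.integer(seed), noise = noise,
                 hetDeletions = hetDeletions,
                 photoSecretion = photoSecretion),
            class = "FixtureSpec")
}

fixtureMets <- function(compounds, compartment) {
  tab <- FIXTURE_COMPOUNDS[match(compounds, FIXTURE_COMPOUNDS$id), ]
  data.frame(id = paste0(tab$id, "_", compartment), name = tab$name,
             formula = tab$formula, charge = 0L, compartment = compartment,
             stringsAsFactors = FALSE)
}

# helper: named stoichiometry in the cytosol ("c1") / extracellular ("e0")
cyt <- function(...) {
  x <- c(...); setNames(unname(x), paste0(names(x), "_c1"))
}
exc <- function(...) {
  x <- c(...); setNames(unname(x), paste0(names(x), "_e0"))
}

fixtureModel <- function(id, rxn_list, cyt_compounds) {
  rxns <- do.call(rbind, lapply(rxn_list, function(r)
    data.frame(id = r$id, name = r$name, lb = r$lb, ub = r$ub, gpr = r$gpr,
               pathway = r$pathway, source_tag = r$tag,
               stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(rxn_list, function(r)
    data.frame(reaction = r$id, metabolite = names(r$st), coef = unname(r$st),
               stringsAsFactors = FALSE)))
  mets <- rbind(fixtureMets(cyt_compounds, "c1"),
                fixtureMets(EXTRACELLULAR_COMPOUNDS, "e0"))
  cmp <- data.frame(id = c("c1", "e0"), label = c("cytosol", "extracellular"),
                    species_index = c(1L, 0L), stringsAsFactors = FALSE)
  bio <- rxns$id[rxns$source_tag == "biomass"]
  MetabolicModel(id, cmp, mets, rxns, st, biomassIds = bio)
}

rxn <- function(id, name, st, gpr = "", pathway = NA_character_,
                lb = 0, ub = BIG_FLUX, tag = "draft") {
  list(id = id, name = name, st = st, gpr = gpr, pathway = pathway,
       lb = lb, ub = ub, tag = tag)
}

exchangeRxns <- function() {
  lapply(EXTRACELLULAR_COMPOUNDS, function(cpd)
    rxn(paste0("EX_", cpd), paste0("exchange of ", cpd),
        exc(setNames(-1, cpd)), tag = "exchange"))
}

#' Generate the toy phototroph model
#'
#' A ~15-core-reaction photoautotroph: photon, CO2 and nitrate uptake, a
#' lumped photosystem producing ATP/NADPH/O2, carbon fixation to glucose,
#' nitrate reduction to ammonia, amino-acid and vitamin synthesis, and a
#' biomass drain. Reversible transporters for the secreted compounds
#' (default glucose, ammonia, O2) let it feed a partner. It grows on
#' autotrophic media by construction, and every non-exchange, non-biomass
#' reaction is elementally balanced.
#'
#' @param spec a [fixtureSpec()].
#' @return a [MetabolicModel-class].
#' @export
makeToyPhototroph <- function(spec = fixtureSpec()) {
  rl <- list(
    rxn("T_photon", "photon uptake", c(exc(photon = -1), cyt(photon = 1)),
        "gP01", "transport", tag = "transport"),
    rxn("T_co2", "CO2 uniport", c(cyt(co2 = -1), exc(co2 = 1)),
        "gP02", "transport", lb = -BIG_FLUX, tag = "transport"),
    rxn("T_no3", "nitrate uptake", c(exc(no3 = -1), cyt(no3 = 1)),
        "gP03", "transport", tag = "transport"),
    rxn("T_h2o", "water transport", c(cyt(h2o = -1), exc(h2o = 1)),
        "", "transport", lb = -BIG_FLUX, tag = "transport"),
    rxn("PSII", "photosystem (lumped light reactions)",
        cyt(photon = -4, h2o = -2, nadp = -2, adp = -4, pi = -4,
            o2 = 1, nadph = 2, atp = 4),
        "gP07 and gP08", "photosynthesis"),
    rxn("CBB", "carbon fixation (lumped CBB cycle)",
        cyt(co2 = -6, nadph = -12, atp = -18,
            glc = 1, nadp = 12, adp = 18, pi = 18, h2o = 6),
        "gP09", "carbon fixation"),
    rxn("NAR", "assimilatory nitrate reduction",
        cyt(no3 = -1, nadph = -4, nh3 = 1, nadp = 4, h2o = 3),
        "gP10", "nitrogen assimilation"),
    rxn("GLY", "glycolysis (lumped)",
        cyt(glc = -1, nad = -2, adp = -2, pi = -2,
            pyr = 2, nadh = 2, atp = 2),
        "gP11", "glycolysis"),
    rxn("ALS1", "alanine synthesis I (amination)",
        cyt(pyr = -1, nh3 = -1, ima = 1, h2o = 1),
        "gP12 or gP13", "amino acid synthesis"),
    rxn("ALS2", "alanine synthesis II (reduction)",
        cyt(ima = -1, nadh = -1, ala = 1, nad = 1),
        "gP14", "amino acid synthesis"),
    rxn("VS1", "vitamin synthesis I (condensation)",
        cyt(ala = -2, pvit = 1, h2o = 1),
        "gP15", "vitamin synthesis"),
    rxn("VS2", "vitamin synthesis II (hydration)",
        cyt(pvit = -1, h2o = -1, vit = 1),
        "gP16", "vitamin synthesis"),
    rxn("ATPM", "ATP maintenance", cyt(atp = -1, adp = 1, pi = 1),
        "", "energy"),
    rxn("BIO", "phototroph biomass",
        cyt(glc = -0.5, ala = -2, vit = -0.1, atp = -10, adp = 10, pi = 10),
        "", "biomass", tag = "biomass")
  )
  sec <- list(
    glc = rxn("T_glc", "sugar uniport", c(cyt(glc = -1), exc(glc = 1)),
              "gP06", "transport", lb = -BIG_FLUX, tag = "transport"),
    nh3 = rxn("T_nh3", "ammonia uniport", c(cyt(nh3 = -1), exc(nh3 = 1)),
              "gP05", "transport", lb = -BIG_FLUX, tag = "transport"),
    o2 = rxn("T_o2", "O2 uniport", c(cyt(o2 = -1), exc(o2 = 1)),
             "gP04", "transport", lb = -BIG_FLUX, tag = "transport"),
    ala = rxn("T_ala", "alanine uniport", c(cyt(ala = -1), exc(ala = 1)),
              "gP17", "transport", lb = -BIG_FLUX, tag = "transport"),
    vit = rxn("T_vit", "vitamin uniport", c(cyt(vit = -1), exc(vit = 1)),
              "gP18", "transport", lb = -BIG_FLUX, tag = "transport")
  )
  rl <- c(rl, unname(sec[spec$photoSecretion]), exchangeRxns())
  fixtureModel("phototroph", rl,
               c("photon", "co2", "o2", "h2o", "no3", "nh3", "glc", "pyr",
                 "ala", "ima", "pvit", "vit", "atp", "adp", "pi",
                 "nadp", "nadph", "nad", "nadh"))
}

#' Generate the toy heterotroph model
#'
#' A ~12-core-reaction obligate aerobic heterotroph: acetate and sugar
#' catabolism through glycolysis and aerobic respiration, importers for
#' ammonia, O2, alanine and the vitamin, and a biomass drain. The
#' annotation gaps listed in the fixture spec (by default the sugar importer,
#' amino-acid synthesis and vitamin synthesis) are absent, and there is no
#' nitrate assimilation at all, so the draft grows on acetate-containing
#' rich media but not on autotrophic media.
#'
#' @param spec a [fixtureSpec()].
#' @return a [MetabolicModel-class].
#' @export
makeToyHeterotroph <- function(spec = fixtureSpec()) {
  rl <- list(
    rxn("T_ac", "acetate uptake", c(exc(ac = -1), cyt(ac = 1)),
        "gH01", "transport", tag = "transport"),
    rxn("T_nh3", "ammonia uniport", c(cyt(nh3 = -1), exc(nh3 = 1)),
        "gH02", "transport", lb = -BIG_FLUX, tag = "transport"),
    rxn("T_o2", "O2 uniport", c(cyt(o2 = -1), exc(o2 = 1)),
        "gH03", "transport", lb = -BIG_FLUX, tag = "transport"),
    rxn("T_co2", "CO2 uniport", c(cyt(co2 = -1), exc(co2 = 1)),
        "gH04", "transport", lb = -BIG_FLUX, tag = "transport"),
    rxn("T_h2o", "water transport", c(cyt(h2o = -1), exc(h2o = 1)),
        "", "transport", lb = -BIG_FLUX, tag = "transport"),
    rxn("T_ala", "alanine uptake", c(exc(ala = -1), cyt(ala = 1)),
        "gH05", "transport", tag = "transport"),
    rxn("T_vit", "vitamin uptake", c(exc(vit = -1), cyt(vit = 1)),
        "gH06", "transport", tag = "transport"),
    rxn("T_glc", "sugar uptake", c(exc(glc = -1), cyt(glc = 1)),
        "gH12", "transport", tag = "transport"),
    rxn("GLY", "glycolysis (lumped)",
        cyt(glc = -1, nad = -2, adp = -2, pi = -2,
            pyr = 2, nadh = 2, atp = 2),
        "gH07", "glycolysis"),
    rxn("ACS", "acetate assimilation",
        cyt(ac = -3, atp = -3, nad = -2, pyr = 2, nadh = 2,
            adp = 3, pi = 3),
        "gH08", "acetate utilization"),
    rxn("RESP", "pyruvate respiration",
        cyt(pyr = -2, o2 = -5, adp = -20, pi = -20,
            co2 = 6, h2o = 4, atp = 20),
        "gH09 and gH10", "respiration"),
    rxn("NDH", "NADH oxidase",
        cyt(nadh = -2, o2 = -1, adp = -4, pi = -4,
            nad = 2, h2o = 2, atp = 4),
        "gH11", "respiration"),
    rxn("ALS1", "alanine synthesis I (amination)",
        cyt(pyr = -1, nh3 = -1, ima = 1, h2o = 1),
        "gH13", "amino acid synthesis"),
    rxn("ALS2", "alanine synthesis II (reduction)",
        cyt(ima = -1, nadh = -1, ala = 1, nad = 1),
        "gH14", "amino acid synthesis"),
    rxn("VS1", "vitamin synthesis I (condensation)",
        cyt(ala = -2, pvit = 1, h2o = 1),
        "gH15", "vitamin synthesis"),
    rxn("VS2", "vitamin synthesis II (hydration)",
        cyt(pvit = -1, h2o = -1, vit = 1),
        "gH16", "vitamin synthesis"),
    rxn("ATPM", "ATP maintenance", cyt(atp = -1, adp = 1, pi = 1),
        "", "energy"),
    rxn("BIO", "heterotroph biomass",
        cyt(ala = -3, vit = -0.1, atp = -10, adp = 10, pi = 10),
        "", "biomass", tag = "biomass")
  )
  keep <- vapply(rl, function(r) !r$id %in% spec$hetDeletions, logical(1))
  rl <- c(rl[keep], exchangeRxns())
  fixtureModel("heterotroph", rl,
               c("co2", "o2", "h2o", "nh3", "glc", "pyr", "ac", "ala",
                 "ima", "pvit", "vit", "atp", "adp", "pi", "nad", "nadh"))
}

#' Generate the toy candidate reaction database
#'
#' Contains (a) the reactions deleted from the heterotroph draft, (b) a
#' multi-reaction photoautotrophy alternative (photosystem + carbon
#' fixation, with a photon transporter template), (c) nitrate assimilation,
#' (d) transporter templates for the consortium-relevant compounds, and
#' (e) three distractor reactions that can never appear in a minimal
#' repair. Fifteen entries in total, small enough for the brute-force
#' oracle to enumerate exhaustively.
#'
#' @param spec a [fixtureSpec()].
#' @return a [ReactionDatabase-class].
#' @export
makeToyDatabase <- function(spec = fixtureSpec()) {
  dbr <- function(id, name, compound, coef, pathway, lb = 0, ub = BIG_FLUX) {
    list(id = id, name = name, pathway = pathway, lb = lb, ub = ub,
         st = data.frame(reaction = id, compound = compound,
                         role = "c", coef = coef, stringsAsFactors = FALSE))
  }
  entries <- list(
    dbr("ALS1", "alanine synthesis I (amination)",
        c("pyr", "nh3", "ima", "h2o"), c(-1, -1, 1, 1), "amino acid synthesis"),
    dbr("ALS2", "alanine synthesis II (reduction)",
        c("ima", "nadh", "ala", "nad"), c(-1, -1, 1, 1), "amino acid synthesis"),
    dbr("VS1", "vitamin synthesis I (condensation)",
        c("ala", "pvit", "h2o"), c(-2, 1, 1), "vitamin synthesis"),
    dbr("VS2", "vitamin synthesis II (hydration)",
        c("pvit", "h2o", "vit"), c(-1, -1, 1), "vitamin synthesis"),
    dbr("PSII", "photosystem (lumped light reactions)",
        c("photon", "h2o", "nadp", "adp", "pi", "o2", "nadph", "atp"),
        c(-4, -2, -2, -4, -4, 1, 2, 4), "photosynthesis"),
    dbr("CBB", "carbon fixation (lumped CBB cycle)",
        c("co2", "nadph", "atp", "glc", "nadp", "adp", "pi", "h2o"),
        c(-6, -12, -18, 1, 12, 18, 18, 6), "carbon fixation"),
    dbr("NAR", "assimilatory nitrate reduction",
        c("no3", "nadph", "nh3", "nadp", "h2o"),
        c(-1, -4, 1, 4, 3), "nitrogen assimilation"),
    dbr("LDH", "lactate dehydrogenase (distractor)",
        c("pyr", "nadh", "lac", "nad"), c(-1, -1, 1, 1), "fermentation"),
    dbr("DST1", "distractor isomerase A->B",
        c("dsta", "dstb"), c(-1, 1), "distractor"),
    dbr("DST2", "distractor isomerase B->A",
        c("dstb", "dsta"), c(-1, 1), "distractor")
  )
  reactions <- do.call(rbind, lapply(entries, function(e)
    data.frame(id = e$id, name = e$name, lb = e$lb, ub = e$ub,
               pathway = e$pathway, stringsAsFactors = FALSE)))
  stoich <- do.call(rbind, lapply(entries, `[[`, "st"))
  ReactionDatabase(reactions, stoich, FIXTURE_COMPOUNDS,
                   transporterCompounds = c("glc", "ala", "vit", "no3",
                                            "photon"))
}

#' Standard fixture media conditions
#'
#' `autotrophicMedia()` supplies only light, CO2, nitrate and water;
#' `glucoseMinimalMedia()` glucose, ammonia, O2 and water;
#' `acetateMinimalMedia()` the heterotroph's native regime plus alanine
#' and vitamin; `richMedia()` everything. Excretion is open (100) for all
#' listed compounds.
#'
#' @return a [MediaCondition-class].
#' @export
autotrophicMedia <- function() {
  MediaCondition("autotrophic", c("photon", "co2", "no3", "h2o"),
                 max_uptake = c(100, 20, 10, 100))
}

#' @rdname autotrophicMedia
#' @export
glucoseMinimalMedia <- function() {
  MediaCondition("glucose_minimal", c("glc", "nh3", "o2", "h2o"),
                 max_uptake = c(10, 10, 20, 100))
}

#' @rdname autotrophicMedia
#' @export
acetateMinimalMedia <- function() {
  MediaCondition("acetate_minimal", c("ac", "nh3", "o2", "ala", "vit", "h2o"),
                 max_uptake = c(10, 10, 20, 5, 1, 100))
}

#' @rdname autotrophicMedia
#' @export
richMedia <- function() {
  MediaCondition("rich",
    c("photon", "ac", "glc", "ala", "vit", "nh3", "no3", "o2", "co2", "h2o"),
    max_uptake = c(100, 10, 5, 5, 1, 10, 10, 20, 20, 100))
}

#' Generate a synthetic expression profile for a model
#'
#' Designates a flux-consistent active gene set (the genes of reactions
#' carrying parsimonious flux on the given media), then draws expression
#' values from a high log-normal band for active genes and a low band for
#' inactive genes; `spec$noise` is the log-scale standard deviation of all
#' bands. Eighty universal-role housekeeping genes (mirroring the size of
#' the universally-active functional-role list used for thresholding real
#' transcriptomes) are drawn from an intermediate band whose 10th
#' percentile lies below the active band, as expected of universally
#' transcribed roles. Deterministic for a given seed.
#'
#' @param model a [MetabolicModel-class].
#' @param spec a [fixtureSpec()].
#' @param media media defining the growth state being profiled (default
#'   autotrophic for the phototroph-bearing models, the model's native
#'   regime otherwise).
#' @return list with `values` (named expression vector, model genes plus
#'   universal roles), `universal` (universal-role gene ids), `truth`
#'   (designated on/off calls for the model's genes), and `table`
#'   (two-column data.frame gene/value).
#' @export
makeExpressionProfile <- function(model, spec = fixtureSpec(), media = NULL) {
  gn <- genes(model)
  if (!length(gn)) stop("model has no genes")
  if (is.null(media)) media <- richMedia()
  sol <- runFBA(model, media, parsimonious = TRUE)
  if (sol@status != "optimal")
    stop("model does not grow on media '", media@name, "'")
  act_rxn <- names(sol@fluxes)[abs(sol@fluxes) >= FLUX_ACTIVITY_DELTA]
  active <- sort(unique(unlist(lapply(
    model@reactions$gpr[model@reactions$id %in% act_rxn], gprGenes))))
  inactive <- setdiff(gn, active)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  universal <- sprintf("ug%02d", 1:80)
  vals <- c(
    setNames(rlnorm(length(active), log(200), spec$noise), active),
    setNames(rlnorm(length(inactive), log(5), spec$noise), inactive),
    setNames(rlnorm(length(universal), log(100), spec$noise), universal)
  )
  vals <- vals[sort(names(vals))]
  # the designated truth covers the model's genes; universal roles exist to
  # anchor the threshold (the percentile convention necessarily calls some
  # of them off) and are not part of the designated set
  truth <- setNames(c(rep("on", length(active)), rep("off", length(inactive))),
                    c(active, inactive))
  list(values = vals, universal = universal, truth = truth[sort(names(truth))],
       table = data.frame(gene = names(vals), value = unname(vals),
                          stringsAsFactors = FALSE))
}

#' Write the full fixture set to a directory
#'
#' Emits the two member models (JSON and SBML), the candidate database
#' (JSON), the four media conditions (TSV), an expression table for the
#' community (TSV) and the universal-role gene list.
#'
#' @param dir output directory (created if needed).
#' @param spec a [fixtureSpec()].
#' @return invisibly, the directory.
#' @export
writeFixtures <- function(dir, spec = fixtureSpec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- makeToyPhototroph(spec)
  het <- makeToyHeterotroph(spec)
  db <- makeToyDatabase(spec)
  writeModelJSON(ph, file.path(dir, "phototroph.json"))
  writeModelJSON(het, file.path(dir, "heterotroph.json"))
  writeModelSBML(ph, file.path(dir, "phototroph.xml"))
  writeModelSBML(het, file.path(dir, "heterotroph.xml"))
  writeDatabaseJSON(db, file.path(dir, "database.json"))
  writeMedia(autotrophicMedia(), file.path(dir, "media_autotrophic.tsv"))
  writeMedia(glucoseMinimalMedia(), file.path(dir, "media_glucose_minimal.tsv"))
  writeMedia(acetateMinimalMedia(), file.path(dir, "media_acetate_minimal.tsv"))
  writeMedia(richMedia(), file.path(dir, "media_rich.tsv"))
  expr <- makeExpressionProfile(ph, spec, autotrophicMedia())
  write.table(expr$table, file.path(dir, "expression_phototroph.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(expr$universal, file.path(dir, "universal_roles.txt"))
  invisible(dir)
}
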