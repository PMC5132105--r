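setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel '", object@id, "'\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions, ",
      length(genes(object)), " genes\n", sep = "")
  cat("  compartments: ",
      paste(sprintf("%s (%s)", object@compartments$id,
                    object@compartments$label), collapse = ", "), "\n",
      sep = "")
  cat("  biomass: ", paste(object@biomassIds, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CommunityModel", function(object) {
  arch <- if (nrow(object@speciesIndex) > 1L) "compartmentalized" else "mixed-bag"
  cat("CommunityModel '", object@id, "' (", arch, ", ",
      object@nMembers, " members)\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites, ",
      nrow(object@reactions), " reactions\n", sep = "")
  if (nrow(object@speciesIndex) > 1L)
    cat("  members: ",
        paste(sprintf("%s [%s]", object@speciesIndex$member_model,
                      object@speciesIndex$compartment), collapse = ", "),
        "\n", sep = "")
  cat("  community biomass: ", object@communityBiomassId, "\n", sep = "")
})

setMethod("show", "MediaCondition", function(object) {
  cat("MediaCondition '", object@name, "' (", nrow(object@entries),
      " compounds)\n", sep = "")
  if (nrow(object@entries)) {
    e <- object@entries
    cat("  ", paste(sprintf("%s (uptake<=%g)", e$compound, e$max_uptake),
                    collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "ReactionDatabase", function(object) {
  cat("ReactionDatabase: ", nrow(object@reactions), " reaction entries, ",
      length(object@transporterCompounds), " transporter templates\n",
      sep = "")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution (", object@status, ")\n", sep = "")
  if (object@status == "optimal") {
    cat("  objective ", object@objectiveId, " = ",
        format(object@objective, digits = 6), "\n", sep = "")
    nz <- sum(abs(object@fluxes) > 1e-9)
    cat("  ", nz, " of ", length(object@fluxes),
        " reactions carry flux\n", sep = "")
  }
})

setMethod("show", "GapfillResult", function(object) {
  cat("GapfillResult (", object@strategy, " on '", object@media, "')\n",
      sep = "")
  cat("  ", nrow(object@additions), " reaction(s) added, total cost ",
      object@totalCost, "; objective ",
      format(object@objectiveValue, digits = 6), "\n", sep = "")
  if (nrow(object@additions))
    cat("  ", paste(sprintf("%s[%s,%s]", object@additions$id,
                            object@additions$compartment,
                            object@additions$direction), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile: ", length(object@values), " genes, threshold ",
      format(object@threshold, digits = 6), " (percentile ",
      object@percentile, " of ", length(object@universalGenes),
      " universal roles)\n", sep = "")
  cat("  ", sum(object@calls == "on"), " on / ",
      sum(object@calls == "off"), " off\n", sep = "")
})

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport over ", object@nClassified,
      " classified reactions\n", sep = "")
  p <- object@percentages
  cat(sprintf("  +F+E %.1f%%  -F-E %.1f%%  +F-E %.1f%%  -F+E %.1f%%\n",
              p[["+F+E"]], p[["-F-E"]], p[["+F-E"]], p[["-F+E"]]))
  a <- object@accuracies
  cat(sprintf("  accuracy: active %.1f%%, inactive %.1f%%, overall %.1f%%\n",
              a[["active"]], a[["inactive"]], a[["overall"]]))
})
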