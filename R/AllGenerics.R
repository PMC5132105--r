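#' @import methods
#' @importFrom stats quantile rlnorm setNames
#' @importFrom utils read.delim write.table head combn modifyList
NULL

#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))

#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @export
setGeneric("biomassIds", function(object) standardGeneric("biomassIds"))

#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @export
setGeneric("validateModel", function(object) standardGeneric("validateModel"))

#' @export
setGeneric("applyMedia", function(object, media, ...) standardGeneric("applyMedia"))

#' @export
setGeneric("runFBA", function(object, media = NULL, ...) standardGeneric("runFBA"))

#' @export
setGeneric("predictGrowth", function(object, media, ...) standardGeneric("predictGrowth"))

#' @export
setGeneric("predictAuxotrophies", function(object, media, ...)
  standardGeneric("predictAuxotrophies"))

#' @export
setGeneric("identifyInteractions", function(object, media, ...)
  standardGeneric("identifyInteractions"))

#' @export
setGeneric("gapfill", function(object, database, media, ...) standardGeneric("gapfill"))

#' @export
setGeneric("communityGapfill", function(object, database, media, ...)
  standardGeneric("communityGapfill"))

#' @export
setGeneric("gapfillIterative", function(object, database, mediaList, ...)
  standardGeneric("gapfillIterative"))

#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @export
setGeneric("solverStatus", function(object) standardGeneric("solverStatus"))

#' @export
setGeneric("addedReactions", function(object) standardGeneric("addedReactions"))

#' @export
setGeneric("totalCost", function(object) standardGeneric("totalCost"))

#' @export
setGeneric("activityCalls", function(object) standardGeneric("activityCalls"))

#' @export
setGeneric("activityThreshold", function(object) standardGeneric("activityThreshold"))

#' @export
setGeneric("categoryPercentages", function(object) standardGeneric("categoryPercentages"))

#' @export
setGeneric("accuracies", function(object) standardGeneric("accuracies"))

#' @export
setGeneric("pathwayBreakdown", function(object) standardGeneric("pathwayBreakdown"))
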