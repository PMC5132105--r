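# Media conditions: construction, TSV IO and application to models.

#' Construct a media condition
#'
#' @param name media name.
#' @param compounds character vector of extracellular compound ids
#'   (without compartment suffix).
#' @param max_uptake,max_excretion nonnegative flux limits, recycled.
#' @return a [MediaCondition-class].
#' @examples
#' autotrophic <- MediaCondition("autotrophic",
#'   c("photon", "co2", "no3", "h2o"), max_uptake = c(100, 20, 10, 100))
#' @export
MediaCondition <- function(name, compounds, max_uptake = 10,
                           max_excretion = BIG_FLUX) {
  entries <- data.frame(
    compound = compounds,
    max_uptake = rep_len(max_uptake, length(compounds)),
    max_excretion = rep_len(max_excretion, length(compounds)),
    stringsAsFactors = FALSE
  )
  new("MediaCondition", name = name, entries = entries)
}

#' Read a media condition from TSV
#'
#' Expects three columns (compound, max_uptake, max_excretion); lines
#' starting with "#" are comments.
#'
#' @param path file path.
#' @param name media name (defaults to the file name).
#' @return a [MediaCondition-class].
#' @export
readMedia <- function(path, name = sub("\\.tsv$", "", basename(path))) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "max_uptake", "max_excretion") %in% names(tab)))
  new("MediaCondition", name = name,
      entries = tab[c("compound", "max_uptake", "max_excretion")])
}

#' Write a media condition to TSV
#'
#' @param media a [MediaCondition-class].
#' @param path output path.
#' @export
writeMedia <- function(media, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# media: ", media@name), con)
  write.table(media@entries, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

exchangeIdFor <- function(compound) paste0("EX_", compound)

# compound id of an extracellular metabolite id ("glc_e0" -> "glc")
compoundOf <- function(metId, compartment) {
  sub(paste0("_", compartment, "$"), "", metId)
}

#' Apply a media condition to a model
#'
#' Sets the bounds of every exchange reaction from the media: a compound
#' with entry (max_uptake, max_excretion) gets bounds
#' (-max_uptake, +max_excretion) on its exchange reaction (exchanges are
#' written in export orientation, so uptake is negative flux). Exchange
#' reactions are created on demand for extracellular metabolites that lack
#' one. Compounds absent from the media get a zero lower bound (no uptake);
#' their excretion bound is left untouched. The input model is not
#' modified; the operation is idempotent.
#'
#' @param object a [MetabolicModel-class].
#' @param media a [MediaCondition-class].
#' @return a new MetabolicModel with media bounds applied.
#' @export
setMethod("applyMedia", "MetabolicModel", function(object, media) {
  exc_cmp <- extracellularCompartments(object)
  if (length(exc_cmp) != 1L)
    stop("model must have exactly one extracellular compartment")
  exc_mets <- object@metabolites[object@metabolites$compartment == exc_cmp, ,
                                 drop = FALSE]
  compounds <- compoundOf(exc_mets$id, exc_cmp)
  missing <- setdiff(media@entries$compound, compounds)
  if (length(missing))
    stop("media '", media@name, "' names compound(s) with no extracellular ",
         "metabolite in model '", object@id, "': ",
         paste(missing, collapse = ", "))

  model <- object
  # create missing exchange reactions (export orientation: met -> nothing)
  have_ex <- model@reactions$id[model@reactions$source_tag == "exchange"]
  need <- exc_mets$id[!exchangeIdFor(compounds) %in% have_ex]
  need_cpd <- compounds[!exchangeIdFor(compounds) %in% have_ex]
  if (length(need)) {
    rx <- data.frame(id = exchangeIdFor(need_cpd),
                     name = paste0("exchange of ", need_cpd),
                     lb = 0, ub = BIG_FLUX, source_tag = "exchange",
                     stringsAsFactors = FALSE)
    st <- data.frame(reaction = rx$id, metabolite = need, coef = -1)
    model <- addReactionsToModel(model, rx, st)
  }

  ex_ids <- exchangeIdFor(compounds)
  idx <- match(ex_ids, model@reactions$id)
  stopifnot(!anyNA(idx))
  in_media <- match(compounds, media@entries$compound)
  lb <- ifelse(is.na(in_media), 0, -media@entries$max_uptake[in_media])
  ub <- ifelse(is.na(in_media), model@reactions$ub[idx],
               media@entries$max_excretion[in_media])
  model@reactions$lb[idx] <- lb
  model@reactions$ub[idx] <- ub
  model
})
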