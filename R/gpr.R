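# Gene-protein-reaction (GPR) boolean rules: parsing and three-valued
# evaluation. Rules are strings like "(g1 and g2) or g3"; "and"/"or" are
# case-insensitive, "&"/"|" are accepted synonyms, "" means no gene.

gprTokenize <- function(x) {
  x <- gsub("&&?", " and ", x)
  x <- gsub("\\|\\|?", " or ", x)
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR rule string
#'
#' @param x rule string; "" yields NULL (no gene association).
#' @return a nested list with elements `op` ("and"/"or") and `args`, with
#'   gene ids as character leaves; NULL for an empty rule.
#' @export
parseGPR <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(NULL)
  toks <- gprTokenize(x)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR rule")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in GPR rule")
      return(e)
    }
    if (t %in% c(")") || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule near '", t, "'")
    t
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR rule")
  out
}

# gene ids (leaves) of a rule string
gprGenes <- function(x) {
  tree <- parseGPR(x)
  leaves <- function(nd) {
    if (is.null(nd)) return(character(0))
    if (is.character(nd)) return(nd)
    unlist(lapply(nd$args, leaves))
  }
  unique(leaves(tree))
}

# three-valued evaluation: calls is a named character vector of "on"/"off";
# genes absent from it are unknown. Returns "on", "off" or "unknown";
# NA for an empty rule.
evalGPR <- function(x, calls) {
  tree <- parseGPR(x)
  if (is.null(tree)) return(NA_character_)
  ev <- function(nd) {
    if (is.character(nd)) {
      if (nd %in% names(calls)) return(calls[[nd]])
      return("unknown")
    }
    vals <- vapply(nd$args, ev, character(1))
    if (nd$op == "or") {
      if (any(vals == "on")) "on"
      else if (any(vals == "unknown")) "unknown"
      else "off"
    } else {
      if (any(vals == "off")) "off"
      else if (any(vals == "unknown")) "unknown"
      else "on"
    }
  }
  ev(tree)
}

# serialize a parsed tree back to a rule string (used by SBML IO)
deparseGPR <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, function(a) {
    s <- deparseGPR(a)
    if (!is.character(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$op, " "))
}
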