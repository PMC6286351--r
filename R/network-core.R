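## GPR rule handling -------------------------------------------------------
## Rules are boolean AND/OR expressions over gene ids, e.g.
##   "b0001", "(b0001 and b0002) or b0003"
## parsed into nested lists: a leaf is a gene id (character), an inner node
## is list(op = "and"|"or", args = list(...)).

.gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}

.gpr_parse <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- .gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: ", rule)
    if (t == "(") {
      take()
      e <- parse_expr()
      if (is.na(peek()) || take() != ")") stop("unbalanced GPR rule: ", rule)
      return(e)
    }
    if (t %in% c(")", "and", "or", "AND", "OR")) {
      stop("malformed GPR rule: ", rule)
    }
    take()
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR rule: ", rule)
  out
}

.gpr_genes <- function(rule) {
  tree <- if (is.character(rule) && length(rule) == 1L &&
              !grepl("^list", rule[1L])) .gpr_parse(rule) else rule
  if (is.null(tree)) return(character(0))
  rec <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, rec), use.names = FALSE)
  }
  unique(rec(tree))
}

## DNF expansion: list of gene sets; each set is one isozyme alternative
## (an AND-complex of its genes).
.gpr_alternatives <- function(rule) {
  tree <- .gpr_parse(rule)
  if (is.null(tree)) return(list())
  rec <- function(node) {
    if (is.character(node)) return(list(node))
    alts <- lapply(node$args, rec)
    if (node$op == "or") {
      return(do.call(c, alts))
    }
    ## AND: cartesian union of the alternatives of each argument
    out <- list(character(0))
    for (a in alts) {
      out <- unlist(lapply(out, function(x)
        lapply(a, function(y) unique(c(x, y)))), recursive = FALSE)
    }
    out
  }
  lapply(rec(tree), sort)
}

## MetabolicNetwork construction -------------------------------------------

#' Construct a MetabolicNetwork
#'
#' @param reactions data.frame with columns \code{id}, \code{lb}, \code{ub}
#'   and optionally \code{reversible} (default \code{lb < 0}) and
#'   \code{exchange} (default: reactions touching a single metabolite).
#' @param metabolites data.frame with columns \code{id} and atom counts
#'   \code{C}, \code{N}, \code{S}, \code{P} (missing columns default to 0).
#' @param stoich stoichiometric matrix (metabolites x reactions), dense or
#'   sparse; rows/columns are matched by the id columns when dimnames are
#'   present.
#' @param biomass id of the biomass reaction.
#' @param gpr named character vector of GPR rules (missing reactions get
#'   \code{""}).
#' @param geneMW named numeric vector of gene molecular weights (g/mmol).
#' @param oxygenExchange id of the oxygen exchange reaction, if any.
#' @return a validated \linkS4class{MetabolicNetwork}
#' @export
metabolicNetwork <- function(reactions, metabolites, stoich, biomass,
                             gpr = character(0), geneMW = numeric(0),
                             oxygenExchange = character(0)) {
  for (el in c("C", "N", "S", "P")) {
    if (is.null(metabolites[[el]])) metabolites[[el]] <- 0
  }
  S <- Matrix::Matrix(stoich, sparse = TRUE)
  if (!is.null(dimnames(S)[[1L]])) {
    S <- S[metabolites$id, reactions$id, drop = FALSE]
  } else {
    dimnames(S) <- list(metabolites$id, reactions$id)
  }
  if (is.null(reactions$exchange)) {
    reactions$exchange <- Matrix::colSums(S != 0) == 1L
  }
  if (is.null(reactions$reversible)) {
    reactions$reversible <- reactions$lb < 0 & !reactions$exchange
  }
  full_gpr <- setNames(rep("", nrow(reactions)), reactions$id)
  if (length(gpr)) full_gpr[names(gpr)] <- gpr
  new("MetabolicNetwork", reactions = reactions, metabolites = metabolites,
      stoich = S, biomassReaction = biomass, gpr = full_gpr,
      geneMW = geneMW, oxygenExchange = as.character(oxygenExchange))
}

## which elements an exchange reaction can supply (metabolite atom content)
.exchange_elements <- function(network, rxn_id) {
  S <- network@stoich
  j <- match(rxn_id, network@reactions$id)
  met <- which(S[, j] != 0)
  if (length(met) != 1L) return(character(0))
  m <- network@metabolites[met, ]
  c("C", "N", "S", "P")[c(m$C, m$N, m$S, m$P) > 0]
}

## exchange reactions able to supply a given element (excluding oxygen and
## the biomass sink)
.source_exchanges <- function(network, element) {
  rx <- network@reactions
  ex <- rx$id[rx$exchange]
  ex <- setdiff(ex, network@oxygenExchange)
  ## the exchange draining a biomass-produced metabolite is a sink, not a
  ## nutrient source
  bj <- match(network@biomassReaction, rx$id)
  bio_prod <- which(network@stoich[, bj] > 0)
  if (length(bio_prod)) {
    sink <- vapply(ex, function(e) {
      j <- match(e, rx$id)
      any(network@stoich[bio_prod, j] != 0)
    }, logical(1L))
    ex <- ex[!sink]
  }
  ex[vapply(ex, function(e) element %in% .exchange_elements(network, e),
            logical(1L))]
}

## carbon atom count of the (single) metabolite behind an exchange reaction
.exchange_atoms <- function(network, rxn_id, element = "C") {
  S <- network@stoich
  j <- match(rxn_id, network@reactions$id)
  met <- which(S[, j] != 0)
  if (length(met) != 1L) return(0)
  network@metabolites[[element]][met]
}
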