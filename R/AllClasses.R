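#' MetabolicNetwork: a constraint-based metabolic model
#'
#' Holds the stoichiometric matrix, flux bounds, gene-protein-reaction (GPR)
#' rules and gene molecular weights of a (toy or genome-scale) metabolic
#' network. Fluxes are in mmol/gDW/h, gene molecular weights in g/mmol
#' (numerically equal to kDa). Elemental balance is tracked for C, N, S and P
#' only; hydrogen and oxygen are deliberately untracked so that water and
#' protons can participate freely.
#'
#' @slot reactions data.frame with columns \code{id}, \code{lb}, \code{ub},
#'   \code{reversible}, \code{exchange}.
#' @slot metabolites data.frame with columns \code{id}, \code{C}, \code{N},
#'   \code{S}, \code{P} (atom counts).
#' @slot stoich sparse stoichiometric matrix, metabolites x reactions.
#' @slot biomassReaction id of the biomass (growth) reaction.
#' @slot gpr named character vector of GPR rules, e.g.
#'   \code{"(g1 and g2) or g3"}; \code{""} means no enzyme is associated.
#' @slot geneMW named numeric vector of gene-product molecular weights
#'   (g/mmol).
#' @slot oxygenExchange id of the oxygen exchange reaction, or
#'   \code{character(0)} if the network has none.
#'
#' @examples
#' net <- generateToyGem(toyGemSpec(seed = 1))
#' net
#' head(reactions(net))
#' @export
setClass("MetabolicNetwork",
  representation(
    reactions = "data.frame",
    metabolites = "data.frame",
    stoich = "Matrix",
    biomassReaction = "character",
    gpr = "character",
    geneMW = "numeric",
    oxygenExchange = "character"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msgs <- character(0)
  rx <- object@reactions
  mets <- object@metabolites
  S <- object@stoich
  need_rx <- c("id", "lb", "ub", "reversible", "exchange")
  if (!all(need_rx %in% names(rx))) {
    return(paste("reactions must have columns",
                 paste(need_rx, collapse = ", ")))
  }
  if (!all(c("id", "C", "N", "S", "P") %in% names(mets))) {
    return("metabolites must have columns id, C, N, S, P")
  }
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rx)) {
    return("stoich dimensions do not match metabolites x reactions")
  }
  if (any(rx$lb > rx$ub + 1e-12)) {
    msgs <- c(msgs, "flux bounds must satisfy lb <= ub")
  }
  if (length(object@biomassReaction) != 1L ||
      !(object@biomassReaction %in% rx$id)) {
    msgs <- c(msgs, "biomassReaction must name an existing reaction")
  }
  if (!identical(names(object@gpr), rx$id)) {
    msgs <- c(msgs, "gpr must be named by reaction id, in reaction order")
  }
  gused <- unique(unlist(lapply(object@gpr, .gpr_genes), use.names = FALSE))
  if (length(gused) && !all(gused %in% names(object@geneMW))) {
    msgs <- c(msgs, paste("genes without molecular weight:",
                          paste(setdiff(gused, names(object@geneMW)),
                                collapse = ", ")))
  }
  ## elemental balance of internal reactions for the tracked elements
  internal <- which(!rx$exchange)
  if (length(internal)) {
    for (el in c("C", "N", "S", "P")) {
      imb <- abs(as.vector(Matrix::crossprod(S[, internal, drop = FALSE],
                                             mets[[el]])))
      if (any(imb > 1e-6)) {
        bad <- rx$id[internal][imb > 1e-6]
        msgs <- c(msgs, paste0(el, "-imbalanced internal reaction(s): ",
                               paste(head(bad, 5L), collapse = ", ")))
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FluxVector: a steady-state flux distribution
#'
#' @slot values named numeric vector of reaction fluxes (mmol/gDW/h).
#' @slot objectiveValue the optimum of the generating problem (e.g. growth
#'   rate in 1/h).
#' @export
setClass("FluxVector",
  representation(values = "numeric", objectiveValue = "numeric")
)

setValidity("FluxVector", function(object) {
  if (is.null(names(object@values))) return("fluxes must be named")
  if (anyNA(object@values)) return("fluxes must not contain NA")
  if (length(object@objectiveValue) != 1L) {
    return("objectiveValue must be a scalar")
  }
  TRUE
})

#' EnsembleModel: the 3 x 4 turnover-number prediction ensemble
#'
#' Twelve regression models (elastic net, random forest, small neural
#' network, each trained under four imputation strategies), together with
#' per-member fallback medians and the global training median used for the
#' median-imputed baseline parameterization.
#'
#' @slot members list of fitted member models; each member carries its
#'   \code{algorithm}, \code{strategy}, fitted object, feature schema,
#'   \code{fallback} median (log10 scale) and seed.
#' @slot globalMedian median of the training response on log10 scale.
#' @slot featureNames character vector naming the feature columns.
#' @export
setClass("EnsembleModel",
  representation(
    members = "list",
    globalMedian = "numeric",
    featureNames = "character"
  )
)

setValidity("EnsembleModel", function(object) {
  algs <- c("elastic_net", "random_forest", "neural_net")
  strs <- c("none", "labelled_only", "unlabelled_only", "all")
  for (m in object@members) {
    if (!is.list(m) || !all(c("algorithm", "strategy", "fallback") %in%
                            names(m))) {
      return("each member needs algorithm, strategy and fallback fields")
    }
    if (!(m$algorithm %in% algs)) return("unknown member algorithm")
    if (!(m$strategy %in% strs)) return("unknown member imputation strategy")
  }
  if (!length(object@members)) return("ensemble has no members")
  TRUE
})

#' MomentSolution: an enzyme-capacity-constrained (MOMENT) optimum
#'
#' @slot growthRate optimal growth rate (1/h).
#' @slot fluxes \linkS4class{FluxVector} of the solution.
#' @slot enzymeConc named numeric, gene-product concentration (mmol/gDW).
#' @slot enzymeMass named numeric, gene-product mass (g/gDW).
#' @slot massFractions named numeric, metabolic mass fraction per expressed
#'   gene (sums to 1).
#' @slot budget the protein budget C (g/gDW) of the generating problem.
#' @export
setClass("MomentSolution",
  representation(
    growthRate = "numeric",
    fluxes = "FluxVector",
    enzymeConc = "numeric",
    enzymeMass = "numeric",
    massFractions = "numeric",
    budget = "numeric"
  )
)

setValidity("MomentSolution", function(object) {
  if (sum(object@enzymeMass) > object@budget + 1e-6) {
    return("total enzyme mass exceeds the protein budget")
  }
  fr <- object@massFractions
  if (length(fr) && abs(sum(fr) - 1) > 1e-9) {
    return("mass fractions must sum to 1")
  }
  TRUE
})
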