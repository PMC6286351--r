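## ---- accessors -----------------------------------------------------------

#' @rdname turnoverML-generics
#' @export
setMethod("reactions", "MetabolicNetwork", function(object) object@reactions)

#' @rdname turnoverML-generics
#' @export
setMethod("metabolites", "MetabolicNetwork",
          function(object) object@metabolites)

#' @rdname turnoverML-generics
#' @export
setMethod("stoichMatrix", "MetabolicNetwork", function(object) object@stoich)

#' @rdname turnoverML-generics
#' @export
setMethod("biomassReaction", "MetabolicNetwork",
          function(object) object@biomassReaction)

#' @rdname turnoverML-generics
#' @export
setMethod("gprRules", "MetabolicNetwork", function(object) object@gpr)

#' @rdname turnoverML-generics
#' @export
setMethod("geneMW", "MetabolicNetwork", function(object) object@geneMW)

#' @rdname turnoverML-generics
#' @export
setMethod("fluxes", "FluxVector", function(object) object@values)

#' @rdname turnoverML-generics
#' @export
setMethod("objectiveValue", "FluxVector",
          function(object) object@objectiveValue)

#' @rdname turnoverML-generics
#' @export
setMethod("fluxes", "MomentSolution", function(object) object@fluxes@values)

#' @rdname turnoverML-generics
#' @export
setMethod("growthRate", "MomentSolution", function(object) object@growthRate)

#' @rdname turnoverML-generics
#' @export
setMethod("enzymeMasses", "MomentSolution",
          function(object) object@enzymeMass)

#' @rdname turnoverML-generics
#' @export
setMethod("massFractions", "MomentSolution",
          function(object) object@massFractions)

#' @rdname turnoverML-generics
#' @export
setMethod("ensembleMembers", "EnsembleModel", function(object) object@members)

## ---- show methods --------------------------------------------------------

setMethod("show", "MetabolicNetwork", function(object) {
  rx <- object@reactions
  cat("MetabolicNetwork:", nrow(object@metabolites), "metabolites,",
      nrow(rx), "reactions (", sum(rx$exchange), "exchange ),",
      length(object@geneMW), "genes\n")
  cat("  biomass:", object@biomassReaction, "\n")
})

setMethod("show", "FluxVector", function(object) {
  cat("FluxVector over", length(object@values), "reactions; objective =",
      format(object@objectiveValue, digits = 6), "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  fam <- table(vapply(object@members, `[[`, "", "algorithm"))
  cat("EnsembleModel with", length(object@members), "members (",
      paste(names(fam), fam, sep = ":", collapse = ", "), ")\n")
  cat("  global training median (log10):",
      format(object@globalMedian, digits = 4), "\n")
})

setMethod("show", "MomentSolution", function(object) {
  cat("MomentSolution: growth =", format(object@growthRate, digits = 6),
      "1/h;", sum(object@enzymeMass > 0), "expressed genes; protein",
      format(sum(object@enzymeMass), digits = 4), "of budget",
      object@budget, "g/gDW\n")
})
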