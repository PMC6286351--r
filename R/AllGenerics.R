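#' @title Generics for turnoverML data objects
#' @description Accessor generics for the central S4 classes
#'   (\linkS4class{MetabolicNetwork}, \linkS4class{FluxVector},
#'   \linkS4class{EnsembleModel}, \linkS4class{MomentSolution}).
#' @param object an object of the appropriate class
#' @name turnoverML-generics
#' @keywords internal
NULL

#' @rdname turnoverML-generics
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname turnoverML-generics
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname turnoverML-generics
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname turnoverML-generics
#' @export
setGeneric("biomassReaction",
           function(object) standardGeneric("biomassReaction"))

#' @rdname turnoverML-generics
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' @rdname turnoverML-generics
#' @export
setGeneric("geneMW", function(object) standardGeneric("geneMW"))

#' @rdname turnoverML-generics
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname turnoverML-generics
#' @export
setGeneric("objectiveValue",
           function(object) standardGeneric("objectiveValue"))

#' @rdname turnoverML-generics
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname turnoverML-generics
#' @export
setGeneric("enzymeMasses", function(object) standardGeneric("enzymeMasses"))

#' @rdname turnoverML-generics
#' @export
setGeneric("massFractions", function(object) standardGeneric("massFractions"))

#' @rdname turnoverML-generics
#' @export
setGeneric("ensembleMembers",
           function(object) standardGeneric("ensembleMembers"))
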