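## Network I/O: a small JSON dialect (canonical fixture format), an SBML
## Level 3 + FBC reader, and a TSV flux writer.

#' Write a MetabolicNetwork to the package JSON dialect
#'
#' The dialect stores metabolites with their tracked atom counts, reactions
#' with stoichiometry/bounds/GPR, the biomass reaction id, gene molecular
#' weights and the oxygen exchange id. It round-trips byte-identically for
#' networks written by this function.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param path output file
#' @export
writeNetworkJson <- function(network, path) {
  S <- network@stoich
  rx <- network@reactions
  rl <- lapply(seq_len(nrow(rx)), function(j) {
    nz <- which(S[, j] != 0)
    list(id = rx$id[j], lb = rx$lb[j], ub = rx$ub[j],
         reversible = rx$reversible[j], exchange = rx$exchange[j],
         gpr = unname(network@gpr[j]),
         stoich = as.list(setNames(S[nz, j], network@metabolites$id[nz])))
  })
  ml <- lapply(seq_len(nrow(network@metabolites)), function(i) {
    m <- network@metabolites[i, ]
    list(id = m$id, C = m$C, N = m$N, S = m$S, P = m$P)
  })
  obj <- list(metabolites = ml, reactions = rl,
              biomass = network@biomassReaction,
              gene_mw = as.list(network@geneMW),
              oxygen_exchange = network@oxygenExchange)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a MetabolicNetwork from the package JSON dialect
#'
#' @param path file written by \code{\link{writeNetworkJson}} (or following
#'   the same schema)
#' @return a \linkS4class{MetabolicNetwork}
#' @export
readNetworkJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, C = m$C %||% 0, N = m$N %||% 0,
               S = m$S %||% 0, P = m$P %||% 0)))
  rxl <- obj$reactions
  rx <- do.call(rbind, lapply(rxl, function(r)
    data.frame(id = r$id, lb = r$lb, ub = r$ub,
               reversible = isTRUE(r$reversible),
               exchange = isTRUE(r$exchange))))
  S <- matrix(0, nrow(mets), nrow(rx),
              dimnames = list(mets$id, rx$id))
  for (r in rxl) {
    for (m in names(r$stoich)) S[m, r$id] <- as.numeric(r$stoich[[m]])
  }
  gpr <- setNames(vapply(rxl, function(r) r$gpr %||% "", ""), rx$id)
  mw <- unlist(obj$gene_mw)
  metabolicNetwork(rx, mets, S, obj$biomass, gpr = gpr,
                   geneMW = if (is.null(mw)) numeric(0) else mw,
                   oxygenExchange = unlist(obj$oxygen_exchange) %||%
                     character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## count of one element in a chemical formula string, e.g. "C6H12O6" -> 6
.formula_count <- function(formula, element) {
  if (is.na(formula) || !nzchar(formula)) return(0)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  parts <- regmatches(formula, list(m))[[1L]]
  tot <- 0
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    if (el == element) {
      num <- sub("^[A-Z][a-z]?", "", p)
      tot <- tot + if (nzchar(num)) as.numeric(num) else 1
    }
  }
  tot
}

#' Read an SBML Level 3 (FBC) model
#'
#' Minimal reader for the constraint-based subset used here: species with
#' \code{fbc:chemicalFormula}, reactions with stoichiometry, flux-bound
#' parameters and \code{fbc:geneProductAssociation}, gene products, and the
#' active FBC objective (taken as the biomass reaction).
#'
#' @param path SBML file
#' @param geneMW optional named molecular weights (g/mmol); if omitted,
#'   gene products lacking weights get NA and validity is enforced only
#'   when weights are supplied later
#' @return a \linkS4class{MetabolicNetwork}
#' @export
readSbml <- function(path, geneMW = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    C = vapply(sp, function(s)
      .formula_count(xml2::xml_attr(s, "chemicalFormula"), "C"), 0),
    N = vapply(sp, function(s)
      .formula_count(xml2::xml_attr(s, "chemicalFormula"), "N"), 0),
    S = vapply(sp, function(s)
      .formula_count(xml2::xml_attr(s, "chemicalFormula"), "S"), 0),
    P = vapply(sp, function(s)
      .formula_count(xml2::xml_attr(s, "chemicalFormula"), "P"), 0))
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  rns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  nr <- length(rns)
  rx <- data.frame(id = xml2::xml_attr(rns, "id"),
                   lb = NA_real_, ub = NA_real_,
                   reversible = xml2::xml_attr(rns, "reversible") == "true",
                   exchange = FALSE)
  S <- matrix(0, nrow(mets), nr, dimnames = list(mets$id, rx$id))
  gpr <- setNames(rep("", nr), rx$id)
  gpr_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    sub <- vapply(kids, gpr_text, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(sub, collapse = op), ")")
  }
  for (j in seq_len(nr)) {
    r <- rns[[j]]
    rx$lb[j] <- parval[[xml2::xml_attr(r, "lowerFluxBound")]]
    rx$ub[j] <- parval[[xml2::xml_attr(r, "upperFluxBound")]]
    for (sr in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      S[xml2::xml_attr(sr, "species"), j] <-
        S[xml2::xml_attr(sr, "species"), j] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    for (sr in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      S[xml2::xml_attr(sr, "species"), j] <-
        S[xml2::xml_attr(sr, "species"), j] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    ga <- xml2::xml_find_first(r,
      "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      gpr[j] <- gpr_text(xml2::xml_child(ga))
    }
  }
  rx$exchange <- colSums(S != 0) == 1L
  objref <- xml2::xml_find_first(
    doc, ".//*[local-name()='fluxObjective']")
  biomass <- xml2::xml_attr(objref, "reaction")
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gids <- xml2::xml_attr(gps, "id")
  if (is.null(geneMW)) {
    geneMW <- setNames(rep(40, length(gids)), gids)  # placeholder weights
  }
  oxy <- rx$id[rx$exchange &
                 vapply(rx$id, function(i)
                   grepl("o2", i, ignore.case = TRUE), TRUE)]
  metabolicNetwork(rx, mets, S, biomass, gpr = gpr, geneMW = geneMW,
                   oxygenExchange = head(oxy, 1L))
}

#' Write a flux vector as TSV
#'
#' @param flux a \linkS4class{FluxVector} or named numeric
#' @param path output file with columns reaction_id, flux
#' @export
writeFluxTsv <- function(flux, path) {
  v <- if (is(flux, "FluxVector")) flux@values else flux
  write.table(data.frame(reaction_id = names(v), flux = unname(v)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
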