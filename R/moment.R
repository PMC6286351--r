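## MOMENT: enzyme-capacity-constrained FBA. Each catalyzed flux is coupled
## to enzyme usage through its effective turnover rate, total enzyme mass
## is capped by the metabolic protein budget, and growth is maximized. A
## second LP stage minimizes total enzyme mass at the optimal growth so the
## reported enzyme concentrations are the parsimonious (and reproducible)
## ones.

#' Assemble a MOMENT problem
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param keff named numeric of effective turnover rates (1/s). Names are
#'   reaction ids; direction-specific rates for reversible reactions may
#'   be given as \code{"<id>_b"} for the backward direction (the forward
#'   rate is used for both when no backward entry exists).
#' @param membraneDefault default rate for membrane-localized reactions
#'   (65 1/s)
#' @param membraneReactions reaction ids treated as membrane-localized
#'   (always parameterized with \code{membraneDefault})
#' @param defaultKeff rate used for catalyzed reactions absent from
#'   \code{keff} (default: \code{NA}, meaning such reactions are an error;
#'   supply e.g. a median to fill gaps)
#' @param budget metabolic protein budget C in g protein / gDW (0.32)
#' @param openUptake lower bound applied to substrate and oxygen exchange
#'   reactions (-1000, effectively unconstrained)
#' @return an object of class \code{MomentProblem}
#' @export
momentProblem <- function(network, keff, membraneDefault = 65,
                          membraneReactions = character(0),
                          defaultKeff = NA_real_, budget = 0.32,
                          openUptake = -1000) {
  stopifnot(budget > 0, all(keff > 0, na.rm = TRUE))
  structure(list(network = network, keff = keff,
                 membraneDefault = membraneDefault,
                 membraneReactions = membraneReactions,
                 defaultKeff = defaultKeff, budget = budget,
                 openUptake = openUptake),
            class = "MomentProblem")
}

## effective rate for one reaction direction, applying membrane default
## and gap filling
.moment_keff <- function(problem, rxn, backward = FALSE) {
  if (rxn %in% problem$membraneReactions) return(problem$membraneDefault)
  key_b <- paste0(rxn, "_b")
  if (backward && key_b %in% names(problem$keff)) {
    return(problem$keff[[key_b]])
  }
  if (rxn %in% names(problem$keff)) return(problem$keff[[rxn]])
  if (is.na(problem$defaultKeff)) {
    stop("no k_eff for catalyzed reaction ", rxn,
         " and no default supplied")
  }
  problem$defaultKeff
}

#' Solve a MOMENT problem
#'
#' LP over fluxes (reversible reactions split into forward/backward parts)
#' and per-(reaction, isozyme-alternative) enzyme usages y: maximize
#' growth subject to Sv = 0, bounds, the capacity couplings
#' v_dir <= 3600 * k_eff * sum(y_alt), and the budget
#' sum_g MW_g E_g <= C where E_g sums the usages of every AND-complex
#' alternative containing gene g (each subunit pays its own mass). A
#' second stage minimizes total enzyme mass at the optimal growth, making
#' enzyme concentrations parsimonious and the solution reproducible.
#'
#' @param problem a \code{\link{momentProblem}}
#' @return a \linkS4class{MomentSolution}
#' @examples
#' net <- generateToyGem(toyGemSpec(seed = 1))
#' keff <- setNames(rep(10, nrow(reactions(net))), reactions(net)$id)
#' sol <- solveMoment(momentProblem(net, keff))
#' growthRate(sol)
#' @export
solveMoment <- function(problem) {
  stopifnot(inherits(problem, "MomentProblem"))
  net <- problem$network
  rx <- net@reactions
  n <- nrow(rx)
  S <- as.matrix(net@stoich)
  ## open uptake for nutrient sources and oxygen
  src <- unique(c(unlist(lapply(c("C", "N", "S", "P"), function(el)
    .source_exchanges(net, el))), net@oxygenExchange))
  rx$lb[rx$id %in% src & rx$lb < 0] <- problem$openUptake

  ## flux variables: forward and backward split
  lbF <- pmax(rx$lb, 0); ubF <- pmax(rx$ub, 0)
  lbB <- pmax(-rx$ub, 0); ubB <- pmax(-rx$lb, 0)
  ## enzyme usage variables per (reaction, alternative)
  alts <- list()
  for (j in seq_len(n)) {
    a <- .gpr_alternatives(net@gpr[[j]])
    if (length(a)) {
      alts[[rx$id[j]]] <- a
    }
  }
  usage_index <- do.call(rbind, lapply(names(alts), function(r)
    data.frame(reaction = r, alt = seq_along(alts[[r]]))))
  nu <- if (is.null(usage_index)) 0L else nrow(usage_index)
  nv <- 2L * n
  ntot <- nv + nu

  ## steady state rows
  A <- cbind(S, -S, matrix(0, nrow(S), nu))
  rhs <- rep(0, nrow(S))
  sense <- rep("=", nrow(S))
  ## capacity couplings: v_dir - 3600 k sum(y) <= 0
  genes <- names(net@geneMW)
  for (d in c("f", "b")) {
    for (r in names(alts)) {
      j <- match(r, rx$id)
      cap <- if (d == "f") ubF[j] else ubB[j]
      if (cap <= 0) next
      k <- .moment_keff(problem, r, backward = d == "b")
      row <- numeric(ntot)
      row[if (d == "f") j else n + j] <- 1
      urows <- which(usage_index$reaction == r)
      row[nv + urows] <- -3600 * k
      A <- rbind(A, row)
      rhs <- c(rhs, 0)
      sense <- c(sense, "<=")
    }
  }
  ## budget: sum_g MW_g * sum_{(r,alt) containing g} y <= C
  budget_row <- numeric(ntot)
  if (nu > 0) {
    for (u in seq_len(nu)) {
      gset <- alts[[usage_index$reaction[u]]][[usage_index$alt[u]]]
      budget_row[nv + u] <- sum(net@geneMW[gset])
    }
    A <- rbind(A, budget_row)
    rhs <- c(rhs, problem$budget)
    sense <- c(sense, "<=")
  }
  lb <- c(lbF, lbB, rep(0, nu))
  ub <- c(ubF, ubB, rep(1e6, nu))
  jbio <- match(net@biomassReaction, rx$id)
  obj <- numeric(ntot); obj[jbio] <- 1
  res <- .lp_solve(obj, A, rhs, sense, lb, ub, maximize = TRUE)
  if (res$status != "optimal") {
    stop("MOMENT problem is ", res$status)
  }
  mu <- res$value
  ## stage 2: parsimonious enzyme allocation at fixed growth
  if (nu > 0) {
    lb2 <- lb; ub2 <- ub
    lb2[jbio] <- mu - 1e-9; ub2[jbio] <- mu + 1e-9
    res2 <- .lp_solve(budget_row, A, rhs, sense, lb2, ub2,
                      maximize = FALSE)
    if (res2$status == "optimal") res <- res2
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  E <- setNames(numeric(length(genes)), genes)
  if (nu > 0) {
    yv <- res$x[nv + seq_len(nu)]
    for (u in seq_len(nu)) {
      gset <- alts[[usage_index$reaction[u]]][[usage_index$alt[u]]]
      E[gset] <- E[gset] + yv[u]
    }
  }
  mass <- E * net@geneMW[genes]
  expressed <- mass > 1e-12
  fr <- setNames(numeric(0), character(0))
  if (any(expressed)) {
    fr <- mass[expressed] / sum(mass[expressed])
  }
  new("MomentSolution", growthRate = mu,
      fluxes = new("FluxVector", values = setNames(v, rx$id),
                   objectiveValue = mu),
      enzymeConc = E, enzymeMass = mass, massFractions = fr,
      budget = problem$budget)
}

#' Predicted metabolic-proteome mass fractions
#'
#' fraction_g = MW_g E_g / sum(MW E) over expressed genes.
#'
#' @param solution a \linkS4class{MomentSolution}
#' @return named numeric summing to 1
#' @export
predictedMassFractions <- function(solution) {
  fr <- solution@massFractions
  if (!length(fr)) stop("no expressed genes in the MOMENT solution")
  fr
}

#' Compare predicted and measured proteome mass fractions
#'
#' Measured copies/cell are converted to mass fractions (copies x MW,
#' normalized over the matched set); genes enter only with predicted
#' fraction > 0 and measured copies > 0, optionally intersected with the
#' matched sets of other parameterizations and with exclusion lists
#' (membrane-complex subunits, expression machinery). The reported error
#' is the RMSE of log10 mass fractions over the final gene set.
#'
#' @param predicted named numeric of predicted mass fractions
#' @param measuredCopies named numeric of measured copies/cell
#' @param geneMW named numeric molecular weights for the measured genes
#' @param intersectWith optional list of gene-id vectors; the comparison
#'   set is intersected with each
#' @param excludeGenes genes excluded from the comparison
#' @return list of class \code{ProteomeComparison}: \code{genes},
#'   \code{rmse}, \code{n}, and the matched log10 fraction vectors
#' @export
compareProteome <- function(predicted, measuredCopies, geneMW,
                            intersectWith = NULL,
                            excludeGenes = character(0)) {
  genes <- intersect(names(predicted)[predicted > 0],
                     names(measuredCopies)[measuredCopies > 0])
  genes <- setdiff(genes, excludeGenes)
  if (!is.null(intersectWith)) {
    for (s in intersectWith) genes <- intersect(genes, s)
  }
  if (!length(genes)) stop("no comparable genes after matching")
  meas_mass <- measuredCopies[genes] * geneMW[genes]
  meas_fr <- meas_mass / sum(meas_mass)
  pred_fr <- predicted[genes] / sum(predicted[genes])
  rmse <- sqrt(mean((log10(pred_fr) - log10(meas_fr))^2))
  structure(list(genes = genes, rmse = rmse, n = length(genes),
                 predictedLog10 = log10(pred_fr),
                 measuredLog10 = log10(meas_fr)),
            class = "ProteomeComparison")
}
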