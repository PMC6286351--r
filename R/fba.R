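#' Flux balance analysis
#'
#' Solves the FBA linear program: optimize the flux of a chosen reaction
#' subject to the steady-state constraint S v = 0 and the flux bounds of the
#' network.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param objective reaction id to optimize (default: the biomass reaction)
#' @param direction \code{"max"} or \code{"min"}
#' @return a \linkS4class{FluxVector}; its \code{objectiveValue} is the LP
#'   optimum
#' @examples
#' net <- generateToyGem(toyGemSpec(seed = 1))
#' sol <- solveFba(net)
#' objectiveValue(sol)
#' @export
solveFba <- function(network, objective = biomassReaction(network),
                     direction = c("max", "min")) {
  direction <- match.arg(direction)
  rx <- network@reactions
  if (!(objective %in% rx$id)) {
    stop("unknown objective reaction: ", objective)
  }
  S <- as.matrix(network@stoich)
  n <- nrow(rx)
  obj <- as.numeric(rx$id == objective)
  res <- .lp_solve(obj, S, rep(0, nrow(S)), rep("=", nrow(S)),
                   rx$lb, rx$ub, maximize = direction == "max")
  if (res$status != "optimal") {
    stop("FBA problem is ", res$status, " for objective ", objective)
  }
  new("FluxVector", values = setNames(res$x, rx$id),
      objectiveValue = res$value)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: first the FBA growth optimum is computed, then, holding
#' growth at that optimum, the total absolute flux is minimized. The L1
#' objective is linearized by splitting every reaction into non-negative
#' forward and backward components. An optional lexicographic refinement
#' stage additionally minimizes each |v_i| in reaction-index order at the
#' fixed growth and total-flux optima, which pins down a unique flux vector
#' on degenerate alternative optima.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param objective reaction whose optimum is held fixed (default biomass)
#' @param lexicographic refine degenerate optima to a reproducible vertex
#'   (default \code{TRUE})
#' @return a \linkS4class{FluxVector}; \code{objectiveValue} is the growth
#'   optimum (not the parsimony objective)
#' @examples
#' net <- generateToyGem(toyGemSpec(seed = 1))
#' sol <- solvePfba(net)
#' sum(abs(fluxes(sol)))
#' @export
solvePfba <- function(network, objective = biomassReaction(network),
                      lexicographic = TRUE) {
  fba <- solveFba(network, objective)
  mu <- fba@objectiveValue
  rx <- network@reactions
  n <- nrow(rx)
  S <- as.matrix(network@stoich)
  ## variables: f (forward), b (backward); v = f - b
  A <- cbind(S, -S)
  lbF <- pmax(rx$lb, 0); ubF <- pmax(rx$ub, 0)
  lbB <- pmax(-rx$ub, 0); ubB <- pmax(-rx$lb, 0)
  j <- match(objective, rx$id)
  ## pin the growth optimum
  if (mu >= 0) {
    lbF[j] <- mu; ubF[j] <- mu; ubB[j] <- lbB[j] <- 0
  } else {
    lbB[j] <- -mu; ubB[j] <- -mu; ubF[j] <- lbF[j] <- 0
  }
  obj <- rep(1, 2L * n)
  rhs <- rep(0, nrow(S)); sense <- rep("=", nrow(S))
  res <- .lp_solve(obj, A, rhs, sense, c(lbF, lbB), c(ubF, ubB),
                   maximize = FALSE)
  if (res$status != "optimal") {
    stop("pFBA stage 2 is ", res$status)
  }
  if (lexicographic) {
    ## fix total |v| and minimize each |v_i| in index order
    A <- rbind(A, obj)
    rhs <- c(rhs, res$value)
    sense <- c(sense, "<=")
    for (i in seq_len(n)) {
      if (i == j) next
      ei <- numeric(2L * n); ei[i] <- 1; ei[n + i] <- 1
      ri <- .lp_solve(ei, A, rhs, sense, c(lbF, lbB), c(ubF, ubB),
                      maximize = FALSE)
      if (ri$status != "optimal") break
      A <- rbind(A, ei)
      rhs <- c(rhs, ri$value + 1e-10)
      sense <- c(sense, "<=")
      res <- ri
    }
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  new("FluxVector", values = setNames(v, rx$id), objectiveValue = mu)
}

## cheap feasibility probe: is growth possible in the current bounds?
.growth_feasible <- function(network, tol = 1e-9) {
  sol <- tryCatch(solveFba(network), error = function(e) NULL)
  !is.null(sol) && sol@objectiveValue > 1e-6
}
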