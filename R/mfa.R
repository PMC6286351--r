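## MFA-constrained flux states: the three-stage fit of a steady-state flux
## distribution to measured (13C-MFA style) fluxes.
##
## Stage 1: quadratic fit    min sum_i (v_i - d_i)^2   s.t. Sv = 0, bounds
## Stage 2: max ATPM         with measured fluxes pinned at stage-1 values
## Stage 3: min ||v||_2      with ATPM additionally pinned at its optimum

#' Fit a steady-state flux distribution to measured fluxes
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param measured named numeric of measured fluxes (mmol/gDW/h); names are
#'   reaction ids
#' @param atpmReaction id of the ATP-maintenance reaction to maximize in
#'   stage 2
#' @param pinTol half-width by which equality pins are widened to avoid
#'   numerical infeasibility (default 1e-6)
#' @return an object of class \code{MfaFitResult}: list with
#'   \code{stage1_flux} and \code{final_flux} (\linkS4class{FluxVector}s),
#'   \code{atpm_optimum}, and \code{pearson_to_data}
#' @examples
#' net <- generateToyGem(toyGemSpec(seed = 1))
#' v <- fluxes(solvePfba(net))
#' fit <- mfaConstrainedFlux(net, v[c("UPT1", "BIOMASS")], "ATPM")
#' fit$pearson_to_data
#' @export
mfaConstrainedFlux <- function(network, measured, atpmReaction,
                               pinTol = 1e-6) {
  rx <- network@reactions
  if (!all(names(measured) %in% rx$id)) {
    stop("measured fluxes reference unknown reactions: ",
         paste(setdiff(names(measured), rx$id), collapse = ", "))
  }
  if (!(atpmReaction %in% rx$id)) {
    stop("unknown ATPM reaction: ", atpmReaction)
  }
  S <- as.matrix(network@stoich)
  n <- nrow(rx)
  midx <- match(names(measured), rx$id)

  ## stage 1: QP fit to the data (tiny ridge keeps the Hessian positive
  ## definite on the unmeasured coordinates)
  w <- rep(1e-8, n)
  w[midx] <- 1
  dlin <- numeric(n)
  dlin[midx] <- -2 * as.numeric(measured)
  qp1 <- tryCatch(
    pracma::quadprog(C = diag(2 * w), d = dlin, Aeq = S,
                     beq = rep(0, nrow(S)), lb = rx$lb, ub = rx$ub),
    error = function(e) stop("MFA stage 1 (QP fit) failed: ",
                             conditionMessage(e)))
  v1 <- qp1$xmin
  stage1 <- new("FluxVector", values = setNames(v1, rx$id),
                objectiveValue = sum((v1[midx] - measured)^2))
  pearson <- if (length(midx) >= 3 && sd(measured) > 0 &&
                 sd(v1[midx]) > 0) {
    cor(v1[midx], as.numeric(measured))
  } else if (max(abs(v1[midx] - measured)) < 1e-6) 1 else NA_real_

  ## stage 2: pin measured fluxes, maximize ATPM
  lb2 <- rx$lb; ub2 <- rx$ub
  lb2[midx] <- v1[midx] - pinTol
  ub2[midx] <- v1[midx] + pinTol
  aidx <- match(atpmReaction, rx$id)
  objA <- as.numeric(seq_len(n) == aidx)
  lp2 <- .lp_solve(objA, S, rep(0, nrow(S)), rep("=", nrow(S)), lb2, ub2,
                   maximize = TRUE)
  if (lp2$status != "optimal") {
    stop("MFA stage 2 (ATPM maximization) is ", lp2$status)
  }
  atpm <- lp2$value

  ## stage 3: pin ATPM as well, minimize the Euclidean norm of v
  lb3 <- lb2; ub3 <- ub2
  lb3[aidx] <- atpm - pinTol
  ub3[aidx] <- atpm + pinTol
  qp3 <- tryCatch(
    pracma::quadprog(C = diag(2, n), d = numeric(n), Aeq = S,
                     beq = rep(0, nrow(S)), lb = lb3, ub = ub3),
    error = function(e) stop("MFA stage 3 (L2 parsimony) failed: ",
                             conditionMessage(e)))
  v3 <- qp3$xmin
  final <- new("FluxVector", values = setNames(v3, rx$id),
               objectiveValue = sqrt(sum(v3^2)))
  structure(list(stage1_flux = stage1, atpm_optimum = atpm,
                 final_flux = final, pearson_to_data = pearson),
            class = "MfaFitResult")
}

#' Write per-condition MFA fit results as TSV
#'
#' @param fits named list of \code{MfaFitResult} (one per condition)
#' @param path output TSV with columns condition, reaction_id, flux,
#'   atpm_optimum, pearson_to_data
#' @export
writeMfaFitTsv <- function(fits, path) {
  rows <- do.call(rbind, lapply(names(fits), function(cond) {
    f <- fits[[cond]]
    data.frame(condition = cond,
               reaction_id = names(f$final_flux@values),
               flux = unname(f$final_flux@values),
               atpm_optimum = f$atpm_optimum,
               pearson_to_data = f$pearson_to_data)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
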