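## Monte Carlo sampling of growth environments and the averaged-pFBA flux
## feature.

#' Sample a random growth environment
#'
#' One draw of the environment sampler: oxygen uptake is allowed with
#' probability 1/2; for each of the elements C, N, S and P one source
#' exchange is drawn uniformly, plus k additional sources with
#' k ~ Binomial(2, 1/2) (truncated to the available candidates, drawn
#' without replacement). Carbon uptake lower bounds are normalized to the
#' carbon atom count of the substrate (\code{-baseCarbonFlux / nC});
#' non-carbon sources and oxygen are opened at -1000. Draws are repeated
#' until the environment sustains growth.
#'
#' Uses R's global RNG stream; seed with \code{set.seed} (or via the
#' \code{seed} argument of \code{\link{averageSampledFlux}}) for
#' reproducibility.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param baseCarbonFlux total carbon uptake budget in mmol carbon/gDW/h
#'   (default 60, so a 6-carbon substrate gets a lower bound of -10)
#' @param attemptCap maximum number of rejected draws before erroring
#' @param cache optional environment used to memoise growth feasibility per
#'   distinct environment signature (the sampler is exact either way)
#' @return an object of class \code{EnvironmentSample}: list with
#'   \code{oxygen_allowed}, \code{sources} (per element),
#'   \code{uptake_bounds} (named lower bounds) and \code{attempts}
#' @export
sampleEnvironment <- function(network, baseCarbonFlux = 60,
                              attemptCap = 10000L, cache = NULL) {
  cand <- lapply(setNames(nm = c("C", "N", "S", "P")),
                 function(el) .source_exchanges(network, el))
  for (el in names(cand)) {
    if (!length(cand[[el]])) {
      stop("network has no exchange able to supply element ", el)
    }
  }
  for (attempt in seq_len(attemptCap)) {
    oxy <- length(network@oxygenExchange) > 0 && runif(1) < 0.5
    src <- lapply(cand, function(cc) {
      k <- rbinom(1L, 2L, 0.5)
      n_extra <- min(k, length(cc) - 1L)
      first <- sample(cc, 1L)
      extra <- if (n_extra > 0)
        sample(setdiff(cc, first), n_extra) else character(0)
      c(first, extra)
    })
    bounds <- numeric(0)
    for (e in unique(unlist(src[c("N", "S", "P")]))) bounds[e] <- -1000
    for (e in src$C) {
      bounds[e] <- -baseCarbonFlux / .exchange_atoms(network, e, "C")
    }
    env <- structure(list(oxygen_allowed = oxy, sources = src,
                          uptake_bounds = bounds, attempts = attempt),
                     class = "EnvironmentSample")
    key <- paste(oxy, paste(sort(names(bounds)), collapse = ","))
    ok <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      grows <- .growth_feasible(applyEnvironment(network, env))
      if (!is.null(cache)) cache[[key]] <- grows
      grows
    }
    if (ok) return(env)
  }
  stop("no growth-sustaining environment found in ", attemptCap,
       " attempts")
}

#' Apply an environment sample to a network
#'
#' Closes uptake for every source exchange, then opens the sampled sources
#' at their drawn lower bounds and oxygen at -1000 when allowed. Secretion
#' bounds are untouched.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param env an \code{EnvironmentSample}
#' @return the bounded \linkS4class{MetabolicNetwork}
#' @export
applyEnvironment <- function(network, env) {
  rx <- network@reactions
  all_src <- unique(unlist(lapply(c("C", "N", "S", "P"),
                                  function(el)
                                    .source_exchanges(network, el))))
  rx$lb[rx$id %in% all_src] <- 0
  for (e in names(env$uptake_bounds)) {
    rx$lb[rx$id == e] <- env$uptake_bounds[[e]]
  }
  if (length(network@oxygenExchange)) {
    rx$lb[rx$id == network@oxygenExchange] <-
      if (isTRUE(env$oxygen_allowed)) -1000 else 0
  }
  network@reactions <- rx
  validObject(network)
  network
}

#' Average pFBA flux over sampled environments (the flux feature)
#'
#' Draws growth-sustaining environments with \code{\link{sampleEnvironment}}
#' (rejected draws do not count toward \code{nEnvironments}), solves pFBA in
#' each, and returns the per-reaction arithmetic mean flux. pFBA solutions
#' are memoised per distinct environment signature, so repeated draws of the
#' same environment cost nothing; the result is deterministic given
#' \code{seed} and invariant to the order in which distinct environments
#' happen to be drawn.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param nEnvironments number of (accepted) environments to average over
#' @param seed RNG seed
#' @param baseCarbonFlux,attemptCap passed to \code{\link{sampleEnvironment}}
#' @param lexicographic passed to \code{\link{solvePfba}}; defaults to
#'   \code{FALSE} here because the mean over environments is insensitive to
#'   which vertex of a degenerate optimal face is reported, and the
#'   refinement multiplies the LP count
#' @return named numeric vector of mean fluxes (mmol/gDW/h)
#' @export
averageSampledFlux <- function(network, nEnvironments = 10000L, seed = 1L,
                               baseCarbonFlux = 60, attemptCap = 10000L,
                               lexicographic = FALSE) {
  stopifnot(nEnvironments >= 1)
  .with_seed(seed, {
    feas_cache <- new.env(parent = emptyenv())
    flux_cache <- new.env(parent = emptyenv())
    rxids <- network@reactions$id
    acc <- setNames(numeric(length(rxids)), rxids)
    for (i in seq_len(nEnvironments)) {
      env <- sampleEnvironment(network, baseCarbonFlux, attemptCap,
                               cache = feas_cache)
      o <- order(names(env$uptake_bounds))
      key <- paste(env$oxygen_allowed,
                   paste(names(env$uptake_bounds)[o],
                         signif(env$uptake_bounds[o], 12),
                         collapse = ","))
      v <- flux_cache[[key]]
      if (is.null(v)) {
        sol <- solvePfba(applyEnvironment(network, env),
                         lexicographic = lexicographic)
        v <- sol@values
        flux_cache[[key]] <- v
      }
      acc <- acc + v
    }
    acc / nEnvironments
  })
}
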