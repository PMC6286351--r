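## Thermodynamic features: reaction Gibbs energies from equilibrium
## constants and metabolite concentrations, the efficiency parameter
## eta_rev = 1 - exp(dG/RT) = 1 - Q/Keq, and a feasibility-constrained
## hit-and-run sampler over concentration/Keq uncertainty.

.RGAS <- 8.314  # J / mol / K

#' Reaction Gibbs energy and reaction quotient
#'
#' Q is the product of metabolite concentrations raised to their signed
#' stoichiometric coefficients; dG = RT ln(Q / Keq) in kJ/mol (natural log,
#' R = 8.314 J/mol/K). At Q = Keq the reaction is at equilibrium and dG = 0.
#'
#' @param stoich named numeric of signed stoichiometric coefficients
#'   (negative = substrate)
#' @param keq equilibrium constant (> 0)
#' @param conc named numeric of concentrations in M (> 0); must cover every
#'   participating metabolite
#' @param temperature temperature in K
#' @return list with \code{deltaG} (kJ/mol) and \code{Q}
#' @examples
#' reactionGibbs(c(A = -1, B = 1), keq = 10, conc = c(A = 1, B = 1))
#' @export
reactionGibbs <- function(stoich, keq, conc, temperature = 298.15) {
  stopifnot(keq > 0, temperature > 0)
  miss <- setdiff(names(stoich), names(conc))
  if (length(miss)) {
    stop("missing concentration for participant(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(conc[names(stoich)] <= 0)) {
    stop("concentrations must be strictly positive")
  }
  lnQ <- sum(stoich * log(conc[names(stoich)]))
  dG <- .RGAS * temperature * (lnQ - log(keq)) / 1000
  list(deltaG = dG, Q = exp(lnQ))
}

#' Thermodynamic efficiency of a reaction
#'
#' eta_rev = 1 - exp(dG/RT) = 1 - Q/Keq. It is 0 at equilibrium and
#' approaches 1 as the reaction becomes perfectly forward-driven
#' (dG -> -Inf); negative values indicate a reaction operating against its
#' nominal forward direction.
#'
#' @param deltaG reaction Gibbs energy in kJ/mol
#' @param temperature temperature in K
#' @return numeric efficiency (<= 1)
#' @examples
#' etaRev(0)            # equilibrium: 0
#' etaRev(-50)          # strongly forward-driven: ~1
#' @export
etaRev <- function(deltaG, temperature = 298.15) {
  stopifnot(temperature > 0)
  1 - exp(deltaG * 1000 / (.RGAS * temperature))
}

#' Describe one growth condition for thermodynamic sampling
#'
#' @param conc named numeric point estimates of metabolite concentrations
#'   (M)
#' @param concLower,concUpper named numerics bracketing \code{conc};
#'   metabolites absent from these default to \code{defaultBounds}
#' @param keq named numeric equilibrium constants per reaction
#' @param keqLower,keqUpper bracketing uncertainty on \code{keq} (defaults:
#'   the point estimate, i.e. no uncertainty)
#' @param temperature temperature in K
#' @param flux named numeric condition flux vector (identifies the
#'   high-flux reactions whose dG sign is constrained)
#' @param defaultBounds concentration range used for unmeasured metabolites
#'   (default 1e-6 to 1e-1 M, a standard physiological range)
#' @return an object of class \code{ThermoCondition}
#' @export
thermoCondition <- function(conc, concLower = NULL, concUpper = NULL,
                            keq, keqLower = NULL, keqUpper = NULL,
                            temperature = 298.15, flux = numeric(0),
                            defaultBounds = c(1e-6, 1e-1)) {
  stopifnot(all(conc > 0), all(keq > 0), temperature > 0)
  lo <- setNames(rep(defaultBounds[1L], length(conc)), names(conc))
  hi <- setNames(rep(defaultBounds[2L], length(conc)), names(conc))
  if (!is.null(concLower)) lo[names(concLower)] <- concLower
  if (!is.null(concUpper)) hi[names(concUpper)] <- concUpper
  klo <- if (is.null(keqLower)) keq else {
    k <- keq; k[names(keqLower)] <- keqLower; k
  }
  khi <- if (is.null(keqUpper)) keq else {
    k <- keq; k[names(keqUpper)] <- keqUpper; k
  }
  if (any(lo > conc | conc > hi)) {
    stop("concentration bounds must bracket the point estimates")
  }
  if (any(klo > keq | keq > khi)) {
    stop("Keq bounds must bracket the point estimates")
  }
  structure(list(conc = conc, concLower = lo, concUpper = hi,
                 keq = keq, keqLower = klo, keqUpper = khi,
                 temperature = temperature, flux = flux),
            class = "ThermoCondition")
}

#' Thermodynamic efficiency feature across growth conditions
#'
#' Per condition, samples log-concentration and log-Keq vectors uniformly
#' within their bounds, subject to the directionality constraint that
#' sign(dG) opposes the flux direction for every reaction with
#' |v| > \code{fluxThreshold} (hit-and-run in log space, after a strictly
#' feasible interior point is found by LP). eta_rev is computed for every
#' evaluated reaction in every sample, averaged over samples, then averaged
#' over conditions.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param conditions list of \code{\link{thermoCondition}} objects
#' @param fluxThreshold flux magnitude above which a reaction's dG sign is
#'   constrained (default 0.1 mmol/gDW/h)
#' @param nSamples accepted samples per condition (default 1000)
#' @param burnIn discarded leading hit-and-run steps (default 100)
#' @param seed RNG seed
#' @return list of class \code{ThermoResult} with \code{perCondition}
#'   (data.frame: condition, reaction, deltaG, Q, eta_rev — per-sample
#'   means) and \code{etaRevMean} (named, averaged across conditions)
#' @export
thermoFeature <- function(network, conditions, fluxThreshold = 0.1,
                          nSamples = 1000L, burnIn = 100L, seed = 1L) {
  stopifnot(nSamples >= 1)
  .with_seed(seed, {
    per <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      per[[ci]] <- .thermo_condition_sample(network, cond, fluxThreshold,
                                            nSamples, burnIn, ci)
    }
    tab <- do.call(rbind, per)
    etaMean <- tapply(tab$eta_rev, tab$reaction, mean)
    structure(list(perCondition = tab,
                   etaRevMean = setNames(as.numeric(etaMean),
                                         names(etaMean))),
              class = "ThermoResult")
  })
}

.thermo_condition_sample <- function(network, cond, fluxThreshold,
                                     nSamples, burnIn, cond_id) {
  rxn_ids <- names(cond$keq)
  S <- network@stoich
  jidx <- match(rxn_ids, network@reactions$id)
  if (anyNA(jidx)) {
    stop("Keq given for unknown reaction(s): ",
         paste(rxn_ids[is.na(jidx)], collapse = ", "))
  }
  mets <- names(cond$conc)
  need <- unique(unlist(lapply(jidx, function(j)
    network@metabolites$id[which(S[, j] != 0)])))
  miss <- setdiff(need, mets)
  if (length(miss)) {
    stop("missing concentration for participant(s): ",
         paste(miss, collapse = ", "))
  }
  d1 <- length(mets)
  d2 <- length(rxn_ids)
  lo <- c(log(cond$concLower), log(cond$keqLower))
  hi <- c(log(cond$concUpper), log(cond$keqUpper))
  ## stoichiometry rows in log space: dG_r propto S_r . z - u_r
  Arow <- matrix(0, d2, d1 + d2)
  for (k in seq_len(d2)) {
    sj <- S[, jidx[k]]
    nz <- which(sj != 0)
    Arow[k, match(network@metabolites$id[nz], mets)] <- sj[nz]
    Arow[k, d1 + k] <- -1
  }
  vthis <- cond$flux[rxn_ids]
  vthis[is.na(vthis)] <- 0
  constrained <- which(abs(vthis) > fluxThreshold)
  Acon <- Arow[constrained, , drop = FALSE] * sign(vthis[constrained])

  d <- d1 + d2
  if (nrow(Acon)) {
    ## interior point: minimize the worst signed margin t
    objt <- c(numeric(d), 1)
    Afe <- cbind(Acon, -1)
    lp <- .lp_solve(objt, Afe, rep(0, nrow(Acon)),
                    rep("<=", nrow(Acon)), c(lo, -1e6), c(hi, 1e6),
                    maximize = FALSE)
    if (lp$status != "optimal" || lp$value >= 0) {
      marg <- if (lp$status == "optimal")
        as.vector(Acon %*% lp$x[seq_len(d)]) else rep(Inf, nrow(Acon))
      stop("no feasible concentration vector; violated reaction(s): ",
           paste(rxn_ids[constrained][marg >= 0], collapse = ", "))
    }
    w <- lp$x[seq_len(d)]
  } else {
    w <- (lo + hi) / 2
  }
  fixed <- hi - lo < 1e-12
  if (all(fixed)) {
    draws <- matrix(w, nSamples, d, byrow = TRUE)
  } else {
    draws <- matrix(NA_real_, nSamples, d)
    total <- burnIn + nSamples
    for (s in seq_len(total)) {
      dir <- rnorm(d)
      dir[fixed] <- 0
      dir <- dir / sqrt(sum(dir^2))
      tmin <- -Inf; tmax <- Inf
      for (i in which(!fixed)) {
        r <- sort(c((lo[i] - w[i]) / dir[i], (hi[i] - w[i]) / dir[i]))
        tmin <- max(tmin, r[1L]); tmax <- min(tmax, r[2L])
      }
      if (nrow(Acon)) {
        aw <- as.vector(Acon %*% w)
        ad <- as.vector(Acon %*% dir)
        for (k in seq_len(nrow(Acon))) {
          if (abs(ad[k]) < 1e-14) next
          bnd <- -aw[k] / ad[k]
          if (ad[k] > 0) tmax <- min(tmax, bnd) else tmin <- max(tmin, bnd)
        }
      }
      if (tmax > tmin) w <- w + runif(1, tmin, tmax) * dir
      if (s > burnIn) draws[s - burnIn, ] <- w
    }
  }
  ## evaluate all reactions (constrained or not) per sample
  lnQmKeq <- draws %*% t(Arow)                 # ln Q - ln Keq, per sample
  RT <- .RGAS * cond$temperature / 1000
  dG <- RT * lnQmKeq
  eta <- 1 - exp(lnQmKeq)
  lnQ <- lnQmKeq + matrix(draws[, d1 + seq_len(d2), drop = FALSE],
                          ncol = d2)
  data.frame(condition = cond_id, reaction = rxn_ids,
             deltaG = colMeans(dG), Q = colMeans(exp(lnQ)),
             eta_rev = colMeans(eta), row.names = NULL)
}
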