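## Synthetic feature tables, turnover observations and proteomics: every
## input the pipeline needs, generated with planted structure so that
## recovery can be checked quantitatively.

#' Planted feature-to-turnover model
#'
#' A log-linear model on the linearized features, with the sign structure
#' expected for catalytic turnover: positive on flux, negative on active
#' site depth, generalist count and solvent exposure. The noise standard
#' deviation is derived from the requested population R^2 and the realized
#' variance of the planted signal, so the implied population R^2 of every
#' generated dataset is known by construction.
#'
#' @param coefficients named numeric of feature coefficients on log10
#'   scale
#' @param targetR2 population fraction of variance explained (0, 1)
#' @param missingness named numeric of per-feature missing fractions
#' @param blockMissing fraction of rows whose active-site features are
#'   missing as a block (emulating enzymes without structural data)
#' @param intercept mean log10 turnover at feature center (default 1.5,
#'   i.e. about 30/s)
#' @param seed RNG seed
#' @return an object of class \code{PlantedTurnoverModel}
#' @export
plantedTurnoverModel <- function(
    coefficients = c(flux_feature = 0.55, molecular_weight = 0.25,
                     generalist = -0.25, active_site_depth = -0.45,
                     active_site_exposure = -0.35, eta_rev = 0.5,
                     km = 0.2),
    targetR2 = 0.76, missingness = c(active_site_depth = 0.15,
                                     eta_rev = 0.2, km = 0.3),
    blockMissing = 0.1, intercept = 1.5, seed = 1L) {
  if (targetR2 <= 0 || targetR2 >= 1) {
    stop("planted population R^2 must lie strictly inside (0, 1)")
  }
  structure(list(coefficients = coefficients, targetR2 = targetR2,
                 missingness = missingness, blockMissing = blockMissing,
                 intercept = intercept, seed = as.integer(seed)),
            class = "PlantedTurnoverModel")
}

.ACTIVE_SITE_FEATURES <- c("active_site_depth", "active_site_exposure",
                           "active_site_hydrophobicity",
                           "n_active_site_residues",
                           "active_site_secondary_structure")

#' Generate a reaction feature table and turnover observations
#'
#' Network features (flux feature, generalist, substrate count, summarized
#' molecular weight) are computed from the network; structural and
#' biochemical features are drawn from fixed documented distributions
#' (depth lognormal, exposure/disorder Beta, hydrophobicity normal, EC
#' class and secondary structure categorical). log10 turnover is the
#' planted linear combination plus Gaussian noise sized for the target
#' population R^2; missingness is applied after generation. Two
#' observation sets are emitted: an in-vivo-flavoured one restricted to
#' unique homomeric reactions, and an in-vitro-flavoured record table with
#' assay pH/temperature plus mutant, inhibitor, duplicate and unmapped
#' decoys for the curation filters.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param planted a \code{\link{plantedTurnoverModel}}
#' @param nEnvironments environments for the flux feature (desk-scale
#'   default 100)
#' @return list with \code{features} (linearized, with missingness),
#'   \code{truth} (reaction, log10 turnover, noiseSigma, populationR2),
#'   \code{invivo} (reaction, value 1/s), \code{invitro}
#'   (\code{TurnoverRecord}-style data.frame) and \code{reactionMap}
#' @export
generateTurnoverDataset <- function(network, planted,
                                    nEnvironments = 100L) {
  stopifnot(inherits(planted, "PlantedTurnoverModel"))
  meanflux <- averageSampledFlux(network, nEnvironments,
                                 seed = planted$seed)
  .with_seed(planted$seed + 1L, {
    rxids <- network@reactions$id[nzchar(network@gpr)]
    nr <- length(rxids)
    genes <- names(network@geneMW)
    gene_tab <- data.frame(
      gene = genes,
      molecular_weight = unname(network@geneMW),
      disorder_fraction = stats::rbeta(length(genes), 2, 8),
      active_site_depth = stats::rlnorm(length(genes), log(10), 0.4),
      active_site_exposure = stats::rbeta(length(genes), 2, 5),
      active_site_hydrophobicity = rnorm(length(genes), -0.3, 1),
      n_active_site_residues = 1 + stats::rpois(length(genes), 4))
    summ <- summarizeGeneFeatures(network, gene_tab)
    summ <- summ[match(rxids, summ$reaction), ]
    raw <- data.frame(
      reaction = rxids,
      flux_feature = abs(meanflux[rxids]),
      generalist = vapply(rxids, function(r)
        as.numeric(generalistFeature(network, r)), 0),
      n_substrates = vapply(rxids, function(r)
        as.numeric(substrateCount(network, r)), 0),
      molecular_weight = summ$molecular_weight,
      disorder_fraction = summ$disorder_fraction,
      active_site_depth = summ$active_site_depth,
      active_site_exposure = summ$active_site_exposure,
      active_site_hydrophobicity = summ$active_site_hydrophobicity,
      n_active_site_residues = summ$n_active_site_residues,
      eta_rev = stats::rbeta(nr, 5, 2),
      km = stats::rlnorm(nr, log(1e-4), 1),
      substrate_conc = stats::rlnorm(nr, log(1e-3), 1),
      product_conc = stats::rlnorm(nr, log(1e-3), 1),
      row.names = NULL)
    raw$ec_class <- factor(sample(as.character(1:6), nr, replace = TRUE))
    raw$active_site_secondary_structure <-
      factor(sample(c("helix", "sheet", "coil"), nr, replace = TRUE))
    lin <- suppressWarnings(
      linearizeFeatures(raw, tempField = "__none__"))
    ## planted signal on the linearized numeric features
    co <- planted$coefficients
    X <- as.matrix(lin[names(co)])
    Xc <- scale(X, center = TRUE, scale = TRUE)
    Xc[is.na(Xc)] <- 0   # missing network feature contributes no signal
    signal <- as.vector(Xc %*% co)
    vs <- var(signal)
    sigma <- sqrt(vs * (1 - planted$targetR2) / planted$targetR2)
    ylog <- planted$intercept + signal + rnorm(nr, 0, sigma)
    truth <- data.frame(reaction = rxids, log10_turnover = ylog,
                        noiseSigma = sigma,
                        populationR2 = planted$targetR2)
    ## missingness after generation
    feats <- lin
    for (f in names(planted$missingness)) {
      if (!(f %in% names(feats))) next
      mi <- runif(nr) < planted$missingness[[f]]
      feats[[f]][mi] <- NA
    }
    if (planted$blockMissing > 0) {
      bl <- runif(nr) < planted$blockMissing
      for (f in intersect(.ACTIVE_SITE_FEATURES, names(feats))) {
        feats[[f]][bl] <- NA
      }
    }
    ## in-vivo set: unique homomers only
    hom <- uniqueHomomers(network)
    iv <- truth[truth$reaction %in% hom$reaction, ]
    invivo <- data.frame(reaction = iv$reaction,
                         value = 10^iv$log10_turnover,
                         kind = "in_vivo_kappmax")
    ## in-vitro records with curation decoys
    base <- truth[sample(nr, max(3L, round(0.8 * nr))), ]
    rec <- data.frame(
      record_id = sprintf("rec%03d", seq_len(nrow(base))),
      reaction_key = paste0("key_", base$reaction),
      value = 10^(base$log10_turnover + rnorm(nrow(base), 0, 0.1)),
      source_db = sample(c("BRENDA", "SABIO", "METACYC"), nrow(base),
                         replace = TRUE),
      publication = sprintf("pub%03d", sample(900, nrow(base))),
      mutant = FALSE, inhibitor = FALSE,
      year = sample(1990:2020, nrow(base), replace = TRUE),
      in_vivo_like = runif(nrow(base)) < 0.3,
      assay_ph = rnorm(nrow(base), 7, 0.5),
      assay_temperature = rnorm(nrow(base), 30, 5),
      kind = "in_vitro_kcat")
    ## decoys: a cross-database duplicate, a mutant, an unmapped record
    nrec <- nrow(rec)
    dup <- rec[1L, ]
    dup$record_id <- "rec_dup"
    dup$source_db <- if (rec$source_db[1L] == "BRENDA") "SABIO"
                     else "BRENDA"
    mut <- rec[min(2L, nrec), ]
    mut$record_id <- "rec_mut"; mut$mutant <- TRUE
    mut$publication <- "pub_mut"
    unm <- rec[min(3L, nrec), ]
    unm$record_id <- "rec_unmapped"
    unm$reaction_key <- "key_not_in_model"
    unm$publication <- "pub_unm"
    invitro <- rbind(rec, dup, mut, unm)
    reactionMap <- setNames(rxids, paste0("key_", rxids))
    list(features = feats, truth = truth, invivo = invivo,
         invitro = invitro, reactionMap = reactionMap)
  })
}

#' Generate a planted-model regression dataset of arbitrary size
#'
#' Draws feature rows directly from the documented feature distributions
#' (no network attached), plants the log-linear signal of the model and
#' adds Gaussian noise sized for its target population R^2. This is the
#' regression-scale companion of \code{\link{generateTurnoverDataset}}:
#' use it when the number of observations, not network realism, is what a
#' test or benchmark needs.
#'
#' @param n number of rows
#' @param planted a \code{\link{plantedTurnoverModel}}
#' @param applyMissingness apply the model's missingness pattern (default
#'   TRUE; disable for complete-data regimes)
#' @return list with \code{features}, \code{y} (log10 turnover),
#'   \code{noiseSigma} and \code{populationR2}
#' @export
generateRegressionDataset <- function(n, planted,
                                      applyMissingness = TRUE) {
  stopifnot(inherits(planted, "PlantedTurnoverModel"), n >= 10)
  .with_seed(planted$seed, {
    feats <- data.frame(
      flux_feature = log10(stats::rlnorm(n, log(1), 1.2)),
      generalist = stats::rpois(n, 1.5),
      n_substrates = 1 + stats::rpois(n, 1),
      molecular_weight = log10(stats::rlnorm(n, log(35), 0.35)),
      disorder_fraction = stats::rbeta(n, 2, 8),
      active_site_depth = stats::rlnorm(n, log(10), 0.4),
      active_site_exposure = stats::rbeta(n, 2, 5),
      active_site_hydrophobicity = rnorm(n, -0.3, 1),
      n_active_site_residues = 1 + stats::rpois(n, 4),
      eta_rev = stats::rbeta(n, 5, 2),
      km = log10(stats::rlnorm(n, log(1e-4), 1)),
      substrate_conc = log10(stats::rlnorm(n, log(1e-3), 1)),
      product_conc = log10(stats::rlnorm(n, log(1e-3), 1)),
      ec_class = factor(sample(as.character(1:6), n, replace = TRUE)),
      active_site_secondary_structure =
        factor(sample(c("helix", "sheet", "coil"), n, replace = TRUE)))
    co <- planted$coefficients
    X <- scale(as.matrix(feats[names(co)]))
    signal <- as.vector(X %*% co)
    vs <- var(signal)
    sigma <- sqrt(vs * (1 - planted$targetR2) / planted$targetR2)
    y <- planted$intercept + signal + rnorm(n, 0, sigma)
    if (applyMissingness) {
      for (f in names(planted$missingness)) {
        if (!(f %in% names(feats))) next
        feats[[f]][runif(n) < planted$missingness[[f]]] <- NA
      }
      if (planted$blockMissing > 0) {
        bl <- runif(n) < planted$blockMissing
        for (f in intersect(.ACTIVE_SITE_FEATURES, names(feats))) {
          feats[[f]][bl] <- NA
        }
      }
    }
    list(features = feats, y = y, noiseSigma = sigma,
         populationR2 = planted$targetR2)
  })
}

.COPIES_PER_MMOL <- 6.022e8  # copies/cell per mmol/gDW at ~1e12 cells/gDW

#' Convert copies/cell to mmol/gDW
#'
#' Uses the fixed documented conversion of about 1e12 cell equivalents per
#' gram dry weight; only relative abundances matter downstream.
#'
#' @param copies numeric copies/cell
#' @return mmol/gDW
#' @export
copiesPerCellToMmol <- function(copies) copies / .COPIES_PER_MMOL

#' Generate synthetic proteomics from MOMENT solutions
#'
#' Solves the capacity-constrained problem per growth condition with the
#' supplied true turnover vector, converts enzyme concentrations to
#' copies/cell and multiplies lognormal noise (sigma on log10 scale).
#' Infeasible conditions are skipped with a warning.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param keffTrue named numeric, true effective turnover rates (1/s)
#' @param conditions named list of \code{EnvironmentSample} objects
#' @param noiseSigmaLog10 lognormal noise SD on log10 scale
#' @param seed RNG seed
#' @param budget protein budget passed to \code{\link{momentProblem}}
#' @return list with \code{abundance} (gene x condition copies/cell),
#'   \code{flux} (reaction x condition), \code{growth} (per condition) and
#'   \code{solutions}
#' @export
generateProteomics <- function(network, keffTrue, conditions,
                               noiseSigmaLog10 = 0.2, seed = 1L,
                               budget = 0.32) {
  stopifnot(all(keffTrue > 0))
  .with_seed(seed, {
    genes <- names(network@geneMW)
    ab <- matrix(NA_real_, length(genes), length(conditions),
                 dimnames = list(genes, names(conditions)))
    fl <- matrix(NA_real_, nrow(network@reactions), length(conditions),
                 dimnames = list(network@reactions$id, names(conditions)))
    gr <- setNames(rep(NA_real_, length(conditions)), names(conditions))
    sols <- list()
    for (ci in seq_along(conditions)) {
      netc <- applyEnvironment(network, conditions[[ci]])
      sol <- tryCatch(
        solveMoment(momentProblem(netc, keffTrue, budget = budget)),
        error = function(e) {
          warning("condition ", names(conditions)[ci], " skipped: ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(sol)) next
      noise <- 10^rnorm(length(genes), 0, noiseSigmaLog10)
      ab[, ci] <- sol@enzymeConc[genes] * .COPIES_PER_MMOL * noise
      fl[, ci] <- sol@fluxes@values
      gr[ci] <- sol@growthRate
      sols[[ci]] <- sol
    }
    keepc <- !is.na(gr)
    list(abundance = ab[, keepc, drop = FALSE],
         flux = fl[, keepc, drop = FALSE], growth = gr[keepc],
         solutions = sols[keepc])
  })
}

#' Write a complete synthetic fixture set
#'
#' Produces the JSON network, feature CSV, turnover CSVs and proteomics
#' CSV under one directory, all derived deterministically from the seeds
#' inside the two specs.
#'
#' @param dir output directory (created if needed)
#' @param gemSpec a \code{\link{toyGemSpec}}
#' @param planted a \code{\link{plantedTurnoverModel}}
#' @param nEnvironments flux-feature environments
#' @return invisibly, the directory
#' @export
writeFixtures <- function(dir, gemSpec = toyGemSpec(),
                          planted = plantedTurnoverModel(),
                          nEnvironments = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generateToyGem(gemSpec)
  writeNetworkJson(net, file.path(dir, "network.json"))
  ds <- generateTurnoverDataset(net, planted, nEnvironments)
  write.csv(ds$features, file.path(dir, "features.csv"),
            row.names = FALSE)
  write.csv(ds$invivo, file.path(dir, "kappmax.csv"), row.names = FALSE)
  write.csv(ds$invitro, file.path(dir, "kcat_records.csv"),
            row.names = FALSE)
  keff <- setNames(10^ds$truth$log10_turnover, ds$truth$reaction)
  env <- .with_seed(gemSpec$seed, sampleEnvironment(net))
  pr <- generateProteomics(net, keff, list(cond1 = env),
                           seed = gemSpec$seed)
  write.csv(as.data.frame(pr$abundance),
            file.path(dir, "proteomics_copies_per_cell.csv"))
  invisible(dir)
}
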