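## End-to-end parameterization experiment: generate a toy network with a
## planted feature-to-turnover law, simulate a measured proteome from the
## true turnover vector, train the prediction ensemble on the
## in-vivo-flavoured observations, and score the three k_eff
## parameterizations (true, ensemble-predicted, median-imputed) by their
## proteome log10 RMSE averaged over growth conditions.
run_ordering_seed <- function(s, n_conditions = 3, noise = 0.2) {
  net <- generateToyGem(toyGemSpec(nCarbon = 4, nInternal = 24,
                                   nIsozyme = 1, nComplex = 1,
                                   pReuse = 0.1, seed = s))
  pl <- plantedTurnoverModel(targetR2 = 0.76, seed = s + 100)
  ds <- generateTurnoverDataset(net, pl, nEnvironments = 60)
  keff_true <- setNames(10^ds$truth$log10_turnover, ds$truth$reaction)
  conds <- list()
  set.seed(s + 200)
  for (ci in seq_len(n_conditions)) {
    conds[[paste0("c", ci)]] <- sampleEnvironment(net)
  }
  pr <- generateProteomics(net, keff_true, conds,
                           noiseSigmaLog10 = noise, seed = s + 300)
  feats <- ds$features
  rownames(feats) <- feats$reaction
  feats$reaction <- NULL
  y <- setNames(rep(NA_real_, nrow(feats)), rownames(feats))
  y[ds$invivo$reaction] <- log10(ds$invivo$value)
  ens <- suppressWarnings(
    buildEnsemble(feats, unname(y), folds = 3, repeats = 1, budget = 4,
                  ntree = 80, seed = s))
  keff_ens <- predictEnsemble(ens, feats)
  med <- 10^ens@globalMedian
  keff_med <- setNames(rep(med, nrow(feats)), rownames(feats))
  score <- function(keff) {
    rmses <- c()
    for (ci in names(conds)) {
      netc <- applyEnvironment(net, conds[[ci]])
      sol <- tryCatch(
        solveMoment(momentProblem(netc, keff, defaultKeff = med)),
        error = function(e) NULL)
      if (is.null(sol)) next
      cmp <- tryCatch(
        compareProteome(massFractions(sol), pr$abundance[, ci],
                        geneMW(net)),
        error = function(e) NULL)
      if (!is.null(cmp)) rmses <- c(rmses, cmp$rmse)
    }
    mean(rmses)
  }
  c(true = score(keff_true), ens = score(keff_ens),
    med = score(keff_med))
}
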