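## The 3 x 4 prediction ensemble: {elastic net, random forest, neural net}
## crossed with four imputation strategies, plus per-member fallback
## medians and the global training median for the median-imputed baseline.

.ENSEMBLE_ALGOS <- c("elastic_net", "random_forest", "neural_net")
.ENSEMBLE_STRATEGIES <- c("none", "labelled_only", "unlabelled_only",
                          "all")

#' Build the turnover-number prediction ensemble
#'
#' Trains one member per algorithm/imputation-strategy combination (twelve
#' in the default configuration). Members with strategy
#' \code{labelled_only} or \code{all} train on the imputed labelled table;
#' members with \code{unlabelled_only} or \code{all} impute the feature
#' rows they are asked to predict on. Each member records the median of
#' its successful training-set predictions as its fallback for rows it
#' cannot predict; the global median of the response parameterizes the
#' median-imputed baseline.
#'
#' @param features data.frame of (labelled) training features
#' @param y response on log10 scale
#' @param folds,repeats,budget,ntree CV protocol and model sizes passed to
#'   \code{\link{modelSpec}} per member
#' @param seed base seed; member m uses seed + m
#' @param algorithms,strategies member grid (defaults give the 12-member
#'   ensemble)
#' @return an \linkS4class{EnsembleModel}
#' @export
buildEnsemble <- function(features, y, folds = 5L, repeats = NULL,
                          budget = 50L, ntree = 500L, seed = 1L,
                          algorithms = .ENSEMBLE_ALGOS,
                          strategies = .ENSEMBLE_STRATEGIES) {
  labelled <- !is.na(y)
  members <- list()
  for (alg in algorithms) {
    ## one seed per algorithm family: its four imputation variants share
    ## fold assignment, so on fully observed data they fit identically
    mseed <- seed + match(alg, algorithms)
    for (strat in strategies) {
      train_x <- features[labelled, , drop = FALSE]
      train_y <- y[labelled]
      if (strat %in% c("labelled_only", "all")) {
        train_x <- imputeFeatures(train_x, strategy = "all",
                                  seed = mseed)
      }
      spec <- modelSpec(alg, folds = folds, repeats = repeats,
                        budget = budget, ntree = ntree, seed = mseed)
      res <- tryCatch(trainCV(train_x, train_y, spec),
                      error = function(e) {
                        warning("ensemble member ", alg, "/", strat,
                                " failed to train: ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(res)) next
      tr_pred <- predictTurnover(res$fit, train_x)
      members[[length(members) + 1L]] <- list(
        algorithm = alg, strategy = strat, fit = res$fit, cv = res$cv,
        fallback = median(tr_pred, na.rm = TRUE),
        yRange = range(train_y),
        imputePrediction = strat %in% c("unlabelled_only", "all"),
        seed = mseed)
    }
  }
  fam <- vapply(members, `[[`, "", "algorithm")
  lost <- setdiff(algorithms, fam)
  if (length(lost)) {
    stop("every member of algorithm family ", paste(lost, collapse = ", "),
         " failed to train")
  }
  new("EnsembleModel", members = members,
      globalMedian = median(y[labelled]),
      featureNames = names(features))
}

#' Predict turnover numbers with the ensemble
#'
#' Each member predicts on log10 scale (imputing the prediction rows first
#' if its strategy says so); rows a member cannot predict receive that
#' member's fallback median. Member predictions are clamped to the member's
#' training response range — an extrapolation guard that matters when small
#' training sets are extrapolated to the genome scale. The ensemble output
#' is the arithmetic mean of the member values per row, exponentiated back
#' to 1/s.
#'
#' @param model an \linkS4class{EnsembleModel}
#' @param rows data.frame of feature rows (row names identify reactions)
#' @param logScale return log10 values instead of 1/s (default FALSE)
#' @return named numeric vector of predicted turnover numbers
#' @export
predictEnsemble <- function(model, rows, logScale = FALSE) {
  stopifnot(is(model, "EnsembleModel"))
  rows <- rows[model@featureNames]
  npr <- nrow(rows)
  mat <- matrix(NA_real_, npr, length(model@members))
  for (mi in seq_along(model@members)) {
    mem <- model@members[[mi]]
    rx <- rows
    if (isTRUE(mem$imputePrediction)) {
      rx <- imputeFeatures(rx, strategy = "all", seed = mem$seed)
    }
    p <- predictTurnover(mem$fit, rx)
    if (!is.null(mem$yRange)) {
      p <- pmin(pmax(p, mem$yRange[1L]), mem$yRange[2L])
    }
    p[is.na(p)] <- mem$fallback
    mat[, mi] <- p
  }
  avg <- rowMeans(mat)
  out <- if (logScale) avg else 10^avg
  setNames(out, rownames(rows))
}
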