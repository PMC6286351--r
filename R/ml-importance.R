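## Random-forest permutation feature importance with a response-permutation
## significance test.

#' Permutation feature importance with significance test
#'
#' Importance is the random-forest out-of-bag permutation measure: the mean
#' increase in out-of-bag MSE across trees when a feature is permuted,
#' scaled by its standard deviation across trees. Significance comes from a
#' response-permutation test: the forest is refit on permuted responses
#' \code{nPermutations} times and each feature's p-value is the fraction of
#' null refits whose importance meets or exceeds the observed one (with the
#' usual +1 correction, so p is in (0, 1]).
#'
#' @param features data.frame of predictors (complete rows are used)
#' @param y response on log10 scale
#' @param nPermutations response permutations for the null (default 500)
#' @param ntree trees per forest (default 500)
#' @param mtry forest mtry (default: randomForest's regression default)
#' @param seed RNG seed
#' @return data.frame of class \code{ImportanceTable}: feature,
#'   importance, p_value — ordered by decreasing importance
#' @export
permutationImportance <- function(features, y, nPermutations = 500L,
                                  ntree = 500L, mtry = NULL, seed = 1L) {
  keep <- complete.cases(features) & !is.na(y)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  template <- .design_template(features)
  Xm <- .design_matrix(features, template)
  if (is.null(mtry)) mtry <- max(floor(ncol(Xm) / 3), 1L)
  .with_seed(seed, {
    rf <- randomForest::randomForest(Xm, y, ntree = ntree, mtry = mtry,
                                     importance = TRUE)
    obs <- randomForest::importance(rf, type = 1L, scale = TRUE)[, 1L]
    exceed <- setNames(numeric(length(obs)), names(obs))
    for (b in seq_len(nPermutations)) {
      yp <- sample(y)
      rfp <- randomForest::randomForest(Xm, yp, ntree = ntree,
                                        mtry = mtry, importance = TRUE)
      nullimp <- randomForest::importance(rfp, type = 1L,
                                          scale = TRUE)[, 1L]
      exceed <- exceed + (nullimp >= obs)
    }
    p <- (1 + exceed) / (nPermutations + 1)
    out <- data.frame(feature = names(obs), importance = unname(obs),
                      p_value = unname(p), row.names = NULL)
    out <- out[order(-out$importance), ]
    rownames(out) <- NULL
    class(out) <- c("ImportanceTable", "data.frame")
    out
  })
}
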