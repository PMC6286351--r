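## Chained-equations imputation: predictive mean matching for continuous
## columns, logistic regression for binary factors, multinomial regression
## for wider factors. The turnover/output column is never used as a
## predictor and never imputed.

.col_mode <- function(v) {
  tb <- table(v)
  names(tb)[which.max(tb)]
}

#' Impute missing feature values
#'
#' Chained single imputation over the feature columns: continuous columns
#' by predictive mean matching (regress on the other features, donate the
#' observed value of one of the \code{k} nearest-prediction neighbours),
#' binary factors by logistic regression draws, multi-category factors by
#' multinomial regression draws. Columns are revisited until the imputed
#' values stabilize or \code{maxIter} passes. The \code{strategy} selects
#' which rows receive imputations (cells outside it are left \code{NA});
#' observed cells are never altered.
#'
#' @param x data.frame of features (numeric and factor columns)
#' @param strategy \code{"none"}, \code{"labelled_only"},
#'   \code{"unlabelled_only"} or \code{"all"}
#' @param labelled logical vector marking rows that carry an output value;
#'   required for the two partial strategies
#' @param exclude columns excluded from imputation and from the predictor
#'   set (the output column goes here)
#' @param k donor-pool size for predictive mean matching
#' @param maxIter maximum number of chained passes
#' @param seed RNG seed (donor draws and categorical draws are stochastic)
#' @return the data.frame with imputed cells filled in
#' @export
imputeFeatures <- function(x, strategy = c("none", "labelled_only",
                                           "unlabelled_only", "all"),
                           labelled = NULL, exclude = character(0),
                           k = 5L, maxIter = 10L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(x)
  if (strategy %in% c("labelled_only", "unlabelled_only") &&
      is.null(labelled)) {
    stop("strategy '", strategy, "' needs the 'labelled' row indicator")
  }
  target_rows <- switch(strategy,
                        labelled_only = which(labelled),
                        unlabelled_only = which(!labelled),
                        all = seq_len(nrow(x)))
  cols <- setdiff(names(x), exclude)
  has_na <- cols[vapply(cols, function(cc)
    anyNA(x[[cc]][target_rows]), logical(1L))]
  if (!length(has_na)) return(x)
  for (cc in has_na) {
    if (all(is.na(x[[cc]]))) {
      stop("column '", cc, "' has no observed values to impute from")
    }
  }
  .with_seed(seed, .impute_chained(x, cols, has_na, target_rows, k,
                                   maxIter))
}

.impute_chained <- function(x, cols, has_na, target_rows, k, maxIter) {
  work <- x[cols]
  obs <- !is.na(work)              # originally observed mask
  ## initial fill: median / mode everywhere (working copy only)
  for (cc in cols) {
    v <- work[[cc]]
    if (!anyNA(v)) next
    if (is.numeric(v)) {
      v[is.na(v)] <- median(v, na.rm = TRUE)
    } else {
      v[is.na(v)] <- .col_mode(v)
    }
    work[[cc]] <- v
  }
  ord <- has_na[order(vapply(has_na, function(cc)
    sum(!obs[, cc]), 0L))]
  prev <- NULL
  for (iter in seq_len(maxIter)) {
    for (cc in ord) {
      miss <- which(!obs[, cc])
      if (!length(miss)) next
      preds <- setdiff(cols, cc)
      ## design matrix over ALL rows so factor levels never go missing
      P <- stats::model.matrix(~ ., data = work[preds])
      fit_rows <- which(obs[, cc])
      v <- work[[cc]]
      if (is.numeric(v)) {
        fit <- stats::lm.fit(P[fit_rows, , drop = FALSE], v[fit_rows])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        yhat <- as.vector(P %*% beta)
        for (i in miss) {
          dist <- abs(yhat[fit_rows] - yhat[i])
          donors <- fit_rows[order(dist)][seq_len(min(k,
                                                      length(fit_rows)))]
          work[i, cc] <- v[donors[sample.int(length(donors), 1L)]]
        }
      } else if (nlevels(factor(v)) <= 2L) {
        yb <- factor(v)
        fit <- suppressWarnings(
          stats::glm.fit(P[fit_rows, , drop = FALSE],
                         as.numeric(yb[fit_rows]) - 1,
                         family = binomial()))
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        eta <- as.vector(P %*% beta)
        p <- 1 / (1 + exp(-eta[miss]))
        lv <- levels(yb)
        work[miss, cc] <- lv[1L + (runif(length(miss)) < p)]
      } else {
        ddf <- as.data.frame(P[, -1L, drop = FALSE])
        ddf$.y <- factor(v)
        fit <- suppressWarnings(
          nnet::multinom(.y ~ ., data = ddf[fit_rows, , drop = FALSE],
                         trace = FALSE))
        p <- predict(fit, newdata = ddf[miss, , drop = FALSE],
                     type = "probs")
        if (is.null(dim(p))) p <- matrix(p, nrow = length(miss))
        lv <- fit$lev
        for (ii in seq_along(miss)) {
          work[miss[ii], cc] <- sample(lv, 1L, prob = p[ii, ])
        }
      }
    }
    cur <- unlist(lapply(cols, function(cc) {
      v <- work[[cc]]
      if (is.numeric(v)) v[!obs[, cc]] else as.character(v)[!obs[, cc]]
    }))
    if (!is.null(prev) && isTRUE(all.equal(prev, cur, tolerance = 1e-8))) {
      break
    }
    prev <- cur
  }
  ## commit only target-row cells; everything else reverts to original
  out <- x
  for (cc in has_na) {
    fill <- intersect(target_rows, which(is.na(x[[cc]])))
    out[fill, cc] <- work[fill, cc]
  }
  out
}
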