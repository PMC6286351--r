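## Regression models of log10 turnover numbers with repeated k-fold
## cross-validation and hyperparameter search.

#' Model specification for turnover-number regression
#'
#' @param algorithm one of \code{"elastic_net"}, \code{"random_forest"},
#'   \code{"neural_net"} (small single-hidden-layer MLP), \code{"linear"},
#'   \code{"pls"}
#' @param folds number of CV folds (default 5)
#' @param repeats CV repeats (default 5; forced to 1 for the neural net,
#'   whose training is the most expensive)
#' @param budget random-search budget for the neural net (default 50
#'   draws); ignored by grid-searched algorithms
#' @param grid optional data.frame of hyperparameter candidates overriding
#'   the default grid
#' @param ntree random-forest tree count (default 500)
#' @param seed RNG seed controlling fold assignment and stochastic fits
#' @return an object of class \code{ModelSpec}
#' @export
modelSpec <- function(algorithm = c("elastic_net", "random_forest",
                                    "neural_net", "linear", "pls"),
                      folds = 5L, repeats = NULL, budget = 50L,
                      grid = NULL, ntree = 500L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(repeats)) {
    repeats <- if (algorithm == "neural_net") 1L else 5L
  }
  stopifnot(folds >= 2L, budget >= 1L)
  structure(list(algorithm = algorithm, folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 budget = as.integer(budget), grid = grid,
                 ntree = as.integer(ntree), seed = as.integer(seed)),
            class = "ModelSpec")
}

## design-matrix helper: factors to dummies with stored levels
.design_template <- function(X) {
  lv <- lapply(X, function(v) if (is.factor(v) || is.character(v))
    levels(factor(v)) else NULL)
  lv[!vapply(lv, is.null, TRUE)]
}

.design_matrix <- function(X, template) {
  for (f in names(template)) {
    X[[f]] <- factor(X[[f]], levels = template[[f]])
  }
  stats::model.matrix(~ . , data = X)[, -1L, drop = FALSE]
}

.default_grid <- function(algorithm, p, budget) {
  switch(algorithm,
    elastic_net = expand.grid(alpha = c(0, 0.25, 0.5, 0.75, 1),
                              lambda = 10^seq(-4, 0.5, length.out = 15)),
    random_forest = data.frame(
      mtry = sort(unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3),
                                    floor(p / 2), p))))),
    neural_net = data.frame(size = sample(2:10, budget, replace = TRUE),
                            decay = 10^runif(budget, -4, 0)),
    linear = data.frame(.dummy = 1),
    pls = data.frame(ncomp = seq_len(min(8L, p)))
  )
}

.fit_one <- function(algorithm, Xm, y, par, ntree) {
  switch(algorithm,
    elastic_net = glmnet::glmnet(Xm, y, alpha = par$alpha,
                                 lambda = par$lambda),
    random_forest = randomForest::randomForest(
      Xm, y, mtry = min(par$mtry, ncol(Xm)), ntree = ntree),
    neural_net = nnet::nnet(Xm, y, size = par$size, decay = par$decay,
                            linout = TRUE, maxit = 500, trace = FALSE),
    linear = {
      df <- as.data.frame(Xm); df$.y <- y
      lm(.y ~ ., data = df)
    },
    pls = {
      if (!requireNamespace("mixOmics", quietly = TRUE)) {
        stop("PLS regression needs the mixOmics package")
      }
      mixOmics::pls(Xm, y, ncomp = par$ncomp, mode = "regression")
    })
}

.predict_one <- function(algorithm, fit, Xm, par = NULL) {
  switch(algorithm,
    elastic_net = as.numeric(predict(fit, Xm, s = par$lambda)),
    random_forest = as.numeric(predict(fit, Xm)),
    neural_net = as.numeric(predict(fit, Xm)),
    linear = as.numeric(predict(fit, newdata = as.data.frame(Xm))),
    pls = {
      pr <- predict(fit, Xm)
      as.numeric(pr$predict[, 1L, fit$ncomp])
    })
}

.r2 <- function(obs, pred) {
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  1 - sse / sst
}

#' Train a turnover-number regression with repeated k-fold CV
#'
#' Hyperparameters are chosen to minimize cross-validated RMSE over the
#' grid (or random-search draws); the CV result reports per-validation R^2
#' (computed as 1 - SSE/SST on each validation fold, which can be
#' negative) and RMSE for the winning candidate. Incomplete rows are
#' dropped before training. Fold assignment and every stochastic fit are
#' deterministic given the spec seed.
#'
#' @param features data.frame of predictor columns (numeric and factors)
#' @param y response on log10 scale
#' @param spec a \code{\link{modelSpec}}
#' @param testFraction optional fraction (e.g. 0.2) held out — stratified
#'   by response quantile — and scored once after hyperparameter selection
#' @return list with \code{fit} (a \code{turnoverFit}) and \code{cv} (a
#'   \code{CVResult}: \code{scores} data.frame of folds x repeats rows,
#'   \code{summary}, \code{best} hyperparameters, \code{testR2})
#' @export
trainCV <- function(features, y, spec, testFraction = 0) {
  stopifnot(inherits(spec, "ModelSpec"))
  keep <- complete.cases(features) & !is.na(y)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 2L * spec$folds) {
    stop("too few complete observations (", n, ") for ", spec$folds,
         "-fold CV")
  }
  if (sd(y) == 0) stop("response is constant; nothing to learn")
  .with_seed(spec$seed, {
    test_idx <- integer(0)
    if (testFraction > 0) {
      strat <- cut(rank(y, ties.method = "first"), breaks = 5L)
      test_idx <- unlist(lapply(split(seq_len(n), strat), function(ii)
        sample(ii, max(1L, round(length(ii) * testFraction)))),
        use.names = FALSE)
    }
    tr_idx <- setdiff(seq_len(n), test_idx)
    Xtr_df <- features[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    template <- .design_template(Xtr_df)
    Xm <- .design_matrix(Xtr_df, template)
    ctr <- colMeans(Xm); scl <- apply(Xm, 2L, sd); scl[scl == 0] <- 1
    scale_fun <- function(M) sweep(sweep(M, 2L, ctr), 2L, scl, "/")
    Xs <- scale_fun(Xm)
    grid <- spec$grid
    if (is.null(grid)) {
      grid <- .default_grid(spec$algorithm, ncol(Xm), spec$budget)
    }
    ncand <- nrow(grid)
    ntr <- length(ytr)
    nv <- spec$folds * spec$repeats
    rmse <- matrix(NA_real_, ncand, nv)
    r2 <- matrix(NA_real_, ncand, nv)
    col <- 0L
    for (rep_i in seq_len(spec$repeats)) {
      fold_of <- sample(rep_len(seq_len(spec$folds), ntr))
      for (fold in seq_len(spec$folds)) {
        col <- col + 1L
        vi <- which(fold_of == fold)
        ti <- which(fold_of != fold)
        preds <- .cv_candidate_predictions(spec, grid, Xs[ti, ,
                                                          drop = FALSE],
                                           ytr[ti],
                                           Xs[vi, , drop = FALSE])
        for (ci in seq_len(ncand)) {
          rmse[ci, col] <- sqrt(mean((ytr[vi] - preds[, ci])^2))
          r2[ci, col] <- .r2(ytr[vi], preds[, ci])
        }
      }
    }
    best <- which.min(rowMeans(rmse))
    best_par <- grid[best, , drop = FALSE]
    scores <- data.frame(
      repeat_i = rep(seq_len(spec$repeats), each = spec$folds),
      fold = rep(seq_len(spec$folds), spec$repeats),
      rmse = rmse[best, ], r2 = r2[best, ])
    final <- .fit_one(spec$algorithm, Xs, ytr, best_par, spec$ntree)
    fit <- structure(list(algorithm = spec$algorithm, fit = final,
                          params = best_par, template = template,
                          center = ctr, scale = scl,
                          featureNames = names(features)),
                     class = "turnoverFit")
    testR2 <- NA_real_
    if (length(test_idx)) {
      ph <- predictTurnover(fit, features[test_idx, , drop = FALSE])
      testR2 <- .r2(y[test_idx], ph)
    }
    cv <- structure(list(scores = scores,
                         summary = list(medianR2 = median(scores$r2),
                                        meanR2 = mean(scores$r2),
                                        medianRMSE = median(scores$rmse)),
                         best = best_par, algorithm = spec$algorithm,
                         n = ntr, testR2 = testR2),
                    class = "CVResult")
    list(fit = fit, cv = cv)
  })
}

## per-fold candidate predictions; elastic net shares one path fit per
## alpha, everything else fits per candidate
.cv_candidate_predictions <- function(spec, grid, Xt, yt, Xv) {
  ncand <- nrow(grid)
  out <- matrix(NA_real_, nrow(Xv), ncand)
  if (spec$algorithm == "elastic_net") {
    for (a in unique(grid$alpha)) {
      rows <- which(grid$alpha == a)
      fit <- glmnet::glmnet(Xt, yt, alpha = a)
      out[, rows] <- as.matrix(predict(fit, Xv, s = grid$lambda[rows]))
    }
  } else {
    for (ci in seq_len(ncand)) {
      fit <- .fit_one(spec$algorithm, Xt, yt, grid[ci, , drop = FALSE],
                      spec$ntree)
      out[, ci] <- .predict_one(spec$algorithm, fit, Xv,
                                grid[ci, , drop = FALSE])
    }
  }
  out
}

#' Predict from a fitted turnover regression
#'
#' @param fit a \code{turnoverFit} from \code{\link{trainCV}}
#' @param features data.frame with the training feature columns; rows with
#'   missing values yield \code{NA}
#' @return numeric predictions on log10 scale
#' @export
predictTurnover <- function(fit, features) {
  stopifnot(inherits(fit, "turnoverFit"))
  features <- features[fit$featureNames]
  ## factor levels unseen in training become NA and the row falls back
  for (f in names(fit$template)) {
    features[[f]] <- factor(features[[f]], levels = fit$template[[f]])
  }
  ok <- complete.cases(features)
  out <- rep(NA_real_, nrow(features))
  if (any(ok)) {
    Xm <- .design_matrix(features[ok, , drop = FALSE], fit$template)
    Xs <- sweep(sweep(Xm, 2L, fit$center), 2L, fit$scale, "/")
    out[ok] <- .predict_one(fit$algorithm, fit$fit, Xs, fit$params)
  }
  out
}
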