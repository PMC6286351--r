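#' @importFrom methods new validObject is
#' @importFrom stats median predict rnorm runif rbinom coef lm glm binomial
#'   quantile sd var cor cor.test setNames complete.cases pt qnorm optimize
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

## Internal dense two-phase simplex with bounded variables.
##
## Solves  max/min  obj' x   s.t.  A x (sense) rhs,  lb <= x <= ub.
## Variables are shifted to y = x - lb >= 0 and upper bounds become explicit
## rows, giving a standard-form tableau. Bland's rule guards against cycling
## (flux problems are routinely degenerate). Intended for desk-scale problems
## (hundreds of variables at most); all solves in this package are that size.

.LP_BIG <- 1e7

.lp_solve <- function(obj, A, rhs, sense, lb, ub, maximize = FALSE,
                      tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  n <- length(obj)
  m0 <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m0, length(sense) == m0,
            length(lb) == n, length(ub) == n)
  lb2 <- pmax(lb, -.LP_BIG)
  ub2 <- pmin(ub, .LP_BIG)
  if (any(lb2 > ub2 + 1e-12)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  ## shift x = lb2 + y, y >= 0, y <= rng
  b0 <- rhs - as.vector(A %*% lb2)
  rng <- ub2 - lb2
  Aall <- rbind(A, diag(n))
  ball <- c(b0, rng)
  sall <- c(sense, rep("<=", n))
  ## internal convention: maximize
  cvec <- if (maximize) obj else -obj

  neg <- ball < 0
  if (any(neg)) {
    Aall[neg, ] <- -Aall[neg, , drop = FALSE]
    ball[neg] <- -ball[neg]
    sall[neg] <- vapply(sall[neg], function(s)
      switch(s, "<=" = ">=", ">=" = "<=", "=" = "="), "")
  }
  m <- nrow(Aall)

  ## columns: n structural | slack/surplus per row (except "=") | artificials
  slack_rows <- which(sall != "=")
  n_slack <- length(slack_rows)
  art_rows <- which(sall != "<=")
  n_art <- length(art_rows)
  ncols <- n + n_slack + n_art
  Tm <- matrix(0, m, ncols + 1L)
  Tm[, seq_len(n)] <- Aall
  Tm[, ncols + 1L] <- ball
  basis <- integer(m)
  for (k in seq_along(slack_rows)) {
    i <- slack_rows[k]
    Tm[i, n + k] <- if (sall[i] == "<=") 1 else -1
    if (sall[i] == "<=") basis[i] <- n + k
  }
  art_cols <- integer(0)
  for (k in seq_along(art_rows)) {
    i <- art_rows[k]
    j <- n + n_slack + k
    Tm[i, j] <- 1
    basis[i] <- j
    art_cols <- c(art_cols, j)
  }

  run_phase <- function(Tm, basis, cost, banned) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) stop("simplex iteration limit reached")
      cB <- cost[basis]
      red <- as.vector(crossprod(Tm[, seq_len(ncols), drop = FALSE], cB)) -
        cost
      red[banned] <- 0
      ent <- which(red < -tol)
      if (!length(ent)) {
        return(list(Tm = Tm, basis = basis, status = "optimal"))
      }
      pc <- ent[1L]  # Bland: smallest eligible index
      colv <- Tm[, pc]
      pos <- which(colv > tol)
      if (!length(pos)) {
        return(list(Tm = Tm, basis = basis, status = "unbounded"))
      }
      ratio <- Tm[pos, ncols + 1L] / colv[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      pr <- cand[which.min(basis[cand])]  # Bland on leaving basis index
      ## pivot
      Tm[pr, ] <- Tm[pr, ] / Tm[pr, pc]
      oth <- setdiff(seq_len(m), pr)
      Tm[oth, ] <- Tm[oth, ] - outer(Tm[oth, pc], Tm[pr, ])
      basis[pr] <- pc
    }
  }

  ## Phase 1
  if (n_art > 0L) {
    cost1 <- numeric(ncols)
    cost1[art_cols] <- -1   # maximize -sum(artificials)
    ph1 <- run_phase(Tm, basis, cost1, banned = integer(0))
    Tm <- ph1$Tm; basis <- ph1$basis
    p1val <- sum(Tm[basis %in% art_cols, ncols + 1L])
    if (p1val > 1e-7) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    ## drive remaining basic artificials out where possible
    for (i in which(basis %in% art_cols)) {
      piv <- which(abs(Tm[i, seq_len(n + n_slack)]) > 1e-9)
      if (length(piv)) {
        pc <- piv[1L]
        Tm[i, ] <- Tm[i, ] / Tm[i, pc]
        oth <- setdiff(seq_len(m), i)
        Tm[oth, ] <- Tm[oth, ] - outer(Tm[oth, pc], Tm[i, ])
        basis[i] <- pc
      }
    }
  }

  ## Phase 2
  cost2 <- c(cvec, numeric(ncols - n))
  ph2 <- run_phase(Tm, basis, cost2, banned = art_cols)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  Tm <- ph2$Tm; basis <- ph2$basis
  y <- numeric(ncols)
  y[basis] <- Tm[, ncols + 1L]
  x <- lb2 + y[seq_len(n)]
  val <- sum(obj * x)
  list(status = "optimal", x = x, value = val)
}
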