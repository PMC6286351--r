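## Spearman rank correlation with the S statistic and AS-89-style
## significance.

#' Spearman rank correlation with significance
#'
#' Ranks use midranks for ties. Without ties, rho is computed from the sum
#' of squared rank differences, rho = 1 - 6 S / (n (n^2 - 1)); with ties
#' it falls back to Pearson correlation on ranks. Two-sided p-values come
#' from full enumeration of the permutation distribution for n <= 9 and
#' from the AS 89 algorithm (exact/Edgeworth as implemented in
#' \code{stats::cor.test}) otherwise; with ties the t approximation is
#' used.
#'
#' @param x,y paired numeric vectors without missing values, n >= 3
#' @return list of class \code{SpearmanResult}: \code{rho}, \code{S},
#'   \code{n}, \code{p_value}
#' @examples
#' spearmanRho(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("rho is undefined for a constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  S <- sum((rx - ry)^2)
  ties <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  rho <- if (ties) cor(rx, ry) else 1 - 6 * S / (n * (n^2 - 1))
  p <- if (!ties && n <= 9L) {
    .spearman_exact_p(rx, ry)
  } else {
    suppressWarnings(cor.test(x, y, method = "spearman",
                              exact = !ties)$p.value)
  }
  structure(list(rho = rho, S = S, n = n, p_value = min(1, p)),
            class = "SpearmanResult")
}

#' Spearman rho from a printed S statistic
#'
#' Convenience inverse of the S formula: rho = 1 - 6 S / (n (n^2 - 1)).
#'
#' @param S sum of squared rank differences
#' @param n number of pairs
#' @return rho
#' @examples
#' rhoFromS(1214, 24)  # 0.4722
#' @export
rhoFromS <- function(S, n) 1 - 6 * S / (n * (n^2 - 1))

## exact two-sided p by full enumeration of rank permutations (n <= 9)
.spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  perms <- .all_perms(n)
  S_obs <- sum((rx - ry)^2)
  rho_obs <- abs(1 - 6 * S_obs / (n * (n^2 - 1)))
  cnt <- 0L
  for (i in seq_len(nrow(perms))) {
    Sp <- sum((rx - ry[perms[i, ]])^2)
    rp <- abs(1 - 6 * Sp / (n * (n^2 - 1)))
    if (rp >= rho_obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, sub[i, ] + (sub[i, ] >= k))
    }
  }
  out
}
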