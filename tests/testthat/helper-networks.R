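## Hand-built fixture networks and independent brute-force oracles.

## linear chain: EX_A (uptake <= 10) -> A -> B -> biomass
chain_network <- function(uptake = 10) {
  rx <- data.frame(id = c("EX_A", "R1", "BIO", "EX_BM"),
                   lb = c(-uptake, 0, 0, 0), ub = c(1000, 1000, 1000, 1000))
  mets <- data.frame(id = c("A", "B", "BM"), C = c(1, 1, 1), N = 0, S = 0,
                     P = 0)
  S <- matrix(0, 3, 4, dimnames = list(mets$id, rx$id))
  S["A", "EX_A"] <- -1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "BIO"] <- -1; S["BM", "BIO"] <- 1
  S["BM", "EX_BM"] <- -1
  metabolicNetwork(rx, mets, S, "BIO")
}

## two parallel routes of equal yield: A -> B directly, or A -> C -> B
parallel_network <- function() {
  rx <- data.frame(id = c("EX_A", "DIRECT", "LONG1", "LONG2", "BIO",
                          "EX_BM"),
                   lb = c(-10, 0, 0, 0, 0, 0), ub = rep(1000, 6))
  mets <- data.frame(id = c("A", "B", "C", "BM"), C = 1, N = 0, S = 0,
                     P = 0)
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rx$id))
  S["A", "EX_A"] <- -1
  S["A", "DIRECT"] <- -1; S["B", "DIRECT"] <- 1
  S["A", "LONG1"] <- -1; S["C", "LONG1"] <- 1
  S["C", "LONG2"] <- -1; S["B", "LONG2"] <- 1
  S["B", "BIO"] <- -1; S["BM", "BIO"] <- 1
  S["BM", "EX_BM"] <- -1
  metabolicNetwork(rx, mets, S, "BIO")
}

## two substrates with different biomass yields feeding one precursor
two_substrate_network <- function() {
  rx <- data.frame(id = c("EX_G", "EX_H", "UG", "UH", "BIO", "EX_BM"),
                   lb = c(-5, -8, 0, 0, 0, 0), ub = rep(1000, 6))
  mets <- data.frame(id = c("G", "H", "P", "BM"),
                     C = c(2, 1, 1, 1), N = 0, S = 0, P = 0)
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rx$id))
  S["G", "EX_G"] <- -1
  S["H", "EX_H"] <- -1
  S["G", "UG"] <- -1; S["P", "UG"] <- 2    # 2 C -> 2 precursor
  S["H", "UH"] <- -1; S["P", "UH"] <- 1
  S["P", "BIO"] <- -1; S["BM", "BIO"] <- 1
  S["BM", "EX_BM"] <- -1
  metabolicNetwork(rx, mets, S, "BIO")
}

## brute-force LP oracle: enumerate basic feasible points of
## {A x = b, lb <= x <= ub} and optimize obj by inspection
brute_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- ncol(A); m <- qr(A)$rank
  best_val <- NULL; best_x <- NULL
  nfix <- n - m
  fix_sets <- if (nfix <= 0) list(integer(0)) else
    combn(n, nfix, simplify = FALSE)
  for (fixed in fix_sets) {
    free <- setdiff(seq_len(n), fixed)
    choices <- if (length(fixed))
      expand.grid(rep(list(1:2), length(fixed))) else
      data.frame(row.names = 1)
    for (gi in seq_len(nrow(choices))) {
      x <- numeric(n)
      if (length(fixed)) {
        ch <- as.numeric(choices[gi, ])
        x[fixed] <- ifelse(ch == 1, lb[fixed], ub[fixed])
      }
      Af <- A[, free, drop = FALSE]
      rhs <- b - as.vector(A[, fixed, drop = FALSE] %*% x[fixed])
      if (length(free)) {
        if (qr(Af)$rank < length(free)) next
        sol <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        x[free] <- sol
      } else if (max(abs(rhs)) > 1e-8) next
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      v <- sum(obj * x)
      if (is.null(best_val) || (maximize && v > best_val + 1e-12) ||
          (!maximize && v < best_val - 1e-12)) {
        best_val <- v; best_x <- x
      }
    }
  }
  list(value = best_val, x = best_x)
}

## brute-force pFBA oracle: minimal total |v| at fixed optimal growth,
## via vertex enumeration of the split-variable LP
brute_pfba_l1 <- function(network, mu) {
  rx <- reactions(network)
  S <- as.matrix(stoichMatrix(network))
  n <- nrow(rx)
  ## forward part for every reaction, backward part only where lb < 0,
  ## to keep the vertex enumeration tractable
  back <- which(rx$lb < 0)
  A <- cbind(S, -S[, back, drop = FALSE])
  lb <- c(pmax(rx$lb, 0), rep(0, length(back)))
  ub <- c(pmax(rx$ub, 0), pmax(-rx$lb[back], 0))
  j <- match(biomassReaction(network), rx$id)
  lb[j] <- ub[j] <- mu
  brute_lp(rep(1, n + length(back)), A, rep(0, nrow(S)), lb, ub,
           maximize = FALSE)
}

.with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

## two 1-carbon substrates feeding disjoint uptake paths with unequal
## yields (G is better), plus N/S/P sources
two_carbon_disjoint_network <- function() {
  rx <- data.frame(id = c("EX_G", "EX_H", "EX_N", "EX_S", "EX_P",
                          "UG", "UH", "AN", "AS", "AP", "BIO", "EX_BM"),
                   lb = c(-60, -30, -1000, -1000, -1000, rep(0, 7)),
                   ub = rep(1000, 12))
  mets <- data.frame(id = c("G", "H", "n", "s", "p", "prc", "np", "sp",
                            "pp", "BM"),
                     C = c(1, 2, 0, 0, 0, 1, 0, 0, 0, 2),
                     N = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 1),
                     S = c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1),
                     P = c(0, 0, 0, 0, 1, 0, 0, 0, 1, 1))
  S <- matrix(0, 10, 12, dimnames = list(mets$id, rx$id))
  S["G", "EX_G"] <- -1; S["H", "EX_H"] <- -1
  S["n", "EX_N"] <- -1; S["s", "EX_S"] <- -1; S["p", "EX_P"] <- -1
  S["G", "UG"] <- -1; S["prc", "UG"] <- 1     # C1 source, 1:1
  S["H", "UH"] <- -1; S["prc", "UH"] <- 2     # C2 source, same C yield
  S["n", "AN"] <- -1; S["np", "AN"] <- 1
  S["s", "AS"] <- -1; S["sp", "AS"] <- 1
  S["p", "AP"] <- -1; S["pp", "AP"] <- 1
  S["prc", "BIO"] <- -2; S["np", "BIO"] <- -1; S["sp", "BIO"] <- -1
  S["pp", "BIO"] <- -1; S["BM", "BIO"] <- 1
  S["BM", "EX_BM"] <- -1
  metabolicNetwork(rx, mets, S, "BIO")
}

## minimal net whose single internal reaction is a unique homomer (g1)
gpr_unique_homomer_net <- function() {
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lb = c(-1000, 0, 0), ub = rep(1000, 3))
  mets <- data.frame(id = c("A", "B"), C = 1, N = 0, S = 0, P = 0)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rx$id))
  metabolicNetwork(rx, mets, S, "R1", gpr = c(R1 = "g1"),
                   geneMW = c(g1 = 40))
}
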