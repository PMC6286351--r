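test_that("reaction Gibbs energy and quotient follow their definitions", {
  ## identity case: Keq 1, all concentrations 1 M
  r <- reactionGibbs(c(A = -1, B = 1), keq = 1, conc = c(A = 1, B = 1))
  expect_equal(r$deltaG, 0)
  expect_equal(r$Q, 1)
  ## hand calculation: Keq 10, Q 1, T 298.15 -> -RT ln 10
  r <- reactionGibbs(c(A = -1, B = 1), keq = 10, conc = c(A = 1, B = 1),
                     temperature = 298.15)
  expect_equal(r$deltaG, -8.314 * 298.15 * log(10) / 1000,
               tolerance = 1e-12)
  expect_equal(r$deltaG, -5.708, tolerance = 1e-3)
  ## A + B -> C at x = (2, 0.5, 1): Q = 1 / (2 * 0.5) = 1
  r <- reactionGibbs(c(A = -1, B = -1, C = 1), keq = 1,
                     conc = c(A = 2, B = 0.5, C = 1))
  expect_equal(r$Q, 1)
  expect_error(reactionGibbs(c(A = -1, B = 1), 1, c(A = 1)),
               "missing concentration")
})

test_that("eta_rev has the right limits and identity", {
  expect_identical(etaRev(0), 0)
  ## perfectly forward-driven limit
  expect_equal(etaRev(-1e6), 1)
  ## Q/Keq = 0.5 corresponds to eta_rev = 0.5
  dg <- reactionGibbs(c(A = -1), keq = 2, conc = c(A = 1))$deltaG
  expect_equal(etaRev(dg), 0.5, tolerance = 1e-12)
  ## the two printed forms agree to 1e-12 across magnitudes
  for (ratio in 10^seq(-6, 2)) {
    dg <- 8.314 * 310 * log(ratio) / 1000
    expect_equal(etaRev(dg, 310), 1 - ratio, tolerance = 1e-12)
  }
  ## strictly decreasing in Q at fixed Keq and T
  qs <- seq(0.1, 3, by = 0.1)
  etas <- vapply(qs, function(q)
    etaRev(8.314 * 298.15 * log(q / 2) / 1000), 0)
  expect_true(all(diff(etas) < 0))
})

thermo_test_net <- function() {
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lb = c(-10, 0, 0), ub = rep(1000, 3))
  mets <- data.frame(id = c("A", "B"), C = 1, N = 0, S = 0, P = 0)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rx$id))
  metabolicNetwork(rx, mets, S, "R1")
}

test_that("point-estimate bounds reduce to the deterministic evaluation", {
  net <- thermo_test_net()
  cond <- thermoCondition(conc = c(A = 1e-3, B = 2e-3), keq = c(R1 = 5),
                          concLower = c(A = 1e-3, B = 2e-3),
                          concUpper = c(A = 1e-3, B = 2e-3),
                          flux = c(R1 = 0))
  res <- thermoFeature(net, list(cond), nSamples = 10, seed = 1)
  ref <- reactionGibbs(c(A = -1, B = 1), 5, c(A = 1e-3, B = 2e-3))
  expect_equal(res$perCondition$deltaG, ref$deltaG, tolerance = 1e-9)
  expect_equal(res$perCondition$Q, ref$Q, tolerance = 1e-9)
  expect_equal(unname(res$etaRevMean["R1"]), etaRev(ref$deltaG),
               tolerance = 1e-9)
})

test_that("all samples satisfy the directionality constraint", {
  net <- thermo_test_net()
  ## forward flux above threshold; symmetric bounds around an infeasible
  ## midpoint (B/A = 1 > Keq would block the reaction at Keq = 1)
  cond <- thermoCondition(conc = c(A = 1e-3, B = 1e-3), keq = c(R1 = 1),
                          concLower = c(A = 1e-4, B = 1e-4),
                          concUpper = c(A = 1e-2, B = 1e-2),
                          flux = c(R1 = 5))
  res <- thermoFeature(net, list(cond), nSamples = 400, seed = 3)
  ## mean eta over feasible samples must be positive and dG negative
  expect_lt(res$perCondition$deltaG, 0)
  expect_gt(res$perCondition$eta_rev, 0)
})

test_that("sampled mean eta_rev matches grid quadrature on a 2-D box", {
  net <- thermo_test_net()
  lo <- 1e-4; hi <- 1e-2
  cond <- thermoCondition(conc = c(A = 1e-3, B = 1e-3), keq = c(R1 = 4),
                          concLower = c(A = lo, B = lo),
                          concUpper = c(A = hi, B = hi),
                          flux = c(R1 = 1))
  nS <- 4000
  res <- thermoFeature(net, list(cond), nSamples = nS, burnIn = 200,
                       seed = 7)
  ## oracle: dense grid over log-concentrations with the constraint
  ## ln(B) - ln(A) < ln(4); eta = 1 - exp(lnB - lnA)/4
  g <- seq(log(lo), log(hi), length.out = 400)
  grid <- expand.grid(a = g, b = g)
  feas <- grid$b - grid$a < log(4)
  eta <- 1 - exp(grid$b[feas] - grid$a[feas]) / 4
  mu <- mean(eta)
  sdm <- sd(eta) / sqrt(nS)   # hit-and-run mixes well on this box
  expect_lt(abs(res$perCondition$eta_rev - mu), max(5 * sdm, 0.02))
})

test_that("infeasible directionality constraints are reported by name", {
  net <- thermo_test_net()
  cond <- thermoCondition(conc = c(A = 1e-3, B = 1e-3), keq = c(R1 = 1e-8),
                          concLower = c(A = 9e-4, B = 9e-4),
                          concUpper = c(A = 1.1e-3, B = 1.1e-3),
                          flux = c(R1 = 5))
  expect_error(thermoFeature(net, list(cond), nSamples = 10, seed = 1),
               "R1")
})
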