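test_that("a network with one source per element opens all four", {
  net <- two_carbon_disjoint_network()
  rx <- reactions(net)
  rx <- rx[rx$id != "EX_H", ]          # exactly one source per element
  S <- as.matrix(stoichMatrix(net))[, rx$id]
  S <- S[rowSums(S != 0) > 0, ]
  mets <- metabolites(net)[metabolites(net)$id %in% rownames(S), ]
  net1 <- metabolicNetwork(rx, mets, S, "BIO")
  set.seed(1)
  for (i in 1:20) {
    env <- sampleEnvironment(net1)
    expect_setequal(unlist(env$sources),
                    c("EX_G", "EX_N", "EX_S", "EX_P"))
  }
})

test_that("carbon uptake bounds are normalized to carbon atom count", {
  ## glucose-like 6C and acetate-like 2C sources under base flux 60
  rx <- data.frame(id = c("EX_glc", "EX_ac", "EX_n", "EX_s", "EX_p",
                          "U1", "U2", "AN", "AS", "AP", "BIO", "EX_BM"),
                   lb = c(-10, -30, -1000, -1000, -1000, rep(0, 7)),
                   ub = rep(1000, 12))
  mets <- data.frame(id = c("glc", "ac", "n", "s", "p", "prc", "BM"),
                     C = c(6, 2, 0, 0, 0, 1, 6),
                     N = c(0, 0, 1, 0, 0, 0, 1),
                     S = c(0, 0, 0, 1, 0, 0, 1),
                     P = c(0, 0, 0, 0, 1, 0, 1))
  S <- matrix(0, 7, 12, dimnames = list(mets$id, rx$id))
  S["glc", "EX_glc"] <- -1; S["ac", "EX_ac"] <- -1
  S["n", "EX_n"] <- -1; S["s", "EX_s"] <- -1; S["p", "EX_p"] <- -1
  S["glc", "U1"] <- -1; S["prc", "U1"] <- 6
  S["ac", "U2"] <- -1; S["prc", "U2"] <- 2
  S["prc", "BIO"] <- -6; S["n", "BIO"] <- -1; S["s", "BIO"] <- -1
  S["p", "BIO"] <- -1; S["BM", "BIO"] <- 1
  S["BM", "EX_BM"] <- -1
  net <- metabolicNetwork(rx, mets, S, "BIO")
  set.seed(42)
  found <- c(glc = NA_real_, ac = NA_real_)
  for (i in 1:50) {
    env <- sampleEnvironment(net, baseCarbonFlux = 60)
    if ("EX_glc" %in% names(env$uptake_bounds)) {
      found["glc"] <- env$uptake_bounds[["EX_glc"]]
    }
    if ("EX_ac" %in% names(env$uptake_bounds)) {
      found["ac"] <- env$uptake_bounds[["EX_ac"]]
    }
    if (!anyNA(found)) break
  }
  expect_equal(unname(found["glc"]), -10)   # 60 / 6 carbons
  expect_equal(unname(found["ac"]), -30)    # 60 / 2 carbons
})

test_that("every sample opens at least one source per element", {
  net <- generateToyGem(toyGemSpec(nCarbon = 3, nNitrogen = 2, seed = 5))
  set.seed(7)
  cache <- new.env()
  for (i in 1:500) {
    env <- sampleEnvironment(net, cache = cache)
    for (el in c("C", "N", "S", "P")) {
      expect_gte(length(env$sources[[el]]), 1)
    }
    ## carbon bounds follow the atom-count rule
    for (e in env$sources$C) {
      nc <- metabolites(net)$C[match(
        sub("^EX_", "", e), metabolites(net)$id)]
      expect_equal(env$uptake_bounds[[e]], -60 / nc)
    }
  }
})

test_that("mean flux equals the single pFBA flux when the environment is unique", {
  net <- generateToyGem(toyGemSpec(nCarbon = 1, seed = 2))
  ## one source per element: environment fixed up to the oxygen flag,
  ## and oxygen never carries flux in these toys
  mf <- averageSampledFlux(net, nEnvironments = 20, seed = 3)
  env <- .with_seed_test(4, sampleEnvironment(net))
  pf <- fluxes(solvePfba(applyEnvironment(net, env), lexicographic = FALSE))
  expect_equal(mf, pf, tolerance = 1e-9)
  ## oxygen-burning reaction is blocked in every environment
  expect_equal(unname(mf["OXD"]), 0)
})

test_that("two equiprobable carbon sources average to the flux mixture", {
  net <- two_carbon_disjoint_network()
  nEnv <- 2000
  mf <- averageSampledFlux(net, nEnvironments = nEnv, seed = 11)
  ## conditional pFBA solutions for the three possible source sets
  envs <- list(
    g = list(oxygen_allowed = FALSE,
             sources = list(C = "EX_G", N = "EX_N", S = "EX_S",
                            P = "EX_P"),
             uptake_bounds = c(EX_G = -60, EX_N = -1000, EX_S = -1000,
                               EX_P = -1000)),
    h = list(oxygen_allowed = FALSE,
             sources = list(C = "EX_H", N = "EX_N", S = "EX_S",
                            P = "EX_P"),
             uptake_bounds = c(EX_H = -30, EX_N = -1000, EX_S = -1000,
                               EX_P = -1000)),
    gh = list(oxygen_allowed = FALSE,
              sources = list(C = c("EX_G", "EX_H"), N = "EX_N",
                             S = "EX_S", P = "EX_P"),
              uptake_bounds = c(EX_G = -60, EX_H = -30, EX_N = -1000,
                                EX_S = -1000, EX_P = -1000)))
  cond <- lapply(envs, function(e)
    fluxes(solvePfba(applyEnvironment(net, structure(e,
      class = "EnvironmentSample")))))
  ## each single source drawn first w.p. 1/2; the extra-source draw adds
  ## the other with P(k>=1) = 3/4, so P(both) = 3/4, P(G only) = 1/8
  expected <- 0.125 * cond$g + 0.125 * cond$h + 0.75 * cond$gh
  p <- c(0.125, 0.125, 0.75)
  for (r in c("UG", "UH")) {
    vals <- c(cond$g[r], cond$h[r], cond$gh[r])
    sd_r <- sqrt((sum(p * vals^2) - sum(p * vals)^2) / nEnv)
    expect_lt(abs(mf[r] - expected[r]), 3 * sd_r + 1e-9)
  }
})

test_that("environment sampling errors when no growth is possible", {
  net <- chain_network(uptake = 10)   # lacks N/S/P sources entirely
  expect_error(sampleEnvironment(net), "supply element")
})
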