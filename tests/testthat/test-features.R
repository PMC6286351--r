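## hand-built network with controlled GPRs for feature tests
gpr_test_net <- function() {
  rx <- data.frame(id = c("EX_A", "R1", "R2", "R3", "EX_B"),
                   lb = c(-10, 0, 0, 0, 0), ub = rep(1000, 5))
  mets <- data.frame(id = c("A", "M1", "M2", "B"), C = 1, N = 0, S = 0,
                     P = 0,
                     formula = c("CH4", "CH3", "CH2", "CH"))
  S <- matrix(0, 4, 5, dimnames = list(mets$id, rx$id))
  S["A", "EX_A"] <- -1
  S["A", "R1"] <- -1; S["M1", "R1"] <- 1
  S["M1", "R2"] <- -1; S["M2", "R2"] <- 1
  S["M2", "R3"] <- -1; S["B", "R3"] <- 1
  S["B", "EX_B"] <- -1
  metabolicNetwork(rx, mets, S, "R3",
                   gpr = c(R1 = "g1", R2 = "g1 or g2",
                           R3 = "(g1 and g2) or g3"),
                   geneMW = c(g1 = 30, g2 = 50, g3 = 20))
}

test_that("generalist counts OTHER reactions using the same genes", {
  net <- gpr_test_net()
  ## g1 appears in R1, R2, R3 -> R1 scores 2
  expect_equal(generalistFeature(net, "R1"), 2L)
  ## R3: g1 in 2 others, g2 in 1 other, g3 in 0 -> max 2
  expect_equal(generalistFeature(net, "R3"), 2L)
  expect_true(is.na(generalistFeature(net, "EX_A")))
})

test_that("generalist matches a brute-force incidence scan on toys", {
  for (seed in 1:5) {
    net <- generateToyGem(toyGemSpec(nInternal = 8, seed = seed))
    gsets <- lapply(gprRules(net), turnoverML:::.gpr_genes)
    for (r in names(gsets)[lengths(gsets) > 0]) {
      oracle <- max(vapply(gsets[[r]], function(g)
        sum(vapply(gsets[names(gsets) != r], function(s) g %in% s,
                   logical(1))), 0L))
      expect_identical(generalistFeature(net, r), as.integer(oracle))
    }
  }
})

test_that("substrate counts exclude water and protons by formula", {
  rx <- data.frame(id = c("EX_A", "RW", "EX_B"),
                   lb = c(-10, 0, 0), ub = rep(1000, 3))
  mets <- data.frame(id = c("A", "B", "h2o", "h"),
                     C = c(1, 1, 0, 0), N = 0, S = 0, P = 0,
                     formula = c("CH2O", "CH2O2", "H2O", "H"))
  S <- matrix(0, 4, 3, dimnames = list(mets$id, rx$id))
  S["A", "EX_A"] <- -1
  S["A", "RW"] <- -1; S["h2o", "RW"] <- -1; S["h", "RW"] <- 1
  S["B", "RW"] <- 1
  S["B", "EX_B"] <- -1
  net <- metabolicNetwork(rx, mets, S, "RW")
  ## A + H2O -> B + H: one substrate forward, one product backward
  expect_equal(substrateCount(net, "RW", "forward"), 1)
  expect_equal(substrateCount(net, "RW", "backward"), 1)
})

test_that("substrate counts equal the set-size oracle on random toys", {
  for (seed in 1:5) {
    net <- generateToyGem(toyGemSpec(nInternal = 8, seed = seed))
    S <- as.matrix(stoichMatrix(net))
    mets <- metabolites(net)
    excl <- mets$id[mets$formula %in% c("H2O", "H")]
    for (r in sample(reactions(net)$id, 6)) {
      j <- match(r, reactions(net)$id)
      fwd <- setdiff(mets$id[S[, j] < 0], excl)
      bwd <- setdiff(mets$id[S[, j] > 0], excl)
      expect_equal(substrateCount(net, r, "forward"), length(fwd))
      expect_equal(substrateCount(net, r, "backward"), length(bwd))
    }
  }
})

test_that("gene features summarize through GPR trees", {
  net <- gpr_test_net()
  gf <- data.frame(gene = c("g1", "g2", "g3"),
                   molecular_weight = c(30, 50, 20),
                   depth = c(10, 20, 60))
  out <- summarizeGeneFeatures(net, gf)
  rownames(out) <- out$reaction
  ## single gene: identity
  expect_equal(out["R1", "molecular_weight"], 30)
  expect_equal(out["R1", "depth"], 10)
  ## OR: averages
  expect_equal(out["R2", "molecular_weight"], 40)
  expect_equal(out["R2", "depth"], 15)
  ## (g1 and g2) or g3: AND sums MW (80) and averages depth (15);
  ## OR averages with g3
  expect_equal(out["R3", "molecular_weight"], (80 + 20) / 2)
  expect_equal(out["R3", "depth"], (15 + 60) / 2)
})

test_that("missing genes are skipped with mask propagation", {
  net <- gpr_test_net()
  gf <- data.frame(gene = c("g1"), molecular_weight = 30, depth = 10)
  out <- summarizeGeneFeatures(net, gf)
  rownames(out) <- out$reaction
  expect_equal(out["R2", "depth"], 10)          # g2 skipped
  expect_equal(out["R3", "molecular_weight"], 30)
  expect_equal(out["R3", "depth"], 10)
  gf_none <- data.frame(gene = "zz", molecular_weight = 1, depth = 1)
  out2 <- summarizeGeneFeatures(net, gf_none)
  expect_true(all(is.na(out2$depth)))
})

test_that("linearization transforms and round-trips", {
  raw <- data.frame(kcat_invitro = c(100, 0.1), flux_feature = c(2, 0),
                    km = c(1e-4, 1e-3), assay_temperature = c(25, 37),
                    generalist = c(1, 2))
  lin <- suppressWarnings(linearizeFeatures(raw))
  expect_equal(lin$kcat_invitro, c(2, -1))
  expect_equal(lin$assay_inverse_temperature[1], 1 / 298.15,
               tolerance = 1e-12)
  ## zero flux is masked missing, not -Inf
  expect_true(is.na(lin$flux_feature[2]))
  expect_warning(linearizeFeatures(raw), "masked as missing")
  ## untouched passthrough
  expect_equal(lin$generalist, raw$generalist)
  ## round trip on the observed cells
  back <- delinearizeFeatures(lin)
  expect_equal(back$kcat_invitro, raw$kcat_invitro, tolerance = 1e-12)
  expect_equal(back$km, raw$km, tolerance = 1e-12)
  expect_equal(back$assay_temperature, raw$assay_temperature,
               tolerance = 1e-9)
})
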