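test_that("k_app conversion and maximum follow the definitions", {
  net <- gpr_unique_homomer_net()
  prot <- matrix(c(1, 2, 1), 1, 3,
                 dimnames = list("g1", c("c1", "c2", "c3")))
  fl <- matrix(c(3600, 3600 * 10, 0), 1, 3,
               dimnames = list("R1", c("c1", "c2", "c3")))
  km <- computeKappMax(prot, fl, net)
  ## v = 3600, E = 1 -> 1/s; max over conditions {1, 5}; v = 0 ignored
  expect_equal(unname(km["R1"]), 5)
})

test_that("reactions without eligible conditions are omitted", {
  net <- gpr_unique_homomer_net()
  prot <- matrix(0, 1, 1, dimnames = list("g1", "c1"))
  fl <- matrix(10, 1, 1, dimnames = list("R1", "c1"))
  expect_length(computeKappMax(prot, fl, net), 0)
})

test_that("single-constraint MOMENT optimum matches the closed form", {
  ## one enzyme catalyzing the only internal reaction:
  ## max flux = C * 3600 * keff / MW
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lb = c(-1000, 0, 0), ub = c(1000, 1000, 1000))
  mets <- data.frame(id = c("A", "B"), C = 1, N = 0, S = 0, P = 0)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rx$id))
  net <- metabolicNetwork(rx, mets, S, "R1", gpr = c(R1 = "g1"),
                          geneMW = c(g1 = 40))
  sol <- solveMoment(momentProblem(net, c(R1 = 10), budget = 0.32))
  expect_equal(growthRate(sol), 0.32 * 3600 * 10 / 40, tolerance = 1e-6)
  expect_equal(growthRate(sol), 288, tolerance = 1e-6)
  ## budget tight at the optimum
  expect_equal(sum(enzymeMasses(sol)), 0.32, tolerance = 1e-6)
})

test_that("doubling every k_eff doubles growth on a linear pathway", {
  net <- generateToyGem(toyGemSpec(seed = 2))
  keff <- setNames(rep(5, nrow(reactions(net))), reactions(net)$id)
  g1 <- growthRate(solveMoment(momentProblem(net, keff)))
  g2 <- growthRate(solveMoment(momentProblem(net, keff * 2)))
  expect_equal(g2, 2 * g1, tolerance = 1e-6)
})

test_that("all flux goes to the cheaper of two isozymes", {
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lb = c(-1000, 0, 0), ub = rep(1000, 3))
  mets <- data.frame(id = c("A", "B"), C = 1, N = 0, S = 0, P = 0)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rx$id))
  net <- metabolicNetwork(rx, mets, S, "R1", gpr = c(R1 = "g1 or g2"),
                          geneMW = c(g1 = 40, g2 = 10))
  sol <- solveMoment(momentProblem(net, c(R1 = 10)))
  masses <- enzymeMasses(sol)
  expect_gt(masses[["g2"]], 0)      # cheaper isozyme carries everything
  expect_equal(masses[["g1"]], 0, tolerance = 1e-9)
  ## capacity coupling v <= 3600 k E holds with equality for g2
  expect_equal(growthRate(sol),
               3600 * 10 * sol@enzymeConc[["g2"]], tolerance = 1e-6)
})

test_that("complex subunits each pay their own mass", {
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lb = c(-1000, 0, 0), ub = rep(1000, 3))
  mets <- data.frame(id = c("A", "B"), C = 1, N = 0, S = 0, P = 0)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rx$id))
  net <- metabolicNetwork(rx, mets, S, "R1", gpr = c(R1 = "g1 and g2"),
                          geneMW = c(g1 = 40, g2 = 10))
  sol <- solveMoment(momentProblem(net, c(R1 = 10), budget = 0.32))
  ## effective cost is MW(g1) + MW(g2) = 50
  expect_equal(growthRate(sol), 0.32 * 3600 * 10 / 50, tolerance = 1e-6)
  expect_equal(sol@enzymeConc[["g1"]], sol@enzymeConc[["g2"]],
               tolerance = 1e-9)
})

test_that("MOMENT growth never decreases when k_eff increases", {
  net <- generateToyGem(toyGemSpec(seed = 4))
  keff <- setNames(rep(3, nrow(reactions(net))), reactions(net)$id)
  g <- growthRate(solveMoment(momentProblem(net, keff)))
  for (i in 1:3) {
    keff2 <- keff
    keff2[sample(length(keff2), 5)] <- 30
    g2 <- growthRate(solveMoment(momentProblem(net, keff2)))
    expect_gte(g2 + 1e-9, g)
  }
})

test_that("membrane reactions use the membrane default rate", {
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lb = c(-1e4, 0, 0), ub = rep(1e4, 3))
  mets <- data.frame(id = c("A", "B"), C = 1, N = 0, S = 0, P = 0)
  S <- matrix(c(-1, 0, -1, 1, 0, -1), 2, 3,
              dimnames = list(mets$id, rx$id))
  net <- metabolicNetwork(rx, mets, S, "R1", gpr = c(R1 = "g1"),
                          geneMW = c(g1 = 240))
  sol <- solveMoment(momentProblem(net, c(R1 = 1),
                                   membraneReactions = "R1"))
  ## the supplied rate (1/s) is overridden by the 65/s membrane default
  expect_equal(growthRate(sol), 0.32 * 3600 * 65 / 240, tolerance = 1e-6)
  ## without the membrane flag the supplied 1/s applies
  sol2 <- solveMoment(momentProblem(net, c(R1 = 1)))
  expect_equal(growthRate(sol2), 0.32 * 3600 * 1 / 240, tolerance = 1e-6)
})

test_that("mass fractions normalize and rescale correctly", {
  masses <- c(g1 = 0.1, g2 = 0.3)
  sol <- new("MomentSolution", growthRate = 1,
             fluxes = new("FluxVector", values = c(R1 = 1),
                          objectiveValue = 1),
             enzymeConc = masses / c(40, 10), enzymeMass = masses,
             massFractions = masses / sum(masses), budget = 0.5)
  fr <- predictedMassFractions(sol)
  expect_equal(unname(fr), c(0.25, 0.75))
  expect_equal(sum(fr), 1)
})

test_that("proteome comparison computes log10 RMSE over matched genes", {
  pred <- c(g1 = 0.2, g2 = 0.8)
  mw <- c(g1 = 10, g2 = 10, g3 = 5)
  ## measured equal to predicted -> RMSE 0
  meas <- c(g1 = 20, g2 = 80)
  cmp <- compareProteome(pred, meas, mw)
  expect_equal(cmp$rmse, 0, tolerance = 1e-12)
  expect_equal(cmp$n, 2)
  ## two genes off by 10x in opposite directions -> RMSE 1 log10 unit
  pred2 <- c(g1 = 10 / 11, g2 = 1 / 11)
  meas2 <- c(g1 = 1, g2 = 10)
  cmp2 <- compareProteome(pred2, meas2, c(g1 = 1, g2 = 1))
  expect_equal(cmp2$rmse, 1, tolerance = 1e-12)
  ## exclusions and intersections restrict the gene set
  cmp3 <- compareProteome(pred, meas, mw, excludeGenes = "g2")
  expect_error(compareProteome(pred, meas, mw,
                               excludeGenes = c("g1", "g2")),
               "no comparable genes")
  expect_equal(cmp3$n, 1)
})
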