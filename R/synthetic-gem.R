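## Synthetic toy genome-scale-model generator. Stands in for a real GEM:
## mass-balanced (C/N/S/P) networks with element-tagged exchange reactions,
## a biomass reaction, GPRs mixing single genes, AND-complexes and
## OR-isozymes, and per-gene molecular weights.

## evaluate expr with a locally seeded RNG, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for a synthetic toy metabolic network
#'
#' @param nCarbon,nNitrogen,nSulfur,nPhosphate number of element sources
#' @param nInternal number of internal carbon-backbone reactions (chain plus
#'   shortcut routes between intermediates)
#' @param fractionReversible fraction of internal backbone reactions made
#'   reversible
#' @param nIsozyme number of internal reactions carrying an OR (isozyme) GPR
#' @param nComplex number of internal reactions carrying an AND (complex) GPR
#' @param pReuse probability that a reaction reuses an existing gene instead
#'   of getting a fresh one (drives the generalist feature; 0.25)
#' @param seed RNG seed; generation is deterministic given the spec
#' @return an object of class \code{ToyGemSpec}
#' @export
toyGemSpec <- function(nCarbon = 2, nNitrogen = 1, nSulfur = 1,
                       nPhosphate = 1, nInternal = 6,
                       fractionReversible = 0.3, nIsozyme = 2, nComplex = 2,
                       pReuse = 0.25, seed = 1) {
  stopifnot(nCarbon >= 1, nNitrogen >= 1, nSulfur >= 1, nPhosphate >= 1,
            nInternal >= 2, nIsozyme + nComplex <= nInternal)
  structure(list(nCarbon = nCarbon, nNitrogen = nNitrogen,
                 nSulfur = nSulfur, nPhosphate = nPhosphate,
                 nInternal = nInternal,
                 fractionReversible = fractionReversible,
                 nIsozyme = nIsozyme, nComplex = nComplex,
                 pReuse = pReuse, seed = seed),
            class = "ToyGemSpec")
}

#' Generate a synthetic toy metabolic network
#'
#' Builds a growth-capable, elementally balanced toy network: each carbon
#' source feeds a C3 central pool through an uptake reaction of
#' source-specific yield (wasteful sources secrete CO2), a backbone of
#' internal C3 reactions (with shortcut and reversible variants) leads to the
#' biomass precursor, and N/S/P sources are assimilated directly. The biomass
#' reaction condenses one precursor of each element class into a biomass
#' metabolite whose formula equals the summed precursor atoms, keeping even
#' the biomass reaction balanced; the biomass metabolite leaves through an
#' exchange. An oxygen exchange and a carbon-wasting oxidase reaction exist
#' but are never required for growth. Genes are reused across reactions with
#' fixed probability so that the generalist feature has signal.
#'
#' @param spec a \code{\link{toyGemSpec}}
#' @return a validated \linkS4class{MetabolicNetwork}
#' @examples
#' net <- generateToyGem(toyGemSpec(seed = 7))
#' objectiveValue(solveFba(net))
#' @export
generateToyGem <- function(spec) {
  stopifnot(inherits(spec, "ToyGemSpec"))
  .with_seed(spec$seed, .build_toy_gem(spec))
}

.build_toy_gem <- function(spec) {
  mets <- data.frame(id = character(0), C = numeric(0), N = numeric(0),
                     S = numeric(0), P = numeric(0),
                     formula = character(0))
  add_met <- function(id, C = 0, N = 0, S = 0, P = 0, formula = "") {
    mets <<- rbind(mets, data.frame(id = id, C = C, N = N, S = S, P = P,
                                    formula = formula))
  }
  rxs <- list()
  add_rx <- function(id, stoich, lb, ub, gpr = "", exchange = FALSE) {
    rxs[[id]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub,
                       gpr = gpr, exchange = exchange)
  }
  genes <- character(0)
  new_gene <- function() {
    g <- sprintf("g%04d", length(genes) + 1L)
    genes <<- c(genes, g)
    g
  }
  pick_gene <- function(p_reuse = spec$pReuse) {
    if (length(genes) && runif(1) < p_reuse) sample(genes, 1L)
    else new_gene()
  }

  add_met("ac", C = 3)           # central C3 pool
  add_met("co2", C = 1, formula = "CO2")
  add_met("o2", formula = "O2")
  add_met("h2o", formula = "H2O")
  add_met("h", formula = "H")
  add_met("npool", N = 1)
  add_met("spool", S = 1)
  add_met("ppool", P = 1)

  ## carbon sources: cycle through carbon counts and yields
  ccounts <- rep(c(6, 3, 6, 9, 3, 6), length.out = spec$nCarbon)
  waste <- rep(c(0, 0, 3, 3, 1, 2), length.out = spec$nCarbon)
  for (i in seq_len(spec$nCarbon)) {
    src <- sprintf("csrc%d", i)
    add_met(src, C = ccounts[i])
    add_rx(paste0("EX_", src), setNames(-1, src),
           lb = -60 / ccounts[i], ub = 1000, exchange = TRUE)
    nac <- (ccounts[i] - waste[i]) / 3
    st <- setNames(c(-1, nac), c(src, "ac"))
    if (waste[i] > 0) st <- c(st, setNames(waste[i], "co2"))
    add_rx(sprintf("UPT%d", i), st, lb = 0, ub = 1000, gpr = pick_gene())
  }
  other <- list(N = c("nsrc", "npool", spec$nNitrogen),
                S = c("ssrc", "spool", spec$nSulfur),
                P = c("psrc", "ppool", spec$nPhosphate))
  for (el in names(other)) {
    base <- other[[el]][1L]; pool <- other[[el]][2L]
    nn <- as.integer(other[[el]][3L])
    for (i in seq_len(nn)) {
      src <- sprintf("%s%d", base, i)
      arg <- list(id = src); arg[[el]] <- 1
      do.call(add_met, arg)
      add_rx(paste0("EX_", src), setNames(-1, src), lb = -1000, ub = 1000,
             exchange = TRUE)
      add_rx(sprintf("AS%s%d", el, i),
             setNames(c(-1, 1), c(src, pool)), lb = 0, ub = 1000,
             gpr = pick_gene())
    }
  }

  ## internal C3 backbone: ac = x0 -> x1 -> ... -> xK = prec_c plus shortcuts
  K <- max(2L, ceiling(spec$nInternal * 0.6))
  nodes <- c("ac", sprintf("x%d", seq_len(K - 1L)), "prec_c")
  for (nd in setdiff(nodes, "ac")) add_met(nd, C = 3)
  internal_ids <- character(0)
  for (k in seq_len(K)) {
    id <- sprintf("INT%d", k)
    st <- setNames(c(-1, 1), nodes[c(k, k + 1L)])
    if (k %% 2L == 0L) {
      st <- c(st, setNames(c(-1, 1), c("h2o", "h")))  # untracked elements
    }
    add_rx(id, st, lb = 0, ub = 1000, gpr = pick_gene())
    internal_ids <- c(internal_ids, id)
  }
  n_short <- spec$nInternal - K
  s_idx <- 0L
  pick1 <- function(x) x[sample.int(length(x), 1L)]  # no 1:n surprise
  while (s_idx < n_short) {
    s_idx <- s_idx + 1L
    from <- pick1(seq_len(length(nodes) - 1L))
    to <- pick1(setdiff(seq_along(nodes), seq_len(from)))
    id <- sprintf("SHC%d", s_idx)
    add_rx(id, setNames(c(-1, 1), nodes[c(from, to)]), lb = 0, ub = 1000,
           gpr = pick_gene())
    internal_ids <- c(internal_ids, id)
  }
  ## reversibility
  nrev <- round(spec$fractionReversible * length(internal_ids))
  if (nrev > 0) {
    for (id in sample(internal_ids, nrev)) rxs[[id]]$lb <- -1000
  }
  ## isozyme / complex GPRs on distinct internal reactions
  tagged <- sample(internal_ids, spec$nIsozyme + spec$nComplex)
  for (id in head(tagged, spec$nIsozyme)) {
    rxs[[id]]$gpr <- paste0("(", rxs[[id]]$gpr, " or ", pick_gene(), ")")
  }
  for (id in tail(tagged, spec$nComplex)) {
    rxs[[id]]$gpr <- paste0("(", rxs[[id]]$gpr, " and ", new_gene(), ")")
  }

  ## oxygen path (never beneficial: burns carbon) and maintenance sink
  add_rx("EX_o2", setNames(-1, "o2"), lb = -1000, ub = 1000,
         exchange = TRUE)
  add_rx("OXD", setNames(c(-1, -3, 3), c("ac", "o2", "co2")),
         lb = 0, ub = 1000, gpr = new_gene())
  add_rx("ATPM", setNames(c(-1, 3), c("ac", "co2")), lb = 0, ub = 1000)
  add_rx("EX_co2", setNames(-1, "co2"), lb = 0, ub = 1000, exchange = TRUE)
  add_rx("EX_h2o", setNames(-1, "h2o"), lb = -1000, ub = 1000,
         exchange = TRUE)
  add_rx("EX_h", setNames(-1, "h"), lb = -1000, ub = 1000,
         exchange = TRUE)

  ## biomass: balanced via a biomass metabolite carrying the summed formula
  add_met("biomass_met", C = 3, N = 1, S = 1, P = 1)
  add_rx("BIOMASS",
         setNames(c(-1, -1, -1, -1, 1),
                  c("prec_c", "npool", "spool", "ppool", "biomass_met")),
         lb = 0, ub = 1000)
  add_rx("EX_biomass", setNames(-1, "biomass_met"), lb = 0, ub = 1000,
         exchange = TRUE)

  rx <- data.frame(
    id = vapply(rxs, `[[`, "", "id"),
    lb = vapply(rxs, `[[`, 0, "lb"),
    ub = vapply(rxs, `[[`, 0, "ub"),
    reversible = vapply(rxs, function(r) r$lb < 0 && !r$exchange, TRUE),
    exchange = vapply(rxs, `[[`, TRUE, "exchange"),
    row.names = NULL)
  S <- matrix(0, nrow(mets), nrow(rx), dimnames = list(mets$id, rx$id))
  for (r in rxs) S[names(r$stoich), r$id] <- r$stoich
  gpr <- setNames(vapply(rxs, `[[`, "", "gpr"), rx$id)
  mw <- setNames(round(stats::rlnorm(length(genes), log(35), 0.35), 3),
                 genes)
  net <- metabolicNetwork(rx, mets, S, "BIOMASS", gpr = gpr, geneMW = mw,
                          oxygenExchange = "EX_o2")
  if (!.growth_feasible(net)) {
    stop("generated toy network cannot sustain growth; adjust the spec")
  }
  net
}
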