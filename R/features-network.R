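## Network-derived reaction features: the generalist property, substrate
## counts, and GPR-based summarization of gene-level features.

#' Generalist feature of a reaction
#'
#' The maximum, over the genes in the reaction's GPR, of the number of
#' OTHER reactions whose GPR references that gene. An enzyme used only by
#' its own reaction scores 0.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param rxn reaction id
#' @return integer count, or \code{NA} when the reaction has no GPR
#' @export
generalistFeature <- function(network, rxn) {
  stopifnot(rxn %in% network@reactions$id)
  genes <- .gpr_genes(network@gpr[[rxn]])
  if (!length(genes)) return(NA_integer_)
  all_genes <- lapply(network@gpr, .gpr_genes)
  counts <- vapply(genes, function(g) {
    sum(vapply(all_genes[names(all_genes) != rxn],
               function(gg) g %in% gg, logical(1L)))
  }, integer(1L))
  max(counts)
}

.is_water_or_proton <- function(formula) {
  f <- toupper(gsub("[[:space:]]", "", formula))
  f %in% c("H2O", "OH2", "H", "H1")
}

#' Number of substrates of a reaction
#'
#' Counts the distinct reactant-side metabolites for the given direction,
#' excluding water and proton species (matched by their chemical formula,
#' not by id).
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param rxn reaction id
#' @param direction \code{"forward"} (negative-coefficient side) or
#'   \code{"backward"}
#' @return integer count
#' @export
substrateCount <- function(network, rxn,
                           direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(rxn %in% network@reactions$id)
  j <- match(rxn, network@reactions$id)
  sj <- network@stoich[, j]
  side <- if (direction == "forward") which(sj < 0) else which(sj > 0)
  mets <- network@metabolites[side, , drop = FALSE]
  formula <- if (!is.null(mets$formula)) mets$formula else rep("", nrow(mets))
  sum(!.is_water_or_proton(formula))
}

#' Summarize gene-level features to the reaction level through GPR rules
#'
#' AND nodes (enzyme complexes) sum the columns named in \code{sumOnAnd}
#' (molecular weight by default) and average the remaining features; OR
#' nodes (isozymes) average everything. The rule is applied recursively
#' over the GPR tree. Genes without data are skipped; a reaction whose GPR
#' has no gene with data gets \code{NA} in every column.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @param geneFeatures data.frame of numeric gene-level features with a
#'   \code{gene} column (or gene rownames)
#' @param sumOnAnd columns summed (not averaged) across AND nodes
#' @return data.frame, one row per reaction with a non-empty GPR
#' @export
summarizeGeneFeatures <- function(network, geneFeatures,
                                  sumOnAnd = "molecular_weight") {
  if (!is.null(geneFeatures$gene)) {
    rownames(geneFeatures) <- geneFeatures$gene
    geneFeatures$gene <- NULL
  }
  feat_names <- names(geneFeatures)
  eval_node <- function(node) {
    if (is.character(node)) {
      if (node %in% rownames(geneFeatures)) {
        return(as.numeric(geneFeatures[node, ]))
      }
      return(rep(NA_real_, length(feat_names)))
    }
    vals <- do.call(rbind, lapply(node$args, eval_node))
    if (node$op == "and") {
      out <- colMeans(vals, na.rm = TRUE)
      for (sc in intersect(sumOnAnd, feat_names)) {
        k <- match(sc, feat_names)
        out[k] <- if (all(is.na(vals[, k]))) NA_real_
                  else sum(vals[, k], na.rm = TRUE)
      }
    } else {
      out <- colMeans(vals, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  with_gpr <- names(network@gpr)[nzchar(network@gpr)]
  rows <- lapply(with_gpr, function(r) eval_node(.gpr_parse(network@gpr[[r]])))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- feat_names
  out$reaction <- with_gpr
  out[c("reaction", feat_names)]
}
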