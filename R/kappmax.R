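## In vivo apparent turnover: k_app = v / (3600 E) per condition, and
## k_app,max as the maximum across conditions, restricted to unique
## homomeric enzymes.

#' Unique homomeric reactions of a network
#'
#' Reactions whose GPR is a single gene that appears in no other
#' reaction's GPR. The in vivo k_app,max estimate is restricted to these.
#'
#' @param network a \linkS4class{MetabolicNetwork}
#' @return data.frame with columns \code{reaction} and \code{gene}
#' @export
uniqueHomomers <- function(network) {
  gsets <- lapply(network@gpr, .gpr_genes)
  single <- names(gsets)[vapply(gsets, length, 0L) == 1L &
                           !grepl("and|or", network@gpr,
                                  ignore.case = TRUE)]
  genes <- vapply(gsets[single], `[[`, "", 1L)
  usage <- table(unlist(gsets, use.names = FALSE))
  ok <- usage[genes] == 1L
  data.frame(reaction = single[ok], gene = unname(genes[ok]),
             row.names = NULL)
}

#' Maximum apparent turnover rate across conditions
#'
#' Per eligible reaction and condition, k_app = v / (3600 E) in 1/s, with
#' the flux v in mmol/gDW/h and the enzyme abundance E in mmol/gDW; the
#' factor 3600 converts hours to seconds. k_app,max is the maximum over
#' conditions with v > 0 and E > 0. Restricted to unique homomers (single
#' gene mapping to a single reaction); reactions with no eligible
#' condition are omitted.
#'
#' @param proteomics gene x condition matrix of abundances (mmol/gDW)
#' @param fluxes reaction x condition matrix of fluxes (mmol/gDW/h);
#'   columns must match \code{proteomics}
#' @param network a \linkS4class{MetabolicNetwork}
#' @return named numeric vector of k_app,max values (1/s)
#' @export
computeKappMax <- function(proteomics, fluxes, network) {
  stopifnot(identical(colnames(proteomics), colnames(fluxes)))
  hom <- uniqueHomomers(network)
  out <- numeric(0)
  for (i in seq_len(nrow(hom))) {
    r <- hom$reaction[i]; g <- hom$gene[i]
    if (!(r %in% rownames(fluxes)) || !(g %in% rownames(proteomics))) next
    v <- fluxes[r, ]
    E <- proteomics[g, ]
    ok <- !is.na(v) & !is.na(E) & v > 0 & E > 0
    if (!any(ok)) next
    out[r] <- max(v[ok] / (3600 * E[ok]))
  }
  out
}
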