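## Linearization: transforms chosen to favour linear feature-response
## relationships. Flux, molecular weight, Km, metabolite concentrations and
## the turnover outputs live on log10 scale; assay temperature enters as a
## reciprocal absolute temperature (Arrhenius form).

.DEFAULT_LOG_FIELDS <- c("flux_feature", "molecular_weight", "km",
                         "substrate_conc", "product_conc", "kcat_invitro",
                         "kappmax")

#' Linearize a raw feature table
#'
#' log10-transforms the listed fields (non-positive values become \code{NA}
#' with a warning: they are treated as missing, not \code{-Inf}) and
#' replaces an assay temperature in Celsius by the reciprocal of the
#' absolute temperature (1/K). All other columns pass through unchanged.
#'
#' @param raw data.frame of raw-scale features
#' @param logFields columns to log10-transform (only those present are
#'   touched)
#' @param tempField assay temperature column in Celsius, replaced by
#'   \code{assay_inverse_temperature}
#' @return the transformed data.frame; attribute \code{"linearized"}
#'   records what was done so \code{\link{delinearizeFeatures}} can invert
#'   it
#' @examples
#' linearizeFeatures(data.frame(kcat_invitro = 100))$kcat_invitro  # 2
#' @export
linearizeFeatures <- function(raw, logFields = .DEFAULT_LOG_FIELDS,
                              tempField = "assay_temperature") {
  out <- raw
  done <- character(0)
  for (f in intersect(logFields, names(out))) {
    v <- out[[f]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive value(s) in '", f,
              "' masked as missing before log transform")
      v[bad] <- NA_real_
    }
    out[[f]] <- log10(v)
    done <- c(done, f)
  }
  if (tempField %in% names(out)) {
    out$assay_inverse_temperature <- 1 / (out[[tempField]] + 273.15)
    out[[tempField]] <- NULL
  }
  attr(out, "linearized") <- list(logFields = done,
                                  tempField = if (tempField %in% names(raw))
                                    tempField else NULL)
  out
}

#' Invert \code{\link{linearizeFeatures}}
#'
#' @param x a linearized table carrying the \code{"linearized"} attribute
#' @return the raw-scale data.frame (masked cells stay \code{NA})
#' @export
delinearizeFeatures <- function(x) {
  info <- attr(x, "linearized")
  if (is.null(info)) stop("table does not carry linearization info")
  out <- x
  for (f in info$logFields) out[[f]] <- 10^out[[f]]
  if (!is.null(info$tempField)) {
    out[[info$tempField]] <- 1 / out$assay_inverse_temperature - 273.15
    out$assay_inverse_temperature <- NULL
  }
  attr(out, "linearized") <- NULL
  out
}
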