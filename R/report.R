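## Run-summary reporting: one JSON with configs, seeds and metrics, plus
## plain TSV tables.

#' Write a run summary as JSON
#'
#' @param path output file
#' @param config named list of configuration values (seeds, sizes)
#' @param metrics named list of numeric results
#' @export
writeRunSummary <- function(path, config = list(), metrics = list()) {
  jsonlite::write_json(list(config = config, metrics = metrics), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' @param x data.frame
#' @param path output file
#' @export
writeTableTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read measured fluxes from TSV
#'
#' Expects columns \code{reaction_id}, \code{flux} and optionally
#' \code{condition}; returns a named flux vector per condition.
#'
#' @param path TSV file
#' @return named list (one named numeric per condition)
#' @export
readMeasuredFluxesTsv <- function(path) {
  tab <- read.delim(path)
  if (is.null(tab$condition)) tab$condition <- "all"
  lapply(split(tab, tab$condition), function(d)
    setNames(d$flux, d$reaction_id))
}

#' Write a turnover-rate vector as CSV
#'
#' @param keff named numeric (1/s); backward-direction entries may use the
#'   \code{"<id>_b"} convention
#' @param path output CSV with columns reaction_id, direction, keff_per_s,
#'   source
#' @param source provenance label per entry (data, median, ensemble,
#'   default), recycled
#' @export
writeKeffCsv <- function(keff, path, source = "data") {
  back <- grepl("_b$", names(keff))
  write.csv(data.frame(reaction_id = sub("_b$", "", names(keff)),
                       direction = ifelse(back, "backward", "forward"),
                       keff_per_s = unname(keff),
                       source = source),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a turnover-rate vector from CSV
#'
#' @param path CSV written by \code{\link{writeKeffCsv}}
#' @return named numeric usable by \code{\link{momentProblem}}
#' @export
readKeffCsv <- function(path) {
  tab <- read.csv(path)
  nm <- ifelse(tab$direction == "backward",
               paste0(tab$reaction_id, "_b"), tab$reaction_id)
  setNames(tab$keff_per_s, nm)
}

#' Write proteome comparison results as TSV
#'
#' @param comparisons named list of \code{ProteomeComparison} objects,
#'   named "condition/parameterization"
#' @param path output TSV with columns condition, parameterization, n,
#'   rmse
#' @export
writeProteomeComparisonTsv <- function(comparisons, path) {
  parts <- strsplit(names(comparisons), "/", fixed = TRUE)
  write.table(data.frame(
    condition = vapply(parts, `[[`, "", 1L),
    parameterization = vapply(parts, function(p)
      if (length(p) > 1L) p[[2L]] else "", ""),
    n = vapply(comparisons, `[[`, 0, "n"),
    rmse = vapply(comparisons, `[[`, 0, "rmse")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
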