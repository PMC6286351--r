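## Curation of in vitro turnover records: mutant and inhibitor filters,
## cross-database deduplication with source preference, reaction mapping,
## and deterministic conflict resolution.

#' Curate in vitro turnover records
#'
#' Applies the filter cascade: (1) drop records flagged as mutant enzymes;
#' (2) drop records measured in the presence of inhibitors; (3) remove
#' cross-database duplicates of the same publication/reaction, keeping
#' BRENDA over MetaCyc over SABIO; (4) drop records whose key does not map
#' to a network reaction; (5) resolve remaining same-reaction conflicts
#' with a deterministic preference comparator: in-vivo-like assay
#' conditions first, then recency, then agreement with the per-reaction
#' median (smallest |log10 value - median log10|), with value and record id
#' as final tie-breaks. Every drop is logged with the rule that fired.
#'
#' @param records data.frame with columns \code{reaction_key},
#'   \code{value} (1/s), \code{source_db} (BRENDA/METACYC/SABIO),
#'   \code{publication}, \code{mutant}, \code{inhibitor}; optional
#'   \code{record_id}, \code{year}, \code{in_vivo_like}
#' @param reactionMap named character mapping \code{reaction_key} to
#'   network reaction ids
#' @return list with \code{records} (curated, one row per reaction, plus a
#'   \code{reaction_id} column), \code{dropLog} (record_id, rule) and
#'   \code{counts} (drops per rule)
#' @export
curateKcatRecords <- function(records, reactionMap) {
  stopifnot(all(c("reaction_key", "value", "source_db", "publication")
                %in% names(records)))
  if (any(records$value <= 0, na.rm = TRUE)) {
    stop("turnover values must be positive")
  }
  x <- records
  if (is.null(x$record_id)) x$record_id <- as.character(seq_len(nrow(x)))
  if (is.null(x$mutant)) x$mutant <- FALSE
  if (is.null(x$inhibitor)) x$inhibitor <- FALSE
  if (is.null(x$year)) x$year <- 0
  if (is.null(x$in_vivo_like)) x$in_vivo_like <- FALSE
  drops <- data.frame(record_id = character(0), rule = character(0))
  drop <- function(ids, rule) {
    if (!length(ids)) return()
    drops <<- rbind(drops, data.frame(record_id = ids, rule = rule))
    x <<- x[!(x$record_id %in% ids), , drop = FALSE]
  }

  drop(x$record_id[x$mutant %in% TRUE], "mutant")
  drop(x$record_id[x$inhibitor %in% TRUE], "inhibitor")

  ## cross-database duplicates: same publication and reaction key
  pref <- c(BRENDA = 1L, METACYC = 2L, SABIO = 3L)
  rank <- pref[toupper(x$source_db)]
  rank[is.na(rank)] <- 4L
  grp <- paste(x$publication, x$reaction_key, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(x)), grp), function(ii) {
    ii[order(rank[ii], x$record_id[ii])][1L]
  }), use.names = FALSE)
  drop(x$record_id[setdiff(seq_len(nrow(x)), keep)], "cross_db_duplicate")

  drop(x$record_id[!(x$reaction_key %in% names(reactionMap))], "unmapped")
  x$reaction_id <- unname(reactionMap[x$reaction_key])

  ## same-reaction conflicts: deterministic preference comparator
  keep <- unlist(lapply(split(seq_len(nrow(x)), x$reaction_id),
                        function(ii) {
    if (length(ii) == 1L) return(ii)
    med <- median(log10(x$value[ii]))
    dev <- abs(log10(x$value[ii]) - med)
    ii[order(-as.integer(x$in_vivo_like[ii]), -x$year[ii], dev,
             x$value[ii], x$record_id[ii])][1L]
  }), use.names = FALSE)
  drop(x$record_id[setdiff(seq_len(nrow(x)), keep)], "conflict")

  list(records = x[order(x$record_id), , drop = FALSE],
       dropLog = drops,
       counts = table(factor(drops$rule,
                             levels = c("mutant", "inhibitor",
                                        "cross_db_duplicate", "unmapped",
                                        "conflict"))))
}

#' Write curation output and drop log
#'
#' @param curated result of \code{\link{curateKcatRecords}}
#' @param recordsPath CSV for the surviving records
#' @param dropLogPath TSV for the drop log (record_id, rule)
#' @export
writeCuration <- function(curated, recordsPath, dropLogPath) {
  write.csv(curated$records, recordsPath, row.names = FALSE)
  write.table(curated$dropLog, dropLogPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}
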