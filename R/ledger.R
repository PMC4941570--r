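# FilterLedger: run accounting, conservation identities and derived metrics.

#' Build a filter ledger
#'
#' All arguments are counts; any may be left \code{NA} while unknown.  See
#' \code{\link{FilterLedger-class}} for the conservation identities.
#'
#' @param assembled total assembled CCSs admitted (>= 2x coverage).
#' @param demultiplexed,non_demultiplexed split of \code{assembled} by
#'   barcode assignment.
#' @param over_length,chimeric,nonspecific discards of the QC cascade.
#' @param usable_pre_filter usable CCSs before the reliability filter.
#' @param wells_recovered_pre wells with >= 1 usable CCS before filtering.
#' @param usable_cov_ge10,wells_recovered_cov the coverage-filter
#'   (>= 10x) comparison counts.
#' @param usable_reliable,reliable_db_hits,reliable_dataset_hits,error_prone
#'   the reliability split: database hits + dataset hits = reliable;
#'   reliable + error-prone = usable_pre_filter.
#' @param wells_recovered_reliable wells with >= 1 reliable CCS.
#' @return a \code{\link{FilterLedger-class}} object.
#' @examples
#' led <- filterLedger(assembled = 100, demultiplexed = 60,
#'                     non_demultiplexed = 40)
#' ledgerCheck(led)
#' @export
filterLedger <- function(assembled = NA, demultiplexed = NA,
                         non_demultiplexed = NA, over_length = NA,
                         chimeric = NA, nonspecific = NA,
                         usable_pre_filter = NA, wells_recovered_pre = NA,
                         usable_cov_ge10 = NA, wells_recovered_cov = NA,
                         usable_reliable = NA, reliable_db_hits = NA,
                         reliable_dataset_hits = NA, error_prone = NA,
                         wells_recovered_reliable = NA) {
  counts <- vapply(
    list(assembled, demultiplexed, non_demultiplexed, over_length, chimeric,
         nonspecific, usable_pre_filter, wells_recovered_pre,
         usable_cov_ge10, wells_recovered_cov, usable_reliable,
         reliable_db_hits, reliable_dataset_hits, error_prone,
         wells_recovered_reliable),
    function(x) as.integer(x), integer(1)
  )
  names(counts) <- .ledger_fields
  new("FilterLedger", counts = counts)
}

#' @rdname FilterLedger-class
#' @export
setMethod("ledgerCounts", "FilterLedger", function(x) x@counts)

#' Check the ledger's conservation identities
#'
#' Verifies every conservation identity whose operands are all present
#' (non-NA).  Identities over missing counts are skipped, so a partially
#' filled ledger checks clean.
#'
#' @param ledger a \code{FilterLedger}.
#' @return character vector of violated identities (empty when consistent).
#' @export
ledgerCheck <- function(ledger) {
  stopifnot(is(ledger, "FilterLedger"))
  k <- as.list(ledger@counts)
  v <- character()
  chk <- function(lhs, rhs, label) {
    if (!any(is.na(c(lhs, rhs))) && lhs != rhs) {
      sprintf("%s (%d != %d)", label, lhs, rhs)
    } else character()
  }
  v <- c(
    v,
    chk(k$assembled, k$demultiplexed + k$non_demultiplexed,
        "assembled = demultiplexed + non_demultiplexed"),
    chk(k$usable_pre_filter,
        k$demultiplexed - k$over_length - k$chimeric - k$nonspecific,
        "usable_pre_filter = demultiplexed - over_length - chimeric - nonspecific"),
    chk(k$usable_reliable, k$reliable_db_hits + k$reliable_dataset_hits,
        "usable_reliable = reliable_db_hits + reliable_dataset_hits"),
    chk(k$usable_pre_filter, k$usable_reliable + k$error_prone,
        "usable_pre_filter = usable_reliable + error_prone")
  )
  v
}

#' Derived run metrics from a ledger
#'
#' Recomputes the headline fractions of a run from its raw counts: the
#' chimera and nonspecific fractions of demultiplexed CCSs, the recovered
#' share of expected wells, the high-coverage share of usable CCSs, and the
#' reliability split.
#'
#' @param ledger a \code{FilterLedger}.
#' @param expected_wells number of wells expected in the run (see
#'   \code{\link{expectedWellCount}}).
#' @return named list of percentages and counts:
#'   \code{chimera_fraction_pct}, \code{nonspecific_fraction_pct},
#'   \code{well_recovery_pct}, \code{high_coverage_usable_pct},
#'   \code{usable_reliable}, \code{error_prone}.
#' @export
ledgerMetrics <- function(ledger, expected_wells = NA) {
  stopifnot(is(ledger, "FilterLedger"))
  k <- as.list(ledger@counts)
  list(
    chimera_fraction_pct = 100 * k$chimeric / k$demultiplexed,
    nonspecific_fraction_pct = 100 * k$nonspecific / k$demultiplexed,
    well_recovery_pct =
      100 * k$wells_recovered_reliable / as.numeric(expected_wells),
    high_coverage_usable_pct = 100 * k$usable_cov_ge10 / k$usable_pre_filter,
    usable_reliable = k$reliable_db_hits + k$reliable_dataset_hits,
    error_prone = k$usable_pre_filter - k$usable_reliable
  )
}

.ledger_labels <- c(
  assembled = "Total number of assembled CCSs (>=2x coverage)",
  demultiplexed = "Demultiplexed CCSs",
  non_demultiplexed = "Non-demultiplexed CCSs",
  over_length = "CCSs larger than expected (>1,600 bp)",
  chimeric = "Chimeric CCSs",
  nonspecific = "Non-specific sequences",
  usable_pre_filter = "Usable CCSs before quality filtering",
  wells_recovered_pre = "Recovered wells before quality filtering",
  usable_cov_ge10 = "Usable CCSs after filtering by coverage (>=10x coverage)",
  wells_recovered_cov = "Recovered wells after filtering by coverage (>=10x coverage)",
  usable_reliable = "Usable CCSs after filtering by reliability",
  reliable_db_hits = "CCSs with hits against the curated database",
  reliable_dataset_hits = "CCSs with no database hit and a hit within the CCS dataset",
  error_prone = "Error-prone CCSs",
  wells_recovered_reliable = "Recovered wells after filtering by reliability"
)

#' Ledger report table
#'
#' @param ledger a \code{FilterLedger}.
#' @param path optional path; when given the table is written as TSV.
#' @return data.frame with columns \code{label} and \code{count}.
#' @export
ledgerReport <- function(ledger, path = NULL) {
  stopifnot(is(ledger, "FilterLedger"))
  out <- data.frame(
    label = unname(.ledger_labels[.ledger_fields]),
    count = unname(ledger@counts[.ledger_fields]),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @rdname FilterLedger-class
#' @param object a \code{FilterLedger}.
#' @export
setMethod("show", "FilterLedger", function(object) {
  rep <- ledgerReport(object)
  cat("FilterLedger\n")
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  %-62s %s\n", rep$label[i],
                ifelse(is.na(rep$count[i]), ".", rep$count[i])))
  }
  bad <- ledgerCheck(object)
  if (length(bad)) cat("  ! violated:", paste(bad, collapse = "; "), "\n")
})
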