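#' Barcode manifest for a multiplexed CBC run
#'
#' Holds the three barcode tables of the combinatorial scheme (plate 9 nt,
#' row 8 nt, column 8 nt), the three constant anchor oligos used to locate
#' them (forward transposase 14 nt, universal reverse primer 16 nt, reverse
#' transposase 15 nt), and the reserved control wells.  The construct layout
#' on the plus strand is fixed:
#'
#' \preformatted{[row bc][fwd anchor][16S insert][univ primer][plate bc][rev anchor][col bc]}
#'
#' so every barcode abuts a known side of its anchor and its position can be
#' predicted from anchor hits.
#'
#' @slot plates named character vector of 9-nt plate barcodes.
#' @slot rows named character vector (names \code{A}..\code{H}) of 8-nt row
#'   barcodes.
#' @slot columns named character vector (names \code{1}..\code{12}) of 8-nt
#'   column barcodes.
#' @slot anchors named character vector with elements
#'   \code{fwd_transposase} (14 nt), \code{univ_reverse_primer} (16 nt) and
#'   \code{rev_transposase} (15 nt).
#' @slot controls data.frame with columns \code{row}, \code{column},
#'   \code{role} marking the reserved control wells (by default H10 positive,
#'   H11/H12 negative).
#'
#' @seealso \code{\link{makeManifest}}, \code{\link{validateManifest}},
#'   \code{\link{readManifest}}
#' @exportClass BarcodeManifest
setClass("BarcodeManifest",
  representation(
    plates = "character",
    rows = "character",
    columns = "character",
    anchors = "character",
    controls = "data.frame"
  )
)

setValidity("BarcodeManifest", function(object) {
  v <- validateManifest(object)
  if (length(v) == 0) TRUE else v
})

#' Set of circular consensus reads with per-read metadata
#'
#' Couples a \code{DNAStringSet} of CCS sequences with the per-read metadata
#' the pipeline tracks: the subread nucleotide total from the sidecar, the
#' derived integer coverage, the decoded well address (or NA while
#' unassigned), the detected strand, the QC status trail and the reliability
#' source.  Status moves only forward along the cascade: \code{raw} ->
#' \code{demultiplexed} -> one of \code{discarded_length},
#' \code{discarded_chimera}, \code{discarded_nonspecific},
#' \code{error_prone} or \code{usable}.
#'
#' @slot sequences \code{DNAStringSet}, names are the unique ccs ids.
#' @slot meta \code{DataFrame} with one row per read: columns
#'   \code{subread_total_nt}, \code{coverage}, \code{ccs_length} (the
#'   original consensus length, kept through insert trimming), \code{plate},
#'   \code{row}, \code{column}, \code{strand}, \code{status},
#'   \code{reliability_source}.
#'
#' @seealso \code{\link{ccsSet}}, \code{\link{readCcsSet}}
#' @exportClass CCSSet
setClass("CCSSet",
  representation(
    sequences = "DNAStringSet",
    meta = "DataFrame"
  )
)

.ccs_statuses <- c(
  "raw", "demultiplexed", "discarded_length", "discarded_chimera",
  "discarded_nonspecific", "error_prone", "usable"
)
.reliability_sources <- c("none", "database_hit", "dataset_hit")

setValidity("CCSSet", function(object) {
  msgs <- character()
  ids <- names(object@sequences)
  if (length(object@sequences) > 0 &&
      (is.null(ids) || anyDuplicated(ids))) {
    msgs <- c(msgs, "sequences must carry unique names (ccs ids)")
  }
  need <- c(
    "subread_total_nt", "coverage", "ccs_length", "plate", "row", "column",
    "strand", "status", "reliability_source"
  )
  if (!all(need %in% colnames(object@meta))) {
    msgs <- c(msgs, paste(
      "meta must have columns:", paste(need, collapse = ", ")
    ))
  } else {
    if (nrow(object@meta) != length(object@sequences)) {
      msgs <- c(msgs, "meta and sequences disagree in length")
    }
    bad <- !object@meta$status %in% .ccs_statuses
    if (any(bad)) msgs <- c(msgs, "unknown status value")
    badr <- !object@meta$reliability_source %in% .reliability_sources
    if (any(badr)) msgs <- c(msgs, "unknown reliability_source value")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Stage-by-stage accounting of a filtered run
#'
#' Mirrors the standard run-report table: how many CCSs were assembled, how
#' many demultiplexed, how many fell at each QC stage, and how many wells
#' remain represented.  Counts left \code{NA} are simply not yet known (the
#' ledger is filled in as stages run).  Conservation identities that must
#' hold once the relevant counts are present:
#'
#' \itemize{
#'   \item \code{assembled == demultiplexed + non_demultiplexed}
#'   \item \code{usable_pre_filter ==
#'     demultiplexed - over_length - chimeric - nonspecific}
#'   \item \code{usable_reliable == reliable_db_hits + reliable_dataset_hits}
#'   \item \code{usable_pre_filter == usable_reliable + error_prone}
#' }
#'
#' @slot counts named integer vector; see \code{\link{filterLedger}} for the
#'   field names.
#'
#' @seealso \code{\link{filterLedger}}, \code{\link{ledgerCheck}},
#'   \code{\link{ledgerMetrics}}, \code{\link{ledgerReport}}
#' @exportClass FilterLedger
setClass("FilterLedger", representation(counts = "integer"))

.ledger_fields <- c(
  "assembled", "demultiplexed", "non_demultiplexed", "over_length",
  "chimeric", "nonspecific", "usable_pre_filter", "wells_recovered_pre",
  "usable_cov_ge10", "wells_recovered_cov", "usable_reliable",
  "reliable_db_hits", "reliable_dataset_hits", "error_prone",
  "wells_recovered_reliable"
)

setValidity("FilterLedger", function(object) {
  if (!identical(names(object@counts), .ledger_fields)) {
    return("counts must be a named integer vector over the ledger fields")
  }
  neg <- !is.na(object@counts) & object@counts < 0
  if (any(neg)) return("ledger counts must be non-negative")
  TRUE
})
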