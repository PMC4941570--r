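#' @rdname CCSSet-class
#' @param x a \code{CCSSet}.
#' @export
setGeneric("ccsSequences", function(x) standardGeneric("ccsSequences"))

#' @rdname CCSSet-class
#' @export
setGeneric("ccsMeta", function(x) standardGeneric("ccsMeta"))

#' @rdname CCSSet-class
#' @export
setGeneric("ccsId", function(x) standardGeneric("ccsId"))

#' @rdname CCSSet-class
#' @export
setGeneric("ccsCoverage", function(x) standardGeneric("ccsCoverage"))

#' @rdname CCSSet-class
#' @export
setGeneric("ccsStatus", function(x) standardGeneric("ccsStatus"))

#' @rdname CCSSet-class
#' @export
setGeneric("ccsWell", function(x) standardGeneric("ccsWell"))

#' @rdname FilterLedger-class
#' @param x a \code{FilterLedger}.
#' @export
setGeneric("ledgerCounts", function(x) standardGeneric("ledgerCounts"))

#' Validate a barcode manifest
#'
#' Checks the structural invariants of a \code{\link{BarcodeManifest-class}}:
#' exact barcode lengths (plate 9 nt, row 8 nt, column 8 nt), exact anchor
#' lengths (14/16/15 nt), a DNA alphabet, uniqueness within each barcode
#' class, and a minimum pairwise Hamming distance of 2 within each class
#' (so a single substitution can never turn one barcode into another).
#'
#' @param manifest a \code{BarcodeManifest}.
#' @return character vector of human-readable violations; empty when the
#'   manifest is valid.
#' @examples
#' m <- makeManifest(n_plates = 2)
#' validateManifest(m)  # character(0)
#' @export
setGeneric("validateManifest", function(manifest) {
  standardGeneric("validateManifest")
})
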