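# CCSSet construction, accessors and the coverage model.

#' Compute integer CCS coverage
#'
#' Coverage of a consensus read is the total number of subread nucleotides
#' that went into it divided by the consensus length, rounded to the
#' nearest integer with ties rounding half away from zero.
#'
#' @param subread_total_nt total subread nucleotides (> 0); vectorized.
#' @param ccs_length consensus length in nt (> 0); vectorized.
#' @return integer coverage vector.
#' @examples
#' computeCcsCoverage(14000, 1400)  # 10
#' computeCcsCoverage(13000, 1400)  # 9  (9.29)
#' computeCcsCoverage(13300, 1400)  # 10 (9.5 rounds up)
#' @export
computeCcsCoverage <- function(subread_total_nt, ccs_length) {
  if (any(!is.finite(subread_total_nt)) || any(subread_total_nt <= 0)) {
    stop("subread_total_nt must be > 0")
  }
  if (any(!is.finite(ccs_length)) || any(ccs_length <= 0)) {
    stop("ccs_length must be > 0")
  }
  # round half away from zero (ratios are positive here)
  as.integer(floor(subread_total_nt / ccs_length + 0.5))
}

#' Coverage class of a CCS
#'
#' Reads are classed as low coverage (< 10x) or high coverage (>= 10x);
#' coverage below the 2x admission minimum is an error.
#'
#' @param coverage integer coverage (vectorized), each >= 2.
#' @return character vector of \code{"low"} / \code{"high"}.
#' @examples
#' coverageClass(c(2, 9, 10))  # low low high
#' @export
coverageClass <- function(coverage) {
  if (any(coverage < 2)) {
    stop("coverage below the 2x admission minimum")
  }
  ifelse(coverage < 10, "low", "high")
}

#' Construct a CCSSet
#'
#' @param sequences named \code{DNAStringSet} (or named character vector);
#'   names are unique ccs ids.
#' @param subread_total_nt numeric vector of subread nucleotide totals,
#'   parallel to \code{sequences} (or named by ccs id).
#' @return a \code{\link{CCSSet-class}} with coverage derived via
#'   \code{\link{computeCcsCoverage}}, all reads in status \code{raw}.
#' @export
ccsSet <- function(sequences, subread_total_nt) {
  if (!is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(setNames(toupper(sequences),
                                                   names(sequences)))
  }
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must carry unique names (ccs ids)")
  }
  if (!is.null(names(subread_total_nt))) {
    missing <- setdiff(ids, names(subread_total_nt))
    if (length(missing) > 0) {
      stop("no subread total for: ", paste(head(missing), collapse = ", "))
    }
    subread_total_nt <- subread_total_nt[ids]
  }
  if (length(subread_total_nt) != length(sequences)) {
    stop("subread_total_nt must parallel sequences")
  }
  cov <- computeCcsCoverage(subread_total_nt, Biostrings::width(sequences))
  meta <- S4Vectors::DataFrame(
    subread_total_nt = as.numeric(subread_total_nt),
    coverage = cov,
    ccs_length = Biostrings::width(sequences),
    plate = NA_character_, row = NA_character_, column = NA_integer_,
    strand = NA_character_,
    status = "raw", reliability_source = "none",
    row.names = ids
  )
  new("CCSSet", sequences = sequences, meta = meta)
}

#' Read a CCS set from FASTA plus subread sidecar
#'
#' @param fasta path to the CCS FASTA.
#' @param sidecar path to the subread sidecar TSV with header columns
#'   \code{ccs_id} and \code{subread_total_nt}.
#' @return a \code{CCSSet}.
#' @export
readCcsSet <- function(fasta, sidecar) {
  for (p in c(fasta, sidecar)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) stop("duplicate ccs_id in FASTA")
  side <- read.delim(sidecar, stringsAsFactors = FALSE)
  if (!all(c("ccs_id", "subread_total_nt") %in% colnames(side))) {
    stop("sidecar TSV must have columns ccs_id, subread_total_nt")
  }
  ccsSet(seqs, setNames(side$subread_total_nt, side$ccs_id))
}

#' Write a CCS set as FASTA plus subread sidecar
#'
#' @param x a \code{CCSSet}.
#' @param fasta,sidecar output paths.
#' @return invisibly, the FASTA path.
#' @export
writeCcsSet <- function(x, fasta, sidecar) {
  stopifnot(is(x, "CCSSet"))
  Biostrings::writeXStringSet(x@sequences, fasta)
  write.table(
    data.frame(ccs_id = ccsId(x), subread_total_nt = x@meta$subread_total_nt),
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(fasta)
}

#' @rdname CCSSet-class
#' @export
setMethod("ccsSequences", "CCSSet", function(x) x@sequences)

#' @rdname CCSSet-class
#' @export
setMethod("ccsMeta", "CCSSet", function(x) x@meta)

#' @rdname CCSSet-class
#' @export
setMethod("ccsId", "CCSSet", function(x) names(x@sequences))

#' @rdname CCSSet-class
#' @export
setMethod("ccsCoverage", "CCSSet", function(x) {
  setNames(x@meta$coverage, ccsId(x))
})

#' @rdname CCSSet-class
#' @export
setMethod("ccsStatus", "CCSSet", function(x) {
  setNames(x@meta$status, ccsId(x))
})

#' @rdname CCSSet-class
#' @export
setMethod("ccsWell", "CCSSet", function(x) {
  setNames(wellId(x@meta$plate, x@meta$row, x@meta$column), ccsId(x))
})

#' @rdname CCSSet-class
#' @export
setMethod("length", "CCSSet", function(x) length(x@sequences))

#' @rdname CCSSet-class
#' @param i index (logical, integer or ccs-id character vector).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CCSSet", function(x, i, j, ..., drop = FALSE) {
  new("CCSSet", sequences = x@sequences[i], meta = x@meta[i, , drop = FALSE])
})

#' @rdname CCSSet-class
#' @param object a \code{CCSSet}.
#' @export
setMethod("show", "CCSSet", function(object) {
  cat(sprintf("CCSSet of %d reads\n", length(object)))
  st <- table(object@meta$status)
  cat("  status:", paste(names(st), st, sep = "=", collapse = " "), "\n")
  assigned <- sum(!is.na(object@meta$plate))
  cat(sprintf("  assigned to wells: %d\n", assigned))
})

#' Canonical well identifier
#'
#' Formats (plate, row, column) as \code{"P1:A01"}; any NA component gives
#' NA.  \code{parseWellId} is the inverse.
#'
#' @param plate,row,column vectors of plate id, row letter A--H, column
#'   1--12.
#' @return character vector of well ids.
#' @export
wellId <- function(plate, row, column) {
  out <- sprintf("%s:%s%02d", plate, row, as.integer(column))
  out[is.na(plate) | is.na(row) | is.na(column)] <- NA_character_
  out
}

#' @rdname wellId
#' @param well character vector of well ids.
#' @export
parseWellId <- function(well) {
  m <- regmatches(well, regexec("^(.+):([A-H])([0-9]{2})$", well))
  data.frame(
    plate = vapply(m, function(x) if (length(x) == 4) x[2] else NA_character_, ""),
    row = vapply(m, function(x) if (length(x) == 4) x[3] else NA_character_, ""),
    column = vapply(m, function(x) if (length(x) == 4) as.integer(x[4]) else NA_integer_, 1L),
    stringsAsFactors = FALSE
  )
}

# internal: forward-only status update for a set of ids
.advance_status <- function(x, ids, new_status) {
  ord <- match(new_status, .ccs_statuses)
  cur <- match(x@meta[ids, "status"], .ccs_statuses)
  if (any(cur > ord)) stop("status may only advance forward along the cascade")
  x@meta[ids, "status"] <- new_status
  x
}
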