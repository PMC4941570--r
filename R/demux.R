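# Demultiplexing: anchor location, barcode position prediction, exact
# position-consistent barcode calling, and run-level well assignment.
#
# Construct layout on the plus strand (lengths in nt):
#   [row bc 8][fwd_transposase 14][insert][univ_reverse_primer 16]
#   [plate bc 9][rev_transposase 15][col bc 8]

.ANCHOR_NAMES <- c("fwd_transposase", "univ_reverse_primer", "rev_transposase")

#' Locate the three anchor oligos on a CCS
#'
#' Scans both orientations of the read for the three constant anchors with
#' at most \code{max_mismatches} substitutions, picks the orientation on
#' which more anchors are found (ties go to plus), and reports the best hit
#' per anchor (fewest mismatches, then leftmost) in the coordinates of the
#' oriented read.
#'
#' @param sequence the read (character or \code{DNAString}).
#' @param manifest a \code{\link{BarcodeManifest-class}}.
#' @param max_mismatches maximum substitutions per anchor (default 3).
#' @return list with \code{strand} (\code{"plus"}/\code{"minus"}),
#'   \code{oriented} (the read on the chosen strand) and \code{anchors}
#'   (data.frame \code{anchor}, \code{start}, \code{end},
#'   \code{mismatches}, \code{found}).
#' @export
locateAnchors <- function(sequence, manifest, max_mismatches = 3) {
  stopifnot(is(manifest, "BarcodeManifest"))
  seq <- .check_seq(sequence, "sequence")
  rc <- .revcomp(seq)
  scan_one <- function(target, oligo) {
    m <- cpp_oligo_scan(target, oligo, as.integer(max_mismatches))
    if (nrow(m) == 0) return(NULL)
    m <- m[order(m[, "mismatches"], m[, "start"]), , drop = FALSE]
    m[1, ]
  }
  best <- function(target) {
    lapply(manifest@anchors[.ANCHOR_NAMES], function(a) scan_one(target, a))
  }
  hits_plus <- best(seq)
  hits_minus <- best(rc)
  n_plus <- sum(!vapply(hits_plus, is.null, TRUE))
  n_minus <- sum(!vapply(hits_minus, is.null, TRUE))
  strand <- if (n_minus > n_plus) "minus" else "plus"
  hits <- if (strand == "plus") hits_plus else hits_minus
  oriented <- if (strand == "plus") seq else rc
  anchors <- data.frame(
    anchor = .ANCHOR_NAMES,
    start = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h[["start"]], 1L),
    mismatches = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h[["mismatches"]], 1L),
    stringsAsFactors = FALSE
  )
  anchors$end <- anchors$start + nchar(manifest@anchors[.ANCHOR_NAMES])
  anchors$found <- !is.na(anchors$start)
  list(strand = strand, oriented = oriented,
       anchors = anchors[, c("anchor", "start", "end", "mismatches", "found")])
}

#' Predict barcode positions from anchor hits
#'
#' Uses the fixed construct layout to turn anchor hits into a predicted
#' [start, end) interval per barcode class.  When a class's flanking anchor
#' is missing, the interval is recovered from the other anchors or, failing
#' that, from the read ends (the 5' block sits at the read start and the
#' 3' block at fixed offsets from the read end).  When no anchor was found
#' at all, every class is unpredictable.
#'
#' @param anchors anchor data.frame from \code{\link{locateAnchors}}.
#' @param read_length length of the oriented read.
#' @return data.frame with \code{class} (\code{row}/\code{plate}/
#'   \code{column}), \code{start}, \code{end} (0-based half-open; NA when
#'   unpredictable).
#' @export
predictBarcodePositions <- function(anchors, read_length) {
  a <- function(nm) anchors[anchors$anchor == nm, ]
  fwd <- a("fwd_transposase"); univ <- a("univ_reverse_primer")
  rev <- a("rev_transposase")
  any_found <- any(anchors$found)
  L <- read_length
  pred <- function(start, len) c(start, start + len)
  row_iv <- if (fwd$found) pred(fwd$start - 8L, 8L)
    else if (any_found) pred(0L, 8L)
    else c(NA_integer_, NA_integer_)
  plate_iv <- if (univ$found) pred(univ$end, 9L)
    else if (rev$found) pred(rev$start - 9L, 9L)
    else if (any_found) pred(L - 32L, 9L)
    else c(NA_integer_, NA_integer_)
  col_iv <- if (rev$found) pred(rev$end, 8L)
    else if (univ$found) pred(univ$end + 24L, 8L)
    else if (any_found) pred(L - 8L, 8L)
    else c(NA_integer_, NA_integer_)
  data.frame(
    class = c("row", "plate", "column"),
    start = c(row_iv[1], plate_iv[1], col_iv[1]),
    end = c(row_iv[2], plate_iv[2], col_iv[2]),
    stringsAsFactors = FALSE
  )
}

#' Call barcodes at their predicted positions
#'
#' Scans the oriented read for exact (0-mismatch) occurrences of every
#' barcode of each class.  A call is made when exactly one distinct barcode
#' of the class occurs within the positional tolerance around its predicted
#' interval; two distinct exact matches in the window give no call.  An
#' exact match found only outside the window is recorded but flagged
#' position-inconsistent, which leaves the read unassigned.
#'
#' @param oriented the plus-oriented read sequence.
#' @param intervals predicted intervals from
#'   \code{\link{predictBarcodePositions}}.
#' @param manifest a \code{BarcodeManifest}.
#' @param tolerance positional tolerance in nt around the predicted start
#'   (default 4).
#' @return data.frame with one row per class: \code{class}, \code{call}
#'   (barcode id or NA), \code{observed_start}, \code{position_consistent}.
#' @export
callBarcodes <- function(oriented, intervals, manifest, tolerance = 4) {
  tabs <- list(
    row = manifest@rows, plate = manifest@plates, column = manifest@columns
  )
  out <- lapply(names(tabs), function(cls) {
    iv <- intervals[intervals$class == cls, ]
    res <- data.frame(
      class = cls, call = NA_character_, observed_start = NA_integer_,
      position_consistent = FALSE, stringsAsFactors = FALSE
    )
    if (is.na(iv$start)) return(res)   # unpredictable class
    bcs <- tabs[[cls]]
    hits <- list()
    for (id in names(bcs)) {
      m <- cpp_oligo_scan(oriented, bcs[[id]], 0L)
      if (nrow(m) > 0) {
        hits[[length(hits) + 1L]] <- data.frame(
          id = id, start = m[, "start"], stringsAsFactors = FALSE
        )
      }
    }
    if (length(hits) == 0) return(res)
    hits <- do.call(rbind, hits)
    in_win <- abs(hits$start - iv$start) <= tolerance
    if (any(in_win)) {
      win <- hits[in_win, , drop = FALSE]
      if (length(unique(win$id)) == 1) {
        win <- win[order(abs(win$start - iv$start)), , drop = FALSE]
        res$call <- win$id[1]
        res$observed_start <- win$start[1]
        res$position_consistent <- TRUE
      }
      # multiple distinct exact matches in the window: ambiguous, no call
    } else {
      # exact match exists but off-position: record, flag inconsistent
      hits <- hits[order(abs(hits$start - iv$start)), , drop = FALSE]
      res$call <- hits$id[1]
      res$observed_start <- hits$start[1]
      res$position_consistent <- FALSE
    }
    res
  })
  do.call(rbind, out)
}

#' Demultiplex a run down to wells
#'
#' Runs anchor location, position prediction and exact barcode calling on
#' every read.  A read is assigned iff all three barcode classes have a
#' position-consistent call; reads with any unassigned barcode are left in
#' the unassigned pool.  Assigned reads are re-oriented to the plus strand
#' of the construct.
#'
#' @param ccs a \code{\link{CCSSet-class}}.
#' @param manifest a \code{BarcodeManifest}.
#' @param max_mismatches maximum substitutions per anchor (default 3).
#' @param tolerance barcode position tolerance in nt (default 4).
#' Assigned reads are also trimmed to their insert -- the region between
#' the forward transposase anchor and the universal reverse primer -- so
#' that all downstream sequence comparisons score the biological insert
#' rather than the barcode/anchor scaffolding.  The original consensus
#' length stays available as \code{ccs_length} in the metadata.
#'
#' @return list with \code{ccs} (updated set: oriented, insert-trimmed
#'   sequences, well fields, status \code{demultiplexed} for assigned
#'   reads), \code{results} (per-read calls data.frame) and \code{ledger}
#'   (a \code{FilterLedger} with the assembled/demultiplexed split).
#' @export
demultiplexRun <- function(ccs, manifest, max_mismatches = 3, tolerance = 4) {
  stopifnot(is(ccs, "CCSSet"), is(manifest, "BarcodeManifest"))
  validObject(ccs)
  n <- length(ccs)
  seqs <- as.character(ccsSequences(ccs))
  res <- vector("list", n)
  oriented <- seqs
  for (i in seq_len(n)) {
    loc <- locateAnchors(seqs[[i]], manifest, max_mismatches)
    iv <- predictBarcodePositions(loc$anchors, nchar(loc$oriented))
    calls <- callBarcodes(loc$oriented, iv, manifest, tolerance)
    g <- function(cls, col) calls[calls$class == cls, col]
    assigned <- all(!is.na(calls$call)) && all(calls$position_consistent)
    res[[i]] <- data.frame(
      ccs_id = ccsId(ccs)[i],
      strand = loc$strand,
      n_anchors = sum(loc$anchors$found),
      plate_call = g("plate", "call"), row_call = g("row", "call"),
      column_call = g("column", "call"),
      plate_consistent = g("plate", "position_consistent"),
      row_consistent = g("row", "position_consistent"),
      column_consistent = g("column", "position_consistent"),
      assigned = assigned,
      stringsAsFactors = FALSE
    )
    if (assigned) {
      # trim to the insert: [fwd anchor end, univ primer start); fall back
      # to the layout's fixed offsets when an anchor is missing
      a <- loc$anchors
      L <- nchar(loc$oriented)
      fwd <- a[a$anchor == "fwd_transposase", ]
      univ <- a[a$anchor == "univ_reverse_primer", ]
      ins_start <- if (fwd$found) fwd$end else 22L
      ins_end <- if (univ$found) univ$start else L - 48L
      oriented[[i]] <- if (ins_end > ins_start) {
        substr(loc$oriented, ins_start + 1L, ins_end)
      } else {
        loc$oriented
      }
    }
  }
  res <- do.call(rbind, res)
  out <- ccs
  if (n > 0) {
    out@sequences <- Biostrings::DNAStringSet(setNames(oriented, ccsId(ccs)))
    ok <- res$assigned
    out@meta$plate[ok] <- res$plate_call[ok]
    out@meta$row[ok] <- res$row_call[ok]
    out@meta$column[ok] <- as.integer(res$column_call[ok])
    out@meta$strand[ok] <- res$strand[ok]
    out@meta$status[ok] <- "demultiplexed"
  }
  ledger <- filterLedger(
    assembled = n,
    demultiplexed = if (n > 0) sum(res$assigned) else 0L,
    non_demultiplexed = if (n > 0) sum(!res$assigned) else 0L
  )
  list(ccs = out, results = res, ledger = ledger)
}

#' Write per-well FASTA bins
#'
#' Writes the assigned reads of a demultiplexed set as one FASTA per well
#' under \code{dir/<plate>/<rowcolumn>.fasta}.
#'
#' @param ccs a demultiplexed \code{CCSSet}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeWellBins <- function(ccs, dir) {
  stopifnot(is(ccs, "CCSSet"))
  wells <- ccsWell(ccs)
  keep <- !is.na(wells)
  paths <- character(0)
  for (w in unique(wells[keep])) {
    sub <- ccs[which(wells == w)]
    pw <- parseWellId(w)
    d <- file.path(dir, pw$plate)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(d, sprintf("%s%02d.fasta", pw$row, pw$column))
    Biostrings::writeXStringSet(ccsSequences(sub), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
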