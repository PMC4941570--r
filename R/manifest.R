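# Barcode manifest: construction, validation, I/O.

.BASES <- c("A", "C", "G", "T")

# run expr under a private RNG stream without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

.random_seq <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# rejection-sample n barcodes of length len with pairwise Hamming >= min_d
.sample_barcodes <- function(n, len, min_d = 2, avoid = character()) {
  out <- character(0)
  tries <- 0
  while (length(out) < n) {
    cand <- .random_seq(len)
    ok <- all(vapply(
      c(out, avoid[nchar(avoid) == len]),
      function(x) .hamming(cand, x) >= min_d, logical(1)
    ))
    if (ok) out <- c(out, cand)
    if ((tries <- tries + 1) > 10000 * n) {
      stop("could not sample distance-checked barcodes")
    }
  }
  out
}

.default_controls <- function() {
  data.frame(
    row = c("H", "H", "H"),
    column = c(10L, 11L, 12L),
    role = c("positive", "negative", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Generate a distance-checked barcode manifest
#'
#' Creates a \code{\link{BarcodeManifest-class}} with randomly drawn but
#' distance-checked barcodes: plate barcodes of 9 nt, eight row and twelve
#' column barcodes of 8 nt, all pairwise Hamming distance >= 2 within their
#' class, and three constant anchors of 14/16/15 nt.  Generation is
#' deterministic under \code{seed} and does not disturb the caller's RNG.
#'
#' @param n_plates number of plates (default 5).
#' @param seed integer seed for barcode generation.
#' @return a valid \code{BarcodeManifest}.
#' @examples
#' m <- makeManifest(n_plates = 5)
#' expectedWellCount(m, 5)  # 480
#' @export
makeManifest <- function(n_plates = 5, seed = 101) {
  stopifnot(n_plates >= 1)
  .with_seed(seed, {
    anchors <- c(
      fwd_transposase = .random_seq(14),
      univ_reverse_primer = .random_seq(16),
      rev_transposase = .random_seq(15)
    )
    plates <- .sample_barcodes(n_plates, 9)
    names(plates) <- paste0("P", seq_len(n_plates))
    rows <- .sample_barcodes(8, 8)
    names(rows) <- LETTERS[1:8]
    cols <- .sample_barcodes(12, 8, avoid = rows)
    names(cols) <- as.character(1:12)
    new("BarcodeManifest",
      plates = plates, rows = rows, columns = cols,
      anchors = anchors, controls = .default_controls()
    )
  })
}

#' @rdname validateManifest
#' @export
setMethod("validateManifest", "BarcodeManifest", function(manifest) {
  v <- character()
  chk_len <- function(x, len, what) {
    bad <- nchar(x) != len
    if (any(bad)) {
      sprintf("%s barcode %s has length %d (expected %d)",
              what, names(x)[bad], nchar(x)[bad], len)
    } else character()
  }
  chk_alpha <- function(x, what) {
    bad <- grepl("[^ACGT]", x)
    if (any(bad)) sprintf("%s sequence %s is not plain DNA", what, names(x)[bad])
    else character()
  }
  chk_dist <- function(x, what) {
    out <- character()
    n <- length(x)
    if (n < 2) return(out)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (nchar(x[i]) != nchar(x[j])) next
      d <- .hamming(x[i], x[j])
      if (d == 0) {
        out <- c(out, sprintf("%s barcodes %s and %s are identical",
                              what, names(x)[i], names(x)[j]))
      } else if (d < 2) {
        out <- c(out, sprintf(
          "%s barcodes %s and %s are Hamming distance %d apart (< 2)",
          what, names(x)[i], names(x)[j], d
        ))
      }
    }
    out
  }
  v <- c(
    v,
    chk_len(manifest@plates, 9, "plate"),
    chk_len(manifest@rows, 8, "row"),
    chk_len(manifest@columns, 8, "column"),
    chk_alpha(manifest@plates, "plate"),
    chk_alpha(manifest@rows, "row"),
    chk_alpha(manifest@columns, "column"),
    chk_alpha(manifest@anchors, "anchor"),
    chk_dist(manifest@plates, "plate"),
    chk_dist(manifest@rows, "row"),
    chk_dist(manifest@columns, "column")
  )
  alens <- c(fwd_transposase = 14L, univ_reverse_primer = 16L,
             rev_transposase = 15L)
  if (!identical(sort(names(manifest@anchors)), sort(names(alens)))) {
    v <- c(v, "anchors must be named fwd_transposase, univ_reverse_primer, rev_transposase")
  } else {
    for (nm in names(alens)) {
      if (nchar(manifest@anchors[[nm]]) != alens[[nm]]) {
        v <- c(v, sprintf("anchor %s has length %d (expected %d)",
                          nm, nchar(manifest@anchors[[nm]]), alens[[nm]]))
      }
    }
  }
  if (!identical(names(manifest@rows), LETTERS[1:8])) {
    v <- c(v, "row barcodes must be named A..H")
  }
  if (!identical(names(manifest@columns), as.character(1:12))) {
    v <- c(v, "column barcodes must be named 1..12")
  }
  v
})

#' Expected number of wells in a run
#'
#' @param manifest a \code{BarcodeManifest}.
#' @param n_plates number of plates pooled in the run.
#' @return \code{n_plates * nrows * ncolumns} (96 wells per plate).
#' @examples
#' expectedWellCount(makeManifest(2), 5)  # 480
#' @export
expectedWellCount <- function(manifest, n_plates) {
  stopifnot(is(manifest, "BarcodeManifest"), n_plates >= 0)
  as.integer(n_plates) * length(manifest@rows) * length(manifest@columns)
}

#' Read / write a barcode manifest TSV
#'
#' The manifest TSV has a header and columns \code{class} (one of
#' \code{plate}, \code{row}, \code{column}, \code{anchor}, \code{control}),
#' \code{id} and \code{sequence}; for control rows \code{id} is the well
#' (e.g. \code{H10}) and \code{sequence} the role.
#'
#' @param path file path.
#' @return \code{readManifest} returns a \code{BarcodeManifest};
#'   \code{writeManifest} returns \code{path} invisibly.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("class", "id", "sequence")
  if (!all(need %in% colnames(tab))) {
    stop("manifest TSV must have columns class, id, sequence")
  }
  pick <- function(cls) {
    sub <- tab[tab$class == cls, ]
    setNames(toupper(sub$sequence), sub$id)
  }
  ctl <- tab[tab$class == "control", ]
  controls <- if (nrow(ctl) > 0) {
    data.frame(
      row = substr(ctl$id, 1, 1),
      column = as.integer(substring(ctl$id, 2)),
      role = ctl$sequence, stringsAsFactors = FALSE
    )
  } else {
    .default_controls()
  }
  m <- new("BarcodeManifest",
    plates = pick("plate"), rows = pick("row"), columns = pick("column"),
    anchors = pick("anchor"), controls = controls
  )
  m
}

#' @rdname readManifest
#' @param manifest a \code{BarcodeManifest}.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "BarcodeManifest"))
  rows <- rbind(
    data.frame(class = "plate", id = names(manifest@plates),
               sequence = unname(manifest@plates)),
    data.frame(class = "row", id = names(manifest@rows),
               sequence = unname(manifest@rows)),
    data.frame(class = "column", id = names(manifest@columns),
               sequence = unname(manifest@columns)),
    data.frame(class = "anchor", id = names(manifest@anchors),
               sequence = unname(manifest@anchors)),
    data.frame(class = "control",
               id = paste0(manifest@controls$row, manifest@controls$column),
               sequence = manifest@controls$role)
  )
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled default manifest
#'
#' Returns the manifest shipped with the package (5 plates, generated with
#' a fixed seed and distance-checked; the anchor and barcode sequences are
#' synthetic stand-ins of the documented lengths).
#'
#' @return a \code{BarcodeManifest}.
#' @export
defaultManifest <- function() {
  readManifest(system.file("extdata", "manifest.tsv", package = "cbcmux",
                           mustWork = TRUE))
}

#' @rdname BarcodeManifest-class
#' @param object a \code{BarcodeManifest}.
#' @export
setMethod("show", "BarcodeManifest", function(object) {
  cat(sprintf(
    "BarcodeManifest: %d plate, %d row, %d column barcodes; %d anchors\n",
    length(object@plates), length(object@rows), length(object@columns),
    length(object@anchors)
  ))
  cat(sprintf("  control wells: %s\n",
              paste0(object@controls$row, object@controls$column,
                     " (", object@controls$role, ")", collapse = ", ")))
})
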