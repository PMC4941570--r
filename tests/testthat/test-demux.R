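# Demultiplexer: anchor location, position prediction, exact barcode
# calling and run-level assignment guarantees.

demo_manifest <- function() makeManifest(n_plates = 2, seed = 77)

test_that("anchors are found on clean reads on either strand", {
  m <- demo_manifest()
  insert <- rand_seq(400, seed = 1)
  read <- make_construct(m, "P1", "C", 7, insert)
  loc <- locateAnchors(read, m)
  expect_equal(loc$strand, "plus")
  expect_true(all(loc$anchors$found))
  expect_true(all(loc$anchors$mismatches == 0))
  expect_equal(loc$anchors$start[loc$anchors$anchor == "fwd_transposase"], 8)

  rc <- locateAnchors(revcomp(read), m)
  expect_equal(rc$strand, "minus")
  expect_true(all(rc$anchors$found))
  expect_identical(rc$anchors, loc$anchors)  # same oriented coordinates
})

test_that("an anchor with four substitutions is reported missing", {
  m <- demo_manifest()
  anchors <- methods::slot(m, "anchors")
  read <- make_construct(m, "P1", "A", 1, rand_seq(400, seed = 2))
  bad_fwd <- plant_subs(anchors[["fwd_transposase"]], c(2, 5, 9, 12))
  read4 <- sub(anchors[["fwd_transposase"]], bad_fwd, read, fixed = TRUE)
  loc <- locateAnchors(read4, m)
  expect_false(loc$anchors$found[loc$anchors$anchor == "fwd_transposase"])
  # three substitutions stay within budget
  ok_fwd <- plant_subs(anchors[["fwd_transposase"]], c(2, 5, 9))
  read3 <- sub(anchors[["fwd_transposase"]], ok_fwd, read, fixed = TRUE)
  loc3 <- locateAnchors(read3, m)
  expect_true(loc3$anchors$found[loc3$anchors$anchor == "fwd_transposase"])
})

test_that("predicted barcode intervals abut their anchors", {
  m <- demo_manifest()
  read <- make_construct(m, "P2", "E", 11, rand_seq(400, seed = 3))
  loc <- locateAnchors(read, m)
  iv <- predictBarcodePositions(loc$anchors, nchar(read))
  a <- loc$anchors
  fwd <- a[a$anchor == "fwd_transposase", ]
  univ <- a[a$anchor == "univ_reverse_primer", ]
  rev <- a[a$anchor == "rev_transposase", ]
  expect_equal(iv$start[iv$class == "row"], fwd$start - 8)
  expect_equal(iv$start[iv$class == "plate"], univ$end)
  expect_equal(iv$start[iv$class == "column"], rev$end)
  expect_equal(iv$end[iv$class == "column"], nchar(read))

  # an insertion upstream of the anchors shifts predictions with them
  shifted <- paste0("GG", read)
  loc2 <- locateAnchors(shifted, m)
  iv2 <- predictBarcodePositions(loc2$anchors, nchar(shifted))
  expect_equal(iv2$start[iv2$class == "plate"],
               iv$start[iv$class == "plate"] + 2)

  # no anchors at all: everything unpredictable
  none <- loc$anchors
  none$found <- FALSE
  none$start <- NA_integer_
  none$end <- NA_integer_
  iv3 <- predictBarcodePositions(none, nchar(read))
  expect_true(all(is.na(iv3$start)))
})

test_that("barcode calls are exact and position-consistent", {
  m <- demo_manifest()
  read <- make_construct(m, "P1", "B", 4, rand_seq(400, seed = 4))
  loc <- locateAnchors(read, m)
  iv <- predictBarcodePositions(loc$anchors, nchar(read))
  calls <- callBarcodes(loc$oriented, iv, m)
  expect_identical(calls$call[calls$class == "plate"], "P1")
  expect_identical(calls$call[calls$class == "row"], "B")
  expect_identical(calls$call[calls$class == "column"], "4")
  expect_true(all(calls$position_consistent))

  # one substitution in a barcode kills the call (exact matching only)
  rows <- methods::slot(m, "rows")
  read1 <- sub(rows[["B"]], plant_subs(rows[["B"]], 3), read, fixed = TRUE)
  loc1 <- locateAnchors(read1, m)
  iv1 <- predictBarcodePositions(loc1$anchors, nchar(read1))
  calls1 <- callBarcodes(loc1$oriented, iv1, m)
  expect_true(is.na(calls1$call[calls1$class == "row"]))

  # the right barcode far from its predicted window is flagged inconsistent
  cols <- methods::slot(m, "columns")
  read2 <- paste0(substr(read, 1, 30), cols[["4"]], substr(read, 31, nchar(read)))
  # remove the true terminal column barcode so only the displaced copy exists
  read2 <- substr(read2, 1, nchar(read2) - 8)
  loc2 <- locateAnchors(read2, m)
  iv2 <- predictBarcodePositions(loc2$anchors, nchar(read2))
  calls2 <- callBarcodes(loc2$oriented, iv2, m)
  col_call <- calls2[calls2$class == "column", ]
  expect_false(col_call$position_consistent)
})

test_that("runs partition into assigned wells and an unassigned pool", {
  m <- demo_manifest()
  withr::with_seed(9, {
    reads <- character(0)
    wells <- character(0)
    i <- 0
    for (p in c("P1", "P2")) for (r in c("A", "D", "H")) for (co in c(1, 12)) {
      i <- i + 1
      construct <- make_construct(m, p, r, co, rand_seq(380))
      # half the reads on the minus strand
      reads[sprintf("rd%03d", i)] <-
        if (i %% 2 == 0) revcomp(construct) else construct
      wells[sprintf("rd%03d", i)] <- wellId(p, r, co)
    }
    # one junk read that cannot demultiplex
    reads["junk"] <- rand_seq(450)
    wells["junk"] <- NA
    x <- ccsSet(reads, setNames(nchar(reads) * 10, names(reads)))
    dm <- demultiplexRun(x, m)
    expect_equal(sum(dm$results$assigned) + sum(!dm$results$assigned),
                 length(reads))
    expect_false(dm$results$assigned[dm$results$ccs_id == "junk"])
    got <- ccsWell(dm$ccs)
    ok <- dm$results$assigned
    expect_identical(got[dm$results$ccs_id[ok]],
                     wells[dm$results$ccs_id[ok]])
    # strand detection matches how the read was emitted
    expect_identical(dm$results$strand[ok],
                     ifelse(seq_len(sum(ok)) %% 2 == 0, "minus", "plus"))
    led <- ledgerCounts(dm$ledger)
    expect_equal(led[["assembled"]],
                 led[["demultiplexed"]] + led[["non_demultiplexed"]])
    # assigned reads are trimmed to their insert
    first <- dm$results$ccs_id[ok][1]
    expect_equal(Biostrings::width(ccsSequences(dm$ccs)[first]), 380)
  })
})

test_that("assigned reads are never misassigned on simulated data", {
  sm <- smallRun()
  dm_results <- sm$res$demux
  truth <- sm$truth
  ok <- dm_results$assigned
  w <- truth[dm_results$ccs_id[ok], ]
  expect_equal(sum(dm_results$plate_call[ok] != w$plate |
                     dm_results$row_call[ok] != w$row |
                     as.integer(dm_results$column_call[ok]) != w$column), 0)
  # reads with an uncorrupted barcode set and no errors in barcodes may
  # drop out, but corrupted-barcode reads must never land in a well
  corrupted <- truth$ccs_id[truth$is_barcode_corrupted]
  expect_equal(sum(dm_results$assigned[dm_results$ccs_id %in% corrupted]), 0)
})

test_that("well bins are written per plate and well", {
  sm <- smallRun()
  dir <- withr::local_tempdir()
  paths <- writeWellBins(sm$res$ccs, dir)
  expect_gt(length(paths), 0)
  expect_true(all(file.exists(paths)))
  one <- Biostrings::readDNAStringSet(paths[1])
  expect_gt(length(one), 0)
})
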