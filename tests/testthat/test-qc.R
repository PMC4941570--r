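# QC cascade: length, chimera, nonspecific, reliability and coverage
# filters, with brute-force oracles for the chimera scorer.

qc_pool <- function() {
  if (!is.null(.fixture_env$qc_pool)) return(.fixture_env$qc_pool)
  .fixture_env$qc_pool <- buildReferencePool(smallSimConfig(seed = 57))
  .fixture_env$qc_pool
}

# a demultiplexed set from raw sequences
demux_set <- function(seqs, coverage = 12) {
  x <- ccsSet(seqs, setNames(nchar(seqs) * coverage, names(seqs)))
  as_demultiplexed(x)
}

test_that("length filter discards strictly above the cutoff", {
  seqs <- setNames(c(rand_seq(1600, seed = 1), rand_seq(1601, seed = 2),
                     rand_seq(1400, seed = 3)), c("a", "b", "c"))
  x <- demux_set(seqs)
  lf <- lengthFilter(x, 1600)
  expect_identical(lf$discard, "b")
  expect_identical(sort(lf$pass), c("a", "c"))
  expect_equal(unname(ccsStatus(lf$ccs)["b"]), "discarded_length")
  # idempotent
  lf2 <- lengthFilter(lf$ccs, 1600)
  expect_equal(lf2$n_discarded, 0)
})

test_that("length filter uses the original consensus length after trimming", {
  m <- makeManifest(2, seed = 3)
  insert <- rand_seq(1580, seed = 4)           # construct length 1650
  read <- make_construct(m, "P1", "A", 1, insert)
  x <- ccsSet(setNames(read, "big"), c(big = nchar(read) * 5))
  dm <- demultiplexRun(x, m)
  expect_true(dm$results$assigned)
  # the stored sequence is the trimmed insert, but the filter still sees
  # the over-long consensus
  expect_equal(unname(Biostrings::width(ccsSequences(dm$ccs))), 1580)
  lf <- lengthFilter(dm$ccs, 1600)
  expect_identical(lf$discard, "big")
})

test_that("bimeras are flagged with their parents and crossover", {
  pool <- qc_pool()
  lin <- pool$lineage
  seqs <- as.character(pool$sequences)
  # parents from different genera (mutual identity well below 90)
  g <- split(lin$taxon_id, lin$genus)
  g <- g[lengths(g) >= 2]
  pa <- g[[1]][1]; pb <- g[[2]][1]
  cx <- 180
  bimera <- paste0(substr(seqs[[pa]], 1, cx),
                   substr(seqs[[pb]], cx + 1, nchar(seqs[[pb]])))
  genuine <- seqs[[g[[3]][1]]]
  x <- demux_set(c(bim = bimera, real = genuine))
  cf <- chimeraFilter(x, pool$sequences)
  v <- cf$verdicts
  expect_true(v$is_chimera[v$ccs_id == "bim"])
  expect_false(v$is_chimera[v$ccs_id == "real"])
  expect_setequal(c(v$parent_a[v$ccs_id == "bim"],
                    v$parent_b[v$ccs_id == "bim"]), c(pa, pb))
  # crossover agrees with the brute-force oracle within 20 nt
  orc <- oracle_two_segment(bimera, seqs[c(pa, pb)])
  expect_lt(abs(v$crossover[v$ccs_id == "bim"] - orc$crossover), 20)
  expect_setequal(c(orc$parent_a, orc$parent_b), c(pa, pb))
  expect_equal(unname(ccsStatus(cf$ccs)["bim"]), "discarded_chimera")
})

test_that("reads identical to a reference are never chimeric", {
  pool <- qc_pool()
  seqs <- as.character(pool$sequences)
  x <- demux_set(setNames(seqs[1:4], paste0("r", 1:4)))
  cf <- chimeraFilter(x, pool$sequences)
  expect_false(any(cf$verdicts$is_chimera))
})

test_that("error-bearing genuine reads stay below the chimera gain", {
  pool <- qc_pool()
  seqs <- as.character(pool$sequences)
  withr::with_seed(66, {
    reads <- vapply(1:20, function(i) {
      s <- seqs[[sample(length(seqs), 1)]]
      plant_subs(s, sample(nchar(s), 9))  # ~2.3% errors on 400 nt
    }, "")
    names(reads) <- paste0("e", 1:20)
    cf <- chimeraFilter(demux_set(reads), pool$sequences)
    expect_equal(sum(cf$verdicts$is_chimera), 0)
  })
})

test_that("nonspecific reads are discarded below 75% identity", {
  pool <- qc_pool()
  seqs <- as.character(pool$sequences)
  off <- rand_seq(400, seed = 71)
  genuine <- plant_subs(seqs[[2]], seq(7, 390, by = 50))  # ~2% divergent
  x <- demux_set(c(off = off, real = genuine))
  nf <- nonspecificFilter(x, pool$sequences)
  expect_identical(nf$discard, "off")
  expect_identical(nf$pass, "real")
  expect_equal(unname(ccsStatus(nf$ccs)["off"]), "discarded_nonspecific")
})

test_that("the 75% floor is inclusive", {
  ref <- rand_seq(100, seed = 81)
  at75 <- plant_subs(ref, seq(2, 98, by = 4))      # 25 isolated subs
  below <- plant_subs(ref, c(seq(2, 98, by = 4), 100))  # 26 subs
  expect_equal(globalIdentity(at75, ref)$identity, 75)
  x <- demux_set(c(at = at75, under = below))
  nf <- nonspecificFilter(x, setNames(Biostrings::DNAStringSet(ref), "ref"))
  expect_identical(nf$pass, "at")
  expect_identical(nf$discard, "under")
})

test_that("reliability keeps db hits, then dataset hits, discards the rest", {
  pool <- qc_pool()
  seqs <- as.character(pool$sequences)
  withr::with_seed(91, {
    db_hit <- plant_subs(seqs[[1]], sample(400, 8))      # ~98% to db
    novel <- rand_seq(400)                               # not in db
    novel_a <- plant_subs(novel, sample(400, 5))         # ~98.8% mutual
    novel_b <- plant_subs(novel, sample(400, 5))
    lonely <- plant_subs(seqs[[3]], sample(400, 35))     # ~91%: below 97
    x <- demux_set(c(dbr = db_hit, na = novel_a, nb = novel_b,
                     lone = lonely))
    rf <- reliabilityFilter(x, pool$sequences)
    v <- rf$verdicts
    expect_equal(v$source[v$ccs_id == "dbr"], "database_hit")
    expect_equal(v$source[v$ccs_id == "na"], "dataset_hit")
    expect_equal(v$source[v$ccs_id == "nb"], "dataset_hit")
    expect_equal(v$source[v$ccs_id == "lone"], "none")
    expect_equal(unname(ccsStatus(rf$ccs)["lone"]), "error_prone")
    expect_equal(unname(ccsStatus(rf$ccs)["dbr"]), "usable")
    expect_equal(rf$n_db_hits + rf$n_dataset_hits + rf$n_error_prone, 4L)
    # a dataset hit implies no database hit existed at the threshold
    exhaust <- dbSearch(novel_a, pool$sequences, 97, prescreen = FALSE)
    expect_true(is.na(exhaust$hit_id))
    # idempotence: re-running leaves the partition unchanged
    rf2 <- reliabilityFilter(rf$ccs, pool$sequences)
    expect_equal(rf2$n_db_hits + rf2$n_dataset_hits, 0L)
    expect_identical(ccsStatus(rf2$ccs), ccsStatus(rf$ccs))
  })
})

test_that("coverage filter splits at 10x without touching statuses", {
  seqs <- setNames(vapply(1:3, function(i) rand_seq(400), ""),
                   c("c9", "c10", "c40"))
  x <- ccsSet(seqs, c(c9 = 400 * 9, c10 = 400 * 10, c40 = 400 * 40))
  x <- as_demultiplexed(x)
  cv <- coverageFilter(x)
  expect_setequal(cv$pass, c("c10", "c40"))
  expect_identical(cv$discard, "c9")
})

test_that("the full cascade passes a clean run untouched and balances", {
  cfg <- smallSimConfig(
    seed = 101,
    error_rate_by_class = c(low = 0, mid = 0, high = 0),
    chimera_fraction = 0, offtarget_fraction = 0,
    barcode_corruption_fraction = 0
  )
  run <- simulateRun(cfg)
  dm <- demultiplexRun(run$ccs, run$manifest)
  qc <- runQc(dm$ccs, run$pool$sequences)
  k <- ledgerCounts(qc$ledger)
  expect_equal(k[["over_length"]], 0L)
  expect_equal(k[["chimeric"]], 0L)
  expect_equal(k[["nonspecific"]], 0L)
  expect_equal(k[["error_prone"]], 0L)
  expect_equal(k[["usable_reliable"]], k[["demultiplexed"]])
  expect_length(ledgerCheck(qc$ledger), 0)
})

test_that("every db-hit read is retained by reliability regardless of coverage", {
  pool <- qc_pool()
  seqs <- as.character(pool$sequences)
  withr::with_seed(111, {
    reads <- vapply(1:12, function(i) {
      plant_subs(seqs[[sample(length(seqs), 1)]], sample(400, 6))
    }, "")
    names(reads) <- paste0("r", 1:12)
    covs <- setNames(nchar(reads) * rep(c(2, 5, 30), 4), names(reads))
    x <- as_demultiplexed(ccsSet(reads, covs))
    rf <- reliabilityFilter(x, pool$sequences)
    expect_true(all(rf$verdicts$source == "database_hit"))
    cv <- coverageFilter(x)
    # the coverage filter would have dropped the low-coverage ones
    expect_lt(cv$n_pass, length(reads))
  })
})
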