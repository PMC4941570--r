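# Synthetic-run generator: determinism, pool divergence structure, well
# assignment rules, and the emitted reads' statistical properties.

test_that("simulation is bit-reproducible under its seed", {
  cfg <- smallSimConfig(seed = 7)
  a <- simulateRun(cfg)
  b <- simulateRun(cfg)
  expect_identical(as.character(ccsSequences(a$ccs)),
                   as.character(ccsSequences(b$ccs)))
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$pool$sequences),
                   as.character(b$pool$sequences))
})

test_that("reference pool honors the within/between-genus divergence bands", {
  pool <- buildReferencePool(smallSimConfig(seed = 13))
  lin <- pool$lineage
  by_genus <- split(lin$taxon_id, lin$genus)
  sizes <- lengths(by_genus)
  expect_gte(sum(sizes >= 3), length(by_genus) - 1)  # all but the control
  seqs <- as.character(pool$sequences)
  withr::with_seed(5, {
    for (g in names(by_genus)) {
      ids <- by_genus[[g]]
      if (length(ids) < 2) next
      p <- sample(ids, 2)
      expect_gte(globalIdentity(seqs[[p[1]]], seqs[[p[2]]])$identity, 97)
    }
    for (i in 1:10) {
      gs <- sample(names(by_genus), 2)
      a <- sample(by_genus[[gs[1]]], 1)
      b <- sample(by_genus[[gs[2]]], 1)
      expect_lte(globalIdentity(seqs[[a]], seqs[[b]])$identity, 90)
    }
  })
})

test_that("well communities follow the size distribution and control rules", {
  cfg <- smallSimConfig(seed = 21)
  pool <- buildReferencePool(cfg)
  sk <- assignWellCommunities(cfg, pool)
  expect_equal(nrow(sk), 96)
  neg <- sk$role == "negative_control"
  expect_identical(paste0(sk$row[neg], sk$column[neg]), c("H11", "H12"))
  expect_true(all(sk$taxa[neg] == ""))
  pos <- sk$role == "positive_control"
  expect_identical(sk$taxa[pos], pool$control_taxon)
  sizes <- lengths(strsplit(sk$taxa[sk$role == "sample"], ","))
  expect_true(all(sizes >= 1))
  expect_gt(sum(sizes >= 2), 0)

  # forcing community size 1 makes every sample well monoclonal
  cfg1 <- smallSimConfig(seed = 22,
                         community_size_distribution = c("1" = 1.0))
  sk1 <- assignWellCommunities(cfg1, buildReferencePool(cfg1))
  expect_true(all(lengths(strsplit(sk1$taxa[sk1$role == "sample"], ",")) == 1))
})

test_that("negative controls emit no reads and truth matches the FASTA", {
  run <- smallRun()$run
  truth <- run$truth
  expect_equal(nrow(truth), length(run$ccs))
  expect_identical(sort(truth$ccs_id), sort(ccsId(run$ccs)))
  expect_false(any(truth$row == "H" & truth$column %in% c(11, 12)))
  # reads per well stay in the configured range
  per_well <- table(truth$well)
  rng <- smallRun()$config$reads_per_well_range
  expect_true(all(per_well >= rng[1] & per_well <= rng[2]))
  # chimera truth records carry two parents and a crossover
  ch <- truth[truth$is_chimera, ]
  if (nrow(ch) > 0) {
    expect_true(all(!is.na(ch$parent_a) & !is.na(ch$parent_b)))
    expect_true(all(ch$parent_a != ch$parent_b))
    expect_true(all(ch$crossover > 0))
  }
})

test_that("sidecar totals reproduce the true coverage exactly", {
  run <- smallRun()$run
  m <- ccsMeta(run$ccs)
  truth <- run$truth
  rownames(truth) <- truth$ccs_id
  recomputed <- computeCcsCoverage(m$subread_total_nt, m$ccs_length)
  expect_identical(as.integer(recomputed),
                   truth[ccsId(run$ccs), "true_coverage"])
})

test_that("a clean channel demultiplexes every read to its true well", {
  cfg <- smallSimConfig(
    seed = 31,
    error_rate_by_class = c(low = 0, mid = 0, high = 0),
    chimera_fraction = 0, offtarget_fraction = 0,
    barcode_corruption_fraction = 0
  )
  run <- simulateRun(cfg)
  dm <- demultiplexRun(run$ccs, run$manifest)
  expect_true(all(dm$results$assigned))
  truth <- run$truth
  rownames(truth) <- truth$ccs_id
  got <- ccsWell(dm$ccs)
  expect_identical(unname(got[truth$ccs_id]), truth$well)
})

test_that("realized injection rates match their configuration", {
  # a dedicated large draw (simulation only, no pipeline): chimera truth
  # fraction within 3 binomial SEs of the configured 12.3%
  cfg <- simulationConfig(seed = 404, n_plates = 5,
                          amplicon_length_range = c(380L, 420L),
                          reads_per_well_range = c(4L, 6L))
  run <- simulateRun(cfg)
  n <- nrow(run$truth)
  expect_gte(n, 2000)
  p <- mean(run$truth$is_chimera)
  se <- sqrt(0.123 * (1 - 0.123) / n)
  expect_lt(abs(p - 0.123), 3 * se)
  # coverage mix: high-coverage share near 74.7%
  ph <- mean(run$truth$true_coverage > 9)
  seh <- sqrt(0.747 * 0.253 / n)
  expect_lt(abs(ph - 0.747), 3 * seh)
})

test_that("emitted high-coverage reads carry the configured error rate", {
  sh <- sharedRun()
  truth <- sh$truth
  pool_chr <- as.character(sh$run$pool$sequences)
  hi <- truth[!truth$is_chimera & !truth$is_offtarget &
                truth$true_coverage > 9, ]
  hi <- hi[seq_len(min(250, nrow(hi))), ]
  seqs <- as.character(ccsSequences(sh$run$ccs))
  mm <- 0; cols <- 0
  for (i in seq_len(nrow(hi))) {
    s <- seqs[[hi$ccs_id[i]]]
    if (hi$emitted_strand[i] == "minus") s <- revcomp(s)
    r <- globalIdentity(s, pool_chr[[hi$taxon[i]]])
    mm <- mm + (r$columns - r$matches)
    cols <- cols + r$columns
  }
  est <- mm / cols
  expect_lt(abs(est - 0.003) / 0.003, 0.15)
})

test_that("simulation config validates its domains", {
  expect_error(smallSimConfig(chimera_fraction = 0.6,
                              offtarget_fraction = 0.2))
  expect_error(smallSimConfig(error_rate_by_class =
                                c(low = 0.2, mid = 0.007, high = 0.003)))
  expect_error(smallSimConfig(taxa_pool_size = 3))
  cfg <- smallSimConfig(seed = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSimulationConfig(cfg, path)
  cfg2 <- readSimulationConfig(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$error_rate_by_class, cfg$error_rate_by_class)
  expect_equal(cfg2$amplicon_length_range, cfg$amplicon_length_range)
})
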