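# Greedy centroid OTU clustering: fixed cases, a brute-force optimal
# partition oracle, and the collection-level re-clustering.

well_from_reads <- function(seqs, coverage) {
  x <- ccsSet(seqs, setNames(nchar(seqs) * coverage, names(seqs)))
  as_demultiplexed(x)
}

test_that("fixed clustering cases behave as defined", {
  tpl <- rand_seq(400, seed = 5)
  far <- plant_subs(tpl, seq(3, 390, by = 10))  # ~90% to tpl
  seqs <- setNames(c(tpl, tpl, tpl, far), paste0("r", 1:4))
  cl <- clusterWell(well_from_reads(seqs, c(30, 20, 10, 15)), well = "w")
  expect_equal(nrow(cl$otus), 2)
  expect_setequal(cl$otus$size, c(3L, 1L))
  expect_equal(sum(cl$otus$singleton), 1)

  # all reads mutually >= 97%: one OTU
  withr::with_seed(6, {
    close <- vapply(1:5, function(i) plant_subs(tpl, sample(400, 3)), "")
  })
  names(close) <- paste0("c", 1:5)
  cl1 <- clusterWell(well_from_reads(close, rep(12, 5)), well = "w")
  expect_equal(nrow(cl1$otus), 1)
  expect_equal(cl1$otus$size, 5L)

  # empty input
  empty <- clusterWell(cbcmux:::.empty_ccs_set())
  expect_equal(nrow(empty$otus), 0)
})

test_that("two well-separated templates recover the template partition", {
  withr::with_seed(8, {
    ta <- rand_seq(400)
    tb <- rand_seq(400)
    reads <- c(
      vapply(1:6, function(i) plant_subs(ta, sample(400, 2)), ""),
      vapply(1:4, function(i) plant_subs(tb, sample(400, 2)), "")
    )
    names(reads) <- paste0("r", 1:10)
    truth <- rep(c("A", "B"), c(6, 4))
    cl <- clusterWell(well_from_reads(reads, sample(2:40, 10, TRUE)),
                      well = "w")
    expect_equal(nrow(cl$otus), 2)
    got <- cl$membership$otu_id[match(names(reads), cl$membership$ccs_id)]
    expect_identical(canon_partition(names(reads), got),
                     canon_partition(names(reads), truth))
  })
})

test_that("greedy clustering matches the optimal partition on random wells", {
  withr::with_seed(99, {
    templates <- vapply(1:5, function(i) rand_seq(300), "")
    for (rep in 1:100) {
      n <- sample(3:10, 1)
      tidx <- sample(5, sample(1:3, 1), replace = FALSE)
      src <- sample(tidx, n, replace = TRUE)
      reads <- vapply(src, function(t) {
        plant_subs(templates[t], sample(300, sample(0:3, 1)))
      }, "")
      names(reads) <- sprintf("r%02d", 1:n)
      ccs <- well_from_reads(reads, sample(2:40, n, TRUE))
      cl <- clusterWell(ccs, well = "w")
      # pairwise similarity matrix for the oracle
      sim <- matrix(FALSE, n, n)
      for (i in 1:n) for (j in 1:n) {
        sim[i, j] <- globalIdentity(reads[[i]], reads[[j]])$identity >= 97
      }
      orc <- oracle_min_partition(sim)
      expect_equal(nrow(cl$otus), orc$k)
      got <- cl$membership$otu_id[match(names(reads), cl$membership$ccs_id)]
      expect_identical(canon_partition(names(reads), got),
                       canon_partition(names(reads), orc$assign))
      # membership validity: every member >= 97% to its centroid
      cent <- setNames(as.character(cl$centroids), names(cl$centroids))
      for (i in seq_len(n)) {
        expect_gte(globalIdentity(reads[[i]], cent[[got[i]]])$identity, 97)
      }
    }
  })
})

test_that("clustering is invariant to input order", {
  withr::with_seed(17, {
    tpl <- rand_seq(350)
    reads <- vapply(1:8, function(i) plant_subs(tpl, sample(350, sample(0:30, 1))), "")
    names(reads) <- paste0("r", 1:8)
    covs <- sample(2:40, 8)
    a <- clusterWell(well_from_reads(reads, covs), well = "w")
    perm <- sample(8)
    b <- clusterWell(well_from_reads(reads[perm], covs[perm]), well = "w")
    expect_identical(a$otus, b$otus)
    expect_identical(
      a$membership[order(a$membership$ccs_id), ],
      b$membership[order(b$membership$ccs_id), ],
      ignore_attr = TRUE
    )
  })
})

test_that("collection re-clustering links wells sharing a taxon", {
  tpl <- rand_seq(400, seed = 31)
  other <- rand_seq(400, seed = 32)
  mk <- function(well, seqs) {
    x <- ccsSet(seqs, setNames(nchar(seqs) * 20, names(seqs)))
    m <- ccsMeta(x)
    pw <- parseWellId(well)
    m$plate <- pw$plate; m$row <- pw$row; m$column <- pw$column
    m$status <- "usable"; m$strand <- "plus"
    m$reliability_source <- "database_hit"
    methods::slot(x, "meta") <- m
    x
  }
  x1 <- mk("P1:A01", setNames(c(tpl, tpl), c("a1", "a2")))
  x2 <- mk("P1:B02", setNames(c(tpl, other), c("b1", "b2")))
  combined <- new("CCSSet",
    sequences = c(ccsSequences(x1), ccsSequences(x2)),
    meta = rbind(ccsMeta(x1), ccsMeta(x2))
  )
  wot <- clusterWells(combined)
  expect_equal(nrow(wot$otus), 3)  # tpl in two wells + other
  cot <- reclusterCollection(wot)
  expect_equal(nrow(cot$otus), 2)
  shared <- cot$otus[cot$otus$n_wells == 2, ]
  expect_equal(shared$n_well_otus, 2L)
  expect_equal(shared$wells, "P1:A01,P1:B02")

  # fully distinct wells: collection OTUs equal well OTUs
  cot2 <- reclusterCollection(clusterWells(mk("P1:C03",
    setNames(c(tpl, other), c("c1", "c2")))))
  expect_equal(nrow(cot2$otus), 2)
  # empty input
  empty <- reclusterCollection(cbcmux:::.empty_clustering())
  expect_equal(nrow(empty$otus), 0)
})

test_that("well summaries count OTUs, singletons and coverage mixing", {
  tpl <- rand_seq(400, seed = 41)
  far <- plant_subs(tpl, seq(2, 390, by = 10))
  seqs <- setNames(c(tpl, tpl, tpl, far), paste0("r", 1:4))
  # three reads of the same template at mixed coverage + one singleton
  ccs <- well_from_reads(seqs, c(30, 9, 5, 9))
  cl <- clusterWell(ccs, well = "w")
  s <- otuWellSummary(cl)
  expect_equal(s$per_well$n_otus, 2)
  expect_equal(s$per_well$n_singletons, 1)
  expect_equal(s$n_mixed_coverage_otus, 1)
  expect_equal(s$n_singletons_low, 1)
  expect_equal(s$low_with_high_fraction, 2 / 3)

  empty <- otuWellSummary(cbcmux:::.empty_clustering())
  expect_equal(nrow(empty$per_well), 0)
  expect_true(is.na(empty$low_with_high_fraction))
})
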