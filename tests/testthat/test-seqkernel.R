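# Pairwise comparison primitives: identity definition, oligo scanning and
# database search, each checked against independent brute-force oracles.

test_that("identity definition behaves at its fixed points", {
  s <- rand_seq(1400, seed = 1)
  expect_equal(globalIdentity(s, s)$identity, 100)

  short <- rand_seq(100, seed = 2)
  one_sub <- plant_subs(short, 50)
  r <- globalIdentity(short, one_sub)
  expect_equal(r$identity, 99)
  expect_equal(r$matches, 99L)
  expect_equal(r$columns, 100L)

  # exact subsequence contained in its source: terminal overhangs of the
  # longer sequence are free
  expect_equal(globalIdentity(substr(s, 301, 550), s)$identity, 100)

  # unrelated full-length sequences sit near random background, far from
  # any decision threshold
  expect_lt(globalIdentity(s, rand_seq(1400, seed = 3))$identity, 65)
})

test_that("identity is symmetric and bounded by the shorter sequence", {
  withr::with_seed(11, {
    for (i in 1:25) {
      la <- sample(80:600, 1)
      a <- rand_seq(la)
      b <- if (i %% 2 == 0) {
        plant_subs(a, sample(la, sample(0:20, 1)))  # related pair
      } else {
        rand_seq(sample(80:600, 1))                 # unrelated pair
      }
      r1 <- globalIdentity(a, b)
      r2 <- globalIdentity(b, a)
      expect_identical(r1, r2)
      expect_gte(r1$columns, min(nchar(a), nchar(b)))
      expect_gte(r1$identity, 0)
      expect_lte(r1$identity, 100)
    }
  })
})

test_that("invalid sequences are rejected", {
  expect_error(globalIdentity("", "ACGT"), "non-empty")
  expect_error(globalIdentity("ACGT", "ACXT"), "alphabet")
  expect_error(oligoSearch("ACGT", "", 0), "non-empty")
})

test_that("oligo search finds planted oligos within the mismatch budget", {
  oligo <- rand_seq(16, seed = 21)
  query <- paste0(rand_seq(40, seed = 22), oligo, rand_seq(60, seed = 23))
  hits <- oligoSearch(query, oligo, 0)
  expect_equal(hits$start[1], 40)
  expect_equal(hits$end[1], 56)
  expect_equal(hits$mismatches[1], 0)
  expect_equal(hits$strand[1], "plus")

  # three substitutions tolerated at max_mismatches = 3, four are not
  m3 <- plant_subs(oligo, c(2, 7, 12))
  q3 <- paste0(rand_seq(30, seed = 24), m3, rand_seq(30, seed = 25))
  expect_true(any(oligoSearch(q3, oligo, 3)$mismatches == 3))
  m4 <- plant_subs(oligo, c(2, 7, 12, 15))
  q4 <- paste0(rand_seq(30, seed = 26), m4, rand_seq(30, seed = 27))
  expect_equal(nrow(oligoSearch(q4, oligo, 3)), 0)

  # oligo planted on the reverse strand
  qrc <- paste0(rand_seq(25, seed = 28), revcomp(oligo),
                rand_seq(25, seed = 29))
  hrc <- oligoSearch(qrc, oligo, 0)
  expect_equal(hrc$strand[1], "minus")
  expect_equal(hrc$start[1], 25)

  # oligo longer than the query: empty result, not an error
  expect_equal(nrow(oligoSearch(rand_seq(10, seed = 30),
                                rand_seq(14, seed = 31), 2)), 0)
})

test_that("oligo search equals a brute-force sliding-window scan", {
  brute <- function(query, oligo, mm) {
    k <- nchar(oligo)
    out <- list()
    for (strand in c("plus", "minus")) {
      o <- if (strand == "plus") oligo else revcomp(oligo)
      ov <- strsplit(o, "")[[1]]
      qv <- strsplit(query, "")[[1]]
      for (s in 0:(nchar(query) - k)) {
        d <- sum(qv[(s + 1):(s + k)] != ov)
        if (d <= mm) {
          out[[length(out) + 1]] <- data.frame(
            start = s, end = s + k, mismatches = d, strand = strand,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, out)
    if (is.null(out)) return(data.frame())
    out <- out[order(out$mismatches, out$start), ]
    rownames(out) <- NULL
    out
  }
  withr::with_seed(33, {
    for (i in 1:10) {
      query <- rand_seq(sample(100:400, 1))
      oligo <- rand_seq(sample(8:16, 1))
      mm <- sample(0:3, 1)
      got <- oligoSearch(query, oligo, mm)
      want <- brute(query, oligo, mm)
      if (nrow(want) == 0) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got, want)
      }
    }
  })
})

test_that("database search returns the best hit at or above threshold", {
  withr::with_seed(44, {
    db <- setNames(
      Biostrings::DNAStringSet(vapply(1:50, function(i) rand_seq(1400), "")),
      sprintf("ref%02d", 1:50)
    )
    # identical query hits its record at 100
    hit <- dbSearch(as.character(db[["ref07"]]), db, 97)
    expect_equal(hit$hit_id, "ref07")
    expect_equal(hit$identity, 100)
    expect_equal(hit$query_strand, "plus")

    # reverse-complemented query: same record, minus strand
    hrc <- dbSearch(revcomp(as.character(db[["ref07"]])), db, 97)
    expect_equal(hrc$hit_id, "ref07")
    expect_equal(hrc$query_strand, "minus")

    # a query at ~90% to its closest record misses a 97% threshold but
    # passes a 85% one
    q90 <- plant_subs(as.character(db[["ref03"]]), seq(5, 1400, by = 10))
    expect_true(is.na(dbSearch(q90, db, 97)$hit_id))
    expect_equal(dbSearch(q90, db, 85)$hit_id, "ref03")

    # random query: no hit at 97, confirmed by the exhaustive scan
    qr <- rand_seq(1400)
    expect_true(is.na(dbSearch(qr, db, 97)$hit_id))
    expect_true(is.na(dbSearch(qr, db, 97, prescreen = FALSE)$hit_id))
  })
  expect_error(dbSearch("ACGTACGT", Biostrings::DNAStringSet(), 97), "empty")
  expect_error(dbSearch("ACGTACGT", c(a = "ACGTACGT"), 0), "threshold")
})

test_that("the k-mer prescreen never changes the search result", {
  withr::with_seed(55, {
    db <- setNames(vapply(1:60, function(i) rand_seq(300), ""),
                   sprintf("r%02d", 1:60))
    # queries: mutated copies at various distances plus pure noise
    queries <- c(
      lapply(sample(60, 8), function(j) {
        plant_subs(db[[j]], sample(300, sample(c(2, 10, 25, 40), 1)))
      }),
      lapply(1:4, function(i) rand_seq(300))
    )
    for (thr in c(75, 90, 97)) {
      for (q in queries) {
        a <- dbSearch(q, db, thr, prescreen = TRUE)
        b <- dbSearch(q, db, thr, prescreen = FALSE)
        expect_identical(a, b)
      }
    }
  })
})

test_that("database search ties break by input order", {
  db <- c(dup1 = "ACGTACGTACGTACGTACGT", dup2 = "ACGTACGTACGTACGTACGT")
  hit <- dbSearch("ACGTACGTACGTACGTACGT", db, 97)
  expect_equal(hit$hit_id, "dup1")
})
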