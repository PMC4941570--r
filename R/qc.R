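# QC cascade after demultiplexing: over-length removal, two-parent chimera
# detection, nonspecific removal, and the reliability filter.  Filters act
# on the reads still in play (status demultiplexed -- unassigned reads
# never enter the cascade) and only ever move status forward, so each
# filter is idempotent.  Reads are expected in construct plus orientation
# (demultiplexRun orients them).

.active_idx <- function(ccs) {
  which(ccsMeta(ccs)$status == "demultiplexed")
}

.wells_recovered <- function(ccs, idx) {
  w <- ccsWell(ccs)[idx]
  length(unique(w[!is.na(w)]))
}

#' Over-length filter
#'
#' Discards reads whose original consensus length exceeds the expected
#' maximum amplicon size (strictly greater than \code{max_length});
#' over-long reads frequently represent chimeras or concatemers.  The
#' original length is used even after the demultiplexer has trimmed reads
#' to their insert.
#'
#' @param ccs a \code{\link{CCSSet-class}}.
#' @param max_length maximum length in nt (default 1600).
#' @return list with \code{ccs} (statuses updated), \code{pass} /
#'   \code{discard} (ccs ids) and \code{n_discarded}.
#' @export
lengthFilter <- function(ccs, max_length = 1600) {
  stopifnot(is(ccs, "CCSSet"))
  idx <- .active_idx(ccs)
  too_long <- idx[ccsMeta(ccs)$ccs_length[idx] > max_length]
  ids <- ccsId(ccs)
  if (length(too_long)) {
    ccs <- .advance_status(ccs, ids[too_long], "discarded_length")
  }
  list(
    ccs = ccs, pass = ids[setdiff(idx, too_long)],
    discard = ids[too_long], n_discarded = length(too_long)
  )
}

#' Two-parent chimera filter
#'
#' Flags reads whose best two-segment explanation (a prefix from one
#' reference and a suffix from another, joined at the best crossover)
#' beats their best single-reference explanation by at least
#' \code{gain_threshold} identity points and reaches
#' \code{min_identity}\%.  Identities here are query-anchored: matches over
#' query length, so the single- and two-segment scores are directly
#' comparable.  Candidate parents are shortlisted by shared k-mers.
#'
#' @param ccs a \code{CCSSet} (reads in plus orientation).
#' @param chimera_free_db named \code{DNAStringSet} of chimera-free
#'   references.
#' @param gain_threshold identity-point gain required to call a chimera
#'   (default 2.0).
#' @param min_identity minimum two-segment identity (default 97).
#' @param top_k candidate parents per read (default 5).
#' @return list with \code{ccs} (chimeras discarded), \code{verdicts}
#'   (data.frame \code{ccs_id}, \code{is_chimera}, \code{parent_a},
#'   \code{parent_b}, \code{crossover}, \code{chimera_score},
#'   \code{best_single_identity}, \code{best_two_segment_identity}),
#'   \code{pass}, \code{discard}, \code{n_discarded}.
#' @export
chimeraFilter <- function(ccs, chimera_free_db, gain_threshold = 2.0,
                          min_identity = 97, top_k = 5) {
  stopifnot(is(ccs, "CCSSet"))
  if (length(chimera_free_db) == 0) stop("chimera-free database is empty")
  ref_ids <- names(chimera_free_db)
  refs <- toupper(as.character(chimera_free_db))
  if (is.null(ref_ids)) ref_ids <- as.character(seq_along(refs))
  index <- kmerIndex(refs)
  idx <- .active_idx(ccs)
  ids <- ccsId(ccs)
  seqs <- as.character(ccsSequences(ccs))
  verdicts <- vector("list", length(idx))
  for (t in seq_along(idx)) {
    i <- idx[t]
    q <- seqs[[i]]
    v <- .chimera_verdict(q, refs, ref_ids, index, gain_threshold,
                          min_identity, top_k)
    v$ccs_id <- ids[i]
    verdicts[[t]] <- v
  }
  verdicts <- if (length(verdicts)) {
    do.call(rbind, lapply(verdicts, as.data.frame, stringsAsFactors = FALSE))
  } else {
    data.frame(
      is_chimera = logical(0), parent_a = character(0),
      parent_b = character(0), crossover = integer(0),
      chimera_score = numeric(0), best_single_identity = numeric(0),
      best_two_segment_identity = numeric(0), ccs_id = character(0)
    )
  }
  bad <- verdicts$ccs_id[verdicts$is_chimera]
  if (length(bad)) ccs <- .advance_status(ccs, bad, "discarded_chimera")
  list(
    ccs = ccs,
    verdicts = verdicts[, c("ccs_id", "is_chimera", "parent_a", "parent_b",
                            "crossover", "chimera_score",
                            "best_single_identity",
                            "best_two_segment_identity")],
    pass = setdiff(ids[idx], bad), discard = bad, n_discarded = length(bad)
  )
}

# candidate parents for the chimera scorer.  A bimera's minor parent can be
# crowded out of a whole-read k-mer ranking by the major parent's close
# relatives, so the shortlist unions the top references over the whole
# read, each half, and the two outer quarters (where a minor parent always
# dominates for crossovers in the middle 60%).
.chimera_candidates <- function(q, index, top_k) {
  Lq <- nchar(q)
  regions <- list(
    c(1L, Lq),
    c(1L, Lq %/% 2L), c(Lq %/% 2L + 1L, Lq),
    c(1L, Lq %/% 4L), c(3L * (Lq %/% 4L) + 1L, Lq)
  )
  take <- c(4L, 2L, 2L, 2L, 2L)
  cand <- integer(0)
  for (t in seq_along(regions)) {
    sub <- substr(q, regions[[t]][1], regions[[t]][2])
    if (nchar(sub) < index$k) next
    shared <- cpp_kmer_shared(sub, index$bits, index$k)
    top <- order(-shared)
    top <- top[shared[top] > 0]
    cand <- union(cand, utils::head(top, take[t]))
  }
  utils::head(cand, max(top_k, 8L))
}

# one read's chimera verdict against shortlisted references.  The read is
# expected to be trimmed to its insert (the demultiplexer removes the
# barcode/anchor scaffolding), so identities are query-anchored: matches
# from a global alignment over the query length, making the single- and
# two-segment scores directly comparable.
.chimera_verdict <- function(q, refs, ref_ids, index, gain_threshold,
                             min_identity, top_k) {
  nohit <- list(
    is_chimera = FALSE, parent_a = NA_character_, parent_b = NA_character_,
    crossover = NA_integer_, chimera_score = NA_real_,
    best_single_identity = NA_real_, best_two_segment_identity = NA_real_
  )
  cand <- .chimera_candidates(q, index, top_k)
  if (length(cand) == 0) return(nohit)
  Lcore <- nchar(q)
  pm <- list(); tot <- numeric(length(cand))
  for (j in seq_along(cand)) {
    r <- .align_prefix(q, refs[[cand[j]]])
    pm[[j]] <- r$prefix_matches
    tot[j] <- r$matches
  }
  I1 <- 100 * max(tot) / Lcore
  best2 <- -Inf; ba <- NA; bb <- NA; bc <- NA_integer_
  if (length(cand) >= 2) {
    for (ja in seq_along(cand)) for (jb in seq_along(cand)) {
      if (ja == jb) next
      sc <- pm[[ja]] + (tot[jb] - pm[[jb]])   # crossover after 0..Lq bases
      m <- max(sc)
      if (m > best2) {
        best2 <- m; ba <- ja; bb <- jb
        bc <- which.max(sc) - 1L               # leftmost best crossover
      }
    }
  }
  I2 <- if (is.finite(best2)) 100 * best2 / Lcore else NA_real_
  isc <- !is.na(I2) && (I2 - I1 >= gain_threshold) && I2 >= min_identity
  list(
    is_chimera = isc,
    parent_a = if (isc) ref_ids[cand[ba]] else NA_character_,
    parent_b = if (isc) ref_ids[cand[bb]] else NA_character_,
    crossover = if (isc) bc else NA_integer_,
    chimera_score = if (!is.na(I2)) I2 - I1 else NA_real_,
    best_single_identity = I1, best_two_segment_identity = I2
  )
}

#' Nonspecific-sequence filter
#'
#' Discards reads with no alignment to the curated database or identity
#' strictly below \code{min_identity}\% (off-target amplification
#' products).
#'
#' @param ccs a \code{CCSSet} (plus orientation).
#' @param curated_db named \code{DNAStringSet} of curated 16S references.
#' @param min_identity identity floor in percent (default 75; a read at
#'   exactly 75.0 passes).
#' @param strand strand(s) to try in the database search.
#' @return list with \code{ccs}, \code{pass}, \code{discard},
#'   \code{n_discarded}, and \code{identities} (best identity per read, NA
#'   for no alignment).
#' @export
nonspecificFilter <- function(ccs, curated_db, min_identity = 75,
                              strand = "plus") {
  stopifnot(is(ccs, "CCSSet"))
  if (length(curated_db) == 0) stop("curated database is empty")
  idx <- .active_idx(ccs)
  ids <- ccsId(ccs)
  seqs <- as.character(ccsSequences(ccs))
  index <- kmerIndex(curated_db)
  best <- rep(NA_real_, length(idx))
  for (t in seq_along(idx)) {
    # threshold at the floor itself: any hit >= min_identity is retained
    h <- dbSearch(seqs[[idx[t]]], curated_db, min_identity, strand = strand,
                  index = index, max_candidates = 6L, first_hit = TRUE)
    best[t] <- h$identity
  }
  fail <- is.na(best)
  bad <- ids[idx[fail]]
  if (length(bad)) ccs <- .advance_status(ccs, bad, "discarded_nonspecific")
  list(
    ccs = ccs, pass = ids[idx[!fail]], discard = bad,
    n_discarded = length(bad),
    identities = setNames(best, ids[idx])
  )
}

#' Reliability filter
#'
#' Retains a read if (1) it aligns at >= \code{threshold}\% identity to a
#' curated reference (source \code{database_hit}), or failing that (2) it
#' aligns at >= \code{threshold}\% to any other read in the dataset
#' (source \code{dataset_hit}; self-hits excluded).  Remaining reads are
#' error-prone and discarded.
#'
#' @param ccs a \code{CCSSet} of demultiplexed, pre-filtered reads (plus
#'   orientation).
#' @param curated_db named \code{DNAStringSet} of curated references.
#' @param threshold percent identity (default 97).
#' @param strand strand(s) to try.
#' @return list with \code{ccs} (statuses \code{usable} /
#'   \code{error_prone}, reliability sources set), \code{verdicts}
#'   (data.frame \code{ccs_id}, \code{reliable}, \code{source},
#'   \code{hit_id}, \code{hit_identity}), \code{usable}, \code{discard},
#'   and the three-way counts \code{n_db_hits}, \code{n_dataset_hits},
#'   \code{n_error_prone}.
#' @export
reliabilityFilter <- function(ccs, curated_db, threshold = 97,
                              strand = "plus") {
  stopifnot(is(ccs, "CCSSet"))
  if (length(curated_db) == 0) stop("curated database is empty")
  idx <- .active_idx(ccs)
  if (length(idx) == 0) {
    return(list(
      ccs = ccs,
      verdicts = data.frame(
        ccs_id = character(0), reliable = logical(0), source = character(0),
        hit_id = character(0), hit_identity = numeric(0),
        stringsAsFactors = FALSE
      ),
      usable = character(0), discard = character(0),
      n_db_hits = 0L, n_dataset_hits = 0L, n_error_prone = 0L
    ))
  }
  ids <- ccsId(ccs)
  seqs <- as.character(ccsSequences(ccs))
  db_index <- kmerIndex(curated_db)
  verdicts <- data.frame(
    ccs_id = ids[idx], reliable = FALSE, source = "none",
    hit_id = NA_character_, hit_identity = NA_real_,
    stringsAsFactors = FALSE
  )
  # stage 1: curated database
  for (t in seq_along(idx)) {
    h <- dbSearch(seqs[[idx[t]]], curated_db, threshold, strand = strand,
                  index = db_index, max_candidates = 6L, first_hit = TRUE)
    if (!is.na(h$hit_id)) {
      verdicts$reliable[t] <- TRUE
      verdicts$source[t] <- "database_hit"
      verdicts$hit_id[t] <- h$hit_id
      verdicts$hit_identity[t] <- h$identity
    }
  }
  # stage 2: the CCS dataset itself, self-hits excluded
  misses <- which(!verdicts$reliable)
  if (length(misses) > 0 && length(idx) > 1) {
    dataset <- setNames(seqs[idx], ids[idx])
    ds_index <- kmerIndex(dataset)
    for (t in misses) {
      h <- dbSearch(dataset[[t]], dataset, threshold, strand = strand,
                    index = ds_index, max_candidates = 8L,
                    exclude = ids[idx[t]], first_hit = TRUE)
      if (!is.na(h$hit_id)) {
        verdicts$reliable[t] <- TRUE
        verdicts$source[t] <- "dataset_hit"
        verdicts$hit_id[t] <- h$hit_id
        verdicts$hit_identity[t] <- h$identity
      }
    }
  }
  usable <- verdicts$ccs_id[verdicts$reliable]
  bad <- verdicts$ccs_id[!verdicts$reliable]
  if (length(usable)) {
    ccs <- .advance_status(ccs, usable, "usable")
    ccs@meta[usable, "reliability_source"] <-
      verdicts$source[verdicts$reliable]
  }
  if (length(bad)) ccs <- .advance_status(ccs, bad, "error_prone")
  list(
    ccs = ccs, verdicts = verdicts, usable = usable, discard = bad,
    n_db_hits = sum(verdicts$source == "database_hit"),
    n_dataset_hits = sum(verdicts$source == "dataset_hit"),
    n_error_prone = length(bad)
  )
}

#' Coverage filter (comparison only)
#'
#' Partition of the reads by the conventional coverage cutoff (pass iff
#' coverage >= \code{min_coverage}).  Reported for comparison with the
#' reliability filter; it does not change read status and is not part of
#' the default cascade.
#'
#' @param ccs a \code{CCSSet}.
#' @param min_coverage coverage cutoff (default 10).
#' @return list with \code{pass}, \code{discard} (ccs ids) over the active
#'   reads, and \code{n_pass}.
#' @export
coverageFilter <- function(ccs, min_coverage = 10) {
  stopifnot(is(ccs, "CCSSet"))
  idx <- .active_idx(ccs)
  cov <- ccsMeta(ccs)$coverage[idx]
  ids <- ccsId(ccs)
  list(
    pass = ids[idx[cov >= min_coverage]],
    discard = ids[idx[cov < min_coverage]],
    n_pass = sum(cov >= min_coverage)
  )
}

#' Run the full QC cascade
#'
#' Applies, in order: over-length removal, chimera removal, nonspecific
#' removal, then the reliability filter, and fills the corresponding
#' ledger rows (including the coverage-filter comparison counts).
#'
#' @param ccs a demultiplexed \code{CCSSet} (assigned reads in plus
#'   orientation; unassigned reads are ignored).
#' @param curated_db named \code{DNAStringSet} of curated references.
#' @param chimera_free_db chimera-free reference set (defaults to
#'   \code{curated_db}).
#' @param max_length over-length cutoff (default 1600).
#' @param chimera_gain chimera identity-gain threshold (default 2.0).
#' @param nonspecific_identity nonspecific identity floor (default 75).
#' @param reliability_threshold reliability identity threshold (default 97).
#' @param min_coverage coverage cutoff for the comparison counts
#'   (default 10).
#' @param strand strand(s) for database searches (default plus; reads are
#'   oriented by the demultiplexer).
#' @return list with \code{ccs} (final statuses), \code{ledger} (a
#'   \code{FilterLedger} with the QC rows filled), \code{chimera_verdicts},
#'   \code{reliability_verdicts}, \code{usable} (ccs ids).
#' @export
runQc <- function(ccs, curated_db, chimera_free_db = curated_db,
                  max_length = 1600, chimera_gain = 2.0,
                  nonspecific_identity = 75, reliability_threshold = 97,
                  min_coverage = 10, strand = "plus") {
  stopifnot(is(ccs, "CCSSet"))
  # only demultiplexed reads enter the cascade
  demux_idx <- which(ccsMeta(ccs)$status == "demultiplexed")
  n_demux <- length(demux_idx)

  lf <- lengthFilter(ccs, max_length)
  cf <- chimeraFilter(lf$ccs, chimera_free_db, gain_threshold = chimera_gain)
  nf <- nonspecificFilter(cf$ccs, curated_db,
                          min_identity = nonspecific_identity,
                          strand = strand)
  pre_idx <- which(ccsMeta(nf$ccs)$status == "demultiplexed")
  covf <- coverageFilter(nf$ccs, min_coverage)
  rf <- reliabilityFilter(nf$ccs, curated_db,
                          threshold = reliability_threshold, strand = strand)
  out <- rf$ccs
  usable_idx <- which(ccsMeta(out)$status == "usable")
  ledger <- filterLedger(
    demultiplexed = n_demux,
    over_length = lf$n_discarded,
    chimeric = cf$n_discarded,
    nonspecific = nf$n_discarded,
    usable_pre_filter = length(pre_idx),
    wells_recovered_pre = .wells_recovered(nf$ccs, pre_idx),
    usable_cov_ge10 = covf$n_pass,
    wells_recovered_cov = .wells_recovered(
      nf$ccs, which(ccsId(nf$ccs) %in% covf$pass)
    ),
    usable_reliable = length(rf$usable),
    reliable_db_hits = rf$n_db_hits,
    reliable_dataset_hits = rf$n_dataset_hits,
    error_prone = rf$n_error_prone,
    wells_recovered_reliable = .wells_recovered(out, usable_idx)
  )
  list(
    ccs = out, ledger = ledger, chimera_verdicts = cf$verdicts,
    reliability_verdicts = rf$verdicts, usable = rf$usable
  )
}

# merge: take b's non-NA counts over a's
.merge_ledger <- function(a, b) {
  ca <- ledgerCounts(a); cb <- ledgerCounts(b)
  ca[!is.na(cb)] <- cb[!is.na(cb)]
  new("FilterLedger", counts = ca)
}
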