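# Pairwise sequence comparison primitives shared by every downstream stage.
#
# One identity definition is used everywhere in the package: semi-global
# (overlap) alignment with free, unscored end gaps on both sequences;
# identity = 100 * matches / aligned columns, internal gap columns count as
# non-matches, N matches nothing.  Scoring is fixed at match +1, mismatch
# -2, gap open -4, gap extend -1.

.check_seq <- function(x, arg = "sequence") {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    stop(arg, " must be a single character string or DNAString")
  }
  if (nchar(x) == 0) stop(arg, " must be non-empty")
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    stop(arg, " contains characters outside the {A,C,G,T,N} alphabet")
  }
  x
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Global percent identity between two nucleotide sequences
#'
#' Aligns two sequences semi-globally: the shorter sequence is aligned
#' over its whole length and the longer sequence's end gaps are free and
#' excluded from the scored columns, so the scored columns always cover at
#' least the shorter sequence.  A short sequence fully contained in a
#' longer one at perfect match therefore scores identity 100, while
#' unrelated full-length pairs score near the random background.  Internal
#' gap columns count as non-match columns and \code{N} matches nothing.
#' The result is symmetric in its arguments.
#'
#' @param a,b nucleotide sequences (character, \code{DNAString}); alphabet
#'   \code{A,C,G,T,N}; must be non-empty.
#' @return list with elements \code{identity} (percent in [0, 100]),
#'   \code{matches}, \code{columns} and \code{query_strand} (always
#'   \code{"plus"}; strand handling lives in \code{\link{dbSearch}}).
#' @examples
#' globalIdentity("ACGTACGT", "ACGTACGT")$identity  # 100
#' globalIdentity("ACGT", "TTACGTTT")$identity      # 100 (contained)
#' @export
globalIdentity <- function(a, b) {
  a <- .check_seq(a, "a")
  b <- .check_seq(b, "b")
  # canonical argument order makes tie-broken alignments, and hence the
  # reported match counts, exactly symmetric
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  r <- cpp_align_overlap(a, b, FALSE)
  list(
    identity = r$identity, matches = r$matches, columns = r$columns,
    query_strand = "plus"
  )
}

# query-anchored variant used by the chimera scorer: global alignment
# (both sequences consumed, so the profile is defined along the whole
# query) returning the cumulative-match profile along the query
.align_prefix <- function(query, ref) {
  cpp_align_overlap(query, ref, TRUE, TRUE)
}

#' Search a short oligo in a query sequence with mismatches
#'
#' Ungapped scan of both strands for every occurrence of \code{oligo} with
#' at most \code{max_mismatches} substitutions.  Minus-strand hits are
#' occurrences of the reverse complement of the oligo; coordinates always
#' refer to the query as given, 0-based and half-open.
#'
#' @param query nucleotide sequence to scan.
#' @param oligo oligo of length 8--30 nt.
#' @param max_mismatches maximum number of substitutions (>= 0).
#' @return data.frame with columns \code{start}, \code{end} (0-based,
#'   half-open), \code{mismatches}, \code{strand}; sorted by mismatches then
#'   position.  Zero rows when the oligo is longer than the query or absent.
#' @examples
#' oligoSearch("AAACGTACGTACGTACGAAA", "ACGTACGTACGTACGA", 0)
#' @export
oligoSearch <- function(query, oligo, max_mismatches) {
  query <- .check_seq(query, "query")
  oligo <- .check_seq(oligo, "oligo")
  k <- nchar(oligo)
  if (k < 8 || k > 30) stop("oligo length must be in [8, 30]")
  if (!is.numeric(max_mismatches) || max_mismatches < 0) {
    stop("max_mismatches must be >= 0")
  }
  fwd <- cpp_oligo_scan(query, oligo, as.integer(max_mismatches))
  rev <- cpp_oligo_scan(query, .revcomp(oligo), as.integer(max_mismatches))
  out <- data.frame(
    start = c(fwd[, "start"], rev[, "start"]),
    mismatches = c(fwd[, "mismatches"], rev[, "mismatches"]),
    strand = rep(c("plus", "minus"), c(nrow(fwd), nrow(rev))),
    stringsAsFactors = FALSE
  )
  out$end <- out$start + k
  out <- out[order(out$mismatches, out$start), c("start", "end", "mismatches", "strand")]
  rownames(out) <- NULL
  out
}

#' Precompute a k-mer presence index for a sequence database
#'
#' Builds the per-sequence k-mer presence bitsets used by
#' \code{\link{dbSearch}} to shortlist candidate references before the exact
#' alignment.  Build the index once when many queries are searched against
#' the same database.
#'
#' @param db \code{DNAStringSet} or character vector of reference sequences.
#' @param k word size (default 8).
#' @return opaque index object to pass as \code{index=} to
#'   \code{\link{dbSearch}}.
#' @export
kmerIndex <- function(db, k = 8) {
  seqs <- toupper(as.character(db))
  structure(
    list(bits = cpp_kmer_index(seqs, as.integer(k)), k = as.integer(k),
         n = length(seqs)),
    class = "cbcmux_kmer_index"
  )
}

#' Best database hit for a query sequence
#'
#' Aligns the query against a reference database and returns the record of
#' maximal identity when that identity reaches the threshold, else a
#' no-hit.  Both strands of the query are tried by default.  Ties are broken
#' by database input order (then plus strand), so results are deterministic.
#' A k-mer prescreen shortlists candidates; it is validated against the
#' exhaustive scan and can be disabled with \code{prescreen = FALSE}.
#'
#' @param query nucleotide sequence.
#' @param db \code{DNAStringSet} (named) or named character vector of
#'   references; must be non-empty.
#' @param identity_threshold percent identity in (0, 100] a hit must reach.
#' @param strand \code{"both"} (default) or \code{"plus"}.
#' @param prescreen use the k-mer shortlist (default TRUE).
#' @param max_candidates number of shortlisted references per strand.
#' @param index optional prebuilt \code{\link{kmerIndex}} of \code{db}.
#' @param exclude character vector of reference ids to ignore (used by the
#'   reliability filter to exclude self-hits).
#' @param first_hit when TRUE, return the first shortlisted candidate
#'   reaching the threshold instead of the global best; used by filters
#'   where only retention at the threshold matters.  The default FALSE
#'   returns the maximal-identity record.
#' @return list with \code{hit_id}, \code{identity}, \code{matches},
#'   \code{columns}, \code{query_strand}; \code{hit_id} is \code{NA} on
#'   no-hit.
#' @export
dbSearch <- function(query, db, identity_threshold,
                     strand = c("both", "plus"),
                     prescreen = TRUE, max_candidates = 10L,
                     index = NULL, exclude = character(),
                     first_hit = FALSE) {
  strand <- match.arg(strand)
  query <- .check_seq(query, "query")
  if (length(db) == 0) stop("reference database is empty")
  if (!is.numeric(identity_threshold) ||
      identity_threshold <= 0 || identity_threshold > 100) {
    stop("identity_threshold must be in (0, 100]")
  }
  ids <- names(db)
  seqs <- toupper(as.character(db))
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  keep <- !(ids %in% exclude)

  strands <- if (strand == "both") c("plus", "minus") else "plus"
  nohit <- list(
    hit_id = NA_character_, identity = NA_real_, matches = NA_integer_,
    columns = NA_integer_, query_strand = NA_character_
  )

  best <- nohit
  best_rank <- Inf # db order of current best, for tie-breaks
  for (s in strands) {
    q <- if (s == "plus") query else .revcomp(query)
    if (prescreen) {
      if (is.null(index)) index <- kmerIndex(seqs)
      shared <- cpp_kmer_shared(q, index$bits, index$k)
      # lower bound on shared k-mers for a pair reaching the threshold:
      # at most lmin * (1 - t) edits, each destroying at most k words, off
      # the query's distinct word count; halved as a further safety
      # margin.  References below their bound cannot hold a qualifying
      # hit.
      lmin <- pmin(nchar(q), nchar(seqs))
      e <- floor(lmin * (1 - identity_threshold / 100))
      dq <- cpp_kmer_count(q, index$k)
      cutoff <- pmax(0, floor(0.5 * (pmin(dq, lmin - index$k + 1) -
                                       index$k * e)))
      cand <- order(-shared)                 # stable: ties keep db order
      cand <- cand[shared[cand] >= cutoff[cand] & keep[cand]]
      cand <- head(cand, max_candidates)
    } else {
      cand <- which(keep)
    }
    for (i in cand) {
      r <- cpp_align_overlap(q, seqs[i], FALSE)
      better <- is.na(best$identity) ||
        r$identity > best$identity + 1e-12 ||
        (abs(r$identity - best$identity) <= 1e-12 && i < best_rank)
      if (better) {
        best <- list(
          hit_id = ids[i], identity = r$identity, matches = r$matches,
          columns = r$columns, query_strand = s
        )
        best_rank <- i
      }
      if (first_hit && !is.na(best$identity) &&
          best$identity >= identity_threshold) {
        return(best)
      }
    }
  }
  if (is.na(best$identity) || best$identity < identity_threshold) {
    return(nohit)
  }
  best
}
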