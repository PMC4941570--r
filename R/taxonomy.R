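# Naive-Bayes k-mer taxonomy with bootstrap confidence.
#
# Word-presence (Bernoulli) model over k-mers with an RDP-style
# word-specific prior.  Genus word frequencies are size-normalized to a
# common pseudo-count S (the median genus training size) so that training
# imbalance between genera does not bias the unseen-word penalty; without
# this, the smallest genus mechanically wins every low-information query.

.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";")
  out <- lapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) != length(.TAX_RANKS)) {
      stop("lineage must have ", length(.TAX_RANKS), " ranks: ", paste(p, collapse = ";"))
    }
    sub("^[a-z]__", "", p)
  })
  m <- do.call(rbind, out)
  colnames(m) <- .TAX_RANKS
  as.data.frame(m, stringsAsFactors = FALSE)
}

#' Train the naive-Bayes taxonomy classifier
#'
#' Computes smoothed genus-conditional k-mer presence log-probabilities
#' from reference sequences with full lineages.
#'
#' @param references named \code{DNAStringSet} (or character vector) of
#'   training sequences.
#' @param lineage data.frame with columns \code{taxon_id} and
#'   \code{lineage} (six semicolon-separated ranks,
#'   \code{d__...;p__...;c__...;o__...;f__...;g__...}); every reference
#'   must be listed.
#' @param k word size (default 8).
#' @return classifier object (class \code{cbcmux_classifier}).
#' @export
trainClassifier <- function(references, lineage, k = 8) {
  if (!is(references, "DNAStringSet")) {
    references <- Biostrings::DNAStringSet(setNames(toupper(references),
                                                    names(references)))
  }
  ids <- names(references)
  if (is.null(ids)) stop("references must be named")
  if (!all(c("taxon_id", "lineage") %in% colnames(lineage))) {
    stop("lineage must have columns taxon_id, lineage")
  }
  missing <- setdiff(ids, lineage$taxon_id)
  if (length(missing) > 0) {
    stop("no lineage for: ", paste(head(missing), collapse = ", "))
  }
  ranks <- .parse_lineage(lineage$lineage[match(ids, lineage$taxon_id)])
  genera <- sort(unique(ranks$genus))
  if (length(genera) < 2) stop("training requires at least 2 genera")
  # one lineage per genus (first occurrence wins; conflicting upper ranks
  # within a genus are a training-data error)
  gl <- ranks[!duplicated(ranks$genus), , drop = FALSE]
  if (anyDuplicated(gl$genus)) gl <- gl[!duplicated(gl$genus), ]
  rownames(gl) <- gl$genus

  pres <- Biostrings::oligonucleotideFrequency(references, width = k) > 0
  n_total <- nrow(pres)
  prior <- (colSums(pres) + 0.5) / (n_total + 1)       # word-specific prior
  sizes <- table(ranks$genus)[genera]
  S <- stats::median(as.numeric(sizes))                # common pseudo-size
  logp <- matrix(NA_real_, nrow = ncol(pres), ncol = length(genera),
                 dimnames = list(NULL, genera))
  for (g in genera) {
    sel <- ranks$genus == g
    f <- colSums(pres[sel, , drop = FALSE]) / sum(sel) # word frequency
    logp[, g] <- log((f * S + prior) / (S + 1))
  }
  structure(
    list(k = as.integer(k), logp = logp, genera = genera,
         genus_lineage = gl[genera, .TAX_RANKS, drop = FALSE],
         n_training = n_total),
    class = "cbcmux_classifier"
  )
}

.query_words <- function(seq, k) {
  freq <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = k
  )
  which(freq > 0)
}

.unassigned_row <- function(id) {
  row <- data.frame(query_id = id, stringsAsFactors = FALSE)
  for (r in .TAX_RANKS) {
    row[[r]] <- NA_character_
    row[[paste0(r, "_confidence")]] <- 0
  }
  row$reported_genus <- NA_character_
  row
}

# classify one query; RNG already seeded by the caller
.classify_one <- function(id, seq, classifier, n_bootstrap,
                          confidence_threshold) {
  k <- classifier$k
  L <- nchar(seq)
  if (L < 8 * k) return(.unassigned_row(id))
  widx <- .query_words(seq, k)
  if (length(widx) == 0) return(.unassigned_row(id))
  lp <- classifier$logp[widx, , drop = FALSE]
  full <- colSums(lp)
  best <- which.max(full)              # ties: first genus alphabetically
  best_genus <- classifier$genera[best]

  nw <- max(1L, L %/% k)
  draws <- matrix(
    sample.int(length(widx), nw * n_bootstrap, replace = TRUE),
    nrow = nw
  )
  votes <- integer(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    votes[b] <- which.max(colSums(lp[draws[, b], , drop = FALSE]))
  }
  vote_genus <- classifier$genera[votes]
  lin <- classifier$genus_lineage
  full_lin <- lin[best_genus, ]
  row <- data.frame(query_id = id, stringsAsFactors = FALSE)
  for (r in .TAX_RANKS) {
    # share of bootstrap winners falling inside the full call's taxon at
    # this rank
    agree <- lin[vote_genus, r] == full_lin[[r]]
    row[[r]] <- full_lin[[r]]
    row[[paste0(r, "_confidence")]] <- mean(agree)
  }
  row$reported_genus <-
    if (row$genus_confidence > confidence_threshold) best_genus
    else NA_character_
  row
}

#' Classify sequences with bootstrap confidence
#'
#' Scores each query against every genus, then re-scores
#' \code{n_bootstrap} subsamples of \code{floor(L/k)} of its words (drawn
#' with replacement) and reports, per rank, the fraction of subsample
#' winners agreeing with the full-data call (votes for genera within the
#' same higher-rank taxon count as agreement at that rank).  The genus is
#' reported only when its confidence exceeds
#' \code{confidence_threshold}.  Queries shorter than \code{8 * k} nt are
#' returned unassigned with zero confidence.
#'
#' @param queries named \code{DNAStringSet} or named character vector.
#' @param classifier a trained \code{\link{trainClassifier}} object.
#' @param n_bootstrap number of bootstrap subsamples (default 100).
#' @param confidence_threshold genus-report rule (default 0.95, strict
#'   greater-than).
#' @param seed integer seed making the bootstrap bit-reproducible.
#' @return data.frame with one row per query: per-rank label and
#'   confidence columns plus \code{reported_genus} (NA when below the
#'   confidence rule).
#' @export
classifySequences <- function(queries, classifier, n_bootstrap = 100,
                              confidence_threshold = 0.95, seed = 1L) {
  stopifnot(inherits(classifier, "cbcmux_classifier"))
  seqs <- toupper(as.character(queries))
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  .with_seed(seed, {
    do.call(rbind, lapply(seq_along(seqs), function(i) {
      .classify_one(ids[i], seqs[[i]], classifier, n_bootstrap,
                    confidence_threshold)
    }))
  })
}

#' @rdname classifySequences
#' @param query a single sequence.
#' @export
classifySequence <- function(query, classifier, n_bootstrap = 100,
                             confidence_threshold = 0.95, seed = 1L) {
  classifySequences(setNames(as.character(query)[1], "query"), classifier,
                    n_bootstrap, confidence_threshold, seed)
}
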