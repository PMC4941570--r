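# Cross-referencing against a culture-independent community profile and
# recovery estimation.

#' Read a community profile TSV
#'
#' Expects a header with columns \code{profile_otu_id}, \code{sequence},
#' \code{compartment}, \code{relative_abundance}.  Abundances must be
#' non-negative and sum to at most 1 (plus a small tolerance) per
#' compartment.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readCommunityProfile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  prof <- read.delim(path, stringsAsFactors = FALSE)
  validateCommunityProfile(prof)
  prof
}

#' @rdname readCommunityProfile
#' @param profile a community-profile data.frame.
#' @export
validateCommunityProfile <- function(profile) {
  need <- c("profile_otu_id", "sequence", "compartment",
            "relative_abundance")
  if (!all(need %in% colnames(profile))) {
    stop("profile must have columns: ", paste(need, collapse = ", "))
  }
  if (any(profile$relative_abundance < 0)) {
    stop("relative abundances must be non-negative")
  }
  sums <- tapply(profile$relative_abundance, profile$compartment, sum)
  if (any(sums > 1 + 1e-6)) {
    stop("per-compartment abundances sum above 1: ",
         paste(names(sums)[sums > 1 + 1e-6], collapse = ", "))
  }
  if (anyDuplicated(profile$profile_otu_id)) {
    stop("profile_otu_id values must be unique")
  }
  invisible(profile)
}

#' Cross-reference a collection against a community profile
#'
#' Aligns every profile representative (typically a short V4 fragment)
#' against every collection sequence with the package's semi-global
#' identity -- the short fragment is scored over its own length inside the
#' longer sequence -- and records every pair at or above the identity
#' threshold.
#'
#' @param collection named \code{DNAStringSet} (or named character vector)
#'   of collection sequences (e.g. OTU centroids).
#' @param profile community-profile data.frame (see
#'   \code{\link{readCommunityProfile}}).
#' @param threshold percent identity (default 97).
#' @param strand strand(s) of the profile fragment to try (default both).
#' @param prescreen shortlist collection sequences by shared k-mers before
#'   aligning (default TRUE); the bound is conservative for the threshold.
#' @return hit table data.frame: \code{profile_otu_id},
#'   \code{collection_id}, \code{identity}.
#' @export
crossref <- function(collection, profile, threshold = 97,
                     strand = c("both", "plus"), prescreen = TRUE) {
  strand <- match.arg(strand)
  validateCommunityProfile(profile)
  if (nrow(profile) == 0) stop("profile is empty")
  ids <- names(collection)
  seqs <- toupper(as.character(collection))
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  index <- if (prescreen && length(seqs) > 0) kmerIndex(seqs) else NULL
  hits <- list()
  # distinct representative sequences may be shared across compartments;
  # align each once
  reps <- unique(profile$sequence)
  for (rep_seq in reps) {
    strands <- if (strand == "both") c(rep_seq, .revcomp(rep_seq)) else rep_seq
    strands <- toupper(strands)
    cand <- seq_along(seqs)
    if (!is.null(index)) {
      # conservative shared-kmer bound (see the clustering prescreen):
      # pairs below it cannot reach the identity threshold
      lmin <- nchar(rep_seq)
      e <- floor(lmin * (1 - threshold / 100))
      dq <- cpp_kmer_count(toupper(rep_seq), index$k)
      cutoff <- max(0, floor(0.5 * (dq - index$k * e)))
      shared <- rep(0L, length(seqs))
      for (q in strands) {
        shared <- pmax(shared, cpp_kmer_shared(q, index$bits, index$k))
      }
      cand <- which(shared >= cutoff)
    }
    for (j in cand) {
      best <- -Inf
      for (q in strands) {
        r <- cpp_align_overlap(q, seqs[[j]], FALSE)
        if (r$identity > best) best <- r$identity
      }
      if (best >= threshold) {
        pids <- profile$profile_otu_id[profile$sequence == rep_seq]
        hits[[length(hits) + 1L]] <- data.frame(
          profile_otu_id = pids, collection_id = ids[j], identity = best,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(profile_otu_id = character(0),
                      collection_id = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Recovery estimate per compartment
#'
#' Sums, per compartment, the relative abundance of profile OTUs that have
#' at least one hit in the collection; each profile OTU counts once no
#' matter how many collection sequences hit it.
#'
#' @param hits hit table from \code{\link{crossref}}.
#' @param profile community-profile data.frame.
#' @return data.frame with columns \code{compartment},
#'   \code{recovered_percent}, \code{n_hit_otus}, \code{n_profile_otus}.
#' @examples
#' prof <- data.frame(
#'   profile_otu_id = c("A", "B", "C"), sequence = c("ACGT", "AGGT", "ATTT"),
#'   compartment = "root", relative_abundance = c(0.30, 0.20, 0.50)
#' )
#' hits <- data.frame(profile_otu_id = c("A", "C"), collection_id = "x",
#'                    identity = 100)
#' recoveryEstimate(hits, prof)$recovered_percent  # 80
#' @export
recoveryEstimate <- function(hits, profile) {
  validateCommunityProfile(profile)
  hit_otus <- unique(hits$profile_otu_id)
  comps <- sort(unique(profile$compartment))
  out <- lapply(comps, function(comp) {
    sub <- profile[profile$compartment == comp, ]
    hit <- sub$profile_otu_id %in% hit_otus
    data.frame(
      compartment = comp,
      recovered_percent = 100 * sum(sub$relative_abundance[hit]),
      n_hit_otus = sum(hit),
      n_profile_otus = nrow(sub),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
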