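# Greedy centroid OTU clustering at 97% identity: per well, then a second
# collection-level pass over well centroids for redundancy assessment.

# greedy centroid pass over sequences in the given (already sorted) order;
# a sequence joins the first centroid (in founding order) at >= threshold
# identity, else founds a new OTU.  A shared-kmer screen skips centroid
# comparisons that provably cannot reach the threshold.
.greedy_cluster <- function(seqs, threshold) {
  n <- length(seqs)
  membership <- integer(n)
  centroids <- integer(0)
  lens <- nchar(seqs)
  k <- 8L
  bits <- if (n > 1) cpp_kmer_index(seqs, k) else NULL
  card <- if (n > 1) cpp_kmer_card(bits) else integer(0)
  # conservative shared-kmer lower bound for a pair at >= threshold
  # identity: each of the <= Lmin*(1-thr) edits destroys at most k of the
  # distinct words; halved as a further safety margin
  can_reach <- function(i, j) {
    lmin <- min(lens[i], lens[j])
    e <- floor(lmin * (1 - threshold / 100))
    cutoff <- max(0, floor(0.5 * (min(card[i], card[j]) - k * e)))
    cpp_kmer_shared_cols(bits, i, j) >= cutoff
  }
  for (i in seq_len(n)) {
    hit <- 0L
    for (j in seq_along(centroids)) {
      cj <- centroids[j]
      if (!is.null(bits) && !can_reach(i, cj)) next
      if (globalIdentity(seqs[[i]], seqs[[cj]])$identity >= threshold) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      hit <- length(centroids)
    }
    membership[i] <- hit
  }
  list(membership = membership, centroid_idx = centroids)
}

#' Cluster the usable reads of one well into OTUs
#'
#' Greedy centroid clustering at \code{threshold}\% identity.  Reads are
#' processed sorted by coverage descending (ties: length descending, then
#' id), so the clustering is a deterministic function of the read set
#' regardless of input order.  Every member is >= \code{threshold}\%
#' identical to its OTU centroid, and each new centroid was below the
#' threshold against all earlier centroids when founded.
#'
#' @param ccs a \code{\link{CCSSet-class}} whose reads belong to one well
#'   (typically the usable reads of that well).
#' @param threshold percent identity (default 97).
#' @param well label for the emitted OTU ids (defaults to the reads' well,
#'   or \code{"unplaced"}).
#' @return list with \code{otus} (data.frame \code{otu_id}, \code{well},
#'   \code{centroid_id}, \code{size}, \code{singleton},
#'   \code{n_low_coverage}, \code{n_high_coverage},
#'   \code{founder_coverage_class}), \code{membership} (data.frame
#'   \code{ccs_id}, \code{otu_id}) and \code{centroids} (named
#'   \code{DNAStringSet}).
#' @export
clusterWell <- function(ccs, threshold = 97, well = NULL) {
  stopifnot(is(ccs, "CCSSet"))
  if (length(ccs) == 0) return(.empty_clustering())
  wells <- unique(ccsWell(ccs))
  wells <- wells[!is.na(wells)]
  if (length(wells) > 1) stop("clusterWell expects reads from a single well")
  if (is.null(well)) well <- if (length(wells) == 1) wells else "unplaced"
  meta <- ccsMeta(ccs)
  ids <- ccsId(ccs)
  ord <- order(-meta$coverage, -Biostrings::width(ccsSequences(ccs)), ids)
  seqs <- as.character(ccsSequences(ccs))[ord]
  cl <- .greedy_cluster(seqs, threshold)
  otu_ids <- sprintf("%s|otu%02d", well, seq_along(cl$centroid_idx))
  covclass <- coverageClass(meta$coverage)[ord]
  otus <- data.frame(
    otu_id = otu_ids,
    well = well,
    centroid_id = ids[ord][cl$centroid_idx],
    size = as.integer(tabulate(cl$membership, length(cl$centroid_idx))),
    n_low_coverage = as.integer(
      vapply(seq_along(cl$centroid_idx),
             function(j) sum(cl$membership == j & covclass == "low"), 1L)
    ),
    n_high_coverage = as.integer(
      vapply(seq_along(cl$centroid_idx),
             function(j) sum(cl$membership == j & covclass == "high"), 1L)
    ),
    founder_coverage_class = covclass[cl$centroid_idx],
    stringsAsFactors = FALSE
  )
  otus$singleton <- otus$size == 1L
  list(
    otus = otus,
    membership = data.frame(
      ccs_id = ids[ord], otu_id = otu_ids[cl$membership],
      stringsAsFactors = FALSE
    ),
    centroids = setNames(
      Biostrings::DNAStringSet(seqs[cl$centroid_idx]), otu_ids
    )
  )
}

.empty_clustering <- function() {
  list(
    otus = data.frame(
      otu_id = character(0), well = character(0), centroid_id = character(0),
      size = integer(0), n_low_coverage = integer(0),
      n_high_coverage = integer(0), founder_coverage_class = character(0),
      singleton = logical(0), stringsAsFactors = FALSE
    ),
    membership = data.frame(ccs_id = character(0), otu_id = character(0),
                            stringsAsFactors = FALSE),
    centroids = Biostrings::DNAStringSet()
  )
}

#' Cluster every well of a run
#'
#' Applies \code{\link{clusterWell}} to the usable reads of each recovered
#' well and concatenates the results.
#'
#' @param ccs a \code{CCSSet} after QC (reads with status \code{usable} are
#'   clustered).
#' @param threshold percent identity (default 97).
#' @return combined list with \code{otus}, \code{membership},
#'   \code{centroids} as in \code{\link{clusterWell}}.
#' @export
clusterWells <- function(ccs, threshold = 97) {
  stopifnot(is(ccs, "CCSSet"))
  usable <- which(ccsMeta(ccs)$status == "usable")
  wells <- ccsWell(ccs)[usable]
  keep <- usable[!is.na(wells)]
  wells <- wells[!is.na(wells)]
  parts <- lapply(sort(unique(wells)), function(w) {
    clusterWell(ccs[keep[wells == w]], threshold = threshold, well = w)
  })
  if (length(parts) == 0) return(.empty_clustering())
  list(
    otus = do.call(rbind, lapply(parts, `[[`, "otus")),
    membership = do.call(rbind, lapply(parts, `[[`, "membership")),
    centroids = do.call(c, lapply(parts, `[[`, "centroids"))
  )
}

#' Re-cluster well OTUs at the collection level
#'
#' Runs the same greedy centroid pass over all well-OTU centroids, sorted
#' by OTU size descending (ties by otu id), to assess redundancy: which
#' wells carry the same organism.
#'
#' @param well_otus result of \code{\link{clusterWells}} (or
#'   \code{clusterWell}).
#' @param threshold percent identity (default 97).
#' @return list with \code{otus} (data.frame \code{collection_otu_id},
#'   \code{centroid_otu_id}, \code{n_well_otus}, \code{n_wells},
#'   \code{wells} comma-joined), \code{membership} (data.frame
#'   \code{otu_id}, \code{collection_otu_id}) and \code{centroids}.
#' @export
reclusterCollection <- function(well_otus, threshold = 97) {
  otus <- well_otus$otus
  if (nrow(otus) == 0) {
    return(list(
      otus = data.frame(
        collection_otu_id = character(0), centroid_otu_id = character(0),
        n_well_otus = integer(0), n_wells = integer(0), wells = character(0),
        stringsAsFactors = FALSE
      ),
      membership = data.frame(otu_id = character(0),
                              collection_otu_id = character(0),
                              stringsAsFactors = FALSE),
      centroids = Biostrings::DNAStringSet()
    ))
  }
  ord <- order(-otus$size, otus$otu_id)
  seqs <- as.character(well_otus$centroids[otus$otu_id[ord]])
  cl <- .greedy_cluster(seqs, threshold)
  coll_ids <- sprintf("cotu%03d", seq_along(cl$centroid_idx))
  member_wells <- split(otus$well[ord], cl$membership)
  out <- data.frame(
    collection_otu_id = coll_ids,
    centroid_otu_id = otus$otu_id[ord][cl$centroid_idx],
    n_well_otus = as.integer(tabulate(cl$membership,
                                      length(cl$centroid_idx))),
    n_wells = vapply(seq_along(cl$centroid_idx),
                     function(j) length(unique(member_wells[[as.character(j)]])),
                     1L),
    wells = vapply(seq_along(cl$centroid_idx), function(j) {
      paste(sort(unique(member_wells[[as.character(j)]])), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  list(
    otus = out,
    membership = data.frame(
      otu_id = otus$otu_id[ord],
      collection_otu_id = coll_ids[cl$membership],
      stringsAsFactors = FALSE
    ),
    centroids = setNames(Biostrings::DNAStringSet(seqs[cl$centroid_idx]),
                         coll_ids)
  )
}

#' Per-well OTU summary
#'
#' Summarizes a run's well OTUs: OTU and singleton counts per well,
#' singletons split by founding-read coverage class, and the low/high
#' coverage composition statistic (what fraction of low-coverage reads
#' cluster together with at least one high-coverage read).
#'
#' @param well_otus result of \code{\link{clusterWells}}.
#' @return list with \code{per_well} (data.frame \code{well},
#'   \code{n_otus}, \code{n_singletons}), \code{n_singletons_low},
#'   \code{n_singletons_high}, \code{n_mixed_coverage_otus}, and
#'   \code{low_with_high_fraction} (NA when no low-coverage reads exist).
#' @export
otuWellSummary <- function(well_otus) {
  otus <- well_otus$otus
  per_well <- if (nrow(otus) == 0) {
    data.frame(well = character(0), n_otus = integer(0),
               n_singletons = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- split(otus, otus$well)
    do.call(rbind, lapply(names(agg), function(w) {
      data.frame(well = w, n_otus = nrow(agg[[w]]),
                 n_singletons = sum(agg[[w]]$singleton),
                 stringsAsFactors = FALSE)
    }))
  }
  n_low_reads <- sum(otus$n_low_coverage)
  low_with_high <- sum(otus$n_low_coverage[otus$n_high_coverage > 0])
  list(
    per_well = per_well,
    n_singletons_low = sum(otus$singleton &
                             otus$founder_coverage_class == "low"),
    n_singletons_high = sum(otus$singleton &
                              otus$founder_coverage_class == "high"),
    n_mixed_coverage_otus = sum(otus$n_low_coverage > 0 &
                                  otus$n_high_coverage > 0),
    low_with_high_fraction =
      if (n_low_reads > 0) low_with_high / n_low_reads else NA_real_
  )
}
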