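# End-to-end pipeline: demultiplex -> QC -> cluster -> classify ->
# crossref, with Table-style ledger reporting.  annotateRun() works on
# in-memory objects; runPipeline() wraps it with file I/O from a
# serializable configuration.

#' Annotate a run (in-memory pipeline)
#'
#' Runs the full annotation chain on objects: demultiplexing, the QC
#' cascade, per-well and collection-level OTU clustering, taxonomy on the
#' well-OTU centroids and, when a profile is given, cross-referencing with
#' the recovery estimate.
#'
#' @param ccs a \code{\link{CCSSet-class}} of raw reads.
#' @param manifest a \code{\link{BarcodeManifest-class}}.
#' @param curated_db named \code{DNAStringSet} of curated references.
#' @param lineage lineage data.frame for \code{curated_db} (columns
#'   \code{taxon_id}, \code{lineage}); NULL skips taxonomy.
#' @param chimera_free_db chimera-free reference set (defaults to
#'   \code{curated_db}).
#' @param profile optional community-profile data.frame; enables the
#'   recovery stage.
#' @param params named list of threshold overrides; see
#'   \code{\link{pipelineParams}}.
#' @param seed seed for the taxonomy bootstrap.
#' @param verbose log one line per stage to standard error.
#' @return list with \code{ccs}, \code{demux}, \code{qc}, \code{ledger},
#'   \code{well_otus}, \code{collection_otus}, \code{taxonomy},
#'   \code{recovery_hits}, \code{recovery}.
#' @export
annotateRun <- function(ccs, manifest, curated_db, lineage = NULL,
                        chimera_free_db = curated_db, profile = NULL,
                        params = pipelineParams(), seed = 1L,
                        verbose = FALSE) {
  stopifnot(is(ccs, "CCSSet"), is(manifest, "BarcodeManifest"))
  log1 <- function(label, n) {
    if (verbose) message(sprintf("[cbcmux] %-55s %d", label, n))
  }
  t0 <- Sys.time()

  dm <- demultiplexRun(ccs, manifest,
                       max_mismatches = params$anchor_max_mismatches,
                       tolerance = params$barcode_tolerance)
  log1("Demultiplexed CCSs", sum(dm$results$assigned))

  qc <- runQc(dm$ccs, curated_db, chimera_free_db,
              max_length = params$max_length,
              chimera_gain = params$chimera_gain,
              nonspecific_identity = params$nonspecific_identity,
              reliability_threshold = params$reliability_threshold,
              min_coverage = params$min_coverage,
              strand = params$db_strand)
  ledger <- .merge_ledger(dm$ledger, qc$ledger)
  log1("Usable CCSs after filtering by reliability",
       ledgerCounts(ledger)[["usable_reliable"]])

  wot <- clusterWells(qc$ccs, threshold = params$otu_threshold)
  log1("Well OTUs", nrow(wot$otus))
  cot <- reclusterCollection(wot, threshold = params$otu_threshold)
  log1("Collection OTUs", nrow(cot$otus))

  tax <- NULL
  if (!is.null(lineage) && nrow(wot$otus) > 0) {
    clf <- trainClassifier(curated_db, lineage, k = params$classifier_k)
    tax <- classifySequences(wot$centroids, clf,
                             n_bootstrap = params$n_bootstrap,
                             confidence_threshold = params$confidence_threshold,
                             seed = seed)
    log1("OTUs with reported genus", sum(!is.na(tax$reported_genus)))
  }

  hits <- NULL; rec <- NULL
  if (!is.null(profile) && nrow(wot$otus) > 0) {
    hits <- crossref(wot$centroids, profile,
                     threshold = params$crossref_threshold,
                     strand = params$crossref_strand)
    rec <- recoveryEstimate(hits, profile)
    log1("Profile OTUs recovered", length(unique(hits$profile_otu_id)))
  }
  if (verbose) {
    message(sprintf("[cbcmux] pipeline finished in %.1f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  list(
    ccs = qc$ccs, demux = dm$results, qc = qc, ledger = ledger,
    well_otus = wot, collection_otus = cot, taxonomy = tax,
    recovery_hits = hits, recovery = rec
  )
}

#' Pipeline threshold parameters
#'
#' All tunable thresholds of the pipeline with their defaults: anchor
#' mismatch budget 3, barcode position tolerance 4 nt, over-length cutoff
#' 1600 nt, chimera gain 2.0 identity points, nonspecific floor 75\%,
#' reliability and OTU and cross-reference thresholds 97\%, comparison
#' coverage cutoff 10x, classifier word size 8 with 100 bootstraps and the
#' 0.95 genus-report rule.
#'
#' @param ... overrides of the defaults listed above.
#' @return named list of parameters.
#' @export
pipelineParams <- function(...) {
  p <- list(
    anchor_max_mismatches = 3L,
    barcode_tolerance = 4L,
    max_length = 1600L,
    chimera_gain = 2.0,
    nonspecific_identity = 75,
    reliability_threshold = 97,
    min_coverage = 10L,
    otu_threshold = 97,
    classifier_k = 8L,
    n_bootstrap = 100L,
    confidence_threshold = 0.95,
    crossref_threshold = 97,
    db_strand = "plus",
    crossref_strand = "both"
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0) {
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(ov)] <- ov
  p
}

#' File-based pipeline configuration
#'
#' Collects the input paths, output directory and thresholds of a run into
#' one serializable list, so a run is fully reproducible from its
#' configuration.
#'
#' @param ccs_fasta,subreads_tsv CCS input: FASTA plus subread sidecar.
#' @param manifest_tsv barcode manifest TSV.
#' @param references_fasta curated reference database FASTA.
#' @param lineages_tsv lineage TSV for the references (optional).
#' @param chimera_db_fasta chimera-free reference FASTA (defaults to
#'   \code{references_fasta}).
#' @param profile_tsv community profile TSV (optional).
#' @param outdir output directory.
#' @param seed integer seed.
#' @param params threshold overrides, as \code{\link{pipelineParams}}.
#' @return configuration list (class \code{cbcmux_pipeline_config}).
#' @export
pipelineConfig <- function(ccs_fasta, subreads_tsv, manifest_tsv,
                           references_fasta, lineages_tsv = NULL,
                           chimera_db_fasta = NULL, profile_tsv = NULL,
                           outdir = "cbcmux_out", seed = 1L,
                           params = pipelineParams()) {
  structure(
    list(
      ccs_fasta = ccs_fasta, subreads_tsv = subreads_tsv,
      manifest_tsv = manifest_tsv, references_fasta = references_fasta,
      lineages_tsv = lineages_tsv, chimera_db_fasta = chimera_db_fasta,
      profile_tsv = profile_tsv, outdir = outdir, seed = as.integer(seed),
      params = params
    ),
    class = "cbcmux_pipeline_config"
  )
}

#' Run the file-based pipeline
#'
#' Reads all inputs named in the configuration, runs
#' \code{\link{annotateRun}}, and writes \code{demux.tsv},
#' \code{ledger.tsv} (qc report), \code{otus_well.tsv},
#' \code{otus_collection.tsv}, \code{centroids_well.fasta},
#' \code{centroids_collection.fasta}, \code{taxonomy.tsv},
#' \code{hits.tsv}, \code{recovery.tsv} and a \code{config.yaml} snapshot
#' under the configured output directory.  Missing input files fail fast
#' with the offending path; an invalid manifest fails with its violation
#' list.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose log per-stage counts to standard error (default TRUE).
#' @return the \code{\link{annotateRun}} result list, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "cbcmux_pipeline_config"))
  needed <- c(config$ccs_fasta, config$subreads_tsv, config$manifest_tsv,
              config$references_fasta, config$lineages_tsv,
              config$chimera_db_fasta, config$profile_tsv)
  for (p in needed) if (!is.null(p) && !file.exists(p)) {
    stop("input file not found: ", p)
  }
  manifest <- readManifest(config$manifest_tsv)
  viol <- validateManifest(manifest)
  if (length(viol) > 0) {
    stop("invalid manifest:\n  ", paste(viol, collapse = "\n  "))
  }
  ccs <- readCcsSet(config$ccs_fasta, config$subreads_tsv)
  curated <- Biostrings::readDNAStringSet(config$references_fasta)
  names(curated) <- sub("\\s.*$", "", names(curated))
  chim <- if (is.null(config$chimera_db_fasta)) curated else {
    x <- Biostrings::readDNAStringSet(config$chimera_db_fasta)
    names(x) <- sub("\\s.*$", "", names(x))
    x
  }
  lineage <- if (is.null(config$lineages_tsv)) NULL else {
    read.delim(config$lineages_tsv, stringsAsFactors = FALSE)
  }
  profile <- if (is.null(config$profile_tsv)) NULL else {
    readCommunityProfile(config$profile_tsv)
  }

  res <- annotateRun(ccs, manifest, curated, lineage = lineage,
                     chimera_free_db = chim, profile = profile,
                     params = config$params, seed = config$seed,
                     verbose = verbose)

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, name) {
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wtsv(res$demux, "demux.tsv")
  ledgerReport(res$ledger, file.path(outdir, "ledger.tsv"))
  wtsv(res$well_otus$otus, "otus_well.tsv")
  wtsv(res$well_otus$membership, "otu_membership.tsv")
  wtsv(res$collection_otus$otus, "otus_collection.tsv")
  if (length(res$well_otus$centroids) > 0) {
    Biostrings::writeXStringSet(res$well_otus$centroids,
                                file.path(outdir, "centroids_well.fasta"))
  }
  if (length(res$collection_otus$centroids) > 0) {
    Biostrings::writeXStringSet(
      res$collection_otus$centroids,
      file.path(outdir, "centroids_collection.fasta")
    )
  }
  if (!is.null(res$taxonomy)) wtsv(res$taxonomy, "taxonomy.tsv")
  if (!is.null(res$recovery)) {
    wtsv(res$recovery_hits, "hits.tsv")
    wtsv(res$recovery, "recovery.tsv")
  }
  snap <- config
  snap$params <- NULL
  yaml::write_yaml(
    c(unclass(snap)[!vapply(unclass(snap), is.null, TRUE)],
      list(params = config$params)),
    file.path(outdir, "config.yaml")
  )
  invisible(res)
}
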