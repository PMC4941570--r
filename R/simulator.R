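# Synthetic-run generator: emits CCS sequences, the subread sidecar and a
# per-read ground-truth table with the statistical structure the pipeline
# assumes (multiplexed construct layout, coverage-dependent error classes,
# chimeras, off-target inserts, corrupted barcodes, control wells).

#' Simulation configuration
#'
#' Builds and validates the configuration of a synthetic run.  The defaults
#' encode the study conditions the pipeline is designed for: five pooled
#' 96-well plates, near-full-length inserts, per-base error rates of 2.3\%
#' below 5x coverage, 0.7\% at 5--9x and 0.3\% above 9x, a 12.3\% chimera
#' and 0.14\% off-target injection rate, and a coverage mix in which 74.7\%
#' of reads exceed 9x coverage.
#'
#' @param seed integer; single global seed, all draws derive from it.
#' @param n_plates number of pooled plates.
#' @param taxa_pool_size number of reference taxa to simulate (>= 6).
#' @param amplicon_length_range integer [min, max] insert length in nt.
#' @param community_size_distribution named probability vector over well
#'   community sizes \code{1..max_members}.
#' @param coverage_distribution named probability vector over integer
#'   coverages \code{2..40}.
#' @param error_rate_by_class named numeric \code{c(low=, mid=, high=)}:
#'   per-base error rate for coverage < 5, 5--9 and > 9.  Each in [0, 0.1].
#' @param chimera_fraction probability a read's insert is a two-parent
#'   bimera.
#' @param offtarget_fraction probability a read carries a random non-16S
#'   insert.
#' @param barcode_corruption_fraction probability one barcode of a read is
#'   mutated at one position.
#' @param reads_per_well_range integer [min, max] reads emitted per
#'   occupied well.
#' @return validated list of class \code{cbcmux_sim_config}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_plates = 5L,
                             taxa_pool_size = 40L,
                             amplicon_length_range = c(1350L, 1450L),
                             community_size_distribution =
                               c("1" = 0.45, "2" = 0.30, "3" = 0.15, "4" = 0.10),
                             coverage_distribution = NULL,
                             error_rate_by_class =
                               c(low = 0.023, mid = 0.007, high = 0.003),
                             chimera_fraction = 0.123,
                             offtarget_fraction = 0.0014,
                             barcode_corruption_fraction = 0.05,
                             reads_per_well_range = c(2L, 6L)) {
  if (is.null(coverage_distribution)) {
    # 74.7% of reads above 9x coverage; remainder split over the two
    # low-accuracy classes
    coverage_distribution <- c(
      setNames(rep(0.100 / 3, 3), 2:4),
      setNames(rep(0.153 / 5, 5), 5:9),
      setNames(rep(0.747 / 31, 31), 10:40)
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    n_plates = as.integer(n_plates),
    taxa_pool_size = as.integer(taxa_pool_size),
    amplicon_length_range = as.integer(amplicon_length_range),
    community_size_distribution = community_size_distribution,
    coverage_distribution = coverage_distribution,
    error_rate_by_class = error_rate_by_class,
    chimera_fraction = chimera_fraction,
    offtarget_fraction = offtarget_fraction,
    barcode_corruption_fraction = barcode_corruption_fraction,
    reads_per_well_range = as.integer(reads_per_well_range)
  )
  class(cfg) <- "cbcmux_sim_config"
  validateSimulationConfig(cfg)
  cfg
}

#' @rdname simulationConfig
#' @param config a simulation configuration.
#' @export
validateSimulationConfig <- function(config) {
  with(config, {
    stopifnot(
      n_plates >= 1,
      taxa_pool_size >= 6,
      length(amplicon_length_range) == 2,
      amplicon_length_range[1] <= amplicon_length_range[2],
      amplicon_length_range[1] >= 100,
      abs(sum(community_size_distribution) - 1) < 1e-6,
      all(community_size_distribution >= 0),
      abs(sum(coverage_distribution) - 1) < 1e-6,
      all(as.integer(names(coverage_distribution)) >= 2),
      all(as.integer(names(coverage_distribution)) <= 40),
      identical(sort(names(error_rate_by_class)), c("high", "low", "mid")),
      all(error_rate_by_class >= 0), all(error_rate_by_class <= 0.1),
      chimera_fraction >= 0, chimera_fraction <= 1,
      offtarget_fraction >= 0, offtarget_fraction <= 1,
      chimera_fraction + offtarget_fraction <= 0.5,
      barcode_corruption_fraction >= 0, barcode_corruption_fraction <= 1,
      length(reads_per_well_range) == 2,
      reads_per_well_range[1] >= 0,
      reads_per_well_range[1] <= reads_per_well_range[2]
    )
  })
  invisible(config)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readSimulationConfig} returns a validated configuration.
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(simulationConfig, lapply(raw, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
}

#' @rdname readSimulationConfig
#' @param config a simulation configuration.
#' @export
writeSimulationConfig <- function(config, path) {
  # yaml drops names on atomic vectors; serialize named vectors as maps
  raw <- lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(raw, path)
  invisible(path)
}

# ---- reference pool ------------------------------------------------------

#' Build a simulated reference pool
#'
#' Generates \code{taxa_pool_size} 16S-like sequences organized into genera
#' (>= 3 taxa per genus where the pool allows, within-genus identity >=
#' 97\%, between-genus identity far below 90\%), plus one designated
#' positive-control taxon in its own genus, each with a six-rank lineage
#' string.  Deterministic under the configuration seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{sequences} (named \code{DNAStringSet}),
#'   \code{lineage} (data.frame \code{taxon_id}, \code{genus},
#'   \code{lineage}) and \code{control_taxon} (the taxon id planted in H10
#'   wells).
#' @export
buildReferencePool <- function(config) {
  validateSimulationConfig(config)
  .with_seed(config$seed + 1L, {
    n <- config$taxa_pool_size
    n_genera <- max(2L, n %/% 3L)
    genus_of <- sort(rep_len(seq_len(n_genera), n))
    lr <- config$amplicon_length_range
    # genus ancestors: independent random sequences (mutually ~50% identity)
    anc_len <- sample(lr[1]:lr[2], n_genera, replace = TRUE)
    ancestors <- vapply(anc_len, .random_seq, "")
    # members: ancestor with ~0.8% substitutions, so within-genus pairs stay
    # comfortably above the 97% OTU radius
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- .substitute_seq(ancestors[genus_of[i]], 0.008)
    }
    ids <- sprintf("T%03d", seq_len(n))
    # dedicated positive-control taxon in its own genus
    ctrl_seq <- .random_seq(sample(lr[1]:lr[2], 1))
    ids <- c(ids, "CTRL")
    seqs <- c(seqs, ctrl_seq)
    genus_name <- c(sprintf("Genus%02d", genus_of), "ControlGenus")
    gidx <- c(genus_of, n_genera + 1L)
    lineage <- data.frame(
      taxon_id = ids,
      genus = genus_name,
      lineage = sprintf(
        "d__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__%s",
        (gidx - 1L) %/% 4L + 1L, (gidx - 1L) %/% 3L + 1L,
        (gidx - 1L) %/% 2L + 1L, gidx, genus_name
      ),
      stringsAsFactors = FALSE
    )
    list(
      sequences = Biostrings::DNAStringSet(setNames(seqs, ids)),
      lineage = lineage,
      control_taxon = "CTRL"
    )
  })
}

# substitutions only, at per-base probability `rate`
.substitute_seq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(.BASES, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# per-base iid errors: 80% substitutions, 20% indels (ins/del 50/50)
.apply_errors <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (!any(hit)) return(s)
  out <- as.list(ch)
  for (i in which(hit)) {
    u <- runif(1)
    if (u < 0.8) {
      out[[i]] <- sample(setdiff(.BASES, ch[i]), 1)
    } else if (u < 0.9) {
      out[[i]] <- c(sample(.BASES, 1), ch[i])   # insertion before the base
    } else {
      out[[i]] <- character(0)                   # deletion
    }
  }
  paste(unlist(out), collapse = "")
}

# ---- well communities ----------------------------------------------------

#' Assign taxa communities to wells
#'
#' Gives each of the 93 sample wells per plate a community of taxa drawn
#' from the pool according to the community-size distribution; the H10
#' positive-control well receives the designated control taxon, H11/H12
#' (negative controls) receive nothing.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param pool a reference pool from \code{\link{buildReferencePool}}.
#' @return data.frame (truth skeleton): \code{plate}, \code{row},
#'   \code{column}, \code{well}, \code{role}, \code{taxa} (comma-joined
#'   taxon ids; empty for negative controls).
#' @export
assignWellCommunities <- function(config, pool) {
  validateSimulationConfig(config)
  .with_seed(config$seed + 2L, {
    sizes <- as.integer(names(config$community_size_distribution))
    sample_taxa <- setdiff(names(pool$sequences), pool$control_taxon)
    out <- list()
    for (p in seq_len(config$n_plates)) {
      plate <- paste0("P", p)
      for (r in LETTERS[1:8]) for (co in 1:12) {
        role <- "sample"
        if (r == "H" && co == 10) role <- "positive_control"
        if (r == "H" && co %in% c(11, 12)) role <- "negative_control"
        taxa <- switch(role,
          sample = paste(
            sample(sample_taxa,
                   sample(sizes, 1, prob = config$community_size_distribution)),
            collapse = ","
          ),
          positive_control = pool$control_taxon,
          negative_control = ""
        )
        out[[length(out) + 1L]] <- data.frame(
          plate = plate, row = r, column = co,
          well = wellId(plate, r, co), role = role, taxa = taxa,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}

# ---- read synthesis ------------------------------------------------------

.error_rate_for <- function(coverage, rates) {
  ifelse(coverage < 5, rates[["low"]],
         ifelse(coverage <= 9, rates[["mid"]], rates[["high"]]))
}

#' Synthesize the reads of a run
#'
#' Emits the multiplexed CCS reads for a truth skeleton: each read is the
#' full construct (row barcode, forward anchor, insert, universal reverse
#' primer, plate barcode, reverse anchor, column barcode) with
#' coverage-dependent per-base errors (80\% substitutions / 20\% indels),
#' chimeric or off-target inserts and corrupted barcodes at the configured
#' rates, and a random 50\% of reads reverse-complemented.  The subread
#' sidecar total is coverage x read length plus sub-half-coverage jitter,
#' so recomputing coverage from the sidecar reproduces the true value.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param manifest a \code{\link{BarcodeManifest-class}} with at least
#'   \code{n_plates} plate barcodes.
#' @param pool reference pool from \code{\link{buildReferencePool}}.
#' @param skeleton truth skeleton from \code{\link{assignWellCommunities}}.
#' @return list with \code{ccs} (a \code{\link{CCSSet-class}}) and
#'   \code{truth} (data.frame with one row per emitted read: \code{ccs_id},
#'   \code{plate}, \code{row}, \code{column}, \code{well}, \code{taxon},
#'   \code{is_chimera}, \code{parent_a}, \code{parent_b},
#'   \code{crossover}, \code{is_offtarget}, \code{is_barcode_corrupted},
#'   \code{corrupted_class}, \code{true_coverage}, \code{emitted_strand}).
#' @export
synthesizeRun <- function(config, manifest, pool, skeleton) {
  validateSimulationConfig(config)
  stopifnot(is(manifest, "BarcodeManifest"))
  if (length(manifest@plates) < config$n_plates) {
    stop("manifest has fewer plate barcodes than n_plates")
  }
  .with_seed(config$seed + 3L, {
    covs <- as.integer(names(config$coverage_distribution))
    lr <- config$amplicon_length_range
    # taxa available per plate, for chimera parent draws
    plate_taxa <- lapply(split(skeleton$taxa, skeleton$plate), function(tt) {
      unique(unlist(strsplit(tt[nzchar(tt)], ",")))
    })
    pool_chr <- as.character(pool$sequences)

    seqs <- character(0); totals <- numeric(0); truth <- list()
    read_no <- 0L
    for (i in seq_len(nrow(skeleton))) {
      wellrec <- skeleton[i, ]
      taxa <- strsplit(wellrec$taxa, ",")[[1]]
      if (length(taxa) == 0) next   # negative control: no template, no reads
      n_reads <- sample(config$reads_per_well_range[1]:config$reads_per_well_range[2], 1)
      if (n_reads == 0) next
      for (k in seq_len(n_reads)) {
        read_no <- read_no + 1L
        id <- sprintf("ccs%06d", read_no)
        taxon <- sample(taxa, 1)
        is_chimera <- FALSE; is_offtarget <- FALSE
        parent_a <- NA_character_; parent_b <- NA_character_
        crossover <- NA_integer_
        u <- runif(1)
        if (u < config$chimera_fraction) {
          cand <- plate_taxa[[wellrec$plate]]
          if (length(cand) >= 2) {
            pa <- sample(cand, 2)
            sa <- pool_chr[[pa[1]]]; sb <- pool_chr[[pa[2]]]
            cx <- as.integer(round(runif(1, 0.2, 0.8) * nchar(sa)))
            insert <- paste0(substr(sa, 1, cx),
                             substr(sb, cx + 1, nchar(sb)))
            # keep bimera length inside the expected amplicon range so the
            # over-length and chimera filters stay independent
            if (nchar(insert) > lr[2]) insert <- substr(insert, 1, lr[2])
            is_chimera <- TRUE
            parent_a <- pa[1]; parent_b <- pa[2]; crossover <- cx
          } else {
            insert <- pool_chr[[taxon]]
          }
        } else if (u < config$chimera_fraction + config$offtarget_fraction) {
          insert <- .random_seq(sample(lr[1]:lr[2], 1))
          is_offtarget <- TRUE
        } else {
          insert <- pool_chr[[taxon]]
        }

        row_bc <- manifest@rows[[wellrec$row]]
        col_bc <- manifest@columns[[as.character(wellrec$column)]]
        plate_bc <- manifest@plates[[wellrec$plate]]
        corrupted <- runif(1) < config$barcode_corruption_fraction
        corrupted_class <- NA_character_
        if (corrupted) {
          corrupted_class <- sample(c("plate", "row", "column"), 1)
          mut1 <- function(bc) {
            p <- sample(nchar(bc), 1)
            old <- substr(bc, p, p)
            paste0(substr(bc, 1, p - 1), sample(setdiff(.BASES, old), 1),
                   substr(bc, p + 1, nchar(bc)))
          }
          if (corrupted_class == "plate") plate_bc <- mut1(plate_bc)
          if (corrupted_class == "row") row_bc <- mut1(row_bc)
          if (corrupted_class == "column") col_bc <- mut1(col_bc)
        }

        construct <- paste0(
          row_bc, manifest@anchors[["fwd_transposase"]], insert,
          manifest@anchors[["univ_reverse_primer"]], plate_bc,
          manifest@anchors[["rev_transposase"]], col_bc
        )
        coverage <- sample(covs, 1, prob = config$coverage_distribution)
        rate <- .error_rate_for(coverage, config$error_rate_by_class)
        read <- .apply_errors(construct, rate)
        strand <- if (runif(1) < 0.5) "plus" else "minus"
        if (strand == "minus") read <- .revcomp(read)
        L <- nchar(read)
        total <- coverage * L + as.integer(round(runif(1, -0.4, 0.4) * L))

        seqs[id] <- read
        totals[id] <- total
        truth[[read_no]] <- data.frame(
          ccs_id = id, plate = wellrec$plate, row = wellrec$row,
          column = wellrec$column, well = wellrec$well,
          taxon = if (is_offtarget) NA_character_ else taxon,
          is_chimera = is_chimera, parent_a = parent_a, parent_b = parent_b,
          crossover = crossover, is_offtarget = is_offtarget,
          is_barcode_corrupted = corrupted,
          corrupted_class = corrupted_class,
          true_coverage = coverage, emitted_strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(
        ccs_id = character(0), plate = character(0), row = character(0),
        column = integer(0), well = character(0), taxon = character(0),
        is_chimera = logical(0), parent_a = character(0),
        parent_b = character(0), crossover = integer(0),
        is_offtarget = logical(0), is_barcode_corrupted = logical(0),
        corrupted_class = character(0), true_coverage = integer(0),
        emitted_strand = character(0), stringsAsFactors = FALSE
      )
    ccs <- if (length(seqs)) ccsSet(seqs, totals) else .empty_ccs_set()
    list(ccs = ccs, truth = truth)
  })
}

.empty_ccs_set <- function() {
  new("CCSSet",
    sequences = Biostrings::DNAStringSet(),
    meta = S4Vectors::DataFrame(
      subread_total_nt = numeric(0), coverage = integer(0),
      ccs_length = integer(0),
      plate = character(0), row = character(0), column = integer(0),
      strand = character(0), status = character(0),
      reliability_source = character(0)
    )
  )
}

#' Simulate a culture-independent community profile
#'
#' Builds a short-fragment community profile from the simulator's reference
#' pool, emulating a V4-style survey: each profiled taxon is represented by
#' a 250-nt window of its reference sequence, and per-compartment relative
#' abundances are drawn from a normalized exponential.  Used to exercise the
#' recovery estimator against a known truth.
#'
#' @param pool reference pool from \code{\link{buildReferencePool}}.
#' @param compartments compartment labels.
#' @param taxa_fraction fraction of pool taxa present in each compartment.
#' @param fragment_window 0-based, half-open [start, end) window cut from
#'   each reference as the profile representative.
#' @param seed integer seed.
#' @return data.frame with columns \code{profile_otu_id}, \code{sequence},
#'   \code{compartment}, \code{relative_abundance} (summing to 1 per
#'   compartment).
#' @export
simulateCommunityProfile <- function(pool,
                                     compartments = c("rhizosphere",
                                                      "endophytic_root",
                                                      "endophytic_stalk"),
                                     taxa_fraction = 0.7,
                                     fragment_window = c(500L, 750L),
                                     seed = 7L) {
  .with_seed(seed, {
    ids <- setdiff(names(pool$sequences), pool$control_taxon)
    if (min(Biostrings::width(pool$sequences[ids])) < fragment_window[2]) {
      stop("fragment_window extends beyond the shortest reference")
    }
    frags <- substr(as.character(pool$sequences[ids]),
                    fragment_window[1] + 1L, fragment_window[2])
    out <- list()
    for (comp in compartments) {
      pick <- sort(sample(seq_along(ids), max(2L, round(taxa_fraction * length(ids)))))
      ab <- stats::rexp(length(pick))
      ab <- ab / sum(ab)
      out[[comp]] <- data.frame(
        profile_otu_id = paste0(comp, "_", ids[pick]),
        sequence = unname(frags[pick]),
        compartment = comp,
        relative_abundance = ab,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Simulate a full run and optionally write its files
#'
#' Convenience wrapper: builds the reference pool, assigns well
#' communities, synthesizes reads, and (when \code{outdir} is given) writes
#' \code{ccs.fasta}, \code{subreads.tsv}, \code{truth.tsv},
#' \code{manifest.tsv}, \code{references.fasta}, \code{lineages.tsv} and a
#' \code{config.yaml} snapshot.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param manifest optional \code{BarcodeManifest}; by default one is
#'   generated from the configuration seed with \code{n_plates} plates.
#' @param outdir optional output directory.
#' @return list with \code{ccs}, \code{truth}, \code{pool},
#'   \code{skeleton}, \code{manifest}, \code{config}.
#' @export
simulateRun <- function(config = simulationConfig(), manifest = NULL,
                        outdir = NULL) {
  validateSimulationConfig(config)
  if (is.null(manifest)) {
    manifest <- makeManifest(n_plates = config$n_plates,
                             seed = config$seed + 10L)
  }
  pool <- buildReferencePool(config)
  skeleton <- assignWellCommunities(config, pool)
  run <- synthesizeRun(config, manifest, pool, skeleton)
  res <- list(
    ccs = run$ccs, truth = run$truth, pool = pool, skeleton = skeleton,
    manifest = manifest, config = config
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeCcsSet(run$ccs, file.path(outdir, "ccs.fasta"),
                file.path(outdir, "subreads.tsv"))
    write.table(run$truth, file.path(outdir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(manifest, file.path(outdir, "manifest.tsv"))
    Biostrings::writeXStringSet(pool$sequences,
                                file.path(outdir, "references.fasta"))
    write.table(pool$lineage, file.path(outdir, "lineages.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeSimulationConfig(config, file.path(outdir, "config.yaml"))
  }
  res
}
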