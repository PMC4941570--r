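# Shared fixtures.  Everything is generated in code; heavyweight objects
# are built once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

rand_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# plant k substitutions at distinct positions (deterministic spacing)
plant_subs <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# a small, fast simulation configuration: short inserts, small pool
smallSimConfig <- function(seed = 42L, reads_per_well_range = c(1L, 3L),
                           ...) {
  simulationConfig(
    seed = seed, n_plates = 1L, taxa_pool_size = 12L,
    amplicon_length_range = c(380L, 420L),
    reads_per_well_range = reads_per_well_range,
    ...
  )
}

# mark reads of a raw CCSSet as demultiplexed into one well, as the QC
# filters expect (unit tests bypass the demultiplexer)
as_demultiplexed <- function(ccs, plate = "P1", row = "A", column = 1L) {
  m <- ccsMeta(ccs)
  m$plate <- plate
  m$row <- row
  m$column <- as.integer(column)
  m$strand <- "plus"
  m$status <- "demultiplexed"
  methods::slot(ccs, "meta") <- m
  ccs
}

# assemble a clean construct for a manifest well
make_construct <- function(manifest, plate, row, column, insert) {
  paste0(
    methods::slot(manifest, "rows")[[row]],
    methods::slot(manifest, "anchors")[["fwd_transposase"]],
    insert,
    methods::slot(manifest, "anchors")[["univ_reverse_primer"]],
    methods::slot(manifest, "plates")[[plate]],
    methods::slot(manifest, "anchors")[["rev_transposase"]],
    methods::slot(manifest, "columns")[[as.character(column)]]
  )
}

# the shared full-scale run at the default study conditions (five pooled
# plates, default error/chimera/off-target rates), with the full
# annotation chain; built once and reused by the acceptance tests
sharedRun <- function() {
  if (!is.null(.fixture_env$shared)) return(.fixture_env$shared)
  cfg <- simulationConfig(seed = 20260920L)
  run <- simulateRun(cfg)
  profile <- simulateCommunityProfile(run$pool, seed = 11L)
  res <- annotateRun(run$ccs, run$manifest, run$pool$sequences,
                     lineage = run$pool$lineage, profile = profile,
                     seed = 99L, verbose = FALSE)
  truth <- run$truth
  rownames(truth) <- truth$ccs_id
  .fixture_env$shared <- list(
    config = cfg, run = run, profile = profile, res = res, truth = truth
  )
  .fixture_env$shared
}

# small annotated run for pipeline-level unit tests
smallRun <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- smallSimConfig()
  run <- simulateRun(cfg)
  res <- annotateRun(run$ccs, run$manifest, run$pool$sequences,
                     lineage = run$pool$lineage, seed = 7L, verbose = FALSE)
  truth <- run$truth
  rownames(truth) <- truth$ccs_id
  .fixture_env$small <- list(config = cfg, run = run, res = res,
                             truth = truth)
  .fixture_env$small
}
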