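# End-to-end orchestration: simulate -> qc -> quantify -> differential
# translation -> 5'UTR features -> enrichment, with a JSON config, one
# seed, per-stage logging, and a run manifest.

#' Pipeline configuration
#'
#' Bundles the simulation block and all analysis thresholds into one
#' serializable object. The configuration round-trips unchanged through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param simulation an [sim_config()] object (or list of its arguments).
#' @param psite_offset P-site offset in nt.
#' @param window metagene half-window in nt.
#' @param alpha,fdr,lower,upper DTG thresholds (see [call_dtgs()]).
#' @param pseudocount,min_mrna_rpkm TE options (see
#'   [translational_efficiency()]).
#' @param effective_length RPKM effective-length convention (see [rpkm()]).
#' @param min_length_fraction,min_frame0 QC thresholds (see [qc_report()]).
#' @param n_random_sets,random_set_size synthetic gene-set collection used
#'   by the enrichment stage, in addition to the planted up/down truth sets.
#' @param seed master seed; all pipeline randomness derives from it.
#' @return object of class `rp_pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            psite_offset = 12L,
                            window = 25L,
                            alpha = 0.05, fdr = 0.05,
                            lower = 0.667, upper = 1.5,
                            pseudocount = 0, min_mrna_rpkm = 1,
                            effective_length = "cds_tx",
                            min_length_fraction = 0.8, min_frame0 = 0.5,
                            n_random_sets = 5L, random_set_size = 100L,
                            seed = NULL) {
  if (!inherits(simulation, "rp_sim_config")) {
    simulation <- do.call(sim_config, as.list(simulation))
  }
  if (!is.null(seed)) {
    simulation$seed <- as.integer(seed)
  }
  if (lower <= 0 || upper <= 0 || lower >= upper) {
    stop("require 0 < lower < upper", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1 || fdr <= 0 || fdr > 1) {
    stop("alpha and fdr must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      simulation = simulation,
      psite_offset = as.integer(psite_offset),
      window = as.integer(window),
      alpha = alpha, fdr = fdr, lower = lower, upper = upper,
      pseudocount = pseudocount, min_mrna_rpkm = min_mrna_rpkm,
      effective_length = match.arg(effective_length, c("cds_tx", "cds_cds")),
      min_length_fraction = min_length_fraction, min_frame0 = min_frame0,
      n_random_sets = as.integer(n_random_sets),
      random_set_size = as.integer(random_set_size),
      seed = simulation$seed
    ),
    class = "rp_pipeline_config"
  )
}

#' Serialize / deserialize a pipeline configuration as JSON
#' @param config an `rp_pipeline_config`.
#' @param path JSON file path.
#' @return `path` (writer) or the configuration (reader).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "rp_pipeline_config"))
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  x$simulation$footprint_length_weights <-
    as.list(x$simulation$footprint_length_weights)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- as.list(x$simulation)
  sim$footprint_length_weights <- unlist(sim$footprint_length_weights)
  sim$feature_plant <- as.list(sim$feature_plant)
  sim$feature_background <- as.list(sim$feature_background)
  sim <- do.call(sim_config, sim)
  args <- x[setdiff(names(x), c("simulation", "seed"))]
  do.call(pipeline_config, c(list(simulation = sim), args))
}

.rp_log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[riboTE] %-10s in=%d out=%d", stage, n_in, n_out))
}

#' Run the full pipeline
#'
#' Executes all stages on a simulated dataset and writes every artifact to
#' `outdir`. Deterministic for a fixed configuration: a rerun produces
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param config an `rp_pipeline_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a result bundle: list with `transcriptome`, `reads`,
#'   `qc`, `te`, `dtg`, `features`, `feature_comparisons`, `enrichment`,
#'   `manifest`.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "rp_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outdir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  counts_of <- list()

  # --- simulate ------------------------------------------------------------
  sim <- config$simulation
  tx <- stage("simulate", simulate_transcriptome(sim))
  reads <- stage("simulate", simulate_libraries(tx, sim))
  write_transcriptome_fasta(tx, pth("transcripts.fasta"))
  write_gene_models_bed(tx, pth("gene_models.bed"))
  write_alignments_tsv(reads, pth("alignments.tsv"))
  write_ground_truth(tx$truth, pth("ground_truth.tsv"))
  .rp_log_stage("simulate", sim$n_genes, nrow(reads))
  counts_of$simulate <- list(genes = nrow(tx$genes), reads = nrow(reads))

  # --- qc -------------------------------------------------------------------
  qc <- stage("qc", qc_report(
    reads[reads$library == "footprint", , drop = FALSE], tx,
    psite_offset = config$psite_offset, window = config$window,
    min_length_fraction = config$min_length_fraction,
    min_frame0 = config$min_frame0
  ))
  write_qc_report(qc, pth("qc.json"))
  .rp_log_stage("qc", sum(reads$library == "footprint"), length(qc$flags))
  counts_of$qc <- list(flags_pass = sum(qc$flags))

  # --- quantify -------------------------------------------------------------
  te <- stage("quantify", {
    cm_fp <- count_reads(reads[reads$library == "footprint", , drop = FALSE],
      tx,
      mode = "cds_psite", psite_offset = config$psite_offset
    )
    cm_m <- count_reads(reads[reads$library == "mrna", , drop = FALSE],
      tx,
      mode = "transcript_overlap"
    )
    translational_efficiency(
      rpkm(cm_fp, config$effective_length),
      rpkm(cm_m, config$effective_length),
      pseudocount = config$pseudocount,
      min_mrna_rpkm = config$min_mrna_rpkm
    )
  })
  write_te_table(te, pth("te_table.tsv"))
  .rp_log_stage("quantify", nrow(reads), nrow(te))
  counts_of$quantify <- list(te_rows = nrow(te), excluded = sum(te$excluded))

  # --- differential translation --------------------------------------------
  dtg <- stage("difftrans", dtg_analysis(te,
    alpha = config$alpha, fdr = config$fdr,
    lower = config$lower, upper = config$upper
  ))
  write_dtg_table(dtg, pth("dtg_table.tsv"))
  s <- attr(dtg, "summary")
  .rp_log_stage("difftrans", nrow(dtg), s$n_up + s$n_down)
  counts_of$difftrans <- list(n_up = s$n_up, n_down = s$n_down)

  # --- 5'UTR features -------------------------------------------------------
  up_ids <- dtg$gene_id[dtg$call == "up"]
  down_ids <- dtg$gene_id[dtg$call == "down"]
  features <- NULL
  cmp <- NULL
  if (length(up_ids) && length(down_ids)) {
    features <- stage(
      "utrfeat",
      utr_feature_table(tx, gene_ids = c(up_ids, down_ids))
    )
    features$set <- ifelse(features$gene_id %in% up_ids, "up", "down")
    cmp <- stage("utrfeat", compare_all_features(
      features[features$set == "up", , drop = FALSE],
      features[features$set == "down", , drop = FALSE]
    ))
    .rp_write_tsv(features, pth("utr_features.tsv"))
    .rp_write_tsv(cmp, pth("feature_comparisons.tsv"))
    .rp_log_stage("utrfeat", nrow(features), nrow(cmp))
  } else {
    message("[riboTE] utrfeat    skipped (empty up or down DTG set)")
  }
  counts_of$utrfeat <- list(
    up = length(up_ids), down = length(down_ids),
    comparisons = if (is.null(cmp)) 0L else nrow(cmp)
  )

  # --- enrichment -----------------------------------------------------------
  enr <- NULL
  universe <- dtg$gene_id[!is.na(dtg$p_value)]
  if (length(up_ids) && length(universe) > 1L) {
    enr <- stage("enrich", {
      sets <- list(
        planted_te_up = intersect(tx$truth$gene_id[tx$truth$condition_class == "te_up"], universe),
        planted_te_down = intersect(tx$truth$gene_id[tx$truth$condition_class == "te_down"], universe)
      )
      withr::with_seed(.rp_subseed(config$seed, 9000L), {
        for (i in seq_len(config$n_random_sets)) {
          sets[[sprintf("random_set_%02d", i)]] <-
            sample(universe, min(config$random_set_size, length(universe)))
        }
      })
      sets <- sets[lengths(sets) > 0]
      coll <- gene_set_collection(sets, universe)
      write_gmt(coll, pth("gene_sets.gmt"))
      hypergeometric_enrichment(up_ids, coll)
    })
    .rp_write_tsv(enr, pth("enrichment.tsv"))
    .rp_log_stage("enrich", length(up_ids), nrow(enr))
  } else {
    message("[riboTE] enrich     skipped (no up-called genes)")
  }
  counts_of$enrich <- list(results = if (is.null(enr)) 0L else nrow(enr))

  # --- manifest -------------------------------------------------------------
  cfg_file <- pth("config.json")
  write_pipeline_config(config, cfg_file)
  manifest <- list(
    package = "riboTE",
    version = as.character(packageVersion("riboTE")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    coordinates = "0-based half-open, transcript space",
    stage_counts = counts_of
  )
  jsonlite::write_json(manifest, pth("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    transcriptome = tx, reads = reads, qc = qc, te = te, dtg = dtg,
    features = features, feature_comparisons = cmp, enrichment = enr,
    manifest = manifest
  ))
}
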