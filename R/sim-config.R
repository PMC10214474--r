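#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_transcriptome()] and [simulate_libraries()]. The defaults
#' describe a two-condition (high-frequency stimulation vs low-frequency
#' test-pulse control) paired footprint / total-mRNA design with three
#' replicates per condition, 28-32 nt footprints with strong frame-0
#' periodicity over the CDS, lognormal per-gene transcript abundance, and a
#' 10% subset of genes carrying a planted |log2| = 1 translational-efficiency
#' change (half up, half down).
#'
#' 5'UTR features (uORF, TOP, G-quadruplex, elevated GC, extended length)
#' are planted on the TE-up subset with probabilities `feature_plant` and on
#' all remaining genes with probabilities `feature_background`, and recorded
#' in the ground-truth table so downstream detectors can be scored against
#' generative truth.
#'
#' @param n_genes number of transcripts to simulate.
#' @param utr5_length_range,cds_length_range,utr3_length_range inclusive
#'   length ranges in nt; CDS lengths are forced to multiples of 3.
#' @param gc_background background GC fraction for generated sequence.
#' @param abundance_log_mean,abundance_log_sd lognormal (meanlog, sdlog)
#'   parameters for per-gene transcript abundance.
#' @param reads_per_library exact number of reads emitted per library.
#' @param footprint_length_weights named probability vector over footprint
#'   lengths 28..32; must sum to 1.
#' @param mrna_length_range inclusive length range for total-mRNA fragments.
#' @param periodicity probability that a footprint P-site is placed in
#'   reading frame 0 (remainder split equally over frames 1 and 2).
#' @param psite_offset P-site offset in nt from the footprint 5' end
#'   (single global value for all lengths).
#' @param te_effect_genes fraction of genes with a planted TE change
#'   (split evenly between up and down).
#' @param te_log2_effect planted |log2 TE fold-change|.
#' @param n_replicates replicates per condition.
#' @param feature_plant named list of planting probabilities
#'   (`uorf`, `top`, `pg4`, `high_gc`, `long_utr`) for the TE-up subset.
#' @param feature_background same names; probabilities for all other genes.
#' @param long_utr_shift nt added to the 5'UTR when `long_utr` is planted.
#' @param high_gc_boost GC increment applied to the 5'UTR when `high_gc`
#'   is planted.
#' @param seed integer seed; identical config + seed reproduces
#'   byte-identical outputs.
#'
#' @return an object of class `rp_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, reads_per_library = 1000, seed = 1)
sim_config <- function(n_genes = 2000,
                       utr5_length_range = c(50L, 300L),
                       cds_length_range = c(300L, 1500L),
                       utr3_length_range = c(100L, 400L),
                       gc_background = 0.5,
                       abundance_log_mean = 3,
                       abundance_log_sd = 1,
                       reads_per_library = 1e5,
                       footprint_length_weights = c(
                         "28" = 0.10, "29" = 0.40, "30" = 0.30,
                         "31" = 0.15, "32" = 0.05
                       ),
                       mrna_length_range = c(50L, 120L),
                       periodicity = 0.95,
                       psite_offset = 12L,
                       te_effect_genes = 0.10,
                       te_log2_effect = 1,
                       n_replicates = 3L,
                       feature_plant = list(
                         uorf = 0.8, top = 0.5, pg4 = 0.5,
                         high_gc = 0.8, long_utr = 1.0
                       ),
                       feature_background = list(
                         uorf = 0.2, top = 0.05, pg4 = 0.05,
                         high_gc = 0, long_utr = 0
                       ),
                       long_utr_shift = 50L,
                       high_gc_boost = 0.15,
                       seed = 1L) {
  chk_range <- function(r, name, min_lo = 1) {
    if (length(r) != 2L || any(!is.finite(r))) {
      stop("`", name, "` must be a finite length-2 vector", call. = FALSE)
    }
    if (r[1] > r[2]) {
      stop("`", name, "` has min > max", call. = FALSE)
    }
    if (r[1] < min_lo) {
      stop("`", name, "` minimum must be >= ", min_lo, call. = FALSE)
    }
    as.integer(r)
  }
  chk_prob <- function(p, name) {
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("`", name, "` must be a probability in [0, 1]", call. = FALSE)
    }
    as.numeric(p)
  }

  utr5_length_range <- chk_range(utr5_length_range, "utr5_length_range")
  utr3_length_range <- chk_range(utr3_length_range, "utr3_length_range")
  cds_length_range <- chk_range(cds_length_range, "cds_length_range", min_lo = 6)
  # force multiples of 3 (ATG + internal codons + stop)
  cds_length_range <- pmax(6L, as.integer(round(cds_length_range / 3) * 3))
  if (cds_length_range[1] > cds_length_range[2]) {
    cds_length_range[1] <- cds_length_range[2]
  }
  mrna_length_range <- chk_range(mrna_length_range, "mrna_length_range")

  gc_background <- chk_prob(gc_background, "gc_background")
  periodicity <- chk_prob(periodicity, "periodicity")
  te_effect_genes <- chk_prob(te_effect_genes, "te_effect_genes")

  w <- footprint_length_weights
  if (is.null(names(w)) || !all(names(w) %in% as.character(28:32))) {
    stop("footprint_length_weights must be named with lengths in 28..32",
      call. = FALSE
    )
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("footprint_length_weights must be non-negative and sum to 1",
      call. = FALSE
    )
  }

  feat_names <- c("uorf", "top", "pg4", "high_gc", "long_utr")
  fill_feat <- function(x, name) {
    x <- as.list(x)
    bad <- setdiff(names(x), feat_names)
    if (length(bad)) {
      stop("unknown feature name(s) in `", name, "`: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    out <- setNames(as.list(rep(0, length(feat_names))), feat_names)
    out[names(x)] <- x
    for (f in feat_names) chk_prob(out[[f]], paste0(name, "$", f))
    out
  }
  feature_plant <- fill_feat(feature_plant, "feature_plant")
  feature_background <- fill_feat(feature_background, "feature_background")

  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (te_log2_effect < 0) stop("te_log2_effect must be >= 0", call. = FALSE)
  if (psite_offset < 0) stop("psite_offset must be >= 0", call. = FALSE)
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)

  structure(
    list(
      n_genes = as.integer(n_genes),
      utr5_length_range = utr5_length_range,
      cds_length_range = cds_length_range,
      utr3_length_range = utr3_length_range,
      gc_background = gc_background,
      abundance_log_mean = as.numeric(abundance_log_mean),
      abundance_log_sd = as.numeric(abundance_log_sd),
      reads_per_library = as.integer(reads_per_library),
      footprint_length_weights = w,
      mrna_length_range = mrna_length_range,
      periodicity = periodicity,
      psite_offset = as.integer(psite_offset),
      te_effect_genes = te_effect_genes,
      te_log2_effect = as.numeric(te_log2_effect),
      n_replicates = as.integer(n_replicates),
      feature_plant = feature_plant,
      feature_background = feature_background,
      long_utr_shift = as.integer(long_utr_shift),
      high_gc_boost = as.numeric(high_gc_boost),
      seed = as.integer(seed)
    ),
    class = "rp_sim_config"
  )
}

#' @export
print.rp_sim_config <- function(x, ...) {
  cat("riboTE simulation config\n")
  cat(sprintf(
    "  %d genes, %d reads/library, %d replicates x 2 conditions\n",
    x$n_genes, x$reads_per_library, x$n_replicates
  ))
  cat(sprintf(
    "  TE effect: %.0f%% of genes at |log2| = %.3g; periodicity %.2f; seed %d\n",
    100 * x$te_effect_genes, x$te_log2_effect, x$periodicity, x$seed
  ))
  invisible(x)
}

# derive a per-stage / per-sample sub-seed, kept below 2^31
.rp_subseed <- function(seed, idx) {
  as.integer((as.double(seed) * 48271 + idx * 7919) %% 2147483647)
}
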