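# Footprint quality control: the three criteria used to judge a ribosome
# profiling library canonical -- (1) footprint length distribution
# concentrated on 28-32 nt, (2) P-site reading-frame distribution dominated
# by frame 0, (3) metagene P-site periodicity around the start codon.

# join read table against gene models; errors on unknown ids
.rp_match_genes <- function(reads, genes) {
  g <- .rp_genes_df(genes)
  i <- match(reads$gene_id, g$gene_id)
  if (anyNA(i)) {
    bad <- unique(reads$gene_id[is.na(i)])
    stop(
      "read(s) map to unknown gene id(s): ",
      paste(head(bad, 5L), collapse = ", "),
      if (length(bad) > 5L) ", ..." else "",
      call. = FALSE
    )
  }
  i
}

#' Footprint length distribution
#'
#' @param reads alignment data.frame from a footprint library.
#' @return named integer vector mapping length to count (empty input gives
#'   an empty vector).
#' @export
#' @examples
#' footprint_length_distribution(
#'   data.frame(gene_id = "g", start = 0, length = c(29, 29, 29),
#'              library = "footprint", sample = "s")
#' )
footprint_length_distribution <- function(reads) {
  if (any(reads$library != "footprint")) {
    stop("library mismatch: non-footprint reads present", call. = FALSE)
  }
  if (nrow(reads) == 0L) {
    return(setNames(integer(0), character(0)))
  }
  tab <- table(reads$length)
  setNames(as.integer(tab), names(tab))
}

#' P-site reading-frame distribution
#'
#' Only reads whose P-site (5' end + `psite_offset`) lies within the CDS are
#' counted; frame is `(psite - cds_start) mod 3`.
#'
#' @param reads footprint alignment data.frame.
#' @param genes gene models.
#' @param psite_offset P-site offset in nt (default 12).
#' @return numeric vector of length 3 (fractions in frames 0/1/2, sum 1).
#' @export
frame_distribution <- function(reads, genes, psite_offset = 12L) {
  g <- .rp_genes_df(genes)
  i <- .rp_match_genes(reads, genes)
  psite <- reads$start + psite_offset
  in_cds <- psite >= g$cds_start[i] & psite < g$cds_end[i]
  if (!any(in_cds)) {
    stop("no read has its P-site within a CDS; frame fractions undefined",
      call. = FALSE
    )
  }
  fr <- (psite[in_cds] - g$cds_start[i][in_cds]) %% 3L
  counts <- tabulate(fr + 1L, nbins = 3L)
  setNames(counts / sum(counts), c("frame0", "frame1", "frame2"))
}

#' Metagene P-site profile around the start and stop codons
#'
#' Counts P-sites per position in a `[-window, +window]` interval anchored at
#' the CDS start (first nt of the initiation codon) and at the first nt of
#' the stop codon. Genes whose UTRs are shorter than `window` are excluded
#' and reported in the `excluded_genes` attribute, so that every profile
#' position is supported by the same gene set.
#'
#' @inheritParams frame_distribution
#' @param window half-width in nt; must be positive.
#' @return list with `start` and `stop` integer vectors of length
#'   `2 * window + 1` (names are positions relative to the anchor) and
#'   attribute `excluded_genes`.
#' @export
metagene_profile <- function(reads, genes, psite_offset = 12L, window = 25L) {
  if (window <= 0L) stop("window must be positive", call. = FALSE)
  g <- .rp_genes_df(genes)
  keep_gene <- g$cds_start >= window & (g$tx_len - g$cds_end) >= window
  i <- .rp_match_genes(reads, genes)
  use <- keep_gene[i]
  psite <- reads$start[use] + psite_offset
  gi <- i[use]

  anchor_profile <- function(anchor) {
    rel <- psite - anchor[gi]
    rel <- rel[rel >= -window & rel <= window]
    prof <- tabulate(rel + window + 1L, nbins = 2L * window + 1L)
    setNames(as.integer(prof), as.character(seq(-window, window)))
  }
  out <- list(
    start = anchor_profile(g$cds_start),
    stop = anchor_profile(g$cds_end - 3L)
  )
  attr(out, "excluded_genes") <- g$gene_id[!keep_gene]
  out
}

# lag-k autocorrelation of a numeric vector (internal; used for the
# periodicity flag)
.rp_autocor <- function(x, lag) {
  n <- length(x)
  if (n <= lag + 1L) {
    return(NA_real_)
  }
  suppressWarnings(cor(x[seq_len(n - lag)], x[seq_len(n - lag) + lag]))
}

#' Footprint QC report
#'
#' Applies the three canonical-library criteria with explicit, configurable
#' thresholds: (1) at least `min_length_fraction` of footprints in
#' `length_range`; (2) frame-0 fraction at least `min_frame0`; (3) the lag-3
#' autocorrelation of the CDS-side start-anchored metagene profile exceeds
#' lags 1 and 2.
#'
#' @inheritParams metagene_profile
#' @param length_range inclusive footprint length window treated as canonical.
#' @param min_length_fraction pass threshold for criterion 1.
#' @param min_frame0 pass threshold for criterion 2 (must exceed the uniform
#'   1/3 to be meaningful).
#' @return object of class `rp_qc_report`: list with `length_histogram`,
#'   `frame_fractions`, `metagene`, `flags` (logical) and `thresholds`.
#' @export
qc_report <- function(reads, genes, psite_offset = 12L, window = 25L,
                      length_range = c(28L, 32L),
                      min_length_fraction = 0.8,
                      min_frame0 = 0.5) {
  fp <- reads[reads$library == "footprint", , drop = FALSE]
  hist <- footprint_length_distribution(fp)
  frac_in <- if (sum(hist) > 0) {
    lens <- as.integer(names(hist))
    sum(hist[lens >= length_range[1] & lens <= length_range[2]]) / sum(hist)
  } else {
    NA_real_
  }
  frames <- frame_distribution(fp, genes, psite_offset)
  prof <- metagene_profile(fp, genes, psite_offset, window)
  cds_side <- prof$start[as.integer(names(prof$start)) >= 0]
  ac <- vapply(1:3, function(l) .rp_autocor(as.numeric(cds_side), l), numeric(1))
  flags <- c(
    length = isTRUE(frac_in >= min_length_fraction),
    frame = isTRUE(frames[["frame0"]] >= min_frame0),
    periodicity = isTRUE(!anyNA(ac) && ac[3] > ac[1] && ac[3] > ac[2])
  )
  structure(
    list(
      length_histogram = hist,
      length_fraction_canonical = frac_in,
      frame_fractions = frames,
      metagene = prof,
      autocorrelation = setNames(ac, c("lag1", "lag2", "lag3")),
      flags = flags,
      thresholds = list(
        length_range = length_range,
        min_length_fraction = min_length_fraction,
        min_frame0 = min_frame0,
        psite_offset = psite_offset,
        window = window
      )
    ),
    class = "rp_qc_report"
  )
}

#' @export
print.rp_qc_report <- function(x, ...) {
  cat("riboTE footprint QC\n")
  cat(sprintf(
    "  lengths %s: %.1f%% in [%d,%d] -> %s\n",
    paste(range(as.integer(names(x$length_histogram))), collapse = "-"),
    100 * x$length_fraction_canonical,
    x$thresholds$length_range[1], x$thresholds$length_range[2],
    ifelse(x$flags["length"], "PASS", "FAIL")
  ))
  cat(sprintf(
    "  frame fractions: %.3f / %.3f / %.3f -> %s\n",
    x$frame_fractions[1], x$frame_fractions[2], x$frame_fractions[3],
    ifelse(x$flags["frame"], "PASS", "FAIL")
  ))
  cat(sprintf(
    "  metagene autocorrelation lag1/2/3: %.3f / %.3f / %.3f -> %s\n",
    x$autocorrelation[1], x$autocorrelation[2], x$autocorrelation[3],
    ifelse(x$flags["periodicity"], "PASS", "FAIL")
  ))
  invisible(x)
}

#' Serialize a QC report
#'
#' Writes the report as JSON plus TSV histograms (length histogram and the
#' two metagene profiles) alongside it.
#' @param report an `rp_qc_report`.
#' @param path output JSON path; TSVs take the same stem.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "rp_qc_report"))
  jsonlite::write_json(
    list(
      length_fraction_canonical = report$length_fraction_canonical,
      frame_fractions = as.list(report$frame_fractions),
      autocorrelation = as.list(report$autocorrelation),
      flags = as.list(report$flags),
      thresholds = report$thresholds
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  stem <- sub("\\.json$", "", path)
  .rp_write_tsv(
    data.frame(
      length = as.integer(names(report$length_histogram)),
      count = as.integer(report$length_histogram)
    ),
    paste0(stem, "_length_histogram.tsv")
  )
  .rp_write_tsv(
    data.frame(
      position = as.integer(names(report$metagene$start)),
      start_anchored = as.integer(report$metagene$start),
      stop_anchored = as.integer(report$metagene$stop)
    ),
    paste0(stem, "_metagene.tsv")
  )
  invisible(path)
}
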