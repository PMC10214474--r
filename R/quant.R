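# Counting, RPKM and translational efficiency.
#
# Counting rule (the upstream convention this package adopts): footprints
# are counted for a gene iff their P-site falls within the CDS
# ("cds_psite" mode); total-mRNA fragments are counted on any transcript
# overlap ("transcript_overlap" mode). Effective lengths are the CDS for
# footprint RPKM and the full transcript for mRNA RPKM by default
# (switchable to CDS/CDS).

#' Count reads per gene and sample
#'
#' @param reads alignment data.frame (any mix of samples of one library
#'   type).
#' @param genes gene models.
#' @param mode `"cds_psite"` counts a read iff its P-site
#'   (start + `psite_offset`) lies within the CDS; `"transcript_overlap"`
#'   counts every aligned fragment.
#' @param psite_offset P-site offset used in `cds_psite` mode.
#' @return object of class `rp_counts`: list with integer matrix `counts`
#'   (genes x samples), `samples` data.frame (sample, library, condition,
#'   replicate), `gene_lengths` (gene_id, cds_len, tx_len) and
#'   `library_size` (column sums).
#' @export
count_reads <- function(reads, genes,
                        mode = c("cds_psite", "transcript_overlap"),
                        psite_offset = 12L) {
  mode <- match.arg(mode)
  g <- .rp_genes_df(genes)
  i <- .rp_match_genes(reads, genes)
  keep <- if (mode == "cds_psite") {
    psite <- reads$start + psite_offset
    psite >= g$cds_start[i] & psite < g$cds_end[i]
  } else {
    rep(TRUE, nrow(reads))
  }
  smp <- sort(unique(reads$sample))
  counts <- matrix(0L, nrow(g), length(smp),
    dimnames = list(g$gene_id, smp)
  )
  if (any(keep)) {
    tab <- table(
      factor(reads$gene_id[keep], levels = g$gene_id),
      factor(reads$sample[keep], levels = smp)
    )
    counts[] <- as.integer(tab)
  }
  meta_cols <- intersect(c("library", "condition", "replicate"), names(reads))
  samples <- unique(reads[c("sample", meta_cols)])
  samples <- samples[match(smp, samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(
      counts = counts,
      samples = samples,
      gene_lengths = data.frame(
        gene_id = g$gene_id,
        cds_len = g$cds_end - g$cds_start,
        tx_len = g$tx_len,
        stringsAsFactors = FALSE
      ),
      library_size = colSums(counts),
      mode = mode
    ),
    class = "rp_counts"
  )
}

#' @export
print.rp_counts <- function(x, ...) {
  cat(sprintf(
    "riboTE counts: %d genes x %d samples (%s mode), %s reads total\n",
    nrow(x$counts), ncol(x$counts), x$mode,
    format(sum(x$library_size), big.mark = ",")
  ))
  invisible(x)
}

#' RPKM from a count matrix
#'
#' `RPKM = count * 1e9 / (effective_length * library_size)`. Effective
#' length is the CDS for footprint samples and the full transcript for mRNA
#' samples (`effective_length = "cds_tx"`), or the CDS for both
#' (`"cds_cds"`).
#'
#' @param cm an `rp_counts` object.
#' @param effective_length `"cds_tx"` (default) or `"cds_cds"`.
#' @return numeric matrix of RPKM values, genes x samples.
#' @export
#' @examples
#' # count 10, length 1000 nt, library 1e6 reads -> RPKM 10
rpkm <- function(cm, effective_length = c("cds_tx", "cds_cds")) {
  stopifnot(inherits(cm, "rp_counts"))
  effective_length <- match.arg(effective_length)
  if (any(cm$library_size <= 0)) {
    stop("zero library size for sample(s): ",
      paste(names(cm$library_size)[cm$library_size <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  len_cds <- cm$gene_lengths$cds_len
  len_tx <- cm$gene_lengths$tx_len
  if (any(len_cds <= 0) || any(len_tx <= 0)) {
    stop("effective lengths must be positive", call. = FALSE)
  }
  is_mrna <- cm$samples$library == "mrna"
  out <- matrix(NA_real_, nrow(cm$counts), ncol(cm$counts),
    dimnames = dimnames(cm$counts)
  )
  for (j in seq_len(ncol(out))) {
    len <- if (effective_length == "cds_tx" && isTRUE(is_mrna[j])) len_tx else len_cds
    out[, j] <- cm$counts[, j] * 1e9 / (len * cm$library_size[j])
  }
  out
}

#' Translational efficiency table
#'
#' `TE = (RPKM_fp + pseudocount) / (RPKM_mrna + pseudocount)` per gene and
#' paired sample. Footprint and mRNA samples are paired by shared
#' `condition`/`replicate` (columns named `<condition>_rep<k>_<library>`).
#' Gene-sample pairs with `RPKM_mrna < min_mrna_rpkm`, or with a zero
#' denominator or numerator after the pseudocount, are flagged excluded with
#' a reason instead of being returned with an unstable TE.
#'
#' @param rpkm_fp,rpkm_mrna RPKM matrices (genes x samples) for the
#'   footprint and mRNA libraries, from [rpkm()].
#' With `normalize = "median"` (the default) each sample's TE values are
#' divided by that sample's median TE over retained genes. This removes the
#' global library-composition constant that the raw RPKM ratio carries
#' (footprint reads are drawn from CDS mass, mRNA fragments from whole
#' transcript mass, so the two RPKM denominators are not on a common
#' scale), centering null genes at TE = 1. Between-condition log2 TE
#' changes are invariant to this centering up to the (tiny) shift in the
#' per-sample median. `normalize = "none"` reports the raw ratio.
#'
#' @param pseudocount non-negative value added to both RPKMs (default 0).
#' @param min_mrna_rpkm expression filter on the mRNA RPKM (default 1).
#' @param normalize `"median"` (per-sample median centering, default) or
#'   `"none"` (raw RPKM ratio).
#' @return object of class `rp_te_table`: data.frame with gene_id,
#'   condition, replicate, rpkm_fp, rpkm_mrna, te, log2_te, excluded,
#'   reason.
#' @export
translational_efficiency <- function(rpkm_fp, rpkm_mrna, pseudocount = 0,
                                     min_mrna_rpkm = 1,
                                     normalize = c("median", "none")) {
  normalize <- match.arg(normalize)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (!identical(rownames(rpkm_fp), rownames(rpkm_mrna))) {
    stop("footprint and mRNA matrices must cover the same genes", call. = FALSE)
  }
  key <- function(cn) sub("_(footprint|mrna)$", "", cn)
  kf <- key(colnames(rpkm_fp))
  km <- key(colnames(rpkm_mrna))
  common <- intersect(kf, km)
  if (!length(common)) {
    stop("no matched footprint/mRNA sample pairs", call. = FALSE)
  }
  rows <- lapply(common, function(k) {
    fp <- rpkm_fp[, which(kf == k)[1L]]
    m <- rpkm_mrna[, which(km == k)[1L]]
    den <- m + pseudocount
    num <- fp + pseudocount
    excluded <- rep(FALSE, length(fp))
    reason <- rep(NA_character_, length(fp))
    low <- m < min_mrna_rpkm
    excluded[low] <- TRUE
    reason[low] <- "low_mrna"
    zd <- !excluded & den == 0
    excluded[zd] <- TRUE
    reason[zd] <- "zero_mrna"
    zn <- !excluded & num == 0
    excluded[zn] <- TRUE
    reason[zn] <- "zero_footprint"
    te <- ifelse(den > 0, num / den, NA_real_)
    if (normalize == "median") {
      med <- stats::median(te[!excluded], na.rm = TRUE)
      if (is.finite(med) && med > 0) te <- te / med
    }
    cr <- regmatches(k, regexec("^(.+)_rep([0-9]+)$", k))[[1L]]
    data.frame(
      gene_id = rownames(rpkm_fp),
      condition = if (length(cr) == 3L) cr[2L] else NA_character_,
      replicate = if (length(cr) == 3L) as.integer(cr[3L]) else NA_integer_,
      rpkm_fp = fp,
      rpkm_mrna = m,
      te = te,
      log2_te = ifelse(!excluded & te > 0, log2(te), NA_real_),
      excluded = excluded,
      reason = reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rp_te_table", "data.frame")
  out
}

#' Write a TE table as TSV
#' @param te an `rp_te_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_te_table <- function(te, path) {
  .rp_write_tsv(as.data.frame(te), path)
  invisible(path)
}
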