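# Differential translation calling: per-gene Welch t-test on replicate
# log2 TE values, Benjamini-Hochberg FDR, and thresholding on the TE ratio
# (defaults ratio < 0.667 or ratio > 1.5, p < 0.05, q < 0.05).

# genes x replicates matrix of log2 TE for one condition; NA where excluded
.rp_log2te_matrix <- function(te, condition) {
  stopifnot(inherits(te, "rp_te_table"))
  d <- te[te$condition == condition, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("condition not present in TE table: ", condition, call. = FALSE)
  }
  genes <- unique(te$gene_id)
  reps <- sort(unique(d$replicate))
  m <- matrix(NA_real_, length(genes), length(reps),
    dimnames = list(genes, paste0("rep", reps))
  )
  m[cbind(
    match(d$gene_id, genes),
    match(d$replicate, reps)
  )] <- ifelse(d$excluded, NA_real_, d$log2_te)
  m
}

#' Per-gene log2 TE change between two conditions
#'
#' Mean replicate log2 TE in the treatment condition minus the control mean.
#' Genes excluded (by the expression filter) in any replicate of either
#' condition are excluded here with a reason.
#'
#' @param te_treatment,te_control `rp_te_table`s (or one table containing
#'   both conditions, passed twice with different `condition`).
#' @param treatment,control condition labels to contrast.
#' @return data.frame with gene_id, log2_te_change, excluded, reason.
#' @export
log2_te_change <- function(te_treatment, te_control,
                           treatment = "treatment", control = "control") {
  mt <- .rp_log2te_matrix(te_treatment, treatment)
  mc <- .rp_log2te_matrix(te_control, control)
  genes <- intersect(rownames(mt), rownames(mc))
  if (!length(genes)) stop("disjoint gene sets", call. = FALSE)
  mt <- mt[genes, , drop = FALSE]
  mc <- mc[genes, , drop = FALSE]
  ok <- !apply(is.na(mt), 1L, any) & !apply(is.na(mc), 1L, any)
  data.frame(
    gene_id = genes,
    log2_te_change = ifelse(ok, rowMeans(mt) - rowMeans(mc), NA_real_),
    excluded = !ok,
    reason = ifelse(ok, NA_character_, "excluded_replicate"),
    stringsAsFactors = FALSE
  )
}

#' Per-gene two-sided Welch t-test on replicate log2 TE
#'
#' Vectorized over genes. Genes with fewer than two non-missing replicates
#' in either group are untestable (`p = NA`). When both groups have zero
#' variance the gene gets `p = 1` if the means agree and is otherwise
#' reported untestable (the test statistic is undefined).
#'
#' @param x,y numeric matrices (genes x replicates) of log2 TE for the
#'   treatment and control groups, rows aligned.
#' @return data.frame with gene_id, mean_diff, t, df, p_value, untestable.
#' @export
test_differential_te <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  n1 <- rowSums(!is.na(x))
  n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- apply(x, 1L, var, na.rm = TRUE)
  v2 <- apply(y, 1L, var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (
    (v1 / n1)^2 / pmax(n1 - 1L, 1L) + (v2 / n2)^2 / pmax(n2 - 1L, 1L)
  )
  p <- 2 * pt(-abs(tt), df)
  zerovar <- !is.na(se2) & se2 == 0
  p[zerovar & (m1 == m2)] <- 1
  untestable <- n1 < 2L | n2 < 2L | (zerovar & m1 != m2)
  p[untestable] <- NA_real_
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1]
  data.frame(
    gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    mean_diff = m1 - m2,
    t = tt,
    df = df,
    p_value = p,
    untestable = untestable,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation test on replicate log2 TE (small-sample alternative)
#'
#' Exact two-sided permutation test of the difference in group means,
#' enumerating all assignments of the pooled replicates into the two group
#' sizes. Used as the independent oracle for [test_differential_te()].
#'
#' @param x,y numeric replicate vectors for one gene.
#' @return p-value in (0, 1].
#' @export
permutation_test_te <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(NA_real_)
  }
  pool <- c(x, y)
  n <- length(pool)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(n, length(x))
  stats <- apply(idx, 2L, function(i) {
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  mean(stats >= obs - 1e-12)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in (0, 1]; NA entries are
#'   propagated and ignored in the correction.
#' @return q-values of the same length, capped at 1.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.04)) # 0.02, 0.04
bh_fdr <- function(p_values) {
  p <- p_values
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m == 0L) {
    return(q)
  }
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  qv <- pmin(1, cummin(m / (m:1) * pv[o]))
  q[ok][o] <- qv
  # cummin above runs from the largest p downwards: q_i = min_{j >= i} m p_(j) / j
  q
}

#' Call differentially translated genes
#'
#' A gene is called `up` iff its TE ratio exceeds `upper`, `p < alpha` and
#' `q < fdr`; `down` symmetrically with `lower`; otherwise `unchanged`.
#' Untestable genes (NA p) are never called.
#'
#' @param records data.frame with columns `gene_id`, `log2_te_change`,
#'   `p_value` and optionally `q_value` (computed via [bh_fdr()] if absent).
#' @param alpha p-value threshold.
#' @param fdr BH q-value threshold.
#' @param lower,upper TE-ratio thresholds (defaults 0.667 and 1.5).
#' @return object of class `rp_dtg_table`: the records with added
#'   `ratio`, `q_value` and `call` columns; summary counts in
#'   `attr(, "summary")`.
#' @export
call_dtgs <- function(records, alpha = 0.05, fdr = 0.05,
                      lower = 0.667, upper = 1.5) {
  if (!all(c("gene_id", "log2_te_change", "p_value") %in% names(records))) {
    stop("records must carry gene_id, log2_te_change, p_value", call. = FALSE)
  }
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || upper <= 0 ||
    lower >= upper) {
    stop("thresholds must satisfy 0 < lower < upper", call. = FALSE)
  }
  if (alpha <= 0 || alpha > 1 || fdr <= 0 || fdr > 1) {
    stop("alpha and fdr must lie in (0, 1]", call. = FALSE)
  }
  out <- as.data.frame(records)
  out$ratio <- 2^out$log2_te_change
  if (!"q_value" %in% names(out)) out$q_value <- bh_fdr(out$p_value)
  sig <- !is.na(out$p_value) & out$p_value < alpha &
    !is.na(out$q_value) & out$q_value < fdr
  out$call <- "unchanged"
  out$call[sig & !is.na(out$ratio) & out$ratio > upper] <- "up"
  out$call[sig & !is.na(out$ratio) & out$ratio < lower] <- "down"
  attr(out, "summary") <- list(
    n_up = sum(out$call == "up"),
    n_down = sum(out$call == "down"),
    n_unchanged = sum(out$call == "unchanged"),
    thresholds = list(alpha = alpha, fdr = fdr, lower = lower, upper = upper)
  )
  class(out) <- c("rp_dtg_table", "data.frame")
  out
}

#' @export
print.rp_dtg_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "riboTE DTG calls: %d up, %d down, %d unchanged (of %d genes)\n",
    s$n_up, s$n_down, s$n_unchanged, nrow(x)
  ))
  invisible(x)
}

#' Full treatment-vs-control differential translation analysis
#'
#' Convenience wrapper: builds replicate log2 TE matrices from a TE table,
#' runs the Welch test, BH correction and DTG calling.
#'
#' @param te an `rp_te_table` containing both conditions.
#' @inheritParams log2_te_change
#' @inheritParams call_dtgs
#' @return an `rp_dtg_table` (see [call_dtgs()]).
#' @export
dtg_analysis <- function(te, treatment = "treatment", control = "control",
                         alpha = 0.05, fdr = 0.05,
                         lower = 0.667, upper = 1.5) {
  mt <- .rp_log2te_matrix(te, treatment)
  mc <- .rp_log2te_matrix(te, control)
  genes <- intersect(rownames(mt), rownames(mc))
  mt <- mt[genes, , drop = FALSE]
  mc <- mc[genes, , drop = FALSE]
  tst <- test_differential_te(mt, mc)
  lfc <- log2_te_change(te, te, treatment, control)
  rec <- data.frame(
    gene_id = genes,
    log2_te_change = lfc$log2_te_change[match(genes, lfc$gene_id)],
    p_value = tst$p_value,
    stringsAsFactors = FALSE
  )
  rec$p_value[rec$gene_id %in% lfc$gene_id[lfc$excluded]] <- NA_real_
  rec$q_value <- bh_fdr(rec$p_value)
  call_dtgs(rec, alpha = alpha, fdr = fdr, lower = lower, upper = upper)
}

#' Squared Pearson correlation between two per-gene vectors
#'
#' The cross-condition concordance statistic (an R^2 on matched per-gene
#' values, e.g. mRNA RPKM or log2 TE of two genotypes).
#'
#' @param x,y matched numeric vectors, length >= 3.
#' @return squared Pearson correlation coefficient.
#' @export
condition_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must be matched", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 matched genes", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in one of the vectors", call. = FALSE)
  }
  cor(x, y)^2
}

#' Write DTG table and summary
#' @param dtg an `rp_dtg_table`.
#' @param path output TSV path; the JSON summary takes the same stem.
#' @return `path`, invisibly.
#' @export
write_dtg_table <- function(dtg, path) {
  .rp_write_tsv(
    as.data.frame(dtg)[c("gene_id", "log2_te_change", "ratio", "p_value", "q_value", "call")],
    path
  )
  s <- attr(dtg, "summary")
  jsonlite::write_json(s, paste0(sub("\\.tsv$", "", path), "_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
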