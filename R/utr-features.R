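# 5'UTR sequence-feature battery: length, GC content, base-pair folding
# score, upstream ORFs, terminal oligopyrimidine (TOP) tracts, and
# predicted G-quadruplex (PG4) motifs, plus the up- vs down-regulated
# feature comparison.

#' GC content of a sequence
#'
#' @param seq nucleotide string over A/C/G/T/U (case-insensitive).
#' @return fraction of G+C in `[0, 1]`.
#' @export
#' @examples
#' gc_content("GATC") # 0.5
gc_content <- function(seq) {
  s <- .rp_seq_chars(.rp_norm_seq(seq))
  mean(s %in% c("G", "C"))
}

#' Minimum base-pair folding score (Nussinov-style DP)
#'
#' Minimum score over all nested (pseudoknot-free) secondary structures
#' under an additive base-pair scoring model, computed by interval dynamic
#' programming. Hairpin loops shorter than `min_loop` are forbidden. This
#' is a deterministic, exhaustively testable proxy for a thermodynamic
#' folding free energy: more negative means more potential structure. It is
#' not a nearest-neighbor energy model.
#'
#' @inheritParams gc_content
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @param pair_scores named numeric vector with elements `GC`, `AU`, `GU`
#'   (all must be <= 0).
#' @return the minimum (most negative) structure score; 0 if no pair is
#'   possible.
#' @export
#' @examples
#' fold_energy("AAAA") # 0
#' fold_energy("GGGAAACCC") # -9
fold_energy <- function(seq, min_loop = 3L,
                        pair_scores = c(GC = -3, AU = -2, GU = -1)) {
  s <- .rp_seq_chars(.rp_norm_seq(seq))
  if (any(pair_scores > 0)) {
    stop("pair scores must be <= 0", call. = FALSE)
  }
  enc <- match(s, .RP_BASES) - 1L # A=0 C=1 G=2 T(U)=3
  .nussinov_min_energy(
    enc, as.integer(min_loop),
    as.numeric(pair_scores[["GC"]]),
    as.numeric(pair_scores[["AU"]]),
    as.numeric(pair_scores[["GU"]])
  )
}

#' Find upstream ORFs in a 5'UTR
#'
#' Every AUG in the 5'UTR followed by an in-frame stop codon fully inside
#' the UTR is a uORF (reported with `overlaps_cds = FALSE`); AUGs with no
#' in-frame UTR stop run into the main CDS and are reported with
#' `overlaps_cds = TRUE`. ORFs spanning fewer than `min_codons` codons
#' (counting the AUG, excluding the stop) are dropped.
#'
#' @param utr5_seq the full 5'UTR sequence.
#' @param cds_offset position of the CDS start = UTR length (defaults to
#'   `nchar(utr5_seq)`); retained for explicitness.
#' @param min_codons minimum ORF length in codons (AUG included, stop
#'   excluded).
#' @return data.frame with 0-based half-open `start`, `end` (end of the
#'   stop codon, or of the UTR for CDS-overlapping AUGs), `n_codons`,
#'   `overlaps_cds`. Empty UTR gives an empty frame.
#' @export
#' @examples
#' find_uorfs("AAATGGCCTAGCC") # one uORF: ATG GCC TAG
find_uorfs <- function(utr5_seq, cds_offset = nchar(utr5_seq),
                       min_codons = 2L) {
  empty <- data.frame(
    start = integer(0), end = integer(0),
    n_codons = integer(0), overlaps_cds = logical(0)
  )
  if (is.na(utr5_seq) || nchar(utr5_seq) < 3L) {
    return(empty)
  }
  s <- .rp_seq_chars(.rp_norm_seq(utr5_seq, "utr5_seq"))
  L <- length(s)
  starts <- .rp_find_atg(s)
  if (!length(starts)) {
    return(empty)
  }
  rows <- lapply(starts, function(a) {
    # walk codons after the AUG looking for an in-frame stop within the UTR
    q <- a + 3L
    while (q + 2L <= L) {
      codon <- paste(s[q:(q + 2L)], collapse = "")
      if (codon %in% .RP_STOPS) {
        n_cod <- (q - a) / 3L
        if (n_cod < min_codons) {
          return(NULL)
        }
        return(data.frame(
          start = a - 1L, end = q + 2L, n_codons = n_cod,
          overlaps_cds = FALSE
        ))
      }
      q <- q + 3L
    }
    data.frame(
      start = a - 1L, end = L, n_codons = (L - a + 1L) %/% 3L,
      overlaps_cds = TRUE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Terminal oligopyrimidine (TOP) motif classifier
#'
#' TRUE iff the first transcribed base is C and it is followed by an
#' uninterrupted pyrimidine (C/U) run of at least `min_pyrimidines` bases
#' (the run is examined up to `max_pyrimidines` bases).
#'
#' @inheritParams find_uorfs
#' @param min_pyrimidines minimum pyrimidine run length after the leading C.
#' @param max_pyrimidines how far past the leading C the run is examined.
#' @return logical.
#' @export
#' @examples
#' has_top_motif("CUUUUGA") # TRUE
#' has_top_motif("GUUUU") # FALSE
has_top_motif <- function(utr5_seq, min_pyrimidines = 4L,
                          max_pyrimidines = 15L) {
  s <- .rp_seq_chars(.rp_norm_seq(utr5_seq, "utr5_seq"))
  if (s[1L] != "C" || length(s) < 1L + min_pyrimidines) {
    return(FALSE)
  }
  run <- 0L
  for (i in seq(2L, min(length(s), max_pyrimidines + 1L))) {
    if (s[i] %in% c("C", "T")) run <- run + 1L else break
  }
  run >= min_pyrimidines
}

# does a PG4 match start at 1-based position i? returns the longest match
# length, or 0; exhaustive over loop lengths, preferring longer matches
.rp_pg4_at <- function(s, i, g_run, loop_max) {
  L <- length(s)
  grun_len <- function(p) {
    n <- 0L
    while (p + n <= L && s[p + n] == "G") n <- n + 1L
    n
  }
  best <- 0L
  # depth-first over the four G-runs and three loops; runs take their
  # maximal extent (a maximal G-run followed by a loop cannot be shortened
  # usefully: trailing Gs may instead be absorbed by the loop)
  recurse <- function(p, runs_done) {
    r <- grun_len(p)
    if (r < g_run) {
      return(invisible(NULL))
    }
    if (runs_done == 3L) {
      best <<- max(best, p + r - i)
      return(invisible(NULL))
    }
    # the run may end anywhere from g_run to its maximal extent; the
    # remainder of the G block is then part of the loop
    for (use in seq.int(g_run, r)) {
      for (loop in seq_len(loop_max)) {
        nxt <- p + use + loop
        if (nxt > L) break
        recurse(nxt, runs_done + 1L)
      }
    }
    invisible(NULL)
  }
  recurse(i, 0L)
  best
}

#' Predicted G-quadruplex (PG4) motifs
#'
#' Scans for the canonical pattern of four G-runs of length >= `g_run`
#' separated by three loops of 1..`loop_max` arbitrary bases
#' (`G{3,}(N{1,7}G{3,}){3}` by default). Matches are taken leftmost-first;
#' at each position the longest valid match is used; matches do not
#' overlap.
#'
#' @inheritParams gc_content
#' @param g_run minimum G-run length.
#' @param loop_max maximum loop length.
#' @return data.frame with 0-based half-open `start`, `end` per match.
#' @export
#' @examples
#' find_pg4("GGGAGGGAGGGAGGG") # one match spanning the whole string
find_pg4 <- function(seq, g_run = 3L, loop_max = 7L) {
  s <- .rp_seq_chars(.rp_norm_seq(seq))
  L <- length(s)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  min_len <- 4L * g_run + 3L
  while (i + min_len - 1L <= L) {
    if (s[i] == "G") {
      len <- .rp_pg4_at(s, i, g_run, loop_max)
      if (len > 0L) {
        starts <- c(starts, i - 1L)
        ends <- c(ends, i - 1L + len)
        i <- i + len
        next
      }
    }
    i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Per-gene 5'UTR feature table
#'
#' Computes the full feature battery for each gene's 5'UTR: length, GC
#' fraction, folding score (raw and per-nucleotide), uORF count (AUGs
#' running into the CDS counted separately), TOP membership and PG4 count.
#'
#' @param genes gene models with sequences.
#' @param gene_ids optional subset of gene ids (folding is cubic in UTR
#'   length; restrict to the genes under comparison when possible).
#' @param min_codons,min_pyrimidines,g_run,loop_max,min_loop,pair_scores
#'   passed to the individual detectors.
#' @param compute_fold set FALSE to skip the (cubic-time) folding DP and
#'   report NA fold energies, e.g. when only motif features are needed.
#' @return data.frame with gene_id, utr5_length, gc, fold_energy,
#'   fold_energy_per_nt, n_uorfs, n_uorfs_overlapping, has_top, n_pg4.
#' @export
utr_feature_table <- function(genes, gene_ids = NULL, min_codons = 2L,
                              min_pyrimidines = 4L, g_run = 3L,
                              loop_max = 7L, min_loop = 3L,
                              pair_scores = c(GC = -3, AU = -2, GU = -1),
                              compute_fold = TRUE) {
  g <- .rp_genes_df(genes)
  if (!"sequence" %in% names(g)) {
    stop("gene table lacks sequences", call. = FALSE)
  }
  if (!is.null(gene_ids)) {
    g <- g[g$gene_id %in% gene_ids, , drop = FALSE]
  }
  utr5 <- substr(g$sequence, 1L, g$cds_start)
  rows <- lapply(seq_len(nrow(g)), function(i) {
    u <- utr5[i]
    uorfs <- find_uorfs(u, min_codons = min_codons)
    data.frame(
      gene_id = g$gene_id[i],
      utr5_length = nchar(u),
      gc = gc_content(u),
      fold_energy = if (compute_fold) {
        fold_energy(u, min_loop = min_loop, pair_scores = pair_scores)
      } else {
        NA_real_
      },
      n_uorfs = sum(!uorfs$overlaps_cds),
      n_uorfs_overlapping = sum(uorfs$overlaps_cds),
      has_top = has_top_motif(u, min_pyrimidines = min_pyrimidines),
      n_pg4 = nrow(find_pg4(u, g_run = g_run, loop_max = loop_max)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fold_energy_per_nt <- out$fold_energy / pmax(out$utr5_length, 1L)
  rownames(out) <- NULL
  out
}

#' Compare one 5'UTR feature between two gene sets
#'
#' Continuous features (`utr5_length`, `gc`, `fold_energy`,
#' `fold_energy_per_nt`) are compared with a two-sided Mann-Whitney U test
#' (Welch t optional); binary incidences (`has_top`, `n_uorfs` > 0,
#' `n_pg4` > 0) with a two-sided Fisher exact test on the 2x2 table.
#'
#' @param up_rows,down_rows feature tables from [utr_feature_table()] for
#'   the two gene sets (e.g. up- and down-regulated DTGs).
#' @param feature one of `utr5_length`, `gc`, `fold_energy`,
#'   `fold_energy_per_nt`, `n_uorfs`, `has_top`, `n_pg4`.
#' @param test `"auto"` picks Mann-Whitney/Fisher by feature type;
#'   `"welch"` forces a Welch t-test for continuous features.
#' @return one-row data.frame: feature, test, statistic, p_value,
#'   direction (`"up"` if the up set has the larger median/incidence,
#'   `"down"` otherwise, `"none"` on ties), untestable.
#' @export
compare_feature <- function(up_rows, down_rows, feature,
                            test = c("auto", "mannwhitney", "welch", "fisher")) {
  test <- match.arg(test)
  if (nrow(up_rows) == 0L || nrow(down_rows) == 0L) {
    stop("both gene sets must be nonempty", call. = FALSE)
  }
  binary_features <- c("n_uorfs", "has_top", "n_pg4")
  is_binary <- feature %in% binary_features
  if (test == "auto") test <- if (is_binary) "fisher" else "mannwhitney"

  as_incidence <- function(v) {
    if (is.logical(v)) v else v > 0
  }
  x <- up_rows[[feature]]
  y <- down_rows[[feature]]
  if (is.null(x) || is.null(y)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }

  if (test == "fisher") {
    xi <- as_incidence(x)
    yi <- as_incidence(y)
    tab <- matrix(
      c(sum(xi), sum(!xi), sum(yi), sum(!yi)),
      nrow = 2L,
      dimnames = list(c("present", "absent"), c("up", "down"))
    )
    if (all(tab["present", ] == 0) || all(tab["absent", ] == 0)) {
      return(data.frame(
        feature = feature, test = "fisher", statistic = NA_real_,
        p_value = NA_real_, direction = "none", untestable = TRUE,
        stringsAsFactors = FALSE
      ))
    }
    ft <- fisher.test(tab)
    inc_up <- mean(xi)
    inc_down <- mean(yi)
    direction <- if (inc_up > inc_down) "up" else if (inc_up < inc_down) "down" else "none"
    return(data.frame(
      feature = feature, test = "fisher",
      statistic = unname(ft$estimate), p_value = ft$p.value,
      direction = direction, untestable = FALSE,
      stringsAsFactors = FALSE
    ))
  }

  if (length(unique(c(x, y))) == 1L) {
    return(data.frame(
      feature = feature, test = test, statistic = NA_real_,
      p_value = NA_real_, direction = "none", untestable = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  if (test == "welch") {
    ht <- stats::t.test(x, y)
    stat <- unname(ht$statistic)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    stat <- unname(ht$statistic)
  }
  med_up <- stats::median(x)
  med_down <- stats::median(y)
  direction <- if (med_up > med_down) {
    "up"
  } else if (med_up < med_down) {
    "down"
  } else if (mean(x) > mean(y)) {
    "up"
  } else if (mean(x) < mean(y)) {
    "down"
  } else {
    "none"
  }
  data.frame(
    feature = feature, test = test, statistic = stat,
    p_value = ht$p.value, direction = direction, untestable = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Feature comparison table for up- vs down-regulated gene sets
#'
#' Runs [compare_feature()] for the standard feature battery.
#' @inheritParams compare_feature
#' @param features features to compare.
#' @return data.frame, one row per feature.
#' @export
compare_all_features <- function(up_rows, down_rows,
                                 features = c(
                                   "utr5_length", "gc", "fold_energy",
                                   "fold_energy_per_nt", "n_uorfs",
                                   "has_top", "n_pg4"
                                 )) {
  out <- do.call(rbind, lapply(
    features,
    function(f) compare_feature(up_rows, down_rows, f)
  ))
  rownames(out) <- NULL
  out
}
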