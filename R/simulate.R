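# Synthetic transcriptome and library generator.
#
# Transcript-space simulation only: each gene is one transcript laid out as
# 5'UTR | CDS | 3'UTR in 0-based half-open coordinates; there is no genome,
# splicing, strand, or sequencing-error model.

# sample n bases at a given GC fraction
.rp_rand_bases <- function(n, gc) {
  sample(.RP_BASES, n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  )
}

# all 64 codons in fixed order
.rp_codon_table <- function() {
  as.vector(outer(
    outer(.RP_BASES, .RP_BASES, paste0), .RP_BASES, paste0
  ))
}

# codon sampling probabilities implied by a base GC fraction, with the three
# stop codons zeroed (used for internal CDS codons)
.rp_codon_probs <- function(gc, stops_only = FALSE) {
  pb <- c(
    A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2
  )
  codons <- .rp_codon_table()
  p <- vapply(strsplit(codons, ""), function(b) prod(pb[b]), numeric(1))
  names(p) <- codons
  if (stops_only) {
    p[!names(p) %in% .RP_STOPS] <- 0
  } else {
    p[.RP_STOPS] <- 0
  }
  p / sum(p)
}

# ATG + internal non-stop codons + stop codon, as a character string
.rp_rand_cds <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 6)
  n_internal <- len / 3 - 2L
  internal <- if (n_internal > 0) {
    p <- .rp_codon_probs(gc)
    paste(sample(names(p), n_internal, replace = TRUE, prob = p),
      collapse = ""
    )
  } else {
    ""
  }
  ps <- .rp_codon_probs(gc, stops_only = TRUE)
  stop_codon <- sample(names(ps)[ps > 0], 1L, prob = ps[ps > 0])
  paste0("ATG", internal, stop_codon)
}

# indices i where chars[i..i+2] == ATG
.rp_find_atg <- function(chars) {
  n <- length(chars)
  if (n < 3L) {
    return(integer(0))
  }
  i <- seq_len(n - 2L)
  i[chars[i] == "A" & chars[i + 1L] == "T" & chars[i + 2L] == "G"]
}

# remove every ATG trinucleotide by mutating its G to C (cannot create a
# new ATG, so one pass suffices)
.rp_scrub_atg <- function(chars) {
  hits <- .rp_find_atg(chars)
  if (length(hits)) chars[hits + 2L] <- "C"
  chars
}

# Plant requested features into a 5'UTR (character vector), preserving a
# clean ground truth: non-planted UTRs carry no AUG, and a planted uORF is
# never destroyed by a later planting step. Returns the modified chars plus
# the flags actually realized (a plant can fail for lack of space).
.rp_plant_utr5 <- function(chars, plant_top, plant_uorf, plant_pg4) {
  L <- length(chars)
  top_zone <- 0L
  uorf_iv <- NULL
  pg4_iv <- NULL
  planted <- c(top = FALSE, uorf = FALSE, pg4 = FALSE)

  chars <- .rp_scrub_atg(chars)

  if (plant_top && L >= 5L) {
    k <- sample(4:14, 1L) # pyrimidine run length after the cap-adjacent C
    k <- min(k, L - 1L)
    chars[1L] <- "C"
    chars[seq(2L, k + 1L)] <- sample(c("C", "T"), k, replace = TRUE)
    top_zone <- k + 1L
    planted["top"] <- TRUE
  } else if (chars[1L] == "C") {
    # keep natural TOP starts out of non-planted genes
    chars[1L] <- if (L >= 3L && chars[2L] == "T" && chars[3L] == "G") "G" else "A"
  }

  reserve <- max(16L, top_zone + 1L)
  if (plant_uorf && L - reserve + 1L >= 9L) {
    ustart <- reserve + sample.int(L - 8L - reserve + 1L, 1L) - 1L
    chars[ustart:(ustart + 8L)] <- c("A", "T", "G", "G", "C", "C", "T", "A", "A")
    uorf_iv <- c(ustart, ustart + 8L)
    planted["uorf"] <- TRUE
  }

  if (plant_pg4 && L - reserve + 1L >= 15L) {
    motif <- strsplit("GGGAGGGAGGGAGGG", "")[[1L]]
    cand <- seq.int(reserve, L - 14L)
    if (!is.null(uorf_iv)) {
      cand <- cand[cand + 14L < uorf_iv[1L] | cand > uorf_iv[2L]]
    }
    if (length(cand)) {
      s <- cand[sample.int(length(cand), 1L)]
      chars[s:(s + 14L)] <- motif
      pg4_iv <- c(s, s + 14L)
      planted["pg4"] <- TRUE
    }
  }

  # remove any spurious AUG created at a planting junction; mutate the first
  # base of the offending triplet that lies outside protected intervals
  protected <- function(p) {
    (!is.null(uorf_iv) && p >= uorf_iv[1L] && p <= uorf_iv[2L]) ||
      (!is.null(pg4_iv) && p >= pg4_iv[1L] && p <= pg4_iv[2L])
  }
  repeat {
    hits <- .rp_find_atg(chars)
    if (!is.null(uorf_iv)) hits <- setdiff(hits, uorf_iv[1L])
    if (!length(hits)) break
    p <- hits[1L]
    for (q in p:(p + 2L)) {
      if (!protected(q)) {
        chars[q] <- "C"
        break
      }
    }
  }

  list(chars = chars, planted = planted)
}

#' Simulate a transcriptome with planted condition classes and 5'UTR features
#'
#' Generates `n_genes` transcripts (5'UTR | CDS | 3'UTR). Every CDS begins
#' with ATG, ends with a stop codon, has length divisible by 3, and contains
#' no in-frame internal stop. 5'UTRs of non-planted genes are scrubbed of
#' AUG so that uORF ground truth is exact; planted features (uORF, TOP,
#' G-quadruplex, high GC, extended length) are recorded in the returned
#' ground-truth table.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `rp_transcriptome`: a list with
#'   `genes` (data.frame: gene_id, sequence, utr5_len, cds_len, utr3_len,
#'   tx_len, cds_start, cds_end, condition_class, abundance, true_log2_te),
#'   `truth` (per-gene planted-feature table) and `config`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "rp_sim_config"))
  withr::with_seed(.rp_subseed(config$seed, 1L), {
    n <- config$n_genes
    gene_id <- sprintf("g%04d", seq_len(n))

    # condition classes: te_effect_genes split evenly into up/down
    n_eff <- round(config$te_effect_genes * n)
    n_up <- ceiling(n_eff / 2)
    n_down <- n_eff - n_up
    condition_class <- rep("null", n)
    if (n_eff > 0) {
      idx <- sample.int(n, n_eff)
      condition_class[idx[seq_len(n_up)]] <- "te_up"
      if (n_down > 0) condition_class[idx[n_up + seq_len(n_down)]] <- "te_down"
    }
    true_log2_te <- ifelse(condition_class == "te_up", config$te_log2_effect,
      ifelse(condition_class == "te_down", -config$te_log2_effect, 0)
    )

    abundance <- rlnorm(n, config$abundance_log_mean, config$abundance_log_sd)

    # per-gene feature plants: feature_plant probs on te_up, background else
    draw_feat <- function(feat) {
      p <- ifelse(condition_class == "te_up",
        config$feature_plant[[feat]], config$feature_background[[feat]]
      )
      runif(n) < p
    }
    want <- list(
      uorf = draw_feat("uorf"), top = draw_feat("top"),
      pg4 = draw_feat("pg4"), high_gc = draw_feat("high_gc"),
      long_utr = draw_feat("long_utr")
    )

    rng_int <- function(r, k) r[1] + sample.int(r[2] - r[1] + 1L, k, replace = TRUE) - 1L
    utr5_len <- rng_int(config$utr5_length_range, n) +
      ifelse(want$long_utr, config$long_utr_shift, 0L)
    cds_len <- as.integer(round(rng_int(config$cds_length_range, n) / 3) * 3)
    cds_len <- pmax(cds_len, 6L)
    utr3_len <- rng_int(config$utr3_length_range, n)

    sequence <- character(n)
    planted <- matrix(FALSE, n, 3L, dimnames = list(NULL, c("uorf", "top", "pg4")))
    for (i in seq_len(n)) {
      gc5 <- min(
        config$gc_background + if (want$high_gc[i]) config$high_gc_boost else 0,
        0.95
      )
      u5 <- .rp_plant_utr5(
        .rp_rand_bases(utr5_len[i], gc5),
        want$top[i], want$uorf[i], want$pg4[i]
      )
      planted[i, ] <- u5$planted[c("uorf", "top", "pg4")]
      sequence[i] <- paste0(
        paste(u5$chars, collapse = ""),
        .rp_rand_cds(cds_len[i], config$gc_background),
        paste(.rp_rand_bases(utr3_len[i], config$gc_background), collapse = "")
      )
    }

    genes <- data.frame(
      gene_id = gene_id,
      sequence = sequence,
      utr5_len = utr5_len,
      cds_len = cds_len,
      utr3_len = utr3_len,
      tx_len = utr5_len + cds_len + utr3_len,
      cds_start = utr5_len,
      cds_end = utr5_len + cds_len,
      condition_class = condition_class,
      abundance = abundance,
      true_log2_te = true_log2_te,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = gene_id,
      condition_class = condition_class,
      true_log2_te = true_log2_te,
      abundance = abundance,
      utr5_length = utr5_len,
      cds_length = cds_len,
      utr3_length = utr3_len,
      uorf_planted = planted[, "uorf"],
      top_planted = planted[, "top"],
      pg4_planted = planted[, "pg4"],
      high_gc_planted = want$high_gc,
      long_utr_planted = want$long_utr,
      stringsAsFactors = FALSE
    )
    structure(
      list(genes = genes, truth = truth, config = config),
      class = "rp_transcriptome"
    )
  })
}

#' @export
print.rp_transcriptome <- function(x, ...) {
  cat(sprintf(
    "riboTE transcriptome: %d genes (%d te_up, %d te_down)\n",
    nrow(x$genes),
    sum(x$genes$condition_class == "te_up"),
    sum(x$genes$condition_class == "te_down")
  ))
  invisible(x)
}

# accept rp_transcriptome or its $genes data.frame
.rp_genes_df <- function(genes) {
  if (inherits(genes, "rp_transcriptome")) {
    return(genes$genes)
  }
  stopifnot(is.data.frame(genes), all(c(
    "gene_id", "tx_len", "cds_start", "cds_end"
  ) %in% names(genes)))
  genes
}

#' Simulate paired footprint and total-mRNA libraries
#'
#' For each of the `2 * n_replicates` samples, emits exactly
#' `reads_per_library` footprint reads and `reads_per_library` total-mRNA
#' fragments. Footprint reads are placed so the P-site
#' (5' end + `psite_offset`) falls on a uniformly chosen CDS codon, in frame
#' 0 with probability `periodicity` (frames 1/2 equally otherwise), with
#' lengths drawn from `footprint_length_weights`. mRNA fragments are uniform
#' over the transcript. Per-gene read allocation is proportional to
#' abundance times feature length (CDS for footprints, transcript for mRNA),
#' with footprint allocation multiplied by `2^(+-te_log2_effect)` for
#' planted genes in the treatment condition only, making TE identifiable
#' and centered at 1 for null genes.
#'
#' @param genes an `rp_transcriptome` or its `genes` data.frame.
#' @param config the [sim_config()] used (supplies depths, weights, seed).
#' @return data.frame of read alignments with columns gene_id, start
#'   (0-based transcript position of the 5' end), length, library
#'   ("footprint" or "mrna"), sample, condition, replicate.
#' @export
simulate_libraries <- function(genes, config) {
  stopifnot(inherits(config, "rp_sim_config"))
  g <- .rp_genes_df(genes)
  if (nrow(g) == 0L) stop("no genes supplied", call. = FALSE)
  if (config$reads_per_library <= 0L) {
    stop("reads_per_library must be positive", call. = FALSE)
  }
  if (!"abundance" %in% names(g)) {
    stop("gene table lacks an `abundance` column", call. = FALSE)
  }

  max_fp <- max(as.integer(names(config$footprint_length_weights)))
  off <- config$psite_offset
  # eligibility: footprints need room for the 5' overhang before the CDS and
  # the 3' overhang past the last codon; mRNA fragments need the transcript
  # to be at least as long as the largest fragment
  ok_fp <- g$cds_start >= off &
    (g$tx_len - g$cds_end + 1L + off) >= max_fp
  ok_m <- g$tx_len >= config$mrna_length_range[2]
  if (any(!ok_fp)) {
    warning(sum(!ok_fp), " gene(s) too short for footprint placement; skipped")
  }
  if (any(!ok_m)) {
    warning(sum(!ok_m), " gene(s) shorter than the longest mRNA fragment; skipped")
  }
  if (!any(ok_fp) || !any(ok_m)) {
    stop("no gene can accommodate the configured fragment lengths", call. = FALSE)
  }

  effect_mult <- if ("true_log2_te" %in% names(g)) 2^g$true_log2_te else rep(1, nrow(g))
  conditions <- c("control", "treatment")
  fp_lens <- as.integer(names(config$footprint_length_weights))
  fp_w <- as.numeric(config$footprint_length_weights)
  per <- config$periodicity

  out <- vector("list", 2L * config$n_replicates * 2L)
  k <- 0L
  for (cond in conditions) {
    for (rep_i in seq_len(config$n_replicates)) {
      for (lib in c("footprint", "mrna")) {
        k <- k + 1L
        smp <- sprintf("%s_rep%d_%s", cond, rep_i, lib)
        seed_k <- .rp_subseed(config$seed, 100L + k)
        out[[k]] <- withr::with_seed(seed_k, {
          if (lib == "footprint") {
            w <- g$abundance * g$cds_len *
              (if (cond == "treatment") effect_mult else 1)
            w[!ok_fp] <- 0
            cnt <- as.vector(rmultinom(1L, config$reads_per_library, w))
            gi <- rep.int(seq_len(nrow(g)), cnt)
            nr <- length(gi)
            len <- fp_lens[sample.int(length(fp_lens), nr,
              replace = TRUE, prob = fp_w
            )]
            f <- sample.int(3L, nr,
              replace = TRUE,
              prob = c(per, (1 - per) / 2, (1 - per) / 2)
            ) - 1L
            n_cod <- g$cds_len[gi] %/% 3L
            u <- floor(runif(nr) * n_cod)
            psite <- g$cds_start[gi] + 3L * u + f
            start <- as.integer(psite - off)
          } else {
            w <- g$abundance * g$tx_len
            w[!ok_m] <- 0
            cnt <- as.vector(rmultinom(1L, config$reads_per_library, w))
            gi <- rep.int(seq_len(nrow(g)), cnt)
            nr <- length(gi)
            lr <- config$mrna_length_range
            len <- lr[1] + as.integer(floor(runif(nr) * (lr[2] - lr[1] + 1L)))
            start <- as.integer(floor(runif(nr) * (g$tx_len[gi] - len + 1L)))
          }
          data.frame(
            gene_id = g$gene_id[gi],
            start = start,
            length = len,
            library = lib,
            sample = smp,
            condition = cond,
            replicate = rep_i,
            stringsAsFactors = FALSE
          )
        })
      }
    }
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  reads
}
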