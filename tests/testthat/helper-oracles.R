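# Independent oracles used across the suite. Each one is a deliberately
# naive reference implementation (enumeration / per-read loops), kept free
# of any code path it is used to check.

# --- folding ----------------------------------------------------------------

# all nested structures of s[i..j] as lists of pair index matrices (1-based),
# including the empty structure
oracle_all_structures <- function(s, i, j, min_loop = 3L) {
  if (i >= j) {
    return(list(matrix(integer(0), ncol = 2)))
  }
  res <- lapply(
    oracle_all_structures(s, i + 1L, j, min_loop),
    identity
  ) # i unpaired
  pairable <- function(a, b) {
    p <- paste0(s[a], s[b])
    p %in% c("GC", "CG", "AT", "TA", "GT", "TG")
  }
  for (k in seq.int(i + min_loop + 1L, j)) {
    if (k > j) break
    if (!pairable(i, k)) next
    left <- oracle_all_structures(s, i + 1L, k - 1L, min_loop)
    right <- oracle_all_structures(s, k + 1L, j, min_loop)
    for (L in left) {
      for (R in right) {
        res[[length(res) + 1L]] <- rbind(matrix(c(i, k), ncol = 2), L, R)
      }
    }
  }
  res
}

# minimum score over explicitly enumerated structures
oracle_fold_energy <- function(seq, min_loop = 3L,
                               scores = c(CG = -3, AT = -2, GT = -1)) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1L]]
  n <- length(s)
  if (n < 2L) {
    return(0)
  }
  structs <- oracle_all_structures(s, 1L, n, min_loop)
  score_of <- function(m) {
    if (nrow(m) == 0L) {
      return(0)
    }
    sum(apply(m, 1L, function(pr) {
      p <- paste0(sort(c(s[pr[1]], s[pr[2]])), collapse = "")
      scores[[p]]
    }))
  }
  min(vapply(structs, score_of, numeric(1)))
}

# --- uORFs ------------------------------------------------------------------

# brute-force scan over every position: ATG -> walk codons to stop
oracle_uorfs <- function(utr, min_codons = 2L) {
  s <- strsplit(toupper(chartr("U", "T", utr)), "")[[1L]]
  L <- length(s)
  out <- list()
  for (a in seq_len(max(L - 2L, 0L))) {
    if (!(s[a] == "A" && s[a + 1L] == "T" && s[a + 2L] == "G")) next
    found <- FALSE
    q <- a + 3L
    while (q + 2L <= L) {
      cod <- paste0(s[q], s[q + 1L], s[q + 2L])
      if (cod %in% c("TAA", "TAG", "TGA")) {
        if ((q - a) / 3L >= min_codons) {
          out[[length(out) + 1L]] <-
            c(start = a - 1L, end = q + 2L, overlaps = 0L)
        }
        found <- TRUE
        break
      }
      q <- q + 3L
    }
    if (!found) {
      out[[length(out) + 1L]] <- c(start = a - 1L, end = L, overlaps = 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0), overlaps = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# --- PG4 --------------------------------------------------------------------

# exhaustive: longest valid match starting at i by trying every
# decomposition (4 run lengths x 3 loop lengths) against the string
oracle_pg4_match_at <- function(s, i, g_run = 3L, loop_max = 7L) {
  L <- length(s)
  best <- 0L
  run_ok <- function(p, r) p + r - 1L <= L && all(s[p:(p + r - 1L)] == "G")
  max_r <- L # run_ok() breaks each loop at the first infeasible length
  for (r1 in g_run:max_r) {
    if (!run_ok(i, r1)) break
    for (l1 in 1:loop_max) {
      p2 <- i + r1 + l1
      for (r2 in g_run:max_r) {
        if (!run_ok(p2, r2)) break
        for (l2 in 1:loop_max) {
          p3 <- p2 + r2 + l2
          for (r3 in g_run:max_r) {
            if (!run_ok(p3, r3)) break
            for (l3 in 1:loop_max) {
              p4 <- p3 + r3 + l3
              for (r4 in g_run:max_r) {
                if (!run_ok(p4, r4)) break
                best <- max(best, p4 + r4 - i)
              }
            }
          }
        }
      }
    }
  }
  best
}

oracle_pg4 <- function(seq, g_run = 3L, loop_max = 7L) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1L]]
  L <- length(s)
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  while (i <= L) {
    len <- oracle_pg4_match_at(s, i, g_run, loop_max)
    if (len > 0L) {
      starts <- c(starts, i - 1L)
      ends <- c(ends, i - 1L + len)
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

# --- hypergeometric ---------------------------------------------------------

# exact upper-tail overlap probability by enumerating all C(N, q) draws
oracle_hypergeom <- function(universe_size, set_size, query_size, overlap) {
  stopifnot(universe_size <= 15)
  draws <- utils::combn(universe_size, query_size)
  in_set <- seq_len(set_size) # WLOG the set is the first set_size elements
  hits <- apply(draws, 2L, function(d) sum(d %in% in_set) >= overlap)
  mean(hits)
}

# --- counting ---------------------------------------------------------------

# per-read loop classification
oracle_count <- function(reads, genes, mode, psite_offset = 12L) {
  g <- if (inherits(genes, "rp_transcriptome")) genes$genes else genes
  smp <- sort(unique(reads$sample))
  counts <- matrix(0L, nrow(g), length(smp), dimnames = list(g$gene_id, smp))
  for (r in seq_len(nrow(reads))) {
    gi <- match(reads$gene_id[r], g$gene_id)
    keep <- if (mode == "cds_psite") {
      ps <- reads$start[r] + psite_offset
      ps >= g$cds_start[gi] && ps < g$cds_end[gi]
    } else {
      TRUE
    }
    if (keep) {
      j <- match(reads$sample[r], smp)
      counts[gi, j] <- counts[gi, j] + 1L
    }
  }
  counts
}

# --- misc -------------------------------------------------------------------

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
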