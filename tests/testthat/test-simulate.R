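# synthetic_data module

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(n_genes = 5), "rp_sim_config")
  expect_error(sim_config(utr5_length_range = c(100, 50)), "min > max")
  expect_error(sim_config(cds_length_range = c(3, 300)), ">= 6")
  expect_error(sim_config(periodicity = 1.2), "probability")
  expect_error(
    sim_config(footprint_length_weights = c("28" = 0.5, "29" = 0.4)),
    "sum to 1"
  )
  expect_error(
    sim_config(footprint_length_weights = c("20" = 1)),
    "28..32"
  )
  expect_error(sim_config(feature_plant = list(bogus = 1)), "unknown feature")
  # CDS range forced to multiples of 3
  expect_equal(sim_config(cds_length_range = c(10, 100))$cds_length_range[1] %% 3, 0)
})

test_that("a forced 9-nt CDS is ATG + codon + stop", {
  cfg <- sim_config(
    n_genes = 1, cds_length_range = c(9, 9),
    utr5_length_range = c(30, 30), utr3_length_range = c(30, 30),
    te_effect_genes = 0, seed = 3
  )
  tx <- simulate_transcriptome(cfg)
  g <- tx$genes
  expect_equal(g$cds_len, 9L)
  cds <- substr(g$sequence, g$cds_start + 1, g$cds_end)
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, 7, 9) %in% c("TAA", "TAG", "TGA"))
})

test_that("generated gene models satisfy their invariants", {
  cfg <- sim_config(n_genes = 80, seed = 11)
  tx <- simulate_transcriptome(cfg)
  g <- tx$genes
  # intervals tile the transcript
  expect_equal(g$utr5_len + g$cds_len + g$utr3_len, g$tx_len)
  expect_equal(nchar(g$sequence), g$tx_len)
  expect_equal(g$cds_start, g$utr5_len)
  expect_true(all(g$cds_len %% 3 == 0))
  for (i in seq_len(nrow(g))) {
    cds <- substr(g$sequence[i], g$cds_start[i] + 1, g$cds_end[i])
    codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    expect_equal(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("identical config + seed reproduces byte-identical outputs", {
  cfg <- sim_config(n_genes = 30, reads_per_library = 5000, seed = 99)
  tx1 <- simulate_transcriptome(cfg)
  tx2 <- simulate_transcriptome(cfg)
  expect_identical(tx1$genes, tx2$genes)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_transcriptome_fasta(tx1, f1)
  write_transcriptome_fasta(tx2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  r1 <- simulate_libraries(tx1, cfg)
  r2 <- simulate_libraries(tx2, cfg)
  expect_identical(r1, r2)
  # and a different seed gives different reads
  cfg2 <- sim_config(n_genes = 30, reads_per_library = 5000, seed = 100)
  r3 <- simulate_libraries(simulate_transcriptome(cfg2), cfg2)
  expect_false(identical(r1, r3))
})

test_that("planted uORFs are re-detectable and non-planted UTRs are clean", {
  cfg <- sim_config(
    n_genes = 60,
    feature_plant = list(uorf = 1.0),
    feature_background = list(uorf = 0),
    seed = 5
  )
  tx <- simulate_transcriptome(cfg)
  g <- tx$genes
  truth <- tx$truth
  utr5 <- substr(g$sequence, 1, g$cds_start)
  n_uorf <- vapply(utr5, function(u) {
    uo <- find_uorfs(u)
    sum(!uo$overlaps_cds)
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(n_uorf[truth$uorf_planted] >= 1))
  expect_true(all(n_uorf[!truth$uorf_planted] == 0))
})

test_that("planted TOP and PG4 motifs are re-detectable", {
  cfg <- sim_config(
    n_genes = 60,
    feature_plant = list(top = 1.0, pg4 = 1.0),
    feature_background = list(),
    seed = 6
  )
  tx <- simulate_transcriptome(cfg)
  g <- tx$genes
  truth <- tx$truth
  utr5 <- substr(g$sequence, 1, g$cds_start)
  top <- vapply(utr5, has_top_motif, logical(1), USE.NAMES = FALSE)
  pg4 <- vapply(utr5, function(u) nrow(find_pg4(u)), numeric(1), USE.NAMES = FALSE)
  expect_true(all(top[truth$top_planted]))
  expect_true(all(!top[!truth$top_planted]))
  expect_true(all(pg4[truth$pg4_planted] >= 1))
})

test_that("libraries have exact depth, valid bounds, and correct lengths", {
  cfg <- small_sim()
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_libraries(tx, cfg)
  per_lib <- table(reads$sample)
  expect_true(all(per_lib == cfg$reads_per_library))
  expect_equal(length(per_lib), 2L * cfg$n_replicates * 2L)
  g <- tx$genes
  i <- match(reads$gene_id, g$gene_id)
  expect_true(all(reads$start >= 0))
  expect_true(all(reads$start + reads$length <= g$tx_len[i]))
  fp <- reads$library == "footprint"
  expect_true(all(reads$length[fp] %in% 28:32))
  expect_true(all(reads$length[!fp] >= cfg$mrna_length_range[1] &
    reads$length[!fp] <= cfg$mrna_length_range[2]))
})

test_that("footprint length frequencies converge to the configured weights", {
  cfg <- sim_config(n_genes = 50, reads_per_library = 1e5, n_replicates = 1, seed = 21)
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_libraries(tx, cfg)
  fp <- reads[reads$library == "footprint" & reads$condition == "control", ]
  obs <- table(factor(fp$length, levels = 28:32))
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = as.numeric(cfg$footprint_length_weights))
  )
  expect_gt(gof$p.value, 0.01)
})

test_that("perfect periodicity forces frame (1, 0, 0)", {
  cfg <- sim_config(
    n_genes = 20, reads_per_library = 3000, periodicity = 1,
    n_replicates = 1, seed = 8
  )
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_libraries(tx, cfg)
  fp <- reads[reads$library == "footprint" & reads$condition == "control", ]
  expect_equal(
    unname(frame_distribution(fp, tx, cfg$psite_offset)),
    c(1, 0, 0)
  )
})

test_that("planted TE effects are recovered at depth (law of large numbers)", {
  # few genes + deep libraries + tight abundance spread so every gene's
  # estimate is well determined
  cfg <- sim_config(
    n_genes = 50, reads_per_library = 2e5, te_effect_genes = 0.2,
    te_log2_effect = 1, n_replicates = 3, abundance_log_sd = 0.3, seed = 31
  )
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_libraries(tx, cfg)
  te <- run_quant(tx, reads)
  lfc <- log2_te_change(te, te)
  truth <- tx$truth
  for (cls in c("te_up", "te_down", "null")) {
    ids <- truth$gene_id[truth$condition_class == cls]
    est <- lfc$log2_te_change[match(ids, lfc$gene_id)]
    expected <- c(te_up = 1, te_down = -1, null = 0)[[cls]]
    expect_true(all(abs(est - expected) < 0.2, na.rm = TRUE),
      label = paste("class", cls)
    )
  }
})

test_that("null config yields near-zero TE changes as depth grows", {
  cfg <- sim_config(
    n_genes = 40, reads_per_library = 5e4, te_effect_genes = 0,
    n_replicates = 2, seed = 13
  )
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_libraries(tx, cfg)
  te <- run_quant(tx, reads)
  lfc <- log2_te_change(te, te)
  expect_lt(mean(abs(lfc$log2_te_change), na.rm = TRUE), 0.1)
})

test_that("degenerate library configs error or warn as specified", {
  cfg <- small_sim()
  tx <- simulate_transcriptome(cfg)
  cfg0 <- cfg
  cfg0$reads_per_library <- 0L
  expect_error(simulate_libraries(tx, cfg0), "positive")
  # genes shorter than the longest mRNA fragment are skipped with a warning
  cfg_short <- sim_config(
    n_genes = 20, utr5_length_range = c(13, 60), cds_length_range = c(9, 9),
    utr3_length_range = c(20, 20), mrna_length_range = c(50, 60),
    reads_per_library = 100, n_replicates = 1, te_effect_genes = 0, seed = 2
  )
  tx_short <- simulate_transcriptome(cfg_short)
  expect_true(any(tx_short$genes$tx_len < 60) && any(tx_short$genes$tx_len >= 60))
  reads_short <- expect_warning(simulate_libraries(tx_short, cfg_short), "skip")
  short_ids <- tx_short$genes$gene_id[tx_short$genes$tx_len < 60]
  expect_false(any(reads_short$gene_id[reads_short$library == "mrna"] %in% short_ids))
})

test_that("FASTA/BED round-trip preserves the gene models", {
  cfg <- sim_config(n_genes = 12, seed = 17)
  tx <- simulate_transcriptome(cfg)
  fa <- tempfile(fileext = ".fasta")
  bed <- tempfile(fileext = ".bed")
  write_transcriptome_fasta(tx, fa)
  write_gene_models_bed(tx, bed)
  g2 <- read_gene_models(bed, fa)
  g1 <- tx$genes[names(g2)]
  expect_equal(g2, g1, ignore_attr = TRUE)
})

test_that("alignment TSV and SAM round-trips preserve the reads", {
  cfg <- sim_config(
    n_genes = 10, reads_per_library = 500, n_replicates = 1, seed = 19
  )
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_libraries(tx, cfg)
  tsv <- tempfile(fileext = ".tsv")
  write_alignments_tsv(reads, tsv)
  back <- read_alignments(tsv)
  expect_equal(back, reads, ignore_attr = TRUE)
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(reads, tx, sam)
  back_sam <- read_alignments(sam)
  key <- function(d) d[order(d$gene_id, d$start, d$length, d$sample), c("gene_id", "start", "length", "library", "sample")]
  expect_equal(key(back_sam), key(reads), ignore_attr = TRUE)
})
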