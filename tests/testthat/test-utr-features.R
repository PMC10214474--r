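# utr_features module

test_that("gc_content on exact cases and input validation", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("gauc"), 0.5) # case and U tolerated
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("ACGN"), "non-nucleotide")
})

test_that("fold_energy on hand-checkable cases", {
  expect_equal(fold_energy("AAAA"), 0) # no pairs possible
  expect_equal(fold_energy("GGGAAACCC"), -9) # three GC pairs, loop 3
  # loop constraint: hairpin shorter than min_loop is forbidden
  expect_equal(fold_energy("GAAAC", min_loop = 3), -3)
  expect_equal(fold_energy("GAAC", min_loop = 3), 0)
  expect_equal(fold_energy("GAAC", min_loop = 2), -3)
  # custom scores flow through
  expect_equal(fold_energy("GGGAAACCC", pair_scores = c(GC = -1, AU = -2, GU = -1)), -3)
  expect_error(fold_energy("GGG", pair_scores = c(GC = 1, AU = -2, GU = -1)), "<= 0")
})

test_that("fold_energy DP equals exhaustive enumeration (short sequences)", {
  withr::with_seed(83, {
    for (i in 1:40) {
      n <- sample(4:12, 1)
      s <- random_seq(n)
      expect_equal(fold_energy(s), oracle_fold_energy(s), label = s)
    }
  })
})

test_that("fold_energy symmetries: reversal always, revcomp without wobble", {
  # NB reverse-complement symmetry cannot hold with GU wobble pairs scored
  # (a G.U pair maps to the unpairable C.A), so it is checked with GU
  # disabled; plain reversal preserves every pair type and must hold with
  # the full scoring.
  rev_s <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rc <- function(s) chartr("ACGT", "TGCA", rev_s(s))
  no_gu <- c(GC = -3, AU = -2, GU = 0)
  withr::with_seed(89, {
    for (i in 1:100) {
      s <- random_seq(12)
      expect_equal(fold_energy(s), fold_energy(rev_s(s)), label = s)
      expect_equal(
        fold_energy(s, pair_scores = no_gu),
        fold_energy(rc(s), pair_scores = no_gu),
        label = s
      )
    }
  })
})

test_that("find_uorfs on constructed cases", {
  # one clean uORF: ATG GCC TAG
  u <- find_uorfs("AAATGGCCTAGCC")
  expect_equal(nrow(u), 1L)
  expect_equal(u$start, 2L)
  expect_equal(u$end, 11L)
  expect_equal(u$n_codons, 2L)
  expect_false(u$overlaps_cds)
  # no AUG -> empty
  expect_equal(nrow(find_uorfs("AAACCC")), 0L)
  # AUG with no in-frame stop -> overlaps_cds
  u2 <- find_uorfs("CCATGAAAAAA")
  expect_equal(nrow(u2), 1L)
  expect_true(u2$overlaps_cds)
  # ORF below min_codons dropped: ATG TAA has 1 codon
  expect_equal(nrow(find_uorfs("CCATGTAACC", min_codons = 2)), 0L)
  expect_equal(nrow(find_uorfs("CCATGTAACC", min_codons = 1)), 1L)
})

test_that("find_uorfs equals the exhaustive scan oracle on random UTRs", {
  withr::with_seed(97, {
    for (i in 1:200) {
      u <- random_seq(sample(10:80, 1))
      got <- find_uorfs(u)
      want <- oracle_uorfs(u)
      expect_equal(nrow(got), nrow(want), label = u)
      if (nrow(got)) {
        expect_equal(got$start, want$start, label = u)
        expect_equal(got$end, want$end, label = u)
        expect_equal(as.integer(got$overlaps_cds), want$overlaps, label = u)
      }
    }
  })
})

test_that("has_top_motif follows the C + pyrimidine-run definition", {
  expect_true(has_top_motif("CUUUUGA"))
  expect_true(has_top_motif("CTTTTGA")) # DNA alphabet equivalent
  expect_false(has_top_motif("GUUUU")) # must start with C
  expect_false(has_top_motif("CUUAG")) # run of 2 < 4
  expect_true(has_top_motif("CCCCCCCCCCCCCCCCCCCC")) # long run still TRUE
  expect_false(has_top_motif("CUUU")) # too short to hold the run
  expect_true(has_top_motif("CUU", min_pyrimidines = 2))
})

test_that("find_pg4 on canonical cases", {
  # canonical quadruplex spans the whole string
  m <- find_pg4("GGGAGGGAGGGAGGG")
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 15L)
  # only two G-runs -> no match
  expect_equal(nrow(find_pg4("GGGAGGG")), 0L)
  # long loops beyond loop_max break the motif
  expect_equal(nrow(find_pg4("GGGAAAAAAAAGGGAGGGAGGG")), 0L)
  expect_equal(nrow(find_pg4("GGGAAAAAAAAGGGAGGGAGGGAGGG")), 1L)
})

test_that("find_pg4 equals the exhaustive oracle on G-rich random strings", {
  withr::with_seed(101, {
    for (i in 1:100) {
      s <- random_seq(80, alphabet = c("G", "G", "A", "T")) # G-rich
      expect_equal(find_pg4(s), oracle_pg4(s), label = s)
    }
  })
})

test_that("utr_feature_table assembles the battery and matches detectors", {
  cfg <- sim_config(
    n_genes = 20,
    feature_plant = list(uorf = 1, top = 1, pg4 = 1),
    seed = 103
  )
  tx <- simulate_transcriptome(cfg)
  ft <- utr_feature_table(tx)
  expect_equal(nrow(ft), 20L)
  expect_true(all(ft$gc >= 0 & ft$gc <= 1))
  expect_true(all(ft$fold_energy <= 0))
  expect_true(all(ft$n_uorfs >= 0))
  up_ids <- tx$truth$gene_id[tx$truth$condition_class == "te_up"]
  expect_true(all(ft$n_uorfs[ft$gene_id %in% up_ids] >= 1))
  # subsetting works
  ft2 <- utr_feature_table(tx, gene_ids = up_ids)
  expect_equal(sort(ft2$gene_id), sort(up_ids))
})

test_that("compare_feature: Fisher exact cases and direction antisymmetry", {
  mk <- function(top) data.frame(
    gene_id = paste0("g", seq_along(top)), utr5_length = 100,
    gc = 0.5, fold_energy = -10, fold_energy_per_nt = -0.1,
    n_uorfs = 0L, has_top = top, n_pg4 = 0L
  )
  # balanced incidence -> p = 1
  bal <- compare_feature(
    mk(rep(c(TRUE, FALSE), each = 5)),
    mk(rep(c(TRUE, FALSE), each = 5)), "has_top"
  )
  expect_equal(bal$p_value, 1)
  # perfectly separated 5/0 vs 0/5 -> two-sided p = 2/252
  sep <- compare_feature(mk(rep(TRUE, 5)), mk(rep(FALSE, 5)), "has_top")
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(sep$direction, "up")
  # swapping the sets flips direction, keeps p
  swp <- compare_feature(mk(rep(FALSE, 5)), mk(rep(TRUE, 5)), "has_top")
  expect_equal(swp$p_value, sep$p_value)
  expect_equal(swp$direction, "down")
  # feature constant in both sets -> untestable
  const <- compare_feature(mk(rep(TRUE, 5)), mk(rep(TRUE, 5)), "has_top")
  expect_true(const$untestable)
})

test_that("compare_feature: continuous features use Mann-Whitney (Welch optional)", {
  mk <- function(len) data.frame(
    gene_id = paste0("g", seq_along(len)), utr5_length = len,
    gc = 0.5, fold_energy = -10, fold_energy_per_nt = -0.1,
    n_uorfs = 0L, has_top = FALSE, n_pg4 = 0L
  )
  up <- mk(withr::with_seed(1, rnorm(50, 200, 20)))
  down <- mk(withr::with_seed(2, rnorm(50, 150, 20)))
  mw <- compare_feature(up, down, "utr5_length")
  expect_equal(mw$test, "mannwhitney")
  expect_lt(mw$p_value, 1e-6)
  expect_equal(mw$direction, "up")
  wt <- compare_feature(up, down, "utr5_length", test = "welch")
  expect_lt(wt$p_value, 1e-6)
  # antisymmetry for the continuous path too
  mw_sw <- compare_feature(down, up, "utr5_length")
  expect_equal(mw_sw$p_value, mw$p_value)
  expect_equal(mw_sw$direction, "down")
  # identical constant sets are untestable
  expect_true(compare_feature(mk(rep(100, 5)), mk(rep(100, 5)), "utr5_length")$untestable)
  expect_error(compare_feature(up[0, ], down, "utr5_length"), "nonempty")
})
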