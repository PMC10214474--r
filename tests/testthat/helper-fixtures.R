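# Hand-built tiny fixtures (no RNG) plus small simulation shortcuts.

# three hand-made genes with known layout
tiny_genes <- function() {
  mk <- function(id, u5, cds, u3) {
    data.frame(
      gene_id = id,
      sequence = paste0(u5, cds, u3),
      utr5_len = nchar(u5),
      cds_len = nchar(cds),
      utr3_len = nchar(u3),
      tx_len = nchar(u5) + nchar(cds) + nchar(u3),
      cds_start = nchar(u5),
      cds_end = nchar(u5) + nchar(cds),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    mk(
      "gA", strrep("CT", 20), # 40 nt UTR5
      paste0("ATG", strrep("GCC", 98), "TAA"), # 300 nt CDS
      strrep("AG", 20) # 40 nt UTR3
    ),
    mk(
      "gB", strrep("AC", 15),
      paste0("ATG", strrep("AAA", 40), "TGA"),
      strrep("TC", 25)
    ),
    mk(
      "gC", strrep("GA", 25),
      paste0("ATG", strrep("CGT", 60), "TAG"),
      strrep("CA", 30)
    )
  )
}

# a single read row
read1 <- function(gene_id, start, length = 30L, library = "footprint",
                  sample = "s1", condition = "control", replicate = 1L) {
  data.frame(
    gene_id = gene_id, start = as.integer(start),
    length = as.integer(length), library = library, sample = sample,
    condition = condition, replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
}

# small but non-trivial simulation used by several module tests
small_sim <- function(seed = 7L, ...) {
  sim_config(
    n_genes = 60, reads_per_library = 20000, n_replicates = 2L,
    seed = seed, ...
  )
}

run_quant <- function(tx, reads, ...) {
  cm_fp <- count_reads(reads[reads$library == "footprint", , drop = FALSE],
    tx,
    mode = "cds_psite"
  )
  cm_m <- count_reads(reads[reads$library == "mrna", , drop = FALSE],
    tx,
    mode = "transcript_overlap"
  )
  translational_efficiency(rpkm(cm_fp), rpkm(cm_m), ...)
}
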