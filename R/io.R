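# File formats. All coordinates on disk are 0-based half-open (BED
# convention) except SAM POS, which is 1-based per the SAM specification.

# canonical TSV writer used for every table the package emits: fixed
# separator, Unix newlines, no quoting, numbers formatted via %.10g so a
# rerun with the same seed is byte-identical
.rp_write_tsv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.10g", fmt[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(fmt), collapse = "\t"), con, sep = "\n")
  if (nrow(fmt)) {
    writeLines(do.call(paste, c(unname(fmt), sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Write transcript sequences as FASTA
#'
#' @param genes an `rp_transcriptome` or its `genes` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(genes, path) {
  g <- .rp_genes_df(genes)
  seqs <- Biostrings::DNAStringSet(setNames(g$sequence, g$gene_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write gene models as BED6+ (one row per region)
#'
#' Each transcript contributes three rows (utr5, cds, utr3) with the
#' transcript id as chrom, 0-based half-open interval, and the region tag in
#' column 4.
#' @inheritParams write_transcriptome_fasta
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  g <- .rp_genes_df(genes)
  bed <- data.frame(
    chrom = rep(g$gene_id, each = 3L),
    start = as.vector(rbind(0L, g$cds_start, g$cds_end)),
    end = as.vector(rbind(g$cds_start, g$cds_end, g$tx_len)),
    name = rep(c("utr5", "cds", "utr3"), times = nrow(g)),
    score = 0L,
    strand = "+",
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(do.call(paste, c(unname(bed), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read gene models from BED6+ plus a transcript FASTA
#'
#' Inverse of [write_gene_models_bed()] / [write_transcriptome_fasta()].
#' @param bed_path BED6+ file with region tags utr5/cds/utr3 in column 4.
#' @param fasta_path transcript FASTA whose names match the BED chrom column.
#' @return a gene-model data.frame as produced by [simulate_transcriptome()]
#'   (without simulation-only columns).
#' @export
read_gene_models <- function(bed_path, fasta_path) {
  bed <- read.delim(bed_path,
    header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand")
  )
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- unique(bed$chrom)
  if (!all(ids %in% names(seqs))) {
    stop("BED transcript(s) missing from FASTA: ",
      paste(head(setdiff(ids, names(seqs))), collapse = ", "),
      call. = FALSE
    )
  }
  pick <- function(id, tag, col) {
    v <- bed[bed$chrom == id & bed$name == tag, col]
    if (length(v) != 1L) stop("expected one ", tag, " row for ", id, call. = FALSE)
    as.integer(v)
  }
  cds_start <- vapply(ids, pick, integer(1), tag = "cds", col = "start")
  cds_end <- vapply(ids, pick, integer(1), tag = "cds", col = "end")
  tx_len <- vapply(ids, pick, integer(1), tag = "utr3", col = "end")
  g <- data.frame(
    gene_id = ids,
    sequence = as.character(seqs[ids]),
    utr5_len = cds_start,
    cds_len = cds_end - cds_start,
    utr3_len = tx_len - cds_end,
    tx_len = tx_len,
    cds_start = cds_start,
    cds_end = cds_end,
    stringsAsFactors = FALSE
  )
  if (any(nchar(g$sequence) != g$tx_len)) {
    stop("BED intervals do not tile the FASTA sequences", call. = FALSE)
  }
  rownames(g) <- NULL
  g
}

#' Write / read read alignments as a tab-delimited table
#'
#' Columns: gene_id, start (0-based 5'-end transcript position), length,
#' library (footprint|mrna), sample, condition, replicate.
#' @param reads alignment data.frame from [simulate_libraries()].
#' @param path file path.
#' @return `path` (writer) or the alignment data.frame (reader).
#' @export
write_alignments_tsv <- function(reads, path) {
  .rp_write_tsv(reads, path)
}

#' @rdname write_alignments_tsv
#' @export
read_alignments_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "length", "library", "sample")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("alignment table lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Write read alignments as SAM (one reference per transcript)
#'
#' Emits an unsorted SAM with one `@SQ` line per transcript and one `@RG`
#' line per sample; each record carries its sample in the RG tag and the
#' library type in an `lb:Z` tag. Sequence and quality fields are `*`.
#' @inheritParams write_alignments_tsv
#' @param genes gene models (for reference lengths).
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(reads, genes, path) {
  g <- .rp_genes_df(genes)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con, sep = "\n")
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", g$gene_id, g$tx_len), con, sep = "\n")
  for (smp in unique(reads$sample)) {
    writeLines(sprintf("@RG\tID:%s", smp), con, sep = "\n")
  }
  rec <- sprintf(
    "r%07d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tRG:Z:%s\tlb:Z:%s",
    seq_len(nrow(reads)), reads$gene_id, reads$start + 1L, reads$length,
    reads$sample, reads$library
  )
  writeLines(rec, con, sep = "\n")
  invisible(path)
}

#' Read alignments from SAM/BAM back into the alignment table
#'
#' Requires the optional Rsamtools package. SAM files are converted to BAM
#' in a temporary directory first.
#' @param path a SAM or BAM file written by [write_alignments_sam()] (or any
#'   transcript-space alignment with RG and lb tags).
#' @return alignment data.frame as in [read_alignments_tsv()].
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package", call. = FALSE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
      destination = tempfile(), overwrite = TRUE,
      indexDestination = FALSE
    )
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar"), tag = c("RG", "lb")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  smp <- x$tag$RG
  df <- data.frame(
    gene_id = as.character(x$rname),
    start = x$pos - 1L,
    length = as.integer(sub("^([0-9]+)M$", "\\1", x$cigar)),
    library = x$tag$lb,
    sample = smp,
    stringsAsFactors = FALSE
  )
  # recover condition/replicate from canonical sample labels when possible
  m <- regmatches(smp, regexec("^(.+)_rep([0-9]+)_", smp))
  ok <- lengths(m) == 3L
  df$condition <- ifelse(ok, vapply(m, function(z) z[2L], "", USE.NAMES = FALSE), NA)
  df$replicate <- ifelse(ok, as.integer(vapply(m, function(z) z[3L], "", USE.NAMES = FALSE)), NA)
  df
}

#' Read alignments from any supported format
#'
#' Dispatches on file extension: `.sam`/`.bam` via [read_alignments_sam()],
#' anything else as the tab-delimited table.
#' @param path alignment file.
#' @return alignment data.frame.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
    read_alignments_sam(path)
  } else {
    read_alignments_tsv(path)
  }
}

#' Write / read the simulation ground-truth table
#' @param truth the `truth` data.frame of an `rp_transcriptome`.
#' @param path file path.
#' @return `path` (writer) or the truth data.frame (reader).
#' @export
write_ground_truth <- function(truth, path) .rp_write_tsv(truth, path)

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) read.delim(path, stringsAsFactors = FALSE)
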