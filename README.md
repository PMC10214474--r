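# riboTE

Ribosome-profiling translational-efficiency analysis with a built-in
synthetic benchmark.

## What this is for

Ribosome profiling sequences two libraries from the same sample:
ribosome-protected footprints (~28-32 nt, a proxy for translation) and
fragmented total mRNA (a proxy for transcription). For gene *g* and
sample *s*,

```
TE_gs = RPKM_fp(g, s) / RPKM_mRNA(g, s),    RPKM = count * 1e9 / (L * N)
```

where `L` is the effective feature length (CDS for footprints, transcript
for mRNA by default) and `N` the library size. Genes whose TE shifts
between a treatment and a control condition — while their mRNA does not —
are translationally regulated. `riboTE` implements the full desk-scale
pipeline around that statistic, for analysts who want every step explicit
and testable:

- **QC**: footprint length distribution, P-site reading-frame fractions
  (frame = `(5'end + offset − cds_start) mod 3`), and metagene P-site
  periodicity around start/stop codons, with explicit pass thresholds.
- **Quantification**: P-site-in-CDS counting for footprints, any-overlap
  counting for mRNA fragments; RPKM; TE with an expression filter and an
  optional per-sample median centering.
- **Differential translation (DTG calling)**: per-gene two-sided Welch
  *t*-test on replicate log2 TE, Benjamini-Hochberg FDR, and joint
  thresholds `p < 0.05`, `q < 0.05`, TE ratio `> 1.5` (up) or `< 0.667`
  (down); exact permutation test and a cross-condition concordance R²
  included.
- **5'UTR features**: length, %GC, a Nussinov-style minimum base-pair
  folding score (GC −3, AU −2, GU −1, min hairpin loop 3), uORF detection,
  TOP (5' C + ≥4 pyrimidines) and PG4 (`G3+ (N1-7 G3+){3}`) motifs, and
  Mann-Whitney / Fisher comparisons between up- and down-regulated DTGs.
- **Enrichment**: one-sided hypergeometric over-representation against GMT
  gene sets with BH correction, plus gene-list overlap/Jaccard statistics.
- **Synthetic data**: a first-class generator emitting FASTA/BED/SAM/TSV
  with lognormal gene abundance, configurable footprint periodicity and
  length weights, planted TE fold-changes and planted 5'UTR features, all
  recorded in a ground-truth table — so every stage is testable without
  downloading anything.

## Worked example

```r
library(riboTE)
cfg <- pipeline_config(
  simulation = sim_config(
    n_genes = 300, reads_per_library = 3e5, te_effect_genes = 0.2,
    te_log2_effect = 1.5, n_replicates = 3, long_utr_shift = 150L, seed = 42
  )
)
res <- run_all(cfg, "demo_run")
print(res$qc)
print(res$dtg)
```

prints (abridged; every line below is actual output):

```
[riboTE] simulate   in=300 out=3600000
[riboTE] qc         in=1800000 out=3
[riboTE] quantify   in=3600000 out=1800
[riboTE] difftrans  in=300 out=59
riboTE footprint QC
  lengths 28-32: 100.0% in [28,32] -> PASS
  frame fractions: 0.950 / 0.025 / 0.025 -> PASS
  metagene autocorrelation lag1/2/3: -0.514 / -0.500 / 1.000 -> PASS
riboTE DTG calls: 30 up, 29 down, 241 unchanged (of 300 genes)
```

The QC block shows the three canonical-library criteria: all footprints in
the 28-32 nt window, 95% of P-sites in the protein-coding frame (matching
the generative periodicity of 0.95), and the 3-nt codon-stepping
periodicity dominating the metagene autocorrelation. The 30 up / 29 down
calls recover the 60 planted genes (20% of 300 at |log2 TE| = 1.5) at
q < 0.05. Downstream, the planted-up truth set is the top enrichment hit
(`fold_enrichment = 10, p = 5.8e-42`) and the planted 5'UTR features
separate up- from down-regulated DTGs (uORF incidence Fisher
`p = 1.3e-08`, UTR length Mann-Whitney `p = 4.1e-07`, folding score more
negative in the up set, `p = 8.7e-08`).

The same run is available from the shell:

```sh
Rscript inst/cli/riboTE run-all --config config.json --out demo_run
```

with subcommands `simulate`, `qc`, `quantify`, `difftrans`, `utrfeat`,
`enrich` for stage-wise use (exit codes: 0 ok, 2 config error, 3 stage
failure).

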