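# captureseq

Targeted RNA sequencing (RNA CaptureSeq) enriches sequencing libraries for
genes of interest: biotinylated oligonucleotide probes hybridize to cDNA
from target genes, pulling them out before sequencing. It delivers large
sensitivity gains for low-expressed genes and for ultra-low-input
("mini-bulk") samples, at the price of a design and QC problem: which
genomic regions to probe, and how to demonstrate that capture enriched,
rescued and still quantified the targets faithfully.

`captureseq` implements that computational workflow for R users — panel
designers and bioinformaticians evaluating capture experiments:

* **Panel design** — rule-based construction of capture target regions
  from a GTF annotation, GWAS SNP tables with LD-block interval sets,
  RepeatMasker/EST tracks: genome-wide-significance SNP filtering
  (p < 5e-8), tiered SNP-to-block assignment, coding-free block selection,
  lncRNA proximity pulls (50 kb), margin trims (50/120/150/500 nt),
  partial-probing of highly expressed genes (last 200 nt of CDS, last
  100 nt of the penultimate and first 150 nt of the final exon), intronic
  control regions, and spike-in region padding.
* **Enrichment evaluation** — on-target read proportions; the sample
  enrichment factor EF = (post-capture on-target proportion)/(pre-capture
  proportion); gene-wise EF as the post/pre ratio of mean CPM with
  `log2(EF + 1)` display scale and enriched / not-enriched / rescued /
  undetected categories; Wilcoxon matched-pairs replicate-CV comparison;
  pre/post read-balance validation.
* **Expression threshold** — a continuous two-segment (broken-stick)
  regression of gene enrichment on log10 pre-capture expression, selected
  against a straight line by small-sample AICc
  (`n ln(RSS/n) + 2K + 2K(K+1)/(n-K-1)`, K = 5 vs 3); the breakpoint
  defines the CPM cut-off below which enrichment estimates are unstable.
* **Spike-in QC** — CPKM quantitation of an ERCC-style 2-fold dilution
  ladder: Spearman correlation and log-log OLS slope against known
  concentration, detection-threshold improvement, depletion of
  non-targeted spike-ins.
* **A generative simulator** — matched pre/post-capture multinomial
  libraries with per-replicate low-input dropout
  (`P(drop) = exp(-lambda/kappa)`), per-gene capture efficiencies and
  spike-in ladders, with full ground truth retained, plus ready-made
  scenarios (`ng-like`, `tf-like`, `low-complexity-minibulk`). The closed
  form EF = C/(Cp + 1 - p) (efficiency C, targeted pre-capture share p)
  anchors recovery tests.

See `vignettes/captureseq-methods.Rmd` for the model details, conventions
and limitations.

## Worked example

Simulate a transcription-factor-panel-like capture experiment (2000 genes,
5% targeted, mean efficiency 80, four replicates per phase at one million
reads) and run the full evaluation:

```r
library(captureseq)
cfg <- capture_config()   # every rule threshold at its standard value
cfg$seed <- 7L
report <- run_pipeline("tf-like", config = cfg)
print(report)
#> capture_report (scenario tf-like, seed 7)
#>   median sample EF: 15 (expected 14.99)
#>   gene categories: enriched=92, rescued=8
#>   enrichment success rate: 100%
#>   expression threshold: NA CPM (linear selected)
#>   spike-in threshold improvement: 4-fold
```

Reading the output: the library-level enrichment factor (15-fold) matches
the generative model's closed-form expectation (14.99) to sampling error.
Of the 100 targeted genes, 92 were detected pre-capture and all of them
were enriched (success rate 100%); 8 were invisible in every pre-capture
replicate and *rescued* by capture — the sensitivity gain capture exists
for. On this run the AICc comparison preferred a straight line over the
broken-stick model, so no expression cut-off is reported. Spike-in QC on
the same run shows capture preserved quantitation (log-log slope 0.98
post-capture vs 0.999 pre, Spearman rho 1 both phases), improved the
spike-in detection threshold 4-fold, depleted non-targeted spike-ins
5.6-fold, and reduced between-replicate variability (Wilcoxon matched
pairs, post < pre, p ~ 1e-16):

```r
report$spikein_qc$depletion          # 5.579398
report$cv_comparison$p_value         # 1.113113e-16
```

Design functions work from plain interval tables and an `annotation_set`:

```r
gen <- generate_annotation(n_genes = 40, chrom_len = 6e5, seed = 12)
panel <- design_ng_panel(gen$snps, gen$annotation$tracks$ld_blocks,
                         gen$annotation, gen$annotation$tracks$repeats)
print(panel)
write_bed(panel$targets, "panel.bed")
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/captureseq.R` (subcommands `simulate`, `run`, `design-ng`,
`evaluate`).

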