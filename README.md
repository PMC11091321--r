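# peakcoloc

Interval-level co-occupancy analysis of transcription-factor ChIP-seq peak
sets.

When two transcription factors are suspected of binding the same
cis-regulatory elements — for example a factor that gates a differentiation
program and a nuclear hormone receptor that can displace it — the evidence
chain runs through called peak intervals, not reads: do the two peak sets
share genomic coordinates more often than chance, where do the shared sites
sit relative to genes, do they coincide with active-chromatin histone marks
(H3K4me3 at promoters, H3K27ac at enhancers), which annotated enhancers and
target genes do they touch, and are those target genes differentially
expressed between conditions? `peakcoloc` implements that chain as a tested,
reusable pipeline for anyone working from BED-like peak files, a gene-model
table, an enhancer annotation, and a differential-expression results table.

## The statistic at the core

Co-occupancy significance is assessed with a binned-genome one-sided
Fisher's exact test. The genome is tiled into bins whose width defaults to
the pooled mean peak length of the two sets (so one typical peak spans about
one bin). Each bin is scored for containing ≥ 1 bp of a peak from set A, set
B, both, or neither, giving a 2×2 table (n00, n10, n01, n11). With N total
bins, K = n11 + n10 bins holding A, n = n11 + n01 bins holding B and
k = n11 jointly occupied bins, the enrichment p-value is the hypergeometric
upper tail

    p = P[X >= k],  X ~ Hypergeometric(N, K, n)

computed in log space via log-gamma so that genome-scale tables do not
underflow (values below the smallest positive double are floored there,
never reported as exactly 0). An exact rational enumeration
(`hyper_tail_exact`, 128-bit integer arithmetic) is included as a
small-table reference; the log-space path agrees with it to at least 12
significant digits on every table with N ≤ 60.

Around that core sit: peak-set containers with BED I/O and strict interval
validation ("overlap" = ≥ 1 shared base; book-ended intervals do not
overlap); co-bound merging (connected components of the overlap graph that
contain peaks of both sets); nearest-peak distances; genomic feature
annotation (promoter distance bands, exon 1 / other exons, intron 1 / other
introns, downstream, distal intergenic) with strand-aware TSS handling;
promoter windows (default 4 kb upstream / 1 kb downstream); TSS occupancy
profiles; histone-mark stratification; enhancer joins with a strict
interaction-score filter (default > 10); and DEG classification of
peak-target genes at strict FDR < 0.05. A synthetic-data generator produces
complete input bundles with recorded ground truth (planted co-occupancy
fraction, mark coverages, planted DEG labels) so every stage is testable
without any external download.

## Worked example

```r
library(peakcoloc)

# a complete synthetic study: genome, genes, two co-bound TF peak sets,
# histone-mark domains, enhancer table, DE table, with recorded truth
bundle <- simulate_bundle(dir = "demo", seed = 1)
report <- run_pipeline(bundle$paths$config, out_dir = "demo_out")

report$coloc
#> <overlap_test_result> WT1_like vs AR_like (synthetic), bin width 660 bp
#>           B absent B present
#> A absent     11628      1713
#> A present     1661       150
#> odds ratio 0.613, one-sided Fisher p = 1

report$strat_promoter_a
#> <stratified_peaks> 316/407 (77.6%) in promoter_mark regions

report$deg_a
#> <deg_join> FDR < 0.05: 20 up, 29 down, 134 ns, 0 untested

report$summary$n_merged_peaks          # 66 merged co-bound peaks
report$summary$overlap_fraction_b_in_a # 0.07 (planted, recovered exactly)
```

Reading the output: exactly 7% of B peaks overlap an A peak — the planted
co-occupancy fraction, recovered exactly by construction. 77.6% of set-A
promoter peaks fall in promoter-mark (H3K4me3-like) domains, matching the
planted coverage. The one-sided p of 1 is correct, not a bug: on a 10 Mb
toy genome the two 1000-peak sets would share ~12% of peaks by chance
alone, so a planted 7% (with the remaining peaks placed to avoid the other
set) is *depletion*; on a 3 Gb genome the same 7% is a massive enrichment.
The `demo_out/` directory holds `summary.json` (all headline numbers),
per-stage TSV tables and `pipeline.log` with every resolved parameter.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/peakcoloc.R simulate --out demo --seed 1
Rscript inst/cli/peakcoloc.R run-all --config demo/config.yaml --out demo_out
Rscript inst/cli/peakcoloc.R coloc --a demo/peaks_a.bed --b demo/peaks_b.bed \
    --genome demo/genome.chrom.sizes --out coloc.tsv
```

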