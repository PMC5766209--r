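# spliceorder

Genome-wide inference of the **order of intron removal** from paired-end
RNA-seq, with a purely kinetic co-transcriptional null model to decide
whether the observed order can be explained by splicing rates alone.

## The problem

Human transcripts carry ~10 introns each, and they are not removed in the
order they are transcribed. Some introns can only be removed after a
neighboring splicing event — a dependency invisible to single-intron
assays, but visible in *partially spliced intermediate reads*: paired-end
reads where one mate spans a spliced exon–exon junction (that intron is
gone) while the other mate sits inside the adjacent intron (that one is
still there). Counting such reads per **adjacent intron pair** gives the
fraction of transcripts that removed the downstream intron first.

The observed genome-wide distribution of that fraction must then be
compared with what independent first-order kinetics would produce. Under
the null, intron *u* (rate $k_u$) races intron *d* (rate $k_d$), whose
exponential clock starts only after the polymerase (rate $v$) has
transcribed the internal exon and the downstream intron
($\Delta = (L_{exon}+L_{down})/v$):

$$P(\text{upstream first}) \;=\; 1 - e^{-k_u\Delta}\,\frac{k_d}{k_u+k_d}.$$

Rates are drawn from the in vivo distribution Normal(0.169, 0.048)
introns/min with $v = 3.87$ kb/min. A chi-square test (sparse bins pooled)
against this simulated null detects an **excess of "always-first"
outcomes** — pairs at a ≥95% margin — that rate variation alone cannot
produce, the signature of intron–intron dependencies. The package also
provides the steady-state "square law" ($[I_1]/[I_2] = (k_1/k_2)^2$),
category analyses (exon skipping, alternative 5'/3' splice sites,
first/middle/last introns, circle-flanking introns), intron
length-difference analysis, RBP motif-density enrichment, and a synthetic
co-transcriptional generator with configurable dependencies for end-to-end
validation. Audience: RNA processing labs with total/nuclear RNA-seq, and
methods developers who need a splicing-order truth set.

## Worked example

A synthetic cohort of 500 adjacent pairs, 20% of them dependency-forced,
classified and tested against the kinetic null:

```r
library(spliceorder)
set.seed(42)
co <- generate_cohort(500, dep_fraction = 0.2, seed = 42)
cc <- apply_depth_filter(co$counts, min_reads = 10)
cc <- call_always_first(cc, threshold = 0.95)
obs  <- bin_distribution(cc$fraction_downstream_first, n_bins = 20)
null <- simulate_null_distribution(co$pairs[co$pairs$pair_id %in% cc$pair_id, ],
                                   kinetic_params(), n_reps = 20, seed = 43)
tt <- excess_test(obs, null)
```

Output:

```
retained pairs: 500
mean fraction downstream-first: 0.467
always-first pairs: 100
chi-square = 495.1 (df 13), p = 1.59e-97
first-bin excess = 47.4, last-bin excess = 51.9
```

Reading it: the null's co-transcriptional delay biases removal toward the
upstream intron (mean fraction < 0.5); the 100 dependency-forced pairs pile
up in the two extreme bins, ~47 and ~52 pairs above the kinetic
expectation, and the excess test rejects independence decisively. On a pure
kinetic cohort (`dep_fraction = 0`) the same test stays at its nominal 5%
rejection rate.

For real data, replace the generator with your inputs: a GTF/BED12/knownGene
annotation (`read_gene_annotation` → `enumerate_adjacent_pairs` →
`annotate_pairs`), coordinate-sorted BAM/SAM alignments
(`read_alignments` → `classify_read_pairs`), and optionally a BED3 circle
list, a FASTA of intron sequences and a motif panel TSV for the category,
length and motif analyses. `run_pipeline()` chains all stages and writes
provenance-headed TSVs.

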