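# pirnakit

Small RNA ping-pong signatures and transposon derepression analysis in R.

`pirnakit` is a pipeline for PIWI-interacting RNA (piRNA) studies of the kind
carried out in silkworm piRNA-pathway knockouts: it takes raw 4N-adapter small
RNA-seq reads through adapter/4N trimming, unique-insert collapsing, mapping
to a classed reference catalog (transposon consensus sequences, gene models,
miRNAs, rRNA-derived repeats) and RPM normalization, and then computes the
statistics that characterize ping-pong piRNA biogenesis and its loss:

* the **ping-pong signature** — the 5′–5′ overlap histogram
  z(o) = Σ_ref Σ_p n₊(p)·n₋(p+o−1), with the 10-nt bin fraction
  z(10)/Σz as the summary;
* **1U/10A strand bias** per transposon (first-base U on the guide strand,
  position-10 A on the responder strand, evaluated on reads as sequenced);
* **piRNA-producer classification** (sense+antisense RPM > 4) with
  three-tissue Venn decomposition;
* **named piRNA quantification** (5′-anchored exact match, ±3 nt of 3′
  heterogeneity);
* the **RNA-seq side**: TPM, MA transform with derepression calls at
  M > 1 & A > 0, a permutation-based differential expression test with BH
  FDR, Z-score + Ward clustering, tissue-specificity and fold-change rules;
* **slicer targeting rules**: target scanning under perfect guide 2–18
  pairing, cleavage bond between positions 10 and 11, and the implied
  responder 5′ end;
* a **synthetic-data generator** that emits 4N-adapter FASTQ libraries with
  known ping-pong structure, ground-truth tables, and negative-binomial
  RNA-seq experiments with planted fold changes, so every stage is testable
  without external sequencing data.

## Worked example

Simulate a wild-type library at a 0.7 ping-pong fraction, run the pipeline,
and recover the signature and the strand bias:

```r
library(pirnakit)

catalog <- make_reference_catalog(35, 10, 12, 3,
                                  length_range = c(3000, 6000), seed = 11)
sim <- simulate_small_rna_library(
  catalog, smallrna_sim_params(pingpong_fraction = 0.7, depth = 1e5, seed = 42))

lib <- process_library(sim$reads, library_id = "WT_ovary")
lib
#> <processed_library> WT_ovary: 100000 reads in, 99995 kept (20315 unique inserts), 5 no adapter, 0 length-rejected

al <- align_reads(lib, catalog, max_mismatches = 1, seed = 5)
mapping_rate(al, lib, "transposon")
#> [1] 85.00325

f <- normalization_factor(al, catalog, "transposon", "WT_ovary")
rt <- rpm_table(al, f, catalog)
sum(rt$rpm[rt$class == "transposon"])   # RPM closure
#> [1] 1e+06

os <- overlap_signature(al, ref_ids = catalog$id[catalog$class == "transposon"])
os
#> <overlap_histogram> z(10) = 1.124e+07, ping-pong fraction = 0.6950
```

The estimated fraction 0.695 recovers the generator's target 0.7: roughly 70%
of the opposite-strand 5′-overlap mass sits in the 10-nt bin, the hallmark of
ping-pong amplification. The strand-bias table puts the 1U and 10A biases on
opposite strands of every well-covered transposon (mean 1U ≈ 90% on the guide
strand, mean 10A ≈ 80% on the responder strand):

```r
sb <- strand_bias_table(al)
head(sb[sb$n_sense >= 20 & sb$n_antisense >= 20,
        c("ref_id", "pct_1U_antisense", "pct_10A_sense")])
```

A knockout library (`ko_depletion = 0.01`) processed the same way but
normalized in `mirna_top10` mode retains about 1% of the wild-type 26–30 nt
RPM mass — the piRNA peak collapses while the miRNA background is untouched.

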