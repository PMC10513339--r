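---
title: "Methods: the piRNA ping-pong and derepression pipeline"
author: "pirnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the piRNA ping-pong and derepression pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

## Scope and model

`pirnakit` implements the computational side of a silkworm-style piRNA study:
small RNA libraries cloned with 4N-randomized adapters are trimmed, collapsed
to unique inserts, mapped to a classed reference catalog (transposon consensus
sequences, gene models, miRNAs, rRNA-derived repeats), normalized to RPM, and
interrogated for the hallmarks of the ping-pong amplification cycle; RNA-seq
count tables from wild-type and piRNA-pathway knockout animals are normalized
to TPM and screened for transposon derepression and differential expression.
A slicer-rule module encodes the sequence geometry of piRNA-guided cleavage.

The biological model is the standard ping-pong cycle. A PIWI protein loaded
with a uridine-starting guide piRNA (1U) cleaves a complementary transcript
between the bases opposite guide positions 10 and 11. The 3' fragment of the
cleaved target is loaded into the partner PIWI protein and matured into a
responder piRNA whose 5' end overlaps the guide's 5' end by exactly 10 nt and
which carries adenine at position 10 (10A) — the base paired opposite the
guide's 1U. The quantitative signature is therefore:

* an enrichment of sense/antisense read pairs with a precise 10-nt 5'–5'
  overlap, summarized by the histogram
  \(z(o) = \sum_{\mathrm{ref}} \sum_p n_+(p)\, n_-(p + o - 1)\)
  and the fraction \(z(10) / \sum_o z(o)\);
* 1U bias on one strand of each transposon and 10A bias on the opposite
  strand.

## Preprocessing

Raw 50-nt single-end reads are laid out as
`[4N][insert][4N][21-nt 3'-adapter core]`. `trim_adapter()` locates the
leftmost position at which the adapter core matches with at most one
substitution ("fewer than two mismatches"); a core prefix of at least 10 nt
is accepted when the read ends before the core does. The four randomized
bases on each side of the insert are removed, and inserts outside 20–40 nt
are discarded. Two conventions are deliberate:

* the length filter applies to the final insert, after both 4N blocks are
  removed (the alternative — filtering before 4N removal — shifts the window
  by 8 nt; the insert-level reading is the one that makes the 20–40 nt window
  describe small RNA lengths);
* reads without a detectable adapter are discarded rather than kept
  untrimmed, because an untrimmed 50-nt read cannot be a genuine ≤ 40-nt
  insert.

Read fates partition exactly: `input = no_adapter + length_rejected + kept`,
and this identity is asserted in the tests against a position-by-position
brute-force rescan.

## Mapping and normalization

`align_reads()` enumerates *all* placements of each unique insert on both
strands of every catalog entry with at most one substitution, keeps the
minimum-mismatch stratum, and resolves ties by a single uniform seeded draw;
multi-mapping reads are counted once, never fractionally. The implementation
joins inserts (exact stage) and their single-substitution variants (1-mismatch
stage) against an enumerated substring table; the test suite checks it against
an independent all-substring scan on small catalogs, and checks tie-break
uniformity by a chi-square test across seeds. A minimal SAM import/export is
provided so an external aligner can be substituted.

Two library-size denominators are carried, mirroring the two normalizations
used for such libraries:

* `transposon`: copy-weighted reads mapped to transposon-class references
  (rRNA-derived repeats carry their own class and are excluded). By
  construction, summed RPM over transposons closes to \(10^6\).
* `mirna_top10`: copy-weighted reads on the ten most abundant miRNAs of the
  library. This denominator is indifferent to the state of the piRNA pathway,
  which is what makes wild-type/knockout comparisons of piRNA abundance
  meaningful — the transposon denominator is itself depleted in a knockout.

## The synthetic-data generator

The generator is first-class code: it produces the study conditions every
downstream statistic is tested against, and it writes a per-read truth table.

**Hotspot structure.** piRNA reads are emitted from discrete 5'-end hotspot
loci on the transposons, not from uniform random positions. This is not a
convenience: at realistic depth, uniformly placed 5' ends generate so many
coincidental opposite-strand overlaps that \(z(10)/\sum z\) is diluted far
below any target. Real libraries concentrate reads on shared 5' ends, which
is precisely why the ping-pong fraction is informative. Each locus carries an
antisense (guide) pile and a sense pile at a fixed 5'–5' offset: 10 nt for a
`pingpong_fraction` share of loci (assigned deterministically, so the realized
fraction is not dominated by locus-sampling noise) and a uniform non-10 offset
otherwise. The default of ~800 reads per locus keeps loci sparse enough that
cross-locus coincidences contribute about 1% of the overlap mass.

**1U versus 10A.** For an exact-overlap pair of template-faithful reads the
guide's first base and the responder's tenth base are the same reference
position seen from opposite strands, so their biases cannot be set
independently through placement alone. The generator therefore biases the
locus choice toward reference-A positions and then sets the read-level bases
(guide position 1 to T with probability `bias_1U`; sense-read position 10 to A
with probability `bias_10A`), introducing at most one substitution per read
relative to the template — absorbed by the 1-mismatch aligner, and consistent
with the fact that both biases are measured on reads as sequenced.

**Background and knockout.** Background reads are miRNAs (fixed 22 nt, the
same prefix of each miRNA precursor in every library, so the top-10-miRNA
denominator is stable across libraries) and short degradation fragments
(20–25 nt, geometric decay), drawn uniformly across catalog classes. Keeping
background out of the 26–30 nt window mirrors knockout libraries, where only
the ~22 nt peak survives, and makes depletion tests honest. `ko_depletion`
scales the piRNA and spiked read mass only; the locus count is set by the
pre-depletion budget, so a knockout thins reads per hotspot and the paired
statistic \(z(10)\) falls with the square of the depletion factor. Spiked
named piRNAs (Fem/Masc-like, at known copy number) deplete with the pathway.

**What the generator does not model** — and hence what green tests do not
certify about real data: sequencing error, 3'-end trimming heterogeneity
beyond the length law, genome-coordinate structure (multi-copy insertions,
clusters), phased trail piRNAs, and real miRNA/rRNA sequence families. The
generator's distributions are modeling choices, not fits to any deposited
library.

## Ping-pong, strand bias and producer statistics

`overlap_signature()` computes \(z(o)\) for \(o \in [1, 25]\) by default:
the denominator then spans all overlaps shorter than a typical read, and the
estimator recovers the generator's truth within ±0.02 at \(10^5\) reads with
20% background. Pair weights are copy-weighted by default; a species-weighted
mode (each unique insert once) is provided because "sense and antisense
pairs" admits both readings. `strand_bias_table()` evaluates 1U/10A on the
read as sequenced, per strand and transposon, within the 26–30 nt window that
operationalizes "around 27 nt"; rows are sorted by the sense-minus-antisense
1U difference, and an external ordering can be imposed so knockout tissues
can be displayed in the wild-type ovary order. `classify_producers()` uses a
strict RPM > 4 rule on sense+antisense RPM, and `venn_regions()` decomposes
three producer sets with an internal inclusion–exclusion assertion.

`quantify_named_pirna()` counts inserts identical to a query over the shared
5'-anchored prefix, tolerating ±3 nt of 3' heterogeneity and no mismatches —
a counting rule that must be stated because length heterogeneity at the 3'
end is the norm for piRNAs.

## Expression analysis

TPM is computed per sample as \(10^6 (c_i/\ell_i) / \sum_j (c_j/\ell_j)\).
MA coordinates use a 0.01 pseudocount on TPM before `log2` so zero-expression
features remain computable; derepression is called at M > 1 and A > 0, both
strict. Replicates are averaged on the TPM scale before the transform.

`differential_test()` is a self-contained permutation engine (the original
count-based FDR machinery used for such data is a different tool and is
deliberately not re-implemented): a moderated Welch statistic on
log2(TPM + 0.01) with a variance floor \(s_0^2\) set to the 90th percentile
of the per-feature squared standard error, a gene-pooled null from label
permutations of group-mean-centered residuals, and Benjamini–Hochberg
adjustment. Three calibration details matter and are tested:

* centered residuals are rescaled by \(\sqrt{n/(n-1)}\) (centering deflates
  their variance, which would make the null too narrow);
* permutations that reproduce the original group partition are skipped (their
  centered group means are identically zero);
* the strong variance floor decouples the statistic's numerator from its own
  denominator; in a residual permutation the two are coupled (large permuted
  numerators require large residuals, which inflate the denominator), which
  otherwise thins the extreme null tail exactly where FDR < 0.001 thresholds
  live. With 3 vs 3 replicates an unmoderated t statistic has tails too heavy
  to reach such thresholds at 2000 features under any permutation scheme.

Under the global null the mean false-discovery proportion at q = 0.05 over 20
simulated experiments is at the nominal level, and planted 16-fold features
are recovered at FDR < 0.001 with full power.

`zscore_cluster()` row-standardizes and applies Ward (`ward.D2`) hierarchical
clustering on Euclidean distances — chosen as the deterministic standard
since no linkage is canonical for this task — cut at k = 6 by default.
`tissue_specific_genes()` and `fold_change_classes()` apply the strict
"more than twice both other tissues" and |log2FC| > 1 rules.

## Slicer targeting rules

`find_cleavage_sites()` scans a target for windows where guide positions 2–18
pair perfectly (antiparallel Watson–Crick, no G:U wobble) with the target;
guide position 1 — the 1U held in the PIWI pocket, not base-paired — and
positions beyond 18 are unconstrained. Each site reports the cleavage bond
between the target bases opposite guide positions 10 and 11, in 0-based
half-open target coordinates. `responder_five_prime()` returns the 5' end of
the 3' cleavage fragment; by construction the implied responder overlaps the
guide by exactly 10 nt, which the tests close through `pairs_by_pingpong()`
and `overlap_signature()`. A mismatch-tolerance argument exists for
exploration but defaults to 0: whether near-perfect 2–18 pairing supports
cleavage is unresolved, so the strict sufficiency rule is the default.

## Numerical and degenerate-input conventions

* Coordinates are 0-based with half-open intervals; the 5' end of a
  minus-strand read is `end - 1`.
* U is folded to T on input everywhere; compositions report U.
* Ties in the aligner's best stratum are broken by one uniform seeded draw;
  every stochastic entry point takes an explicit integer seed and restores
  the caller's RNG state.
* Empty inputs return empty (typed) results rather than errors wherever the
  quantity is well-defined (an empty library is a valid `ProcessedLibrary`
  with zero stats); errors are reserved for contract violations (empty
  catalog, zero normalization denominator, fewer than two replicates,
  malformed FASTQ records — reported with the record index).
* Percentage tables with a read-free strand carry `NA` rather than 0, so
  absence of evidence is not reported as absence of bias.

## Problem sizes used in the checks

The test suite and the acceptance script run the full pipeline on simulated
libraries of \(10^5\) reads over a 35-transposon catalog (3–6 kb consensus
each), expression experiments with 420–2020 features in triplicate, and 20
repeated null experiments for the error-control check. These sizes were
chosen so each statistic's sampling error is several times smaller than the
tolerance it is tested against.

## Known limitations

* The aligner is substitution-only (no indels, no splicing) and caps at one
  mismatch, matching the analysis contract rather than a general-purpose
  read mapper.
* Ping-pong significance testing (z-score against a permuted null) is out of
  scope; the fraction is a descriptive statistic here.
* The 65–75% ping-pong fractions and 15–25% transposon mapping rates of real
  silkworm libraries are properties of the animal's piRNA repertoire; the
  generator reproduces the former by construction and makes no attempt to
  imitate the latter, since synthetic piRNAs all derive from the catalog's
  transposons.
* `genic_silencing_candidates()` expects per-gene RPM/TPM matrices computed
  upstream; it encodes only the selection rule (both-strand RPM > 10,
  > 2-fold up-regulation in at least one tissue).
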