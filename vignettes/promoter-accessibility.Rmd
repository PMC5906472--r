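---
title: "Promoter accessibility of random sequences and avoidance of accidental intragenic promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter accessibility of random sequences and avoidance of accidental intragenic promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoprom)
```

## The scientific question

The canonical bacterial sigma70 promoter is defined by two hexameric
elements — the −35 (consensus `TTGACA`) and the −10 (consensus `TATAAT`) —
separated by a spacer with an optimal length of 17 nt. Because these
elements are short and degenerate, a surprisingly large share of *random*
DNA is close, in mutational terms, to promoter activity. This package
quantifies two consequences of that proximity:

1. **Accessibility.** How many single-base substitutions separate a random
   ~100-nt sequence (the typical length of an *E. coli* intergenic region)
   from sigma70 promoter activity?
2. **Avoidance.** If promoters are that easy to make by accident, are
   coding regions — which cannot choose their amino-acid sequence but can
   choose synonymous codons — depleted of promoter-like sites relative to
   what their protein sequence forces on them?

## The promoter model

Two promoter criteria are implemented, deliberately spanning the
strict/lenient range:

* **Core-motif criterion.** A sequence passes if it contains `TTGnnn` and
  `TAnnnT` (six fixed bases in total; `n` is any base) separated by a
  spacer in `[15, 19]` nt. This captures only the most information-rich
  positions of the two elements. Because each fixed-base mismatch costs
  exactly one substitution and placements are independent, the *exact*
  mutational distance under this criterion is the minimum mismatch count
  over all placements (`core_distance()`), which is also checked in the
  test suite against exhaustive enumeration of all 0/1/2-substitution
  neighbours.

* **PWM criterion.** Position weight matrices for the two hexamers plus an
  additive spacer-length weight. Per-position weights are log-odds,
  `log2((count + pseudocount) / (N + 4·pseudocount) / 0.25)`, built by
  `build_pwm()` from an alignment of training windows; the spacer weight is
  the log-ratio of the smoothed empirical spacer-length distribution to a
  uniform one, maximal at 17 nt. A sequence is scanned with a sliding
  window over all placements and strands requested (`best_window_score()`),
  and *passes* when its best window reaches a threshold calibrated as the
  **median score of a constitutive-promoter set** (`calibrate_threshold()`)
  — the benchmark used in the source study. The greedy trajectory
  (`greedy_pwm_evolve()`) repeatedly applies the single substitution that
  maximizes the new score, mirroring selection of the best first mutation.

### The packaged default model

The original position-specific matrix behind the study is not published, so
the shipped default (`default_promoter_model()`) is built from a packaged
**synthetic** alignment of 50 canonical-like windows
(`inst/extdata/sigma70_training_windows.tsv`). Its column base counts
follow classic consensus-match frequencies for sigma70 promoters (roughly
0.5–0.9 per position, strongest at the `TA` and terminal `T` of the −10)
and its spacer counts peak at 17 nt. Any user-trained model built with
`build_pwm()` on real aligned promoters is a drop-in replacement. Because
the matrix differs from the unpublished original, *absolute* scores are not
comparable to published software scores; all supported conclusions are
distributional or fractional.

### Calibration noise

The threshold is the median best-window score of a synthetic
constitutive-promoter set (`synth_promoter_set()`, n = 556). Its default
per-position mutation probability is **0.30**: real constitutive promoters
match the 12 core consensus positions at only about two thirds of
positions, and with this setting the calibrated benchmark classifies
roughly one in ten filtered random 103-mers as promoters — the same
operating point the core-motif criterion and the published experimental
fraction indicate. Spec-level checks that exercise lower-noise sets (0.15)
do so explicitly.

## Random-sequence generation

`generate_random_sequences()` draws i.i.d. uniform bases and rejects
sequences whose GC fraction falls outside `[45.6%, 56.0%]` (bounds
inclusive; the published exclusion rule names the open outside intervals)
or that contain a homopolymer run longer than 5 nt. Defaults are 103 nt —
the length of the replaced *lac* intergenic region. About two thirds of
unconstrained draws survive both filters, so rejection sampling is cheap; a
cap of 10,000 attempts per requested sequence guards pathological settings.
One root seed drives a single RNG stream, making the whole batch
reproducible.

## Accidental-expression score

For a coding sequence, both strands are scanned; placements scoring at or
above the threshold are reduced by non-maximum suppression (no two retained
hits whose −10 starts lie within 10 nt on the same strand; the higher total
wins, ties to the leftmost) and then summed:

\[
\mathrm{score} = \sum_{\mathrm{hits}} (s_{35} + s_{10}) \times
\bigl(1 + (\mathrm{total} - \mathrm{threshold})\bigr) \times 1000 / L
\]

The `1 + margin` factor is a monotone surrogate for a discriminant-function
margin ("how far above the detection threshold"); element scores and margin
both increase with promoter strength, so comparative statements (wild type
vs nulls, group contrasts) are well defined even though absolute magnitudes
are scorer-specific. Scores are reported per kb, split into sense and
antisense components. The 10-nt suppression radius is a documented choice:
it sums distinct (even overlapping) promoters without double-counting a
single site.

## Null ensembles and ranking

Two null models generate alternative versions of each gene:

* **usage** — every codon is resampled from the genome-wide codon-usage
  distribution conditional on its amino acid (`recode_gene()`): the protein
  is preserved exactly, codon bias in expectation. This is the simplest
  faithful reading of "preserving the amino-acid sequence and the overall
  codon bias"; exact per-gene count preservation is available via the
  second null.
* **shuffle** — the gene's codons are permuted (`shuffle_codons()`): codon
  multiset and hence exact GC content are preserved, the protein is not.

The terminal stop codon is kept verbatim in both modes — it is not part of
the translated sequence's synonymous freedom. Each replicate is seeded by a
stable hash of (root seed, gene id, replicate index), so any replicate can
be regenerated in isolation.

The wild-type gene is ranked within its ensemble by the mid-rank percentile
`(#{null < wt} + 0.5·#{null == wt}) / N` and binned into deciles
(`floor(10p) + 1`, clipped to `[1, 10]`). Decile 1 means the wild type has
fewer predicted accidental promoters than at least ~90% of its own recoded
versions. Group contrasts use the asymptotic two-sample Kolmogorov–Smirnov
test (`group_ks()`) and the exact two-sided sign test at p0 = 0.5
(`paired_sign_test()`), as single planned tests without multiplicity
correction.

A caveat of the mid-rank rule worth knowing: when a gene and many of its
nulls all score exactly zero (short genes under a strict threshold), the
tied mass collapses onto a single percentile instead of spreading
uniformly, which can distort decile histograms away from flatness even for
neutral genes. At the default operating point (most ~1-kb genes contain at
least one above-threshold site on some strand) this effect is small.

## Six-mer analysis

`count_sixmers()` counts all 4096 hexanucleotides in overlapping windows,
within each sequence only and on the coding strand only — a documented
choice; `both_strands = TRUE` additionally counts the reverse complement of
every sequence, off by default. Enrichment flags
come from the empirical z-score against the null ensemble with a default
cutoff of |z| ≥ 3 — distribution-free and matched to the ensemble design.
Motifs whose null standard deviation is zero are flagged neutral with a
missing z.

## The synthetic genome generator

`synth_genome()` emulates the genomic analysis end to end with known ground
truth: genes of 150–500 codons (uniform; mean ~325 codons, close to a
typical bacterial gene) sampled codon-by-codon from a usage table whose
implied GC is tilted to a target (default 50.8%, `synth_usage_table()`);
group labels (essential 10%, toxin 5%, antitoxin 5% by default) with
one-to-one toxin–antitoxin pairing; and three per-group modes:

* *neutral* — genes share the generator with their usage-mode nulls, so
  decile histograms are flat up to sampling noise;
* *avoid* — codon choices creating core-motif hits (either strand) are
  resampled synonymously with bounded retries (genes still carrying hits
  are labelled `partial`), emulating selection against promoter-like
  sequences through alternative codons;
* *enrich* — consensus −35/−10 hexamers at 17-nt spacing are written over
  the sampled bases (1 site/kb by default), optionally on the antisense
  strand of toxin genes. Planting is nucleotide-level and may create
  internal stop codons; planted sites are recorded in the truth table.

What the generator does *not* emulate: operon structure, real gene-length
and amino-acid composition distributions, dicodon bias, mRNA structure, or
chromosome-scale context. Passing tests on synthetic genomes therefore
demonstrate correctness and statistical power of the machinery, not
biological conclusions about any particular genome — those require running
the same pipeline on real annotated genome data (`read_genbank_cds()` plus
label lists).

## Problem sizes and determinism

The packaged analyses use 30,000 random sequences for the accessibility
histogram (seconds), and 200 genes × 100 null replicates for synthetic
genome-scale checks (minutes) — the generator supports full study scale
(thousands of genes × 1000 replicates) through the same interfaces, which
is an hours-long single-CPU run. All tie-breaks (leftmost position, smaller
spacer, `+` strand, alphabetical target base) are fixed so that distance
results are seed-free, and every stochastic step funnels through one root
seed.

## Worked example

```{r example, eval = FALSE}
model <- default_promoter_model()

# accessibility of random sequences under the core criterion
acc <- run_accessibility(n = 30000, seed = 1)
acc$histogram

# synthetic genome with promoter-avoiding wild type
u <- synth_usage_table(0.508)
sg <- synth_genome(synth_genome_spec(n_genes = 200, usage = u,
                                     avoidance = "avoid", seed = 41))
res <- run_minimization(sg$genes, model, mode = "usage", n_nulls = 100,
                        usage = u, seed = 7)
res$decile_hist
```

## Known limitations

* The default PWM is a synthetic reconstruction; absolute scores and any
  threshold-crossing counts depend on it. Retrain on real aligned
  promoters for genome-specific work.
* The extended −10 (`TGn`) element and UP elements are not modeled;
  transcription-factor binding sites are out of scope.
* The accidental-expression surrogate preserves ordering, not absolute
  scale, relative to discriminant-based promoter finders.
* The KS p-values are asymptotic; for very small groups the exact sign
  test is the more trustworthy of the two contrasts.
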