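---
title: "Identifying sex-chromosome scaffolds and genes from sexed coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sex-chromosome scaffolds and genes from sexed coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The model

In a male-heterogametic (XY) species, sequencing depth carries copy-number
information: autosomes are present twice in both sexes, the X twice in
females but once in males, and the Y only in males. The **Chromosome
Quotient (CQ)** — the female/male ratio of normalized coverage — therefore
has expectation

* CQ ≈ 1 on autosomes,
* CQ ≈ 2 on the X,
* CQ ≈ 0 on the Y,

independent of library sizes, because both coverages are normalized as RPKM
(reads per kilobase per million mapped reads). `sexscan` computes CQ at
three scales:

1. **Region CQ** in non-overlapping 10 kb windows along every scaffold
   (`tile_windows()`, `window_rpkm()`, `region_cq()`). Windows with CQ
   strictly above 2 are tagged X, strictly below 0.2 tagged Y
   (`tag_regions()`); scaffolds with at least 40% of their *length* in X-
   or Y-tagged windows become X- or Y-candidates (`call_scaffolds()`).
2. **Gene CQ** from sexed read counts over gene intervals, normalized by
   library size (`count_gene_reads()`, `gene_cq()`). A gene is assigned X
   (or Y) only when both its own CQ and the CQ of its **context window**
   — the 10 kb region the gene lies in — pass the same thresholds
   (`context_cq()`, `assign_genes()`). The joint criterion suppresses
   assignments driven by a single noisy quantity.
3. **25-mer scale**: canonical 25-mers counted per sexed library
   (`count_kmers()`); k-mers seen at least twice in the male library and
   never in the female library (`male_unique()`) are located on the
   assembly (`locate_kmers()`), merged into **Y-unique regions** of ≥ 25 bp
   (`merge_y_regions()`), and summarized as density in 1.8 Mb bins along
   chromosome-scale scaffolds (`density_track()`). A local density spike
   inside an otherwise autosomal scaffold is the signature of misassembled
   Y material.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| window size | 10,000 bp | region-CQ resolution; large enough that Poisson noise on window counts is a few percent at ~20× depth |
| `x_min` | 2 (exclusive) | CQ above the X copy-ratio expectation counts as an X signature |
| `y_max` | 0.2 (exclusive) | CQ near zero counts as a Y signature |
| `scaffold_min_fraction` | 0.40 (inclusive) | fraction of scaffold *length* in tagged windows required for a candidate call |
| `min_window_fraction` | 0.5 | terminal windows shorter than half a window are left untagged rather than amplifying noise |
| k | 25 bp | male-unique k-mer length; long enough to be effectively unique in a ~0.5 Gb genome |
| `min_male_count` | 2 | "present in male" excludes singleton k-mers, which are dominated by sequencing errors; 1 restores the literal reading |
| `max_female_count` | 0 | "absent from female" taken literally; a tolerance knob exists for noisy real libraries |
| density bin | 1,800,000 bp | chromosome-scale summary window for Y-unique regions |
| MAPQ threshold | 20 | conventional unique-mapping proxy for externally aligned BAMs |

## Numerical choices

* **Zero denominators.** CQ is `f/m` when `m > 0`, `+Inf` when `m = 0`
  and `f > 0` (tagged X: the limit is X-consistent), and undefined when
  both are 0. This avoids pseudocount bias; windows with undefined CQ are
  excluded from tags and from scaffold average CQ, and the number of
  infinite windows excluded from the average is reported.
* **Strict inequalities** at both thresholds ("above 2", "below 0.2");
  the 40% scaffold rule is inclusive, and its denominator is total
  scaffold length including untagged windows.
* **Window assignment by read start.** A read belongs to the window
  containing its start coordinate — conservation-friendly (window counts
  sum exactly to retained placements) and indistinguishable from
  fractional assignment at 10 kb resolution.
* **Ambiguous reads are excluded** from coverage by default (a read with
  more than one best location is discarded), mimicking alignment to a
  repeat-masked genome. A `"random"` policy (seeded) retains them at one
  best location. Library size for RPKM is the count of *retained* reads,
  which keeps the normalization self-consistent after filtering.
* **Context window by gene midpoint**, with a midpoint on a window
  boundary belonging to the later window (half-open convention). Genes
  spanning windows also get a length-weighted mean of defined window CQs,
  reported alongside.
* **Canonical k-mers** (the lexicographic minimum of a k-mer and its
  reverse complement, held as 2-bit codes) collapse the strand ambiguity
  of double-stranded sequencing; counting a read set and its reverse
  complement yields identical tables.
* **Merging** unions k-mer spans that overlap or abut (gap 0, the
  bedtools-merge default); density is reported both as region count per
  bin (by region midpoint) and as exact base count per bin.

## What the synthetic data emulate

`sim_config()`/`simulate_assembly()`/`simulate_reads()` generate the
study design the CQ analysis assumes: autosomal, X and Y scaffolds with
copy numbers (2,2), (2,1) and (0,1) for (female, male); interspersed
repeat tracts copied from repeat libraries at 2% divergence and
soft-masked in the FASTA; gene intervals per scaffold; optional Y segments
spliced into autosomal scaffolds; and sexed single-end read sets with
Poisson counts, uniform positions and strands, and optional substitution
errors. The female library is sampled ~11% deeper than the male by
default, emulating the typical unequal sequencing effort between sexed
libraries; RPKM normalization cancels it exactly, which is itself a useful
property to exercise.

Two design points deserve emphasis:

* **Reads come from a per-sex genome, not from the assembly verbatim.**
  Each scaffold is sampled with fixed random flanking context (shared
  between the sexes, never written to the FASTA), so per-base depth is
  uniform across the whole scaffold. Without this, terminal bases are
  covered by only a handful of possible read starts, and a Poisson zero in
  the *female* library combined with two or more male reads would
  fabricate male-unique k-mers at scaffold ends (~0.3 expected per
  scaffold end at 20×) — an artifact of truncated sampling, not of the
  method.
* **Injected Y segments model misassembly faithfully.** The female genome
  lacks the segment entirely (her autosome is the assembly scaffold with
  the segment excised); the male genome carries the same excised autosome
  *plus* the segment as a separate source with its own flanking context.
  Junction k-mers of the misassembled scaffold are consequently covered by
  neither library — exactly as for a real chimeric join — while every
  interior segment base is covered by male reads only.

The generator does **not** emulate: indels, paired-end inserts, quality
profiles, GC bias, contamination, or heterozygosity. Passing recovery
tests therefore demonstrates correctness of the inference machinery under
the copy-number model, not robustness to every artifact of real
libraries.

## Problem sizes used by the tests

The recovery studies simulate 10 scaffolds per compartment of 100 kb each
(3 Mb assembly, ~1.7 million reads at 20× per haploid copy), and a
separate 4 Mb chromosome-scale scaffold carrying a 50 kb Y injection for
the k-mer screen (~3.2 million reads). Unit tests run on 40–100 kb toy
simulations. `scripts/acceptance.R` reruns both studies from scratch at
the seed given on its command line.

## A sharp edge worth knowing about: X calls sit on the threshold

The X copy-ratio expectation **equals** the X tag threshold: E[CQ] = 2,
and the rule is "strictly above 2". At 20× depth a 10 kb X window has
roughly F ~ Poisson(4000) female and M ~ Poisson(2000) male reads, so
CQ ≈ 2 with standard deviation ≈ 0.055 — and P(CQ > 2) ≈ 0.5. Each X
window is close to a fair coin, and a 100 kb X scaffold (10 windows)
clears the 40% rule with probability ≈ 0.83; ten such scaffolds are all
recovered only ~15% of the time. The joint gene+context X criterion
compounds two such coin flips and succeeds for only ~30–40% of X genes.
Y recovery has no such edge (CQ = 0 is far from 0.2) and is essentially
deterministic.

This is a property of the strict threshold at the exact copy-ratio
expectation, visible only because the simulation is unbiased; real
libraries often sit asymmetrically around 2. Consequences worth noting:
X-side recovery improves rapidly with scaffold length (a 4.5 Mb X
scaffold with 455 windows fails the 40% rule with probability ~1e-6), and
users screening short scaffolds for X linkage should prefer the window
*fraction* and mean CQ reported by `call_scaffolds()` over the binary
call. The package deliberately does not lower `x_min` below the
copy-ratio expectation by default; that choice is the user's.

## Known limitations

* The internal read placer is exact-match with a seed-anchored 95%
  identity fallback — appropriate for the simulator's substitution-only
  errors and for desk-scale screens; real data should be aligned
  externally and supplied as BAM (`load_alignments()`).
* In-memory k-mer tables are sized for desk-scale data (tens of millions
  of reads), not for tens of human genomes.
* Repeat annotation is consumed (soft-masks, RepeatMasker `.out`), never
  produced.
* PCR validation support stops at exporting candidate amplicon intervals
  (`validate_targets()`); primer design is external.
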