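---
title: "Discovering breed-specific genetic signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering breed-specific genetic signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsig)
```

## The model

Closed breeding populations fix alleles quickly. A variant that is
homozygous in every sampled dog of one breed, and rare or absent in all
others, is a *breed-specific genetic signature* (BSGS): a deterministic
set condition on genotype frequencies, not a statistical association
test. `breedsig` implements that condition and everything needed to
apply it honestly to a real multi-sample VCF: per-sample quality
gating, per-locus breed validity, both allele orientations, repeat-group
typing for STRs, and positional aggregation of the results.

The core quantity is the breed variant frequency,
$\mathrm{BVF}(b,l,o) = n_{\mathrm{hom}}(b,l,o)\,/\,n_{\mathrm{solid}}(b,l)$:
the fraction of breed $b$'s *solid-call* dogs homozygous for the
oriented state $o$ at locus $l$. Heterozygous dogs count in the
denominator, never the numerator. The scans are:

| record | condition |
|---|---|
| GS   | $\mathrm{BVF} \ge$ `bvf_high` in $\ge 1$ valid breed |
| BSGS | $\mathrm{BVF} \ge$ `bvf_high` in exactly 1 breed and $\le$ `bvf_low` in all other valid breeds |
| pair | $\mathrm{BVF} \ge$ `bvf_high` in exactly 2 breeds, $\le$ `bvf_low` elsewhere |

All comparisons are inclusive (a breed at exactly 0.9 carries; a breed
at exactly 0.1 is still clear). Both orientations are scanned: a breed
fixed for the *reference* allele while others carry the alternative is
as much a signature as the converse — the reference genome is just one
individual. A state carried homozygously by every solid dog in the
whole cohort is excluded as a reference-individual artifact. The pair
scan runs on bi-allelic SNPs, where exclusively shared segments are
interpretable as common descent.

## Tunable parameters

All thresholds live in one `signature_config()` object:

* `bvf_high = 0.9`, `bvf_low = 0.1` — the fixation/exclusion cutoffs
  (fractions). With 3–7 dogs per breed these are effectively "all dogs"
  / "no dogs", which is the intent: tolerance for one discordant dog
  begins only at breed sample sizes ≥ 10.
* `depth_autosome = 10`, `depth_x = 5` reads — a call is *solid* when
  the summed depth of the called allele types reaches the threshold.
  The X threshold is halved because male dogs carry one X, so expected
  X coverage is lower in a mixed-sex cohort. The same summed-depth rule
  serves bi-allelic and multi-allelic loci (one consistent definition).
* `min_breed_n = 3` dogs — below this a breed's frequency at a locus is
  too noisy to assert fixation or absence; the breed is simply ignored
  *at that locus*, on both sides of the BSGS condition.
* `min_reference_n = 300` samples — a signature means little if almost
  nobody informative was typed in the other breeds. The default mirrors
  a ~400-dog cohort; **scale it to your cohort** (the synthetic-cohort
  tests use 20 of 40 dogs). It is evaluated per candidate, i.e. per
  allele orientation.
* `max_short_indel = 10` bp (exclusive) — BSGS reporting for INDELs is
  restricted to short events; longer events stay in the GS catalog.
* STR typing: `unit_len_range = 1–6` bp, `repeat_diff_report = 3` units
  flags large expansions/contractions.
* Aggregation: `hotspot_min = 5`, `stretch_min = 10`,
  `stretch_density = 10`/kb, `structure_gap = 100` kb (inclusive),
  `structure_min = 10`, `block_size = 10` kb, `block_high = 40`.

## STR typing

Multi-allelic INDEL loci are candidate STRs. `decompose_str_locus()`
accepts a locus only when **one** primitive repeat unit explains every
allele as `anchor + unit^k (+ shared suffix)`; compound or interrupted
repeats are rejected as values, not errors. Two canonicalisation rules
make the representation unique: the *shortest* primitive unit wins
(`ATAT` is two `AT`s), and the *maximal* common anchor wins — which
means that when every allele carries at least $m$ repeats, those $m$
copies are absorbed into the anchor and counts are reported relative to
it. Group structure, expansion/contraction calls and the group gap are
invariant under that shift. A shared suffix after the tract is allowed
because variant callers differ in how much right context they include.

Repeat counts are split into low and high groups by two-group k-means
on the distinct counts. In one dimension the optimal two clusters are
contiguous in sorted order, so the package minimises the within-group
sum of squares exactly over all contiguous cuts — the optimum that
Lloyd iterations seeded at the minimum and maximum count aim for.
(Plain Lloyd from those seeds can stall in a local optimum on scattered
count sets such as $\{0, 11, 13\}$; the exact solution is cheap, order
invariant, and matches an exhaustive-partition oracle on random inputs,
which the test suite verifies.) Ties between equally good cuts go to
the larger low group: deterministic, and conservative toward calling
contractions. Group recovery on planted bimodal counts is guaranteed
only when the between-group gap exceeds the within-group spreads;
that is the regime the simulator plants and the only regime in which a
two-group summary is meaningful.

A dog's STR *group call* is `LOW`/`HIGH` when both called alleles fall
in that group, `MIXED` when they straddle, `NO_CALL` when not solid.
Group fixation then feeds the ordinary BSGS condition, with `MIXED`
dogs in the denominator.

## Positional aggregation

Segment arithmetic follows the conventions that reproduce the published
tables exactly: span is `end − start` without `+1`, `length_kb =
span/1000`, `density = n/length_kb`, both printed at two decimals with
half-up rounding (13 signatures spanning 1,166 bp → 1.17 kb at
11.15/kb; 204 spanning 185,776 bp → 185.78 kb at 1.10/kb). Stretches
are *maximal* qualifying windows (no one-member extension still
qualifies); overlapping maximal windows reduce to the longest, then
most members, then leftmost. The structure gap rule is inclusive
(exactly 100 kb stays joined). Blocks are 1-based closed intervals
`[k·10000+1, (k+1)·10000]`, so position 10,000 is in block 0 and 10,001
in block 1. Block-density strata use inclusive thresholds (`≥
block_high`). The stretch finder materialises an $n^2$ window matrix
per breed/chromosome: fine for catalogs of thousands of members, not
for millions — acceptable because stretch inputs are per-breed BSGS
lists, which are orders of magnitude smaller than the variant pool.

## Similarity and composition

Each GS carrier set of size $k$ credits all $k$ breeds and all
$\binom{k}{2}$ pairs in the sharing matrix $N$; similarity is
$s_{ij} = N_{ij}/\sqrt{N_{ii}N_{jj}}$, reported raw, as a percentage,
and min–max standardised over the off-diagonal. Per-dog composition
scores each GS locus 0/0.5/1 by the dog's genotype against the stored
orientation (hom-reference scores 1 on reference-orientation
signatures), leaves non-solid loci at 0 while keeping them in the
denominator (the breed's total GS count), and returns the full ranked
breed profile.

The exact two-sided Fisher test used for coding/non-coding enrichment
sums hypergeometric point probabilities not exceeding the observed
table's (with the customary $1+10^{-7}$ relative tolerance). Two-sided
is a choice — the direction of the enrichment was not prescribed — and
the implementation is verified against exhaustive enumeration over all
tables with total ≤ 60 and spot-checked against `stats::fisher.test`.

## The synthetic cohort

`cohort_design()` + `simulate_cohort()` generate a deterministic
(seeded) 8-breed × 5-dog cohort over two autosomes and an X chromosome,
~5,000 loci by default, with a truth table listing every record the
scanner must and must not find. Planted content covers every code path:
scattered SNP/INDEL BSGS in both orientations, a 13-member/1.17-kb
high-density stretch, a 15-member multi-type structure, gene hotspots,
STR expansions and contractions across unit lengths 1–4, multi-carrier
GS, four breed-pair-exclusive signature sets, a 45-signature
pseudoautosomal-region block cluster, X-specific signatures whose
carriers sit at depth 5–9 (solid only under the X rule), universal
variants, AD-less sites, non-STR multi-allelic loci, and five decoys
each violating exactly one rule (one heterozygous carrier dog, an
invalid carrier breed, insufficient reference support, a `MIXED` dog in
the carrier breed, three carrier breeds for the pair scan).

Two constructions make recovery a *seed-independent* property rather
than a lucky draw. Background loci give every breed at most two
homozygotes per orientation among its five dogs, so no solid subset of
≥ 3 dogs can reach BVF ≥ 0.9 under any dropout realisation. And planted
carrier sets never exceed 4 of the 8 breeds, so the scaled
`min_reference_n = 20` is always satisfiable. Depths follow a negative
binomial (mean 30, size 8) with a 5% dropout fraction pushed below
threshold at background loci, so the quality filter genuinely runs.

What the simulator does **not** emulate: linkage disequilibrium,
realistic site-frequency spectra, allele-calling error modes,
population structure within breeds, or male X hemizygosity (genotypes
are used exactly as written in the VCF, as the frequency analyzer
itself does). Passing the planted-truth suite therefore demonstrates
the *scan logic* is exact, not that the thresholds are well calibrated
for any particular real cohort.

## Numerical and degenerate-input choices

* Missing genotype (`./.`) and depth-unknown (absent/`.` AD) are
  distinct states; both fail the solid-call test.
* Half-open ANN parsing: only allele, effect term, gene/region label
  and protein position are retained; `&`-joined effect terms are split
  for functional/coding classification.
* Multi-allelic SNPs are dropped (class `OTHER`) — the scans operate on
  the bi-allelic SNP/INDEL pools and the multi-allelic INDEL pool only.
* A zero-span stretch window (coincident positions) counts as
  infinitely dense and qualifies if long enough.
* Breeds with zero signatures yield `NA` similarity rows and an `NA`
  composition column, each with a warning, never a crash.
* Degenerate Fisher margins (empty row or column) give p = 1.
* Reported p-values, densities and percentages are computed in double
  precision and only rounded at the reporting boundary
  (`write_report`, half-up at two decimals).

## Scale

The default desk-scale problem sizes — ~5,000 loci × 40 samples for the
end-to-end suites, 200 random instances per oracle comparison, all 2×2
tables with total ≤ 60 for the Fisher check — were chosen so the whole
validation runs in about a minute on one core while still exercising
every branch. The engine itself is single-threaded and deterministic;
the command-line wrapper accepts `--threads` for interface
compatibility and guarantees byte-identical output regardless of its
value.
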