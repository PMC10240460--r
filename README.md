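# breedsig

Genome-wide discovery of breed-specific genetic signatures in
multi-breed cohorts.

Modern dog breeds are closed, strongly selected populations: many
variants that are polymorphic across the species are *fixed* within a
single breed. Given a jointly called, SnpEff-annotated multi-sample VCF
and a sample→breed panel, `breedsig` finds the variants whose
homozygous state characterises a breed (or a pair of breeds), across
three variant classes — bi-allelic SNPs, short INDELs, and short tandem
repeats (STRs) typed from multi-allelic INDEL alleles — and then maps
where in the genome those signatures cluster. The same machinery
applies to any set of labelled populations (strains, lineages, isolates),
not only dogs.

## The statistic

For breed *b* at locus *l* and allele orientation *o* (alternative
allele, reference allele, or an STR repeat group), the **breed variant
frequency** is

```
BVF(b, l, o) = n_hom(b, l, o) / n_solid(b, l)
```

where `n_hom` counts dogs homozygous for the oriented state and
`n_solid` counts dogs with a *solid call*: a non-missing genotype whose
summed called-allele read depth is ≥ 10 on autosomes (≥ 5 on X). A
breed is *valid* at a locus when it has ≥ 3 solid dogs. Then, scanning
both orientations and excluding states carried homozygously by every
solid dog (artifacts of the reference individual):

* **GS** (genetic signature): BVF ≥ 0.9 in at least one valid breed;
* **BSGS** (breed-specific GS): BVF ≥ 0.9 in exactly one breed *and*
  ≤ 0.1 in every other valid breed;
* **pair signature**: BVF ≥ 0.9 in exactly two breeds, ≤ 0.1 elsewhere.

Candidates supported by fewer than `min_reference_n` solid samples in
non-carrier breeds are dropped (300 in a 412-dog cohort; scale it to
your cohort). STR loci are typed by decomposing the alleles as
`anchor + unit^k` for a single primitive 1–6 bp unit, splitting the
repeat counts into low/high groups by two-group k-means, and scanning
the group fixation (`EXPANSION` when the carrier breed is fixed in the
high-repeat group, `CONTRACTION` for low).

Downstream, BSGS catalogs are merged across variant types and
aggregated into gene **hotspots** (≥ 5 BSGS in one gene region),
high-density **stretches** (≥ 10 BSGS at ≥ 10/kb), breed-specific
**structures** (≥ 10 BSGS with inter-member gaps ≤ 100 kb, with
protein-altering effect flags), and 10-kb **block** summaries. GS
carrier sets yield a breed×breed sharing matrix, geometric-mean
similarity scores `s_ij = N_ij / √(N_ii·N_jj)` with min–max
standardisation, and a per-dog breed composition (each GS locus scores
0 / 0.5 / 1 by genotype).

## Worked example

No external data is needed: the package ships a cohort simulator that
plants known signatures (and near-miss decoys) into a synthetic
8-breed × 5-dog cohort and writes the VCF, panel and truth table.

```r
library(breedsig)

sim    <- simulate_cohort(cohort_design(n_background = 500), seed = 1,
                          out_dir = "sim")
cfg    <- signature_config(min_reference_n = 20)   # scaled to 40 dogs
cohort <- read_cohort(sim$vcf, read_breed_panel(sim$panel_path))
scan   <- discover_signatures(cohort, cfg)
scan
#> Signature scan
#>   GS records:    205
#>   BSGS records:  100 (SNP 64, INDEL 19, STR 17)
#>   pair records:  12
#>   STR loci typed: 22

head(scan$bsgs[scan$bsgs$type == "STR",
     c("pos", "breed", "signature_type", "unit", "unit_diff",
       "carrier_range", "reference_range")], 3)
#>         pos           breed signature_type unit unit_diff carrier_range reference_range
#> 60 35180000 AlaskanMalamute      EXPANSION   TG         4      A(TG)6-7        A(TG)0-2
#> 83  5400000           Akita      EXPANSION TTCT         5   A(TTCT)8-10      A(TTCT)0-3
#> 84  5600000           Akita    CONTRACTION TTCT         3      A(TTCT)0      A(TTCT)3-4

compare_to_truth(scan, sim$truth)
#>   catalog n_expected n_observed precision recall decoy_rejection
#> 1      gs        205        205         1      1               1
#> 2    bsgs        100        100         1      1              NA
#> 3    pair         12         12         1      1              NA
```

The `carrier_range` column reads as allele notation: `A(TTCT)8-10`
means the carrier breed's alleles hold 8–10 copies of the `TTCT` unit
after the `A` anchor, versus 0–3 copies in every other breed — a
5-unit breed-specific expansion. `compare_to_truth` shows the scan
recovered every planted signature and rejected every decoy.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/breedsig.R`
(`simulate`, `discover`, `segments`, `blocks`, `similarity`,
`infer-breed`, `stats` subcommands; outputs are byte-identical for any
`--threads` value).

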