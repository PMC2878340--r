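---
title: "Measuring allele-specific expression of polymorphic gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allele-specific expression of polymorphic gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelequant)
```

## The problem

The classical HLA class I loci (HLA-A, -B, -C) are the most polymorphic
genes in the human genome, and their alleles within and across loci are
extremely similar to one another. Measuring the expression of *one allele*
— rather than the locus or the whole class — therefore requires assays that
discriminate sequences differing at a handful of positions: PCR primers
whose 3′-terminal base sits on a position unique to the target allele
(the ARMS principle), and, at the protein level, allele-specific antibodies
quantified against a bead standard. `allelequant` implements this
measurement chain end to end:

1. **allele database** — parse and index an IMGT/HLA-style cDNA FASTA,
   with ATG-anchored coordinates and exon models;
2. **primer design** — enumerate allele-specific primer pairs under a
   constraint set (length, nearest-neighbor Tm, amplicon size, 3′
   discrimination, no in-silico cross-reactivity), plus locus-specific
   long-range assays spanning every exon–exon junction;
3. **absolute qPCR** — plasmid dilution-series standard curves, Pfaffl
   amplification efficiency, copy numbers, reference-gene normalization,
   geometric-mean ratios and fold-induction kinetics;
4. **quantitative flow cytometry** — bead-calibrated antibody binding
   capacity (ABC) and a semi-quantitative MFI-ratio scale;
5. **CDC scoring** — complement-dependent microcytotoxicity typing calls;
6. **synthetic data** — seeded generators for every input, with recorded
   ground truth, so the whole chain is testable without any download.

## Coordinates and primer-name labels

Assay primers in this field are named by the start of the primer relative
to the +1 A of the ATG, with no coordinate zero (−1 immediately precedes
+1). The printed fragment length of an assay equals the reverse label minus
the forward label by plain subtraction; this holds for positive labels and
for labels straddling the ATG (labels −2 and 1063 give 1065 bp).
`coord_to_index()` / `index_to_coord()` convert between this convention and
sequence indices; `amplicon_length_from_labels()` applies the subtraction.
For pairs designed by this package the labels are generated so that the
label difference always equals the amplicon length — labels are
presentation only, the half-open index interval on the template is
authoritative. (For an amplicon straddling the ATG, a label computed
naively from the reverse primer's coordinate would be off by one because
the label axis has no zero.)

## The melting-temperature model

No Tm model is universal; what matters is that one documented model with
fixed conditions is used consistently for design and validation. We use
the unified nearest-neighbor parameter set of SantaLucia (1998, PNAS
95:1460–1465): ten stacking ΔH°/ΔS° terms plus terminal A·T / G·C
initiation terms, the entropic salt correction ΔS° + 0.368·(N−1)·ln[Na⁺],
and the bimolecular term R·ln(C_T/4) for non-self-complementary duplexes.
Default conditions are 50 mM monovalent salt and 500 nM total primer.
The parameter table is frozen in the package source, and the test suite
pins the model to values computed by an independent implementation of the
same published table. Under this model Tm is invariant under reverse
complement, monotone in GC content, and increases with salt and primer
concentration — all property-tested.

The published assays this package mirrors were designed with a commercial
tool whose internal model and conditions differ; their primers evaluate to
≈59–64 °C under our conditions. The 66 °C target in the default constraint
set refers to *our* model's scale and is met by the designer's own output.

## Design constraints and their defaults

`design_constraints()` encodes the assay rules:

| parameter | default | unit | why |
|---|---|---|---|
| `primer_len` | 21 | nt | the family's target primer length |
| `len_range` | 17–25 | nt | published assay primers actually span 18–24 nt despite the 21-mer target |
| `tm_target`, `tm_tol` | 66 ± 2 | °C | one annealing temperature for all assays on a plate |
| `amp_min`–`amp_max` | 70–120 | bp | short amplicons for SYBR-based quantification |
| `three_prime_k` | 1 | nt | "a 3′ base difference": one terminal base on a discriminating position; configurable upward because single-base 3′ discrimination can be leaky |
| `max_internal_mismatches` | 2 | nt | binding model: mismatches tolerated outside the 3′ window |
| `product_window` | 50–2000 | bp | plausible off-target product sizes in the cross-reactivity screen |

The 70–120 bp bound is kept *hard*: one published assay (A\*03:01, 128 bp)
violates it, and `validate_pair()` reports that violation rather than
assuming the bound was soft in practice.

The in-silico PCR binding model (`in_silico_pcr()`) emits a product for
every convergent forward/reverse binding-site pair whose size falls in
`product_window`, where a binding site allows at most
`max_internal_mismatches` outside the 3′-terminal window and none inside
it. It deliberately models only the designed orientation of each primer
(no single-primer or inverted products) and no dimer or secondary-structure
thermodynamics — the published design process states none. The scanner is
verified against a brute-force all-offsets oracle on instances up to 1 kb.

**Discrimination comparison set.** By default a discriminating position
must differ from *every* other allele in the database regardless of locus,
because HLA-A/-B/-C are cross-similar enough to cross-prime;
`within_locus = TRUE` restricts the comparison. Alleles with identical
cDNA but distinct names are kept distinct (such a pair is simply
undesignable), since collapsing them would silently weaken the
cross-reactivity screen.

**Ranking.** Emitted pairs are ordered by ascending |Tm − target| summed
over both primers, then by distance of the amplicon from the midpoint of
the size bounds, then lexicographically by primer sequence. The third key
makes the output byte-deterministic for identical inputs.

**Degenerate inputs.** Alignment gap columns are masked from candidate
windows and map to "no position" in the coordinate system; gapped templates
are degapped before binding-site scanning.

**Long-range locus-specific design.** `design_locus_specific()` anchors
primers in windows identical across all alleles of the locus and without
predicted products on any other locus, with amplicon bounds 1000–1200 bp
covering every exon–exon junction (so a predominant splice variant would
appear as a shorter product; `splice_check()` predicts the size with each
exon skipped). The default long-range constraints widen the Tm window to
±5 °C and the length range to 18–25 nt: these primers must anchor in
locus-private UTRs whose composition the designer does not control, and
long-range protocols tolerate a broader Tm spread.

## Absolute qPCR quantification

The standard curve is an ordinary least-squares fit of CT on
log₁₀(copies) over a serial 10-fold plasmid dilution series (six levels,
2×10⁻² to 2×10⁻⁷ ng/µL by default in the simulator; at least four levels
required). Copy numbers come from the plasmid mass via
copies = conc·volume·10⁻⁹·N_A/(size·650) with 650 g/mol per bp.
The Pfaffl efficiency is E = 10^(−1/slope); E = 2 is perfect doubling
(slope −3.3219). Efficiency QC uses a hard floor of 1.92 and a warning
band below 1.96, mirroring an acceptance rule of "exceeding 1.96" with an
observed working range down to 1.92; both thresholds are arguments.
Technical replicates are averaged on the CT scale before quantification
(common practice). Each sample's target copies are divided by the
reference-gene copies from the same sample; ratios are summarized across
independent experiments by geometric mean, and fold inductions are taken
against the earliest timepoint. Zero or negative inputs are errors — no
imputation. There is no inter-plate calibrator: a standard curve per
target per run is required input, matching the protocol in which curves
are on every plate.

## Quantitative flow cytometry

Bead kits provide beads with known numbers of IgG molecules stained with
the same secondary antibody as the cells. We fit log₁₀(ABC) on log₁₀(MFI)
(the standard model for such kits; a linear-scale option exists behind the
`scale` argument) and invert it with `abc_from_mfi()`. No isotype or
background subtraction is applied before ABC — the reference workflow
reports ABC directly — and only the semi-quantitative scale uses the
isotype ratio. That scale is adopted literally from its published
definition: with ratio = specific/isotype MFI, "−" is ratio ≤ 3, "+/−"
below 10, "1+" at least 10, "2+" at least 30, "3+" at least 50 and "4+" at
least 100. The bins have mixed openness (the "−"/"+/−" boundary is closed
at 3 from the left, the graded bins are closed from the right); a ratio of
exactly 3 scores "−". Fold differences between ABC values are presented
with the field's rounding: nearest integer at ≥10, one decimal below.

## CDC scoring

A well's kill percentage is 100·red/(red+green); wells (duplicates ×
experiments) are averaged unweighted (cell counts per well are similar by
design, and no weighting rule is standard), and a serum types positive
only when the mean *strictly* exceeds 50% killing. Wells with fewer than
200 counted cells are flagged, not dropped. The negative-control (AB
serum) background is reported alongside and not subtracted before calling
— the raw >50% criterion is the standard — with subtraction available
behind a flag.

## What the synthetic generators emulate — and what they do not

Every generator is a pure function of (parameters, seed). The master seed
is split into named sub-streams (one fixed offset per assay, sub-seed =
(seed·7919 + offset) mod 2³¹−1), so adding one generator never perturbs
another's draws.

`gen_allele_family()` builds what the *designer* needs, not a population
genetics model: a shared ancestral coding sequence, per-locus substitutions
(4% by default, so cross-locus divergence exceeds within-locus divergence),
locus-private UTRs (independently generated, 60 nt each; at least 40 nt of
5′UTR so negative coordinates are exercised), an 8-exon model partitioning
the coding region, and exactly one engineered site per allele at which that
allele differs from every other allele. Within-locus random SNPs are
assigned to *two* alleles of a locus (with at least two non-carriers), so
they mimic lineage-shared polymorphism and never create additional
discriminating positions — which makes the engineered sites exactly the
ground-truth answer the designer must find. Sequences are GC-rich (62%)
like real class I cDNA, which is also what makes a 66 °C Tm reachable at
17–25 nt. The generator does **not** emulate indels, intron-containing
genomic sequence, recombination, or the empirical site-frequency spectrum
of IMGT/HLA; passing tests show the algorithmic chain recovers planted
truth under the stated noise models, not that it handles every quirk of
real nomenclature-era data.

The assay generators forward-simulate exactly the models the fitting code
inverts: CT = intercept + slope·log₁₀(copies) + N(0, σ_CT), lognormal MFI
noise around the log-log calibration, binomial CDC counts. The default
scenario (`simulate_scenario()`) mirrors the published study shape: six
target alleles (two per locus) plus one reference gene, a 0/24/48/72 h
induction time course in three independent experiments with duplicate
wells, constitutive ratios 1.8/1.7/0.9/2.0/1.6/7.4, fold inductions
8.9/10.7/30.1/41.8/18.6/5.4, ABC truth 204 370 / 12 076 / 5 174, and kill
fractions 0.96/0.28/0.09 (0.81/0.26 after stimulation) — the published
point values adopted once as the scenario's conditions. Fold induction
follows fold(t) = fold₇₂^(t/72), a geometric ramp culminating at 72 h.

## Validation problem sizes

The suite validates the chain at these sizes, chosen to give the
statistical assertions comfortable resolution: 100 seeded families
(2 loci × 4 alleles × 600 nt) for designer soundness, with every emitted
pair re-checked by the independent validator; exhaustive brute-force
equality of the in-silico PCR scanner on instances up to 1 kb; 200 seeded
qPCR replicates at σ_CT = 0.1 (slope recovered within ±0.05, log-ratio
bias < 2%); 100 bead panels at 5% noise (median ABC error < 10%); and 500
CDC simulations (binomial interval coverage ≥ 93%).

## Known limitations and open decisions

* The published assay table embeds two internal inconsistencies, which
  `fixture_check()` reports instead of fixing: the long-range B-locus row's
  labels (−40, 1091) imply 1131 bp against a printed 1143 bp, and one
  C-locus assay lists no reverse primer. Likewise the prose's "40-fold"
  protein difference is 39.5 from the printed ABC values and rounds to 39;
  the check reports the computed value.
* The published mRNA column is treated as fold-inductions in the default
  scenario (its values match the prose's fold statements); this is an
  interpretation, flagged as such.
* `in_silico_pcr()` predicts products only for the designed orientation of
  each primer and uses a mismatch-count binding model, not binding
  thermodynamics.
* The qPCR module is absolute-quantification only; there is no ΔΔCT mode
  and no melt-curve analytics. The flow module consumes per-population
  summary MFIs, not FCS events or gates. The CDC module consumes counts,
  not images.
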