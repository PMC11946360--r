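---
title: "Screening canine exomes against a phenotype-associated variant panel: methods and design notes"
author: "ExomeScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening canine exomes against a variant panel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ExomeScreen)
```

# The problem

Whole-exome sequencing (WES) captures and sequences the protein-coding
fraction of a genome. In veterinary genetics it is attractive as a
*screening* instrument: a single assay can in principle genotype every
known phenotype-associated variant at once, including variants published
after the capture design was frozen. Whether that promise holds depends
on two things this package quantifies:

1. **Coverage.** Is every base of every panel variant sequenced deeply
   enough for a reliable genotype? Off-target loci (intronic, UTR,
   promoter variants) receive only incidental coverage and are expected
   to fare far worse than coding loci.
2. **Interpretation.** Given a multi-sample VCF, can panel variants be
   located reliably (indel representations differ between catalogues and
   callers) and can the genotype be read out correctly for autosomal,
   X-linked and mitochondrial inheritance?

The package implements the full analysis as reusable, tested components:
catalogue curation, per-base depth qualification, VCF screening with
zygosity interpretation, carrier-accumulation analysis, and
clinical-style reporting. A synthetic-data module generates catalogues,
depth tracks and VCFs with known ground truth, so every stage is
verifiable without access to sequencing data.

# Catalogue curation

The raw input is an OMIA-style table of phenotype-associated variants.
Four inclusion criteria are applied, in order, and each excluded record
receives exactly one primary reason code:

| # | criterion | reason code |
|---|-----------|-------------|
| 1 | location parses as `g.<digits>` / `m.<digits>`, with a usable chromosome and well-formed alleles | `NO_GENOMIC_LOCATION` |
| 2 | reference build tag equals the accepted build (default `CanFam3.1`) | `WRONG_BUILD` |
| 3 | gene symbol present and a well-formed alphanumeric token | `BAD_GENE_SYMBOL` |
| 4 | variant size `max(nchar(ref), nchar(alt))` at most 20 bp | `SIZE_GT_MAX` |

Criterion 3 is deliberately operationalised without an external gene
database: a syntactic token check is reproducible and dependency-free,
which is what a curation criterion must be to be testable. The report
separates criteria 1–3 (annotation failures, "stage 1") from the size
criterion ("stage 2") because that is how a manual curation pass
naturally proceeds — first discard records that cannot be located at
all, then apply the size cutoff to the locatable ones. The counts always
reconcile: `n_input = stage1 + stage2 + retained` (a validity invariant
of the `CurationReport` class).

Retained variants are classified into the three categories that drive
all downstream summaries: `CDS_1BP` (single-nucleotide variants in
coding sequence), `NONCODING_1BP` (1 bp variants in introns, UTRs or
promoters — folded into one group because they share the off-target
coverage regime), and `LARGER` (2–20 bp, any location). `splitByYear()`
additionally partitions the panel at the capture-design year (default
2014, boundary year inclusive on the *pre* side), which is how the
design's ability to pick up post-design discoveries is assessed.

# Depth qualification

A variant locus is *successfully sequenced* in a sample at cutoff
$T \in \{10, 20, 30\}$ iff **every** base of its span has depth
$\ge T$. One shallow base fails the whole variant — for larger variants
this is intentionally conservative, since a partial genotype over an
indel is not a genotype.

Span conventions:

* substitution: the variant base itself;
* deletion / delins of $k$ reference bases: all $k$ bases;
* pure insertion: inserted bases have no reference coordinate, so the
  **two flanking anchor bases** must qualify instead.

The insertion rule is a package convention (a catalogue states where an
insertion goes, not which reference bases prove it was sequenced); it is
the strictest choice that stays on the reference, and it is exposed
through `variantSpan()` so alternative conventions can be layered on
top. Internally an insertion is stored with `position` equal to the
first reference base *after* the insertion point — the natural fixed
point of reference-free allele trimming (below) — so its span is
`{position - 1, position}`.

Positions absent from a depth file are depth 0. This makes "a locus
with no coverage at all" representable without sentinel values and
means depth lookups never fail.

`qualifyPanel()` returns a `QualificationMatrix`, a
`SummarizedExperiment` subclass with one logical assay per threshold.
Its validity method enforces *threshold monotonicity* (qualified at 30x
⇒ 20x ⇒ 10x), so a violated invariant is caught at object construction,
not in a downstream table. Summary tables report min / max / median /
mean of per-sample qualified counts per category, plus the same as
percentages of the category size.

Two numerical choices matter for table reproduction:

* **Rounding** is half-up to 2 decimals (`roundHalfUp()`), not base R's
  round-half-to-even; percentage cells in performance tables are
  conventionally printed half-up.
* **Median** uses the standard midpoint rule for even sample counts, so
  cohorts of any size work; for odd cohorts (like the default 49-sample
  cohort) it is a single order statistic.

Percentages are always recomputed from counts (`pct =
round(100 * count / n, 2)`), never carried as independent numbers, so a
summary table can always be audited against its own count columns.

# Allele normalization and VCF screening

Catalogues describe indels minimally (`TG` deleted at 1301); callers
emit anchored records (`CTG > C` at 1300). `normalizeAllele()` maps both
to one key by trimming the shared suffix, then the shared prefix
(advancing the position), with no reference sequence involved. Applying
the *same* function to both sides makes matching representation-robust;
the trimming is idempotent, and the test suite checks it against an
exhaustive trimming oracle on randomized allele pairs. Reference-free
trimming cannot left-align across repeat runs (that requires the
reference); within a panel whose loci are well separated this is
irrelevant, and the limitation is documented rather than papered over.

`scanVcf()` then walks every (sample, panel variant) pair:

* multi-allelic records are split per alternate allele, and the dosage
  counted is that of the *matching* allele index only;
* records failing the hard filter (FILTER other than `PASS`/`.`) are
  `NOT_ASSESSABLE` — a failed site is not evidence either way;
* genotypes with any missing allele (`./1`, `./.`) are
  `NOT_ASSESSABLE`;
* a panel variant **absent** from the VCF is `WILDTYPE` only where its
  span qualified at the reporting depth threshold (default ≥10x).
  Callers emit variant sites only, so absence of a record is evidence
  of the reference genotype only where there was coverage;
* if several VCF records match one panel key, the first by position is
  used with a warning — duplicates indicate upstream problems.

Zygosity interpretation is keyed on chromosome context and sex:
autosomes (and the female X) map dosage 0/1/2 to
`WILDTYPE`/`CARRIER`/`HOMOZYGOUS_ALT`; any dose on the male X is
`HEMIZYGOUS_ALT` (a dose of 2 there is flagged as a data inconsistency
but still reported hemizygous, the least-wrong reading); any dose on MT
is `MITO_PRESENT` under a homoplasmic assumption — heteroplasmy
fractions are out of scope. Pseudoautosomal regions are ignored; no
panel variant is annotated as PAR.

The carrier/hemizygous distinction matters downstream: autosomal
recessive carriers can be used in breeding when mated to homozygous
wildtype partners, whereas dominant and X-linked findings cannot be
managed that way — so `buildReport()` groups findings by inheritance
mode (it generates no advice text).

# Carrier accumulation

`accumulationCurve()` asks how the fraction of samples with at least
one detected variant grows as the screened panel grows by random
increments (default grid: 50-variant steps, full panel appended). The
draw protocol is configurable because the analysis it mirrors does not
pin it down:

* **NESTED** (default): each replicate grows one subset incrementally,
  so every replicate's curve is non-decreasing — the behaviour a single
  published curve implies;
* **INDEPENDENT**: each size drawn afresh; with `exact = TRUE` the
  expectation is computed in closed form — a sample with $d$ of $m$
  variants detected is missed by a random $k$-subset with probability
  $\binom{m-d}{k}/\binom{m}{k}$ — which the tests verify against
  exhaustive enumeration of all $\binom{m}{k}$ subsets on a toy matrix.

Defaults: 100 replicates, seed 1, both exposed. The full-panel point is
computed directly (not sampled), so it is identical across seeds, modes
and replicate counts.

# The synthetic cohort

The generators emulate the statistical structure the analysis assumes,
with ground truth serialized alongside every output:

* **Catalogue**: 352 valid records in a 251 / 7 / 94 category mix, 323
  disease-flagged, 170 published after 2014 (118 CDS / 6 noncoding / 46
  larger), 6 X-linked records on X and 2 mitochondrial on MT, plus a
  configurable number of invalid records per curation criterion, each
  violating exactly one criterion. Variants live on an artificial
  mini-genome (chr1–chr10, X, MT; kilobase scale, 200 bp spacing) so no
  reference download is needed and panel keys cannot collide.
* **Depth**: per-locus coverage is zero-inflated gamma-Poisson
  (negative binomial): one gamma rate per (sample, locus) drives all
  span positions, mimicking the local correlation of real coverage.
  Defaults — mean 35x for CDS, 5x for noncoding (with a 15 % zero
  mass), 37x for larger variants; dispersion 3 (0.6 noncoding) — echo
  the coverage contrast between on- and off-target loci that motivates
  the whole depth analysis. The marginal category mean is
  $(1 - z)\mu$, which tests recover within ±10 % at cohort sizes
  chosen for that tolerance (60 samples × 60 noncoding loci).
* **VCF**: dosages are drawn per inheritance context under
  Hardy–Weinberg allele frequencies, with the per-variant carrier
  probability calibrated as $p = 1 - 0.2^{1/n_\text{disease}}$ so that
  a 323-variant disease panel on 49 samples yields an expected
  ≥1-detection fraction of 0.8 — the saturation regime of interest.
  Males never carry two X alleles; MT genotypes are haploid. Indels are
  emitted in anchored caller representation (deliberately different
  from the catalogue's minimal form), a fraction of SNV sites gains a
  decoy alternate allele (sometimes listed first, so allele-index
  bookkeeping is exercised), a fraction of sites fails the hard filter,
  and one genotype is emitted half-missing. Deterministic plants
  guarantee one hemizygous male-X carrier, mitochondrial presence in
  two samples and one indel carrier regardless of the random rates
  (skipped when the carrier rate is 0 so the zero case stays exact).

What the synthetic cohort does **not** emulate: linkage and breed
structure (genotypes are independent across variants and samples),
capture-bait geometry (depth is locus-local, not bait-driven),
alignment and calling artefacts (genotypes are planted, not called),
and heteroplasmy. Passing tests therefore demonstrate that the
*analysis logic* is correct under the stated statistical structure —
not that any particular real cohort will show the same percentages.

# Problem sizes and reproducibility

The test suite runs the full default cohort (49 samples × 352 variants)
once for the end-to-end recovery check, a 12-sample × 44-variant cohort
for pipeline-level properties, 10,000 randomized loci for the
qualification oracle, and 60 × 140 for depth-model recovery — sizes
chosen so each check has the statistical resolution it needs while the
whole suite stays quick. All randomness is seed-controlled;
`runPipeline()` with a fixed configuration is byte-identical across
runs, which the suite asserts on the written TSVs.

# Known limitations

* Reference-free trimming cannot disambiguate indels inside repeat
  runs; panels with such loci need reference-aware left-alignment
  upstream.
* Structural and copy-number variants are out of scope, as is
  pathogenicity (re-)classification; the package screens a curated
  panel, it does not discover or re-evaluate variants.
* The clinical report lists findings and coverage gaps; it deliberately
  generates no breeding or medical advice text.
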