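---
title: "Screening cohorts for germline cancer predisposition variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cohorts for germline cancer predisposition variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germscreen)
```

## The analysis this package implements

Plasma cell dyscrasias — multiple myeloma (MM) and its precursor and
related conditions (smouldering myeloma, MGUS, plasma cell leukaemia) —
show familial clustering, and a number of dominantly inherited cancer
genes have been proposed as predisposition candidates. The analysis
pattern this package supports screens the germline exomes of an
unselected patient cohort against a candidate gene panel and asks three
questions:

1. Which rare, protein-impacting variants in panel genes do patients
   carry, after conventional quality, panel, rarity and impact
   filtering?
2. Which of those variants are pathogenic (P) or likely pathogenic
   (LP) under the ACMG/AMP 2015 evidence-combination framework?
3. Do patients carry more P/LP variants than reference populations —
   summarized as odds ratios against per-variant allele counts from a
   population database, both a global and an ancestry-matched subset —
   and do any single genes recur in at least two patients?

Each stage is exposed as its own function (`run_cascade()`,
`classify_variant_table()`, `associate()`, the summary helpers) and
`run_screen()` orchestrates them over a bundle of inputs.

## The filtering cascade

`run_cascade()` applies four steps in a fixed order and records a
telescoping audit trail (each step's survivor count is the next step's
input count; removed-variant sets are disjoint):

* **quality** — per-carrier read depth ≥ 10, genotype quality ≥ 20,
  heterozygous allele balance in [0.25, 0.75]. These are conventional
  short-read thresholds; a carrier failing them is removed, and a
  variant left with no carriers is dropped. Tables without genotype
  metrics (the TSV dialect) skip this step with a warning.
* **panel** — the gene must be on the candidate panel; survivors are
  annotated with the gene's inheritance mode (AD/AR/XL).
* **rarity** — allele frequency AC/AN must be at or below the
  threshold (default 0.001) in *every* reference subset independently,
  mirroring dual-subset reporting against a global and a
  population-matched stratum. Variants absent from a subset count as
  frequency zero ("absent-as-zero"), matching databases that report
  no frequency at all for unobserved variants. Rarity is an *allele*
  frequency, the semantics population databases publish, not a carrier
  frequency.
* **impact** — the coding consequence must be protein-impacting
  (missense, nonsense, frameshift, splice site, start loss, in-frame
  indel); synonymous and unclassified consequences are removed.

The panel, rarity and impact steps are pure per-variant predicates, so
any ordering of those three yields the same surviving set (a property
the test suite checks); the fixed order is for the audit trail's
readability. All thresholds live in `filter_config()` and are
deliberately overridable: published screens rarely print their full
QC recipe, so the defaults here are chosen to be conventional and to
retain every variant of the packaged worked example, not asserted as
the only defensible values.

## The ACMG/AMP combining engine

Evidence arrives as coded criteria — PVS1 (very strong), PS1–PS4
(strong), PM1–PM6 (moderate), PP1–PP5 (supporting) in the pathogenic
direction; BA1 (stand-alone), BS1–BS4, BP1–BP7 in the benign
direction — and `classify_criteria()` combines them by the published
rule table into one of five tiers. The engine evaluates clauses with
"at least" semantics (e.g. PVS1 + 1 PM + 1 PP is satisfied by two
supporting items) in a canonical order, pathogenic clauses before
likely-pathogenic and benign before likely-benign; `matched_rule`
names the first satisfied clause and `acmg_explain()` returns the full
trace. Design points:

* **Conflicts.** If both a pathogenic-direction and a benign-direction
  clause are satisfied the classification is VUS with a conflict flag —
  the framework's prescribed behaviour for contradictory evidence.
* **PP5/BP6.** The reputable-source codes are accepted by default
  because published classifications use them heavily; later guidance
  deprecates them, so `use_pp5 = FALSE` removes them before counting.
* **Strength overrides.** A code may be used at a non-default strength
  within its direction (`strength_override = c(PVS1 = "strong")`);
  unused by default.
* **Published tiers vs engine tiers.** Curated inputs sometimes print a
  tier their listed evidence does not support under the standard
  clauses. With `prefer_printed = TRUE` the printed tier governs
  downstream carrier counting — it is the published expert assessment —
  while the engine's own tier is kept alongside and disagreements are
  flagged `known_discrepancy`. The packaged worked example contains
  exactly two such rows (one printed P whose evidence reaches only a
  likely-pathogenic clause, one printed LP whose evidence satisfies no
  clause); they are shipped verbatim and flagged rather than
  second-guessed, since the original combining procedure may have
  differed in unstated ways.

The engine is validated two ways: against the printed classifications
of the worked example, and exhaustively against an independent
brute-force transcription of the rule table over every evidence subset
of size ≤ 4 (24,158 sets).

## Carrier burden against reference allele counts

The counting unit is the **carrier**, not the allele, because cohort
results are reported as patient fractions. Reference carriers for a
variant are estimated as AC − nHom (a homozygote contributes two
alleles but one carrier), summed over member variants for gene- or
panel-scope tests; for ultra-rare variants AC is essentially the
carrier count and distinct variants essentially never share reference
carriers. At gene and panel scope a cohort patient carrying several
qualifying variants is counted once.

For a 2×2 table (a cohort carriers, b cohort non-carriers, c reference
carriers, d reference non-carriers):

* **Odds ratio** OR = ad/(bc), with the Woolf log-normal interval
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)). With any zero cell the
  estimate is reported NA — the convention used when reference
  carriage is absent — unless the Haldane–Anscombe +0.5 correction is
  opted into for exploration. An exact conditional
  maximum-likelihood interval is out of scope in this version.
* **p-value** from the two-sided Fisher exact test, summing all
  margin-fixed tables whose point probability does not exceed the
  observed one (the minimum-likelihood definition; sidedness of the
  original analyses is typically unstated, and this is the common
  choice). Computed via `stats::fisher.test()` and verified in the
  tests against exhaustive hypergeometric enumeration.
* **Multiple testing** is off by default (screens of this kind report
  raw p); `bh_adjust()` adds Benjamini–Hochberg q-values within each
  (scope, subset) family.

Reproducing any specific published odds ratio against a live
population database is explicitly out of scope: such numbers depend on
unprinted, version-dependent reference carrier counts. The machinery
is instead validated by calibration (below) and demonstrated on
synthetic references with a known generative odds ratio.

## Cohort summaries

* Carrier percents are rounded **half-up** to one decimal
  (12/128 → 9.4), matching how such fractions are printed; R's default
  banker's rounding would disagree on exact halves.
* The inheritance summary counts unique patients twice over: carriers
  of P/LP variants in AD genes, then additionally heterozygous
  carriers in AR genes (carrier state only, not a recessive diagnosis).
  A patient with several variants counts once per stratum but
  contributes to each gene's count in the recurrence screen.
* The recurrence screen lists genes with ≥ 2 distinct P/LP carriers —
  the usual bar for taking a gene forward as a candidate.
* Onset summaries use the standard median and report the range;
  carriers without a recorded onset age are dropped with a warning. In
  the packaged worked example the fourth carrier's age is known only
  from a printed range and the fixture uses the range maximum,
  labelled inferred.
* `cosegregation_summary()` partitions the affected members of a
  pedigree by tested genotype for one variant (carrier / non-carrier /
  untested). This is a descriptive count, not a LOD-style linkage
  statistic.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design end to end: by default a
128-patient cohort whose planted variants are the worked example's
(same genes, evidence codes and carrier counts), 100 background
variants in off-panel genes with MAF log-uniform on [1e-4, 0.2]
carried at Hardy–Weinberg proportions, and reference subsets of
118,477 (global) and 10,816 (population-matched) individuals with
background allele counts drawn binomially at the subset MAF. A
`finnish_enrichment` factor can scale non-global subset MAFs to
emulate population clustering of rare alleles. Every planted fact —
carrier assignments, evidence codes, expected survivor and P/LP sets —
is recorded in a manifest, so pipeline outputs are checkable against
ground truth alone. Bundles are emitted both in the TSV dialect and as
VCF v4.2 with GT:DP:GQ:AD over all samples, and the two parse to
identical record sets.

What the generator does **not** emulate: linkage disequilibrium,
within-cohort relatedness, genotyping error structure beyond simple
per-call metrics, site-level missingness, or realistic gene-level
mutation rates. Passing tests on synthetic bundles therefore
demonstrate the pipeline's bookkeeping and statistical calibration,
not robustness to the messiness of real exome data.

`simulate_null_and_enriched()` generates replicate 2×2 carrier tables
with a known generative odds ratio for calibration. The designs are
fixed as the package's own choices:

* **Type-I error**: cohort 200 vs reference 20,000 at carrier
  probability 0.1 — between the AD-only (~9%) and AR-inclusive (~21%)
  carrier fractions seen at panel scope — where the exact test's
  discreteness is mild; 1,000 replicates, α = 0.05.
* **Interval coverage**: cohort 200 vs reference 5,000 at reference
  carrier probability 0.05, so all expected cells stay ≥ 5 at
  generative OR ∈ {1, 2, 5}; 2,000 replicates each.
* **Recovery demonstration**: generative OR 3 at the type-I design,
  200 replicates, summarized by the median estimate.

These sizes keep the full suite and the acceptance script to a few
tens of seconds while leaving the binomial noise on the measured rates
well inside the acceptance bands.

## Numerical and representational choices

* Variant identifiers are `chrom:pos:ref:alt` after trimming shared
  suffix then prefix bases (keeping one anchor base, adjusting
  position). Full left-alignment needs a reference genome and is not
  attempted; caller output is assumed parsimony-aligned, which is the
  common case and is sufficient for a canonical join key between
  cohort and reference tables.
* HGVS strings are carried as opaque annotations and never parsed;
  coding impacts are supplied explicitly.
* Multi-allelic VCF sites are decomposed into biallelic records;
  carriers are samples with ≥ 1 alternate allele of the specific
  alternate.
* Ploidy is fixed diploid autosomal; X-linked dosage is out of scope.
* A listed reference variant with AN = 0 is treated as unobserved (with
  a warning) rather than as a division-by-zero.
* Degenerate inputs — empty cohorts, empty criteria sets, pedigrees
  without genotype data — return empty or all-untested results rather
  than errors, except where silence would be misleading (a cohort of
  size 0, a gene missing from the panel, unresolved pedigree parents).

## Known limitations

Evidence codes are inputs, not derived: the package does not compute
PM2 from the frequency tables it already holds, nor PVS1 from impact
classes, because automated evidence assignment is a substantial
interpretive layer of its own and curated inputs arrive pre-coded.
Reference carrier counts are approximated from allele counts rather
than genotype-level data. The burden test is a per-unit 2×2 — no
covariates, no relatedness correction, no regression-based
aggregation. Pedigree summaries are descriptive counts over typically
tiny families.
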