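---
title: "Methods: case-only genetic diagnosis of congenital heart disease cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-only genetic diagnosis of congenital heart disease cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdtriage)
```

## The diagnostic problem

Congenital heart disease (CHD) is the most common congenital malformation,
and in a sporadic, case-only cohort — no parents, no controls — the
diagnostic question is per sample: does this fetus or neonate carry an
identifiable genetic etiology? Two assays answer complementary parts of the
question. Low-coverage whole-genome sequencing detects chromosomal
abnormalities: whole-chromosome aneuploidies and segmental copy-number
variants (CNVs). Whole-exome sequencing detects single-nucleotide variants
and short indels in disease genes. `chdtriage` implements the interpretation
layer that sits on top of both call sets: it classifies, filters and
combines the calls into five per-sample etiology categories and aggregates
them into cohort-level diagnostic-yield statistics.

The five categories are:

1. pathogenic / likely-pathogenic (P|LP) variants in *definitive* CHD genes
   — members of a curated panel of CHD-associated genes;
2. P|LP variants in *candidate* CHD genes — genes outside the panel,
   adjudicated as CHD-relevant by expert review;
3. whole-chromosome aneuploidies (e.g. trisomy 18, monosomy X);
4. P|LP segmental CNVs;
5. CNVs of uncertain significance (VUS) whose interval contains at least
   one panel gene — proposed, weaker candidate etiologies.

A sample is *diagnosed* when it carries at least one category; a sample may
carry several. Categories 1–2 form the gene channel (exome), 3–5 the
chromosomal channel (genome); the report splits the yield into
chromosomal-only, gene-only and both-channel fractions.

## The ACMG evidence-combination engine

Variant pathogenicity follows the ACMG/AMP framework: each variant carries
a set of evidence codes (PVS1; PS1–PS4; PM1–PM6; PP1–PP5 on the pathogenic
side; BA1; BS1–BS4; BP1–BP7 on the benign side), and fixed combining rules
map the code set to one of five tiers (Pathogenic, LikelyPathogenic, VUS,
LikelyBenign, Benign). Code *assignment* — population frequencies, in
silico predictors, literature — is upstream of this package and is consumed
as an annotation; the *combination* step is implemented here.

The 2015 combining rules are shipped as a plain TSV
(`inst/extdata/acmg_combining_rules.tsv`): one row per rule, one column per
strength class giving the minimum count for the rule to fire. Rows are
ordered strongest-first within each side, so the first firing row gives the
tier. Design choices that the rule text leaves open:

* **Contradictory evidence.** If both a pathogenic-side and a benign-side
  rule fire, the call is VUS with `matched_rule = "conflict-VUS"`, per the
  framework's contradictory-evidence clause.
* **PVS1 alone** is not sufficient for any call and yields VUS — a strict
  reading of the combining table, with no stand-alone upgrade.
* **No strength modulation.** Codes are taken at face strength; downgraded
  or upgraded applications (e.g. PVS1 at moderate strength) are not
  modelled, because the inputs carry plain codes.

Because the engine is a data table, `enumerate_rule_table()` can
exhaustively enumerate every count signature with up to six codes; the test
suite compares that enumeration against an independent hand transcription
of the rules and verifies monotonicity: adding pathogenic-side evidence
never moves a call toward benign (and symmetrically).

```{r}
classify_evidence(c("PVS1", "PM2", "PP3"))$tier
classify_evidence(c("PVS1", "PM2"))$tier
```

## Small-variant triage

Classified variants pass three technical gates, in fixed order, with
inclusive thresholds:

1. `FILTER == "PASS"` (caller-level quality);
2. alternate-allele depth ≥ 5 reads (`min_alt_depth`);
3. for heterozygous calls only, alternate-allele fraction
   `alt/(ref+alt)` ≥ 25% (`min_het_allele_fraction`).

The depth threshold is read as *alternate-allele* depth, not total depth:
the paired condition concerns the alternate allele's fraction, and a
total-depth reading would make the pair redundant at 25%. The fraction uses
the AD-based denominator `ref+alt` rather than `DP`, which makes the
worked boundary case — a heterozygous call at 23/(77+23) = 23% is excluded
— deterministic. The boolean outcome is order-independent (the gates are a
conjunction); only the reported failure reason depends on the fixed order.

Gene-level evidence then requires zygosity consistent with the gene's
recorded OMIM-style inheritance modes, tried in the fixed order AD, XLD,
AR, XLR (first qualifying mode is reported):

* AD / XLD: any single het, hom or hemizygous P|LP variant qualifies;
* AR: a hom variant qualifies; two or more distinct het variants are a
  *suspected compound heterozygote* — with unconfirmed phase they are
  flagged, excluded from the yield, and reported separately;
* XLR: hemizygous (males) or hom variants qualify. How hemizygous male
  calls are genotyped varies by caller (`1` vs `0/1`), so both hemi and hom
  genotypes are accepted for the X-linked modes.

Qualifying genes become `definitive_panel` etiologies when in the curated
panel and `candidate_gene` etiologies when on the adjudicated candidate
list (panel membership wins if both). Candidate-list genes carry no curated
inheritance mode; autosomal dominant is assumed, matching the adjudicated
gene set this models. Genes on neither list are dropped — but logged in an
attribute, never silently.

## CNV and aneuploidy triage

CNV calls arrive with a five-tier classification (B/LB/VUS/LP/P) already
attached; the evidence arithmetic behind those tiers (point-based CNV
scoring) is out of scope and consumed as annotation. The triage rules:

* events smaller than `min_cnv_size` (default 100 kb, the assay's
  reporting floor) are excluded, with a logged reason;
* events spanning at least `aneuploidy_span_fraction` (default 0.9) of
  their chromosome are promoted to whole-chromosome calls: duplications
  become trisomies, deletions monosomies. The source data report
  aneuploidies and segmental CNVs separately without stating a boundary;
  0.9 is this package's configurable choice.
* remaining P or LP events are definitive etiologies (`pathogenic_cnv`);
* remaining VUS events whose interval overlaps at least one panel gene are
  candidate etiologies (`vus_cnv_panel_gene`). "Containing" a gene is read
  as any 1-bp overlap by default; a strict containment mode
  (`cnv_gene_overlap = "containment"`) is available because the rule's
  source wording does not distinguish the two.
* mosaic fractions (chimeric ratios) are carried through and reported but
  never gate any decision — events at 12–14% mosaicism are retained.

Every input call lands in exactly one of five bins (excluded-small,
aneuploidy, pathogenic CNV, VUS-over-panel, non-causative), and the bin
counts sum to the input count — a partition invariant the tests assert.
Interval overlap is delegated to `GenomicRanges::findOverlaps` and checked
against a brute-force interval scan.

## Cohort statistics

**Binomial confidence intervals.** Published cohort intervals of this form
do not always name their method. Of the standard candidates, the
Agresti–Coull interval — add $z^2/2$ pseudo-successes and $z^2$
pseudo-trials, then a Wald-style interval around the adjusted centre
$\tilde p = (x + z^2/2)/(n + z^2)$ — reproduces every printed interval on
the $n = 121$ denominator to two decimals, while Wilson and
Clopper–Pearson do not. It is therefore the default
(`ci_method = "agresti-coull"`), with Wilson and Clopper–Pearson
selectable.

```{r}
agresti_coull_ci(42, 121)
```

**Odds ratios.** Subgroup ORs (sex, ultrasound period, phenotype group)
use Fisher's exact framework: the estimate is the conditional maximum
likelihood estimate (CMLE) under the noncentral hypergeometric
distribution — the value solving $E[A \mid \text{margins}, \psi] = a$ —
and the two-sided p sums the conditional probabilities of all tables with
fixed margins no more probable than the observed one. The CMLE was chosen
because printed ORs of the modelled cohort (2.41, 1.81, 1.80) sit just
below the sample cross-product ratios (2.43, 1.82, 1.81), the CMLE's
signature; the cross-product estimator remains available
(`or_estimator = "cross-product"`). Zero-cell tables return 0 or infinity
with a flag, and the corresponding conditional bound is one-sided.
Subgroup denominators come from the cohort metadata table, and `unknown`
levels are excluded from each comparison. No multiple-testing correction
is applied across the three subgroup tests, matching the analysis this
package models.

**Rounding.** Percentages are rendered to two decimals, rounding half
away from zero, at the reporting boundary only; all internal arithmetic is
full precision.

**Landscape matrix.** `landscape_matrix()` emits the sample × feature
table behind a cohort landscape ("oncoprint"-style) figure: five binary
category indicators plus four metadata columns, rows ordered
diagnosed-first, then by category count, then by sample id. A pheatmap
rendering is available via `plot_landscape()`.

## Network-based panel expansion

Candidate genes prioritised by rare-disease causal-variant analysis are
filtered against the curated panel using a weighted interaction network:
after removing candidates already in the panel, a gene is retained when it
interacts with at least 2 distinct panel genes at interaction confidence
≥ 0.9 — both thresholds inclusive. "Interactions" counts distinct panel
partners, not edges; parallel and reversed duplicate edges collapse during
normalisation (keeping the maximum confidence), and self-edges are
dropped. Confidence is treated as an opaque column in $[0,1]$; inputs on
the common 0–999 interaction-database scale are detected (any value > 1)
and divided by 1000 with a message. Results are ranked by panel degree
(descending), then gene symbol. The retained list is emitted in a flat
format suitable for external enrichment services; enrichment itself
depends on external annotation-database versions and is out of scope.

## The synthetic cohort generator

Real per-sample calls cannot be redistributed, so validation rests on
`generate_cohort()`: a generator that writes a complete, internally
consistent cohort — multi-sample annotated VCF, CNV table, metadata,
panel, candidate lists, interaction network, chromosome lengths — with
known per-sample ground truth. Its defaults are the study conditions of
the modelled cohort:

* 121 samples: 69 male / 52 female, 79 fetus / 42 neonate, 51 isolated /
  68 non-isolated / 2 unknown;
* category counts 16 / 8 / 12 / 13 / 8 (definitive gene, candidate gene,
  aneuploidy, pathogenic CNV, VUS-CNV-over-panel), with 11 two-category
  and 2 three-category samples — hence 42 diagnosed, split 20
  chromosomal-only / 12 gene-only / 10 both. The generator solves this
  overlap structure by inclusion–exclusion and fails loudly if a custom
  specification is unsatisfiable;
* recurrence structure mirroring the modelled cohort: a recurrent
  pathogenic deletion planted in 6 samples, a second in 2; aneuploidies
  T18/T21/XO three times each plus three singletons; recurrent
  definitive-gene variants (4/3/3/3/2/1 samples across six panel genes);
  eight candidate genes in one sample each;
* three mosaic events with fractions 0.12, 0.13 and 0.14, carried on an
  aneuploidy and two segmental deletions;
* decoys that each fail exactly one named gate: non-PASS calls, 4-read
  alternate depths, 23% heterozygous fractions, benign evidence sets,
  sub-100 kb pathogenic-tier CNVs, VUS CNVs over no panel gene, plus
  inheritance decoys (single het in an AR gene; two hets in an AR gene —
  the suspected-compound-het case);
* a network with planted high-confidence panel degrees: a hub gene with
  13 qualifying panel partners, two with 11, seven more at 2–5 (one of
  them with edges at exactly 0.9, the inclusive boundary), and decoy
  candidates with one qualifying edge, two sub-threshold edges, or none.

Coordinates live on a miniature genome of 24 chromosomes × 10 Mb (shipped
as `mini_genome.tsv`) so whole-chromosome logic is testable at toy scale;
real chromosome lengths can be supplied through the same
chromosome-length TSV. Monosomy-X events are planted only in
female-designated samples. Aneuploidy chromosomes carry no panel genes,
so a whole-chromosome event can never double as a gene-overlap CNV
etiology. The generator is byte-deterministic in (specification, seed)
and writes a `manifest.json` with the specification and file MD5 hashes.

Because planted positives pass every gate by construction and every decoy
fails exactly one, pipeline output must equal the planted truth *exactly*
— no tolerance — and loosening a single threshold must flip exactly the
decoy class aimed at that gate. The test suite asserts exact recovery
across 20 seeds and runs per-gate ablations (allele fraction 0.25 → 0.20,
alternate depth 5 → 0, CNV size 100 kb → 50 kb).

**What passing does and does not show.** The generator emulates the
*decision structure* of real data — category prevalences, overlap and
recurrence patterns, boundary-sitting failures — not its noise: no read
errors, no caller-specific artefacts, no allele-frequency spectrum, no
linkage between clinical covariates and genotype (subgroup odds ratios on
synthetic cohorts are therefore null). Exact recovery demonstrates that
the deterministic interpretation rules are implemented correctly, not that
the rules themselves are well calibrated for real cohorts.

## Numerical choices and degenerate inputs

* Positions are 1-based (VCF convention); CNV intervals are 1-based
  inclusive with `size = end − start + 1`, which makes the 100 kb
  threshold unambiguous. Strand is ignored throughout.
* Malformed inputs are hard errors, never warnings: silently dropped
  records would corrupt every downstream yield. Readers either parse a
  record or fail naming it.
* `fisher_or` requires non-degenerate margins and errors otherwise;
  `agresti_coull_ci` requires `n > 0`; CI bounds are clamped to
  `[0, 100]`%.
* Ties in ranking (network expansion, recurrence tables) break
  lexicographically, making every output deterministic.
* Problem sizes in the test suite — 121-sample cohorts across 20 seeds,
  exhaustive rule enumeration to six codes, exact-p enumeration to table
  totals of 40, 100 random networks — were chosen so the full suite
  validates every module in about half a minute.

## Known limitations

* Evidence-code assignment, CNV tier scoring, variant calling and phasing
  are all upstream: the package interprets annotated calls.
* True compound-heterozygote confirmation requires phase; the package can
  only flag suspicion and exclude it from the yield.
* Quantities bound to the raw modelled cohort or to a fixed
  interaction-database release — the identity of diagnosed samples, real
  recurrence counts, the 886/86-gene candidate lists and specific panel
  degrees — cannot be reproduced from summary statistics; see
  `replication_scope()`. The property-based suites cover the *rules* that
  produced them.
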