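# chdtriage

Case-only genetic diagnosis for congenital heart disease (CHD) cohorts
profiled by combined whole-exome (WES) and low-coverage whole-genome
sequencing (WGS).

CHD is the most common congenital malformation, yet more than half of
patients lack a genetic diagnosis. In a sporadic case-only cohort (no
parents, no controls), diagnosis means triaging two call sets per sample —
small variants from WES and copy-number/aneuploidy calls from low-coverage
WGS — into identifiable genetic etiologies. `chdtriage` implements that
interpretation layer for clinical-genetics analysts:

* **ACMG/AMP evidence combination** — maps a set of evidence codes (PVS1,
  PS1–4, PM1–6, PP1–5; BA1, BS1–4, BP1–7) to the five-tier call
  P / LP / VUS / LB / B with the 2015 combining rules encoded as a
  swappable TSV rule table.
* **Small-variant triage** — technical gates (FILTER = PASS, alternate
  depth ≥ 5 reads, heterozygous allele fraction ≥ 25%), zygosity
  consistency with OMIM-style inheritance modes (AD/AR/XLD/XLR, with
  suspected compound heterozygotes flagged and excluded), and panel /
  candidate-list membership.
* **CNV triage** — 100 kb size floor, promotion of near-whole-chromosome
  events to aneuploidies, P|LP CNVs as definitive etiologies, VUS CNVs
  overlapping curated panel genes as candidate etiologies, mosaic
  fractions reported but never gating.
* **Cohort statistics** — five-category etiology assignment per sample;
  diagnostic yields with Agresti–Coull 95% CIs
  ($\tilde p = (x+z^2/2)/(n+z^2) \pm z\sqrt{\tilde p(1-\tilde p)/\tilde n}$);
  subgroup odds ratios as Fisher conditional-MLE estimates with exact
  two-sided p; sample-level recurrence tables; a landscape
  (oncoprint-style) matrix.
* **Network panel expansion** — retain candidate genes interacting with
  ≥ 2 curated panel genes at confidence ≥ 0.9 (both inclusive), ranked by
  panel degree.
* **Synthetic cohorts with planted truth** — a deterministic generator
  producing complete inputs (VCF, CNV/metadata/panel/network TSVs) whose
  expected output is known exactly, plus per-gate decoys for ablation
  testing.

## Worked example

```r
library(chdtriage)

# a 121-sample synthetic cohort with planted ground truth
cohort <- generate_cohort(cohort_spec(seed = 1), "demo_cohort")
res <- run_pipeline("demo_cohort")
res$report
#> Cohort of 121 samples; 42 diagnosed
#>   overall:           34.71% [42/121, 95%CI (26.80%-43.56%), agresti-coull]
#>   chromosomal_only:  16.53% [20/121, 95%CI (10.88%-24.23%), agresti-coull]
#>   gene_only:         9.92% [12/121, 95%CI (5.63%-16.67%), agresti-coull]
#>   both:              8.26% [10/121, 95%CI (4.39%-14.70%), agresti-coull]
#>   categories (samples): PLP_definitive_gene=16, PLP_candidate_gene=8,
#>     aneuploidy=12, pathogenic_cnv=13, vus_cnv_panel_gene=8
#>   multi-category: two_categories=11, three_or_more_categories=2

# exact recovery of the planted truth
truth_recovery_report(cohort$truth, res$calls)$match
#> [1] TRUE
```

Reading: 42 of 121 samples received at least one of the five etiology
categories (34.71% overall yield; the CI is the Agresti–Coull interval).
20 samples were explained by chromosomal abnormalities alone, 12 by gene
variants alone, and 10 by both channels simultaneously. The recovery
check confirms the pipeline's calls equal the generator's planted truth
exactly.

Individual building blocks work standalone:

```r
classify_evidence(c("PVS1", "PM2", "PP3"))$tier   # "Pathogenic"
agresti_coull_ci(42, 121)                          # 34.71% (26.80-43.56)
fisher_or(24, 28, 18, 51)$or_cmle                  # 2.41 (female vs male)
```

A thin command-line front end ships in `inst/scripts/chd-triage`
(subcommands `simulate`, `classify`, `triage`, `stats`, `network`,
`report`; exit code 2 on validation errors).

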