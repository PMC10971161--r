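# nbscreen

Variant filtering and interpretation for NGS-based newborn screening of
inherited metabolic disorders (IMDs).

Genetics-first newborn screening sequences DNA from a dried blood spot and
asks, for a panel of disease genes, whether a newborn carries a genotype that
fits the mode of inheritance (MOI) of a treatable disorder. The hard part is
not sequencing but interpretation at population scale: which variants are
surfaced, how recessive genotypes are called without phenotype information,
and how often a filtering strategy would flag healthy individuals. `nbscreen`
implements that interpretation layer as a tested, reusable pipeline for
laboratory scientists and pipeline developers evaluating screening
strategies:

* **Strict (L)P filter** — a variant survives iff its population allele
  frequency is < 1% and it is (a) conclusively classified
  pathogenic/likely-pathogenic (P/LP) in at least one knowledge base (HGMD
  "DM", ClinVar, VKGL, or a local database) with no benign counter-entry,
  (b) truncating (nonsense, frameshift, start/stop-loss, canonical ±1–2
  splice site, or a gene-disrupting CNV deletion) and absent from all
  databases — unless the premature stop escapes nonsense-mediated decay under
  the 50-nt rule, or (c) an intronic splice-region position at ±3.
* **VUS extension** — in an autosomal-recessive (AR) or X-linked-recessive
  (XLR) gene holding exactly one (L)P variant at a heterozygous variant
  allele fraction (VAF 40–60%), variants of uncertain significance (VUS) in
  the same gene are additionally surfaced, so one-(L)P-plus-VUS genotypes can
  be called positive.
* **MOI screening** — per-gene calls (positive / carrier / negative) with
  compound-heterozygote, hemizygous and CNV-allele counting; carriership
  (one het (L)P at ~50% VAF in an AR gene) is computed but flagged
  non-reportable.
* **Background-cohort funnel** — the staged assessment of a large
  presumed-healthy cohort (no-SNV → no-(L)P → MOI-fit → review →
  single-het-(L)P → VUS extension → review), with auditable per-stage counts.
* **Outcome scoring** — TP/FP/FN/TN against diagnostic truth, plus a replay
  of the bundled per-sample × per-method (tNGS/WES/WGS) detection-status
  fixture.
* **Synthetic data** — deterministic generators for panels, knowledge bases,
  patients with planted causal genotypes, controls and background cohorts, so
  every stage is testable without access to patient data.

## Worked example

Replay the bundled detection fixture (47 patient samples; 3 samples failed
library preparation per method, leaving 44 evaluable):

```r
library(nbscreen)
fx <- detection_fixture()$fixture
replay_detection(fx, "tNGS", "strict")[c("tp", "fn")]
#> $tp
#> [1] 33
#> $fn
#> [1] 11
replay_detection(fx, "tNGS", "extended")[c("tp", "fn")]
#> $tp
#> [1] 40
#> $fn
#> [1] 4
```

33 of 44 evaluable patients are detected by the strict (L)P filter on the
targeted panel; including VUS in recessive genes with one (L)P resolves most
misses (40 detected), and the remaining false negatives are dominated by
homozygous-VUS genotypes, which neither strategy can surface.

Run a synthetic background cohort through the funnel:

```r
cfg  <- sim_config(seed = 1)
objs <- generate_panel(cfg)
bg   <- generate_background_cohort(cfg, objs, 4833, seed = 42)
fr   <- run_funnel(bg$variants, objs$panel, objs$kb, objs$transcripts,
                   sample_ids = bg$sample_ids)
funnel_report(fr)
#>                                         stage count percent
#> total                                   total  4833    100%
#> no_snv                                 no_snv   329      7%
#> no_lp                                   no_lp  3342     69%
#> moi_fit_prereview           moi_fit_prereview    11      0%
#> moi_fit_postreview         moi_fit_postreview    11      0%
#> single_lp_het                   single_lp_het   941     19%
#> vus_moi_fit_prereview   vus_moi_fit_prereview    12      0%
#> vus_moi_fit_postreview vus_moi_fit_postreview    12      0%
#> other                                   other   210      4%
```

About 7% of individuals carry no panel SNV, ~69% carry SNVs but nothing
(likely) pathogenic, and ~20% carry exactly one heterozygous (L)P in a
recessive gene — carriers, not positives. A handful of individuals reach MOI
fit, almost all through homozygous (L)P variants in genes flagged as
mild-phenotype.

A shell entry point wrapping the same functions ships in
`inst/scripts/nbscreen` (`replay`, `simulate`, `screen`, `funnel`
subcommands).

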