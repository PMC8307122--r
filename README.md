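# alltriage

Whole-exome variant triage for small acute lymphoblastic leukemia (ALL)
cohorts sequenced **without matched normal tissue** — the situation of most
small, demographically focused cohort studies, where somatic and germline
variants cannot be separated directly. `alltriage` is aimed at groups doing
exactly that kind of study: a handful of patients, a handful of healthy
controls, annotated VCFs in hand, and the question *"which of these variants
are plausibly driving disease, and are any of them clinically actionable?"*

## What it does

Given annotated patient and control VCFs plus snapshot catalogue tables
(population allele frequencies, a COSMIC Cancer Mutation Census-style table
of per-amino-acid-change evidence factors, OncoKB-style gene
clinical-evidence levels, pathway membership), the package:

1. **Filters** the cohort variants through a three-stage cascade —
   restrict to coding consequences, remove anything carried by *any*
   control, remove anything with reference-population allele frequency
   strictly above 5% (default population: Latino/Admixed American). A
   deliberately liberal cascade: it enriches for somatic mutations while
   keeping rare germline variants that may matter in an under-studied
   population.
2. **Classifies** each survivor by mutational-significance tier from three
   boolean evidence factors — f1: recurrence among driver-gene mutations,
   f2: pathogenic status in ClinVar, f3: positive selection by dN/dS:

   | rule | tier |
   |---|---|
   | f1 ∧ f2 | Tier 1 |
   | any two factors otherwise | Tier 2 |
   | exactly one factor | Tier 3 |
   | no factor | Other |

   plus **Tier X**: an uncatalogued (or catalogue-labelled "other") change
   at an amino-acid position that carries Tier 1–3 records — a flag for
   changes at known hotspots whose specific substitution has no curated
   evidence yet. Each gene also gets its strongest clinical-evidence level
   (1 = FDA-recognised biomarker … 4 = compelling biological evidence) and
   its targetable-pathway memberships.
3. **Summarises** the cohort: a patient × variant carrier matrix,
   position-level aggregation (`KRAS G12X` = any change at codon 12),
   carrier frequencies in percent, stratified by ethnicity / disease
   status / subtype, with two-stratum fold comparisons.
4. **Infers ancestry** by classical (Torgerson) multidimensional scaling of
   1 − identity-by-state genotype distances against a labelled reference
   panel, assigning each query sample its nearest population centroid in
   the first two MDS dimensions.
5. **Generates synthetic data** for all of the above — seeded, byte-stable
   cohort/control VCFs with a cascade truth table, reference genotype
   panels, and a packaged fixture encoding a published nine-patient
   borderland ALL cohort.

## Worked example

```r
library(alltriage)

dir <- tempfile("triage_demo_")
fx  <- borderland_fixture(dir)          # packaged 9-patient fixture
run <- run_pipeline(file.path(dir, "config.yaml"))
print(run)
```

```
<triage_run>
  restrict_coding           16 ->    15  (removed 1)
  subtract_controls         15 ->    14  (removed 1)
  filter_population_af      14 ->    13  (removed 1)
  13 classified variant(s), 14 carrier key(s)
```

Sixteen variant alleles enter; one non-coding decoy, one control-shared
decoy and one common (12% allele frequency) decoy are removed, and the 13
clinically interesting variants survive. Carrier frequencies:

```r
fr <- run$frequencies
fr[fr$stratum == "all" &
   fr$key %in% c("NOTCH2 C19W", "KRAS G12A", "KRAS G12X", "STAT5B N642H"), ]
```

```
          key stratum n_carriers n_total  percent
    KRAS G12A     all          1       9 11.11111
  NOTCH2 C19W     all          5       9 55.55556
 STAT5B N642H     all          1       9 11.11111
    KRAS G12X     all          1       9 11.11111
```

NOTCH2 C19W is carried by 5 of the 9 patients; KRAS G12A and STAT5B N642H
by one patient each. `KRAS G12X` is the codon-12 position group added by
the config's `groups: [KRAS:12]` entry. The level-grouped report (the
tabular analogue of a per-level variant figure) starts:

```r
head(run$level_report, 5)
```

```
 level   gene protein_change  tier                         pathway n_newonset n_relapse
     1    ATM         E2366* TierX             DNA damage response          0         1
     1   KRAS           G12A Tier1                            MAPK          1         0
     1   ROS1         S1109L Tier3                             RTK          0         1
     2 DNMT3A          A999G TierX epigenetic/chromatin remodeling          0         1
     2   TET2          A999G TierX epigenetic/chromatin remodeling          0         1
```

Level 1 holds ROS1, ATM and KRAS; KRAS G12A is Tier 1 (both recurrence and
ClinVar factors); ATM E2366\* is Tier X — the stop change itself is not
catalogued, but codon 2366 carries tiered records. (`A999G` changes are the
fixture's clearly marked placeholders for variants whose exact substitution
is not public.)

Ancestry inference runs the same way on a genotype panel:

```r
sim <- simulate_ancestry_cohort(n_loci = 500, gap = 0.5,
                                n_ref = 50, n_query = 20, seed = 1)
res <- ancestry_mds(sim$panel)
head(res$assignments, 3)
#>   sample assigned    distance ambiguous
#> 1     Q1     POPA 0.003923563     FALSE
#> 2     Q2     POPB 0.014828158     FALSE
#> 3     Q3     POPA 0.011359298     FALSE
```

A thin command-line front end lives at `inst/cli/triage`
(`triage run --config config.yaml`, `triage fixture --out-dir DIR`,
`triage simulate --seed N --out-dir DIR`).

## Limitations

- Annotation is consumed, not computed: VCFs must already carry a
  `gene|consequence|protein_change` INFO field (VEP/SnpEff-style).
- No somatic/germline separation — that requires matched tissue by design.
- Catalogue tables are snapshots; there are no live database queries.
- External comparison-cohort frequencies (dbGaP controlled access) are
  gated behind a user-supplied count export (`read_target_counts()`).

See the methods vignette (`vignettes/variant-triage.Rmd`) for the model
details, parameter defaults, and what the synthetic generator does and does
not emulate.
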