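# domainburden

Protein-domain aggregation analysis of somatic mutations in tumor cohorts.

## The problem

In most tumor cohorts only a handful of genes are mutated frequently; the
long tail of genes mutated in one or two patients is invisible to
gene-by-gene significance tests. Protein-domain families offer a natural
aggregation unit: the same Pfam domain recurs in many genes, so mutations
that are rare per gene can be recurrent per family. `domainburden` is for
cancer-genomics analysts who have per-patient mutation calls with protein
positions (a MAF subset), Pfam-style domain coordinates, and clinical
annotations, and who want to find domain families recurrently hit by
infrequent mutations — and to relate those families to tumor stage and
survival.

## The statistic at its core

For a family with member genes *i = 1..G*, gene *i* has protein length
*L_i*, family span-union *S_i*, and *n_i* eligible (default: missense)
mutations with known protein position. Under the null that mutations are
placed uniformly and independently, each mutation is a Bernoulli trial
hitting the domain with probability *p_i = S_i / L_i*, and the family-wide
in-domain count *N* is Poisson-binomial over the concatenated trial list.
The package computes the pmf exactly by the dynamic-programming recurrence

    f_j(k) = f_{j-1}(k) (1 - p_j) + f_{j-1}(k-1) p_j

and reports the exact tail p-value P(N ≥ N_obs) (the strict tail
P(N > N_obs) is selectable). Families then pass a three-part recurrence
screen: in-domain mutations in ≥ ceil(0.064 × cohort) distinct patients,
p < 0.05, and normalized Shannon entropy across member genes ≥ 0.71 — all
thresholds configurable. Around this core the package provides per-gene
mutation coverage and exact stage-enrichment tests, a subsample-consensus
harness for any per-gene significance function, projection of domain
mutations onto multiple-alignment columns, Kaplan–Meier / log-rank /
Cox-PH survival stratification by carrier status, and a seeded synthetic
cohort generator whose null is exactly the test's null.

## Worked example

Simulate a 468-patient cohort with two planted families (within-domain
odds × 8, carrier hazard × 2), run the burden test and screen, and
stratify survival by carrier status:

```r
library(domainburden)

cfg <- cohort_config(enriched_families = c("FAM0001", "FAM0002"),
                     enrichment_lambda = 8,
                     hazard_ratio_domain_mut = 2, seed = 11)
cohort <- generate_cohort(cfg)
#> domain_cohort: 20273 mutations, 3000 domain instances, 468 patients

burden <- domain_burden(cohort$mutations, cohort$domains, cohort_size = 468)
hits <- screen_families(burden, screen_thresholds(), cohort_size = 468)
hits[, c("family_acc", "n_trials", "N_obs", "genomes_hit",
         "entropy", "p_value", "q_value")]
#>   family_acc n_trials N_obs genomes_hit entropy  p_value  q_value
#> 1    FAM0001       78    55          54   0.987 1.92e-13 3.84e-11
#> 2    FAM0002       49    34          34   0.967 1.54e-08 1.54e-06
#> 3    FAM0089       72    31          31   0.946 1.28e-02 6.23e-01
#> 4    FAM0127       71    30          30   0.969 1.90e-02 6.23e-01
#> 5    FAM0112       75    31          30   0.975 2.40e-02 6.23e-01
#> 6    FAM0074       77    31          30   0.930 3.52e-02 6.23e-01

sv <- survival_by_mutation(cohort$mutations, cohort$clinical,
                           cohort$domains, family_acc = "FAM0001")
#> FAM0001 carriers: 54;  log-rank p = 0.0002
#> HR = 1.831 [1.326, 2.528], Wald p = 0.0002
```

Reading the output: both planted families rank first with p-values far
below the genuine-null families (whose best p ≈ 0.01 is what a 200-family
screen at p < 0.05 is expected to let through); `N_obs` of 55 in-domain
hits out of 78 trials against an expectation of ~23 is the enrichment the
test quantifies; `genomes_hit` = 54 distinct patients clears the
30-genome cutoff; entropy near 1 shows the hits are spread across member
genes rather than one hot gene. The survival analysis recovers an
elevated carrier hazard (true HR 2.0, estimated 1.83 with the 95% CI
covering the truth).

Real data enter through `read_mutation_table()` (MAF-style TSV, column
map configurable), `read_domain_table()` (Pfam-scan style, E-value < 1e-5),
`read_clinical_table()` (stage IV merged into III by default), and
`read_domain_alignment()` (aligned FASTA). `run_pipeline(run_config(...))`
orchestrates the whole analysis from one config and writes TSVs plus a
manifest; `inst/scripts/domainburden-cli.R` exposes `simulate`, `burden`
and `run-all` subcommands for shell use.

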