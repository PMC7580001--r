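---
title: "Domain-level aggregation of infrequent somatic mutations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level aggregation of infrequent somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainburden)
```

## The problem

Most genes in a tumor cohort are mutated in only a handful of patients, so
gene-by-gene significance tests miss drivers whose mutations are individually
rare. Protein domains offer a natural aggregation unit: a domain family
(a Pfam accession) recurs across many genes, and mutations that are rare in
any one gene can be recurrent at the family level. `domainburden` implements
this aggregation: it tallies missense mutations falling inside the
domain-encoding regions of every gene carrying a family, tests the tally
against an exact null, screens the results for genuine cross-gene
recurrence, and connects the surviving families to tumor stage and survival.

## The null model and the exact test

Two assumptions define the null:

1. a mutation in a gene is placed uniformly along the protein, so it hits
   the domain-encoding region with probability \(p_i = S_i / L_i\), the
   family's span-union length over the protein length; and
2. mutations occur independently of one another.

Under these assumptions, if gene \(i\) carries \(n_i\) eligible mutations,
the family-wide in-domain count \(N\) is a sum of independent Bernoulli
trials with heterogeneous success probabilities — a Poisson-binomial
variable over the concatenated trial list \((p_1, \dots, p_1, p_2, \dots)\).
The pmf is computed exactly by the prefix-convolution dynamic programme

\[ f_j(k) = f_{j-1}(k)\,(1-p_j) + f_{j-1}(k-1)\,p_j , \]

and the p-value is the upper tail at the observed count. Two tail
conventions are exposed. The default is the standard exact one-sided
p-value \(P(N \ge N_{obs})\); the strict event \(P(N > N_{obs})\) is
available via `inclusive = FALSE`. The strict convention returns 0 whenever
\(N_{obs} = n\), which is why the inclusive form is the default; the choice
is recorded in the output's `tail` attribute and in the run manifest.

Numerically, the DP runs in plain double precision. Because every term in
the recurrence is a non-negative multiply-add, relative error grows only
like \(n \cdot \epsilon_{mach}\), so tails down to \(10^{-300}\) remain
accurate to far better than one part in \(10^{9}\) — the regime that
matters when a permutation test would need more than \(10^7\) draws to
resolve a tail at all. When the summed tail underflows below \(10^{-280}\)
the implementation switches to a log-space (log-sum-exp) form of the same
recurrence, so even sub-underflow tails are reported rather than rounded
to zero. The test suite verifies the DP elementwise against full \(2^n\)
enumeration for \(n \le 15\), against the binomial closed form for equal
probabilities, against Monte-Carlo sampling for moderate tails, and
against an independently coded log-space recomputation deep in the tail.

Only protein-domain matches with E-value below \(10^{-5}\) enter the
analysis (the conventional Pfam-scan confidence cutoff); overlapping
instances of one family in one protein contribute their span *union*, so
no residue is counted twice. Eligible mutations default to missense only:
the uniform-placement null is a model of single-residue substitutions, and
truncating classes have different positional biases. Both the E-value
cutoff and the class set are arguments.

## The recurrence screen

A small p-value alone does not establish cross-gene recurrence: a single
hypermutated gene can dominate a family. The screen therefore applies three
filters, all configurable through `screen_thresholds()`:

- **genome coverage** — in-domain mutations must be spread over at least
  `ceiling(min_genome_fraction * cohort_size)` distinct patients (default
  fraction 0.064; with 468 patients the cutoff is exactly 30), or an
  absolute `min_genomes`;
- **significance** — exact p-value strictly below `p_max` (default 0.05);
- **evenness** — normalized Shannon entropy
  \(H = -\sum f_g \ln f_g / \ln m \ge\) `entropy_min` (default 0.71).

Boundary semantics follow the filters' definitions: the p-value bound is
strict, the coverage and entropy bounds are non-strict.

The entropy axis is the one genuinely open design choice in this screen.
The package computes \(H\) over the distribution of in-domain mutations
across member **genes**, with \(m\) the number of member genes carrying at
least one in-domain mutation — this directly operationalizes "recurrent
across many genes, not driven by one gene", which is the purpose of domain
aggregation. Both the axis (`gene`, `patient`, `position`) and the
normalization base (`hit` categories vs `all` member genes) are arguments,
and the chosen convention is echoed in the output metadata, so a different
reading can be reproduced without touching code. Benjamini–Hochberg
q-values are always reported alongside, but the default pass/fail uses the
raw p-value threshold; an optional `fdr_q` bound can be added.

## Cohort statistics and the consensus harness

Mutation coverage (MC) of a gene is the fraction of patients in a group
carrying at least one mutation in it; a patient counts once regardless of
how many mutations they carry. Stage enrichment compares carrier counts in
one stage against the rest with a one-sided exact 2×2 test; the exact test
is computed directly from the hypergeometric distribution, with the
two-sided p-value defined as the total probability of tables no more
likely than the one observed (the same convention as `fisher.test`, against
which it is cross-checked in the tests). Published analyses of this kind
report enrichment p-values without naming the test; the one-sided exact
test on carrier counts is the standard choice and is what this package
logs.

The subsample-consensus harness wraps *any* per-gene significance function
`(mutations, patients) -> genes`: it reruns the function on the full
cohort and on seeded subsamples (defaults 410–460 of a 468 cohort, without
replacement) and intersects the per-run gene sets, retaining each run for
audit. Intersection is the default rule; union and majority are options.
The built-in `binomial_gene_test()` — carrier count against a binomial
null at the cohort-median MC, BH-adjusted — is an intentionally simple
stand-in so the harness is testable end-to-end; for real analyses a
dedicated background-aware caller should be plugged in, and the harness
makes no assumption about what the function does internally.

Stage labels use the three-level I/II/III convention with stage IV merged
into III at ingestion (late-stage groups are typically too small to treat
separately); the merge map is an argument of `read_clinical_table()`.

## Positional recurrence

For a family with a multiple alignment of its instances,
`aligned_instance()` + `column_tally()` project each in-domain mutation to
its alignment column, so positional hot-spots shared across genes become
visible even when every individual protein is mutated only once. The
instance start offset in the protein is a required input — the package
does not infer alignments or offsets. Mutations that fall outside every
instance are kept in an explicit `unmapped` bucket so the tally conserves
its input. A per-column binomial test against uniform expectation is
available (`column_uniform_test()`) but clearly labelled an extension: the
core analysis only tallies.

## Survival stratification

Patients are grouped by carrier status — at least one eligible mutation in
the family's domain spans (or anywhere in a gene) — and compared with the
standard machinery of the `survival` package behind a stable surface:
Kaplan–Meier product-limit curves (`km_curve()`), the log-rank test
(`logrank_test()`), and a single-binary-covariate Cox proportional-hazards
hazard ratio with Wald p-value (`hazard_ratio()`, Efron tie handling by
default, Breslow selectable). The tests validate these against hand
calculations: the product-limit form on small fixtures, the
observed-minus-expected log-rank statistic, and parameter recovery on
simulated exponential data with a known hazard ratio.

## The synthetic cohort generator

Because the motivating cohort (TCGA breast exomes) cannot be redistributed,
every stage is exercised on synthetic cohorts whose generating process *is*
the null model, plus controlled departures from it:

- per-gene mutation counts are Poisson with mean
  `background_mutation_rate × n_patients`; placement within the protein is
  uniform — exactly assumptions 1–2 above;
- planted enrichment multiplies the within-domain *odds* of missense
  mutations by λ, so λ = 1 reproduces the null identically (the same
  Bernoulli(\(S/L\)) indicator), and the type-I error of the downstream
  test is interpretable;
- survival times are exponential with the hazard multiplied by a
  configurable ratio for carriers, censored by an independent uniform
  time — the simplest model with a known true HR for recovery tests;
- a single master seed drives per-stage child seeds, so cohorts are
  byte-reproducible and individual stages can be regenerated.

Default conditions are chosen once to emulate the motivating study where
it states them and a realistic mid-scale regime where it does not: 468
patients with stage frequencies 89/287/92 and IDBC histology; 200 domain
families of 15 member genes each (Pfam families commonly have tens of
human members); domain span fraction 0.3 of the protein; background rate
0.012 mutations per gene per patient, typical of the large, domain-rich
genes this analysis targets and sufficient to give each family some
60 Bernoulli trials — the regime in which family aggregation is
informative and in which a planted λ = 8 family should clear a 6.4%
genome-coverage cutoff by design rather than by luck. Simulation sizes in
the tests (2,000 null families for type-I error; 50 seeds for planted
recovery; 100 replicates of 400-per-arm survival) were likewise fixed as
the package's own study design.

What the generator does **not** emulate: trinucleotide signature biases,
per-gene covariate-driven background variation (replication timing,
expression), copy-number events, subclonality, or correlated hot-spot
positions. Passing tests therefore demonstrate the statistics are computed
correctly under the stated null and recover planted effects — not that the
uniform-placement null is adequate for any particular real cohort; on real
data the usual cautions about covariate-driven mutation rates apply.

## Degenerate inputs and numerical conventions

- A family with zero eligible trials gets p = 1 with a logged note.
- All-zero hit probabilities give a valid point mass at zero.
- Entropy of a single-category axis is 0 by convention; all-zero counts
  are an error.
- Protein coordinates are 1-based and spans inclusive at both ends, the
  Pfam convention; a mutation at `start` or `end` is in-domain.
- Screen ties on p-value are broken lexicographically by family accession
  so output ordering is deterministic.
- The fraction-based genome cutoff uses `ceiling`, which reproduces the
  conventional "at least 30 of 468 (6.4%)" arithmetic exactly.

## Known limitations

- The burden test conditions on the observed per-gene mutation counts
  \(n_i\); it does not model between-gene background-rate differences, so
  it answers "are this family's mutations concentrated in its domains"
  rather than "is this gene set hypermutated".
- The default missense-only tally discards truncating variants entirely;
  users studying domains inactivated by truncation should widen
  `eligible_classes` deliberately.
- The survival interface fits a single binary covariate; confounders
  (age, stage, subtype) require an external multivariate analysis.
- The positional module requires pre-computed alignments and instance
  offsets; it performs no alignment itself.
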