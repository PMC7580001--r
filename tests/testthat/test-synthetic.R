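test_that("generation is deterministic given the seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$domains, b$domains)
  expect_identical(a$clinical, b$clinical)

  c2 <- generate_cohort(small_config(seed = 43L))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("every mutation lies inside its protein and spans are valid", {
  co <- generate_cohort(small_config())
  lens <- co$domains$protein_length[match(co$mutations$gene,
                                          co$domains$gene)]
  in_dom_genes <- !is.na(lens)
  expect_true(all(co$mutations$protein_pos[in_dom_genes] >= 1))
  expect_true(all(co$mutations$protein_pos[in_dom_genes] <=
                    lens[in_dom_genes]))
  expect_true(all(co$domains$start >= 1))
  expect_true(all(co$domains$end <= co$domains$protein_length))
  expect_true(all(co$domains$start <= co$domains$end))
})

test_that("within-domain indicator is Bernoulli(span/length) under the null", {
  # one gene, one family, ~10,000 mutations, domain fraction 0.3
  cfg <- cohort_config(n_patients = 500, n_genes = 1, n_families = 1,
                       genes_per_family = 1,
                       protein_length_range = c(1000L, 1000L),
                       domain_span_fraction = 0.3,
                       background_mutation_rate = 20,
                       variant_class_probs = c(missense = 1),
                       seed = 9L)
  co <- generate_cohort(cfg)
  d <- co$domains[1, ]
  p_true <- (d$end - d$start + 1) / d$protein_length
  frac <- mean(co$mutations$protein_pos >= d$start &
                 co$mutations$protein_pos <= d$end)
  se <- sqrt(p_true * (1 - p_true) / nrow(co$mutations))
  expect_lt(abs(frac - p_true), 3 * se)
})

test_that("positions are uniform over the protein under the null", {
  cfg <- cohort_config(n_patients = 500, n_genes = 1, n_families = 1,
                       genes_per_family = 1,
                       protein_length_range = c(400L, 400L),
                       background_mutation_rate = 30,
                       variant_class_probs = c(missense = 1),
                       seed = 12L)
  co <- generate_cohort(cfg)
  # chi-square against uniform over 8 equal position bins
  bins <- cut(co$mutations$protein_pos, breaks = seq(0, 400, by = 50))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("planted odds multiplier raises the within-domain rate", {
  cfg <- cohort_config(n_patients = 400, n_genes = 10, n_families = 2,
                       genes_per_family = 5,
                       protein_length_range = c(600L, 600L),
                       background_mutation_rate = 0.5,
                       enriched_families = "FAM0001",
                       enrichment_lambda = 8, seed = 31L)
  co <- generate_cohort(cfg)
  dom <- co$domains
  in_span <- function(m, d) {
    i <- match(m$gene, d$gene)
    ok <- !is.na(i)
    mean(m$protein_pos[ok] >= d$start[i[ok]] &
           m$protein_pos[ok] <= d$end[i[ok]])
  }
  mis <- co$mutations[co$mutations$variant_class == "missense", ]
  f1 <- in_span(mis, dom[dom$family_acc == "FAM0001", ])
  f2 <- in_span(mis, dom[dom$family_acc == "FAM0002", ])
  expect_gt(f1, f2 + 0.2)   # odds x8 at p ~ 0.3 lifts the rate to ~ 0.77
})

test_that("stage labels follow the configured multinomial", {
  cfg <- cohort_config(n_patients = 900, n_genes = 50, n_families = 2,
                       genes_per_family = 5,
                       stage_probs = c(I = 1, II = 1, III = 1) / 3,
                       seed = 77L)
  co <- generate_cohort(cfg)
  counts <- table(co$clinical$stage)
  se <- sqrt(900 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 300) < 3 * se))
})

test_that("null_cohort disables all planted effects and records it", {
  cfg <- small_config(enriched_families = "FAM0001",
                      enrichment_lambda = 8,
                      hazard_ratio_domain_mut = 2)
  co <- null_cohort(cfg)
  expect_identical(co$config$enriched_families, character(0))
  expect_identical(co$config$enrichment_lambda, 1)
  expect_identical(co$config$hazard_ratio_domain_mut, 1)
})

test_that("infeasible configs fail before sampling", {
  expect_error(cohort_config(n_genes = 10, n_families = 5,
                             genes_per_family = 5),
               "Infeasible")
  expect_error(cohort_config(domain_span_fraction = 1.2), "0, 1")
  expect_error(cohort_config(stage_probs = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(cohort_config(enrichment_lambda = 0.5))
  cfg <- small_config()
  expect_error({cfg$enriched_families <- "NOPE"; generate_cohort(cfg)},
               "NOPE")
})

test_that("written cohorts read back through the io layer", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_config())
  write_cohort(co, dir)
  d <- read_domain_table(file.path(dir, "domains.tsv"))
  cl <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(d), nrow(co$domains))   # all generated E-values pass
  expect_equal(nrow(cl), co$config$n_patients)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  m <- readr::read_tsv(file.path(dir, "mutations.tsv"),
                       show_col_types = FALSE)
  expect_equal(nrow(m), nrow(co$mutations))
})
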