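test_that("domain hit probability is the span-union over protein length", {
  expect_equal(domain_hit_probability(10, 69, 300), 0.2)
  expect_equal(domain_hit_probability(c(10, 30), c(40, 70), 122), 0.5)
  expect_equal(domain_hit_probability(1, 250, 250), 1)
  # disjoint and nested spans against a direct interval-union oracle
  set.seed(8)
  for (rep in 1:20) {
    L <- 500L
    s <- sample(1:450, 4)
    e <- pmin(L, s + sample(10:80, 4))
    covered <- logical(L)
    for (i in 1:4) covered[s[i]:e[i]] <- TRUE
    expect_equal(domain_hit_probability(s, e, L), sum(covered) / L)
  }
  expect_error(domain_hit_probability(integer(0), integer(0), 100),
               "No domain instances")
})

test_that("tally respects 1-based inclusive span boundaries", {
  dom <- tibble::tibble(gene = "GA", protein_length = 100L,
                        family_acc = "F", family_name = "f",
                        start = 10L, end = 30L, e_value = 0)
  mk <- function(pos) tibble::tibble(
    patient_id = paste0("P", seq_along(pos)), gene = "GA",
    variant_class = "missense", variant_type = "SNP",
    protein_pos = as.integer(pos), aa_change = NA_character_)
  at_start <- tally_families(mk(10), dom)
  at_end <- tally_families(mk(30), dom)
  past_end <- tally_families(mk(31), dom)
  expect_equal(at_start$N_obs, 1L)
  expect_equal(at_end$N_obs, 1L)
  expect_equal(past_end$N_obs, 0L)
  expect_equal(past_end$n_trials, 1L)   # still an eligible trial
})

test_that("a hand-tallied toy family reproduces k, N_obs and genomes", {
  fam <- tally_families(toy_mutations(), toy_domains())
  prof <- fam$profiles[[1]]
  expect_equal(prof$k[match(c("GA", "GB", "GC"), prof$gene)],
               c(2L, 0L, 1L))
  expect_equal(fam$N_obs, 3L)
  expect_equal(fam$genomes_hit, 2L)     # P1 (twice) and P3
  # conservation: in-domain + out-of-domain = all eligible trials
  expect_equal(fam$n_trials, 5L)        # the silent mutation is excluded
  expect_equal(fam$N_obs + (fam$n_trials - fam$N_obs), fam$n_trials)
})

test_that("overlapping instances never double-count a mutation", {
  dom <- tibble::tibble(gene = "GA", protein_length = 100L,
                        family_acc = "F", family_name = "f",
                        start = c(10L, 20L), end = c(40L, 50L),
                        e_value = 0)
  m <- tibble::tibble(patient_id = "P1", gene = "GA",
                      variant_class = "missense", variant_type = "SNP",
                      protein_pos = 25L, aa_change = NA_character_)
  fam <- tally_families(m, dom)
  expect_equal(fam$N_obs, 1L)
  expect_equal(fam$profiles[[1]]$S, 41L)   # union [10,50]
})

test_that("family_test reduces to the binomial tail for one gene", {
  row <- tibble::tibble(
    family_acc = "F", family_name = "f", n_genes = 1L, n_trials = 10L,
    N_obs = 2L, genomes_hit = 2L, entropy = 0,
    profiles = list(tibble::tibble(gene = "GA", L = 100L, S = 20L,
                                   p = 0.2, n = 10L, k = 2L)))
  out <- family_test(row)
  expect_equal(out$p_value, pbinom(1, 10, 0.2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(out$p_value, 0.6242, tolerance = 1e-4)

  row$N_obs <- 0L
  expect_equal(family_test(row)$p_value, 1)

  row$profiles <- list(tibble::tibble(gene = "GA", L = 100L, S = 20L,
                                      p = 0.2, n = 0L, k = 0L))
  expect_message(z <- family_test(row), "zero eligible trials")
  expect_equal(z$p_value, 1)
})

test_that("multi-gene trial lists match brute-force enumeration", {
  # two genes with (n, p) = (3, 0.5) and (2, 0.1)
  trials <- c(rep(0.5, 3), rep(0.1, 2))
  for (k in 0:5) {
    expect_equal(poisson_binomial_tail(trials, k),
                 enum_pb_tail(trials, k), tolerance = 1e-12)
  }
})

test_that("tally_family errors on unknown accessions", {
  expect_error(tally_family(toy_mutations(), toy_domains(), "NOPE"),
               "NOPE")
})

test_that("domain_burden orders by p-value and attaches conventions", {
  co <- generate_cohort(small_config(enriched_families = "FAM0001",
                                     enrichment_lambda = 10,
                                     background_mutation_rate = 0.05))
  b <- domain_burden(co$mutations, co$domains, cohort_size = 120)
  expect_equal(nrow(b), 15L)
  expect_false(is.unsorted(b$p_value))
  expect_equal(b$family_acc[1], "FAM0001")
  expect_equal(attr(b, "tail"), "inclusive")
  expect_equal(b$genome_fraction, b$genomes_hit / 120)
  expect_true(all(b$q_value >= b$p_value - 1e-15))

  # the strict-event convention gives smaller-or-equal tails
  b_ex <- domain_burden(co$mutations, co$domains, cohort_size = 120,
                        inclusive = FALSE)
  joined <- merge(b[, c("family_acc", "p_value")],
                  b_ex[, c("family_acc", "p_value")], by = "family_acc")
  expect_true(all(joined$p_value.y <= joined$p_value.x + 1e-15))
})

test_that("eligible classes control which mutations become trials", {
  m <- toy_mutations()
  all_classes <- tally_families(m, toy_domains(),
                                eligible_classes = c("missense", "silent"))
  expect_equal(all_classes$n_trials, 6L)
  expect_equal(all_classes$N_obs, 4L)   # the silent GC:12 lands in-domain
})
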