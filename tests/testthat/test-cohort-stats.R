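test_that("mutation coverage counts carriers once each", {
  pats <- paste0("P", 1:10)
  m <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P3", "P3", "P3"),
    gene = "GA", variant_class = "missense", variant_type = "SNP",
    protein_pos = 1L, aa_change = NA_character_)
  expect_equal(mutation_coverage(m, pats, "GA"), 0.3)
  expect_equal(mutation_coverage(m, pats, "GA", group = c("P3", "P4")), 0.5)
  expect_error(mutation_coverage(m, pats, "GA", group = character(0)),
               "Empty")
  expect_error(mutation_coverage(m, pats, "GA", group = "PX"), "subset")
})

test_that("per-stage coverage matches a hand tally", {
  cl <- toy_clinical()            # stages I: P1-P3, II: P4-P7, III: P8-P10
  m <- tibble::tibble(
    patient_id = c("P1", "P2", "P4", "P8", "P8"),
    gene = "GA", variant_class = "missense", variant_type = "SNP",
    protein_pos = 1L, aa_change = NA_character_)
  cov <- gene_coverage(m, cl)
  expect_equal(cov$mc_overall, 4 / 10)
  expect_equal(cov$mc_I, 2 / 3)
  expect_equal(cov$mc_II, 1 / 4)
  expect_equal(cov$mc_III, 1 / 3)
  expect_equal(cov$carriers_III, 1L)   # P8's two rows count once
})

test_that("exact 2x2 p-values match hypergeometric enumeration", {
  expect_equal(fisher_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_2x2(3, 1, 1, 3), 0.4857, tolerance = 1e-4)
  expect_equal(fisher_2x2(5, 5, 5, 5), 1)
  set.seed(6)
  for (rep in 1:50) {
    cells <- as.integer(rmultinom(1, sample(5:30, 1), rep(1 / 4, 4)))
    two <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])
    gt <- fisher_2x2(cells[1], cells[2], cells[3], cells[4], "greater")
    lt <- fisher_2x2(cells[1], cells[2], cells[3], cells[4], "less")
    expect_equal(two, enum_fisher_2x2(cells[1], cells[2], cells[3],
                                      cells[4]), tolerance = 1e-12)
    expect_equal(gt, enum_fisher_2x2(cells[1], cells[2], cells[3],
                                     cells[4], "greater"),
                 tolerance = 1e-12)
    expect_lte(min(gt, lt), two + 1e-12)   # one-sided <= two-sided
    # complementary one-sided tests overlap at the observed table
    expect_gte(gt + lt, 1 - 1e-12)
  }
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("exact 2x2 agrees with the standard conditional test", {
  set.seed(16)
  for (rep in 1:25) {
    cells <- as.integer(rmultinom(1, sample(10:60, 1), rep(1 / 4, 4)))
    tab <- matrix(cells, 2, byrow = TRUE)
    expect_equal(fisher_2x2(cells[1], cells[2], cells[3], cells[4]),
                 fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(fisher_2x2(cells[1], cells[2], cells[3], cells[4],
                            "greater"),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("stage enrichment detects carriers concentrated in one stage", {
  cl <- toy_clinical()
  m <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),   # all of stage I mutated, no one else
    gene = "GA", variant_class = "missense", variant_type = "SNP",
    protein_pos = 1L, aa_change = NA_character_)
  se <- stage_enrichment(m, cl, "GA", "I")
  expect_equal(se$p_enrich, enum_fisher_2x2(3, 0, 0, 7, "greater"),
               tolerance = 1e-12)
  expect_equal(se$direction, "enriched")
  expect_gte(se$p_enrich + se$p_deplete, 1)

  # carriers proportional to stage sizes: no signal
  m2 <- tibble::tibble(
    patient_id = c("P1", "P4", "P8"),
    gene = "GB", variant_class = "missense", variant_type = "SNP",
    protein_pos = 1L, aa_change = NA_character_)
  se2 <- stage_enrichment(m2, cl, "GB", "II")
  expect_gt(se2$p_enrich, 0.3)

  cl_empty <- cl[cl$stage != "III", ]
  expect_error(stage_enrichment(m, cl_empty, "GA", "III"), "no patients")
})

test_that("consensus harness intersects per-run significant sets", {
  pats <- paste0("P", 1:20)
  m <- tibble::tibble(patient_id = "P1", gene = "GA",
                      variant_class = "missense", variant_type = "SNP",
                      protein_pos = 1L, aa_change = NA_character_)

  fixed <- function(mut, p) c("GX", "GY")
  res <- subsample_consensus(fixed, m, pats, sizes = c(10, 15), seed = 2)
  expect_equal(res$consensus, c("GX", "GY"))
  expect_equal(length(res$runs), 3L)      # full + two subsamples

  # a gene significant only on the complete cohort disappears from the
  # intersection as soon as any subsample drops a patient
  fragile <- function(mut, p) {
    if (length(p) == 20) c("GFULL", "GROBUST") else "GROBUST"
  }
  res2 <- subsample_consensus(fragile, m, pats, sizes = c(19), seed = 2)
  expect_equal(res2$consensus, "GROBUST")
  expect_equal(res2$runs$full, c("GFULL", "GROBUST"))
  for (r in res2$runs) expect_true(all(res2$consensus %in% r))

  res3 <- subsample_consensus(fragile, m, pats, sizes = c(19), seed = 2,
                              mode = "union")
  expect_equal(res3$consensus, c("GFULL", "GROBUST"))

  expect_error(subsample_consensus(fixed, m, pats, sizes = 25), "exceeds")
})

test_that("consensus subsampling is seeded and reproducible", {
  pats <- paste0("P", 1:30)
  m <- tibble::tibble(patient_id = pats, gene = "GA",
                      variant_class = "missense", variant_type = "SNP",
                      protein_pos = 1L, aa_change = NA_character_)
  echo <- function(mut, p) sort(p)[1:3]   # depends on the draw
  a <- subsample_consensus(echo, m, pats, sizes = c(10, 20), seed = 5)
  b <- subsample_consensus(echo, m, pats, sizes = c(10, 20), seed = 5)
  expect_identical(a, b)
})

test_that("the default gene test flags genes with excess carrier counts", {
  set.seed(23)
  pats <- paste0("P", 1:200)
  # 30 background genes with ~4 carriers, one gene with 60
  bg <- tibble::tibble(
    patient_id = sample(pats, 30 * 4, replace = TRUE),
    gene = rep(sprintf("BG%02d", 1:30), each = 4))
  hot <- tibble::tibble(patient_id = sample(pats, 60), gene = "HOT")
  m <- dplyr::bind_rows(bg, hot)
  m$variant_class <- "missense"; m$variant_type <- "SNP"
  m$protein_pos <- 1L; m$aa_change <- NA_character_
  sig <- binomial_gene_test(m, pats)
  expect_true("HOT" %in% sig)
  expect_lt(length(sig), 5)
})
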