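#' Mutation coverage of a gene
#'
#' Fraction of patients in a group carrying at least one eligible mutation
#' in the gene (also called mutation prevalence). A patient with several
#' mutations in the gene counts once.
#'
#' @param mutations Canonical mutation tibble.
#' @param cohort_patients Character vector of all patient IDs.
#' @param gene Gene symbol.
#' @param group Optional subset of `cohort_patients` to restrict to.
#' @param eligible_classes Variant classes counted; `NULL` counts all.
#' @return A fraction in \[0, 1\].
#' @export
mutation_coverage <- function(mutations, cohort_patients, gene,
                              group = NULL, eligible_classes = NULL) {
  if (is.null(group)) group <- cohort_patients
  if (length(group) == 0L) stop("Empty patient group.", call. = FALSE)
  if (!all(group %in% cohort_patients)) {
    stop("`group` must be a subset of `cohort_patients`.", call. = FALSE)
  }
  carriers <- gene_carriers(mutations, gene, eligible_classes)
  length(intersect(carriers, group)) / length(group)
}

gene_carriers <- function(mutations, gene, eligible_classes = NULL) {
  m <- mutations[mutations$gene == gene, , drop = FALSE]
  if (!is.null(eligible_classes)) {
    m <- m[m$variant_class %in% eligible_classes, , drop = FALSE]
  }
  unique(m$patient_id)
}

#' Per-gene, per-stage mutation coverage table
#'
#' @param mutations Canonical mutation tibble.
#' @param clinical Clinical tibble with `patient_id` and `stage`.
#' @param genes Genes to report; defaults to all mutated genes.
#' @param eligible_classes Variant classes counted; `NULL` counts all.
#' @return Tibble with overall and per-stage coverage and carrier counts.
#' @export
gene_coverage <- function(mutations, clinical, genes = NULL,
                          eligible_classes = NULL) {
  if (is.null(genes)) genes <- sort(unique(mutations$gene))
  pats <- clinical$patient_id
  by_stage <- split(clinical$patient_id, clinical$stage)
  rows <- lapply(genes, function(g) {
    carriers <- gene_carriers(mutations, g, eligible_classes)
    cs <- vapply(by_stage, function(p) length(intersect(carriers, p)),
                 integer(1))
    tibble::tibble(
      gene = g,
      mc_overall = length(intersect(carriers, pats)) / length(pats),
      carriers_I = cs[["I"]], carriers_II = cs[["II"]],
      carriers_III = cs[["III"]],
      mc_I = cs[["I"]] / max(length(by_stage[["I"]]), 1L),
      mc_II = cs[["II"]] / max(length(by_stage[["II"]]), 1L),
      mc_III = cs[["III"]] / max(length(by_stage[["III"]]), 1L))
  })
  dplyr::bind_rows(rows)
}

#' Exact test on a 2x2 contingency table
#'
#' Conditional exact (Fisher) test computed directly from the
#' hypergeometric distribution. One-sided p-values are hypergeometric
#' tails; the two-sided p-value sums the probabilities of all tables (with
#' the observed margins) no more likely than the observed one, using the
#' conventional relative tolerance of 1e-7 when comparing likelihoods.
#'
#' The table is `rbind(c(a, b), c(c, d))`; `"greater"` tests for
#' association concentrating counts in cell `a`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param sided `"two"`, `"greater"`, or `"less"`.
#' @return A p-value.
#' @examples
#' fisher_2x2(3, 1, 1, 3)  # 0.4857
#' @export
fisher_2x2 <- function(a, b, c, d, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != trunc(cells))) {
    stop("Cell counts must be non-negative integers.", call. = FALSE)
  }
  m <- a + b        # row-1 margin
  n <- c + d        # row-2 margin
  k <- a + c        # column-1 margin
  if (m + n == 0) return(1)
  switch(sided,
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE),
    less = stats::phyper(a, m, n, k),
    two = {
      support <- max(0, k - n):min(k, m)
      dens <- stats::dhyper(support, m, n, k)
      d_obs <- stats::dhyper(a, m, n, k)
      min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
    })
}

#' Stage enrichment of a gene's mutation carriers
#'
#' One-sided exact test of whether carriers of mutations in `gene`
#' concentrate in stage `stage` versus the other stages, on the 2x2 table
#' (carrier / non-carrier) x (stage / rest). Returns both the enrichment
#' and depletion p-values plus the observed coverages.
#'
#' @param mutations Canonical mutation tibble.
#' @param clinical Clinical tibble with `patient_id` and `stage`.
#' @param gene Gene symbol.
#' @param stage One of `"I"`, `"II"`, `"III"`.
#' @param eligible_classes Variant classes counted; `NULL` counts all.
#' @return One-row tibble with counts, coverages and p-values.
#' @export
stage_enrichment <- function(mutations, clinical, gene, stage,
                             eligible_classes = NULL) {
  stopifnot(stage %in% stage_levels)
  in_stage <- clinical$patient_id[clinical$stage == stage]
  rest <- clinical$patient_id[clinical$stage != stage]
  if (length(in_stage) == 0L) {
    stop("Stage ", stage, " has no patients.", call. = FALSE)
  }
  carriers <- gene_carriers(mutations, gene, eligible_classes)
  a <- length(intersect(carriers, in_stage))
  b <- length(in_stage) - a
  c_ <- length(intersect(carriers, rest))
  d <- length(rest) - c_
  tibble::tibble(
    gene = gene, stage = stage,
    carriers_stage = a, n_stage = a + b,
    carriers_rest = c_, n_rest = c_ + d,
    mc_stage = a / (a + b), mc_rest = c_ / (c_ + d),
    p_enrich = fisher_2x2(a, b, c_, d, sided = "greater"),
    p_deplete = fisher_2x2(a, b, c_, d, sided = "less"),
    direction = ifelse(a / (a + b) >= c_ / (c_ + d),
                       "enriched", "depleted"))
}

#' Default per-gene significance test for the consensus harness
#'
#' An intentionally simple stand-in for an external significance caller:
#' for each gene, tests the carrier count against a binomial null at the
#' cohort-wide median mutation coverage (one-sided, upper tail), then
#' selects genes with BH q-value at or below `q_max`.
#'
#' @param mutations Canonical mutation tibble.
#' @param patients Patient IDs defining the (sub)cohort.
#' @param q_max BH q-value cutoff (default 0.1).
#' @return Character vector of significant genes, sorted.
#' @export
binomial_gene_test <- function(mutations, patients, q_max = 0.1) {
  m <- mutations[mutations$patient_id %in% patients, , drop = FALSE]
  carr <- m |>
    dplyr::distinct(.data$gene, .data$patient_id) |>
    dplyr::count(.data$gene, name = "carriers")
  if (nrow(carr) == 0L) return(character(0))
  n <- length(patients)
  p0 <- stats::median(carr$carriers / n)
  p <- stats::pbinom(carr$carriers - 1, n, p0, lower.tail = FALSE)
  sort(carr$gene[bh_fdr(p) <= q_max])
}

#' Subsample-consensus harness around a per-gene significance test
#'
#' Runs `gene_test` on the full cohort and on seeded random subsamples of
#' the given sizes (without replacement, one draw per size), then combines
#' the per-run significant gene sets: the consensus is their intersection
#' (default), union, or majority vote. Per-run lists are retained for
#' audit. The default sizes for a 468-patient cohort step from 410 to 460
#' by tens.
#'
#' @param gene_test Function `(mutations, patients) -> character vector` of
#'   significant genes; must be deterministic given its input.
#' @param mutations Canonical mutation tibble.
#' @param patients Full-cohort patient IDs.
#' @param sizes Subsample sizes; each must be <= `length(patients)`.
#' @param seed Master seed; one child seed per subsample.
#' @param mode Consensus rule.
#' @return List with `consensus` (character vector), `runs` (named list of
#'   per-run gene sets), and `sizes`.
#' @export
subsample_consensus <- function(gene_test, mutations, patients,
                                sizes = c(410, 420, 430, 440, 450, 460),
                                seed = 1L,
                                mode = c("intersection", "union",
                                         "majority")) {
  mode <- match.arg(mode)
  if (any(sizes > length(patients))) {
    stop("Subsample size exceeds cohort size.", call. = FALSE)
  }
  runs <- list(full = sort(gene_test(mutations, patients)))
  for (i in seq_along(sizes)) {
    set.seed(derive_seed(seed, 100L + i))
    sub <- sample(patients, sizes[i])
    runs[[paste0("n", sizes[i])]] <- sort(gene_test(mutations, sub))
  }
  consensus <- switch(mode,
    intersection = Reduce(intersect, runs),
    union = sort(unique(unlist(runs))),
    majority = {
      tab <- table(unlist(runs))
      sort(names(tab)[tab > length(runs) / 2])
    })
  list(consensus = sort(consensus), runs = runs, sizes = sizes)
}
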