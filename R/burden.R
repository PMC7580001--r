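#' Per-mutation domain-hit probability for one gene
#'
#' Probability that a mutation placed uniformly along the protein lands in
#' the family's domain-encoding region: |union of instance spans| divided by
#' the protein length. Overlapping instances of the same family are merged,
#' so no residue is double-counted.
#'
#' @param starts,ends Integer vectors of 1-based inclusive span coordinates
#'   for the family's instances in this protein.
#' @param protein_length Protein length in amino acids.
#' @return A probability in \[0, 1\].
#' @examples
#' domain_hit_probability(10, 69, 300)          # 0.2
#' domain_hit_probability(c(10, 30), c(40, 70), 122)  # union 61/122 = 0.5
#' @export
domain_hit_probability <- function(starts, ends, protein_length) {
  if (length(starts) == 0L) {
    stop("No domain instances supplied.", call. = FALSE)
  }
  stopifnot(length(starts) == length(ends),
            all(starts >= 1), all(starts <= ends),
            all(ends <= protein_length))
  span_union_length(starts, ends) / protein_length
}

span_union_length <- function(starts, ends) {
  red <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  sum(IRanges::width(red))
}

#' Tally mutations against every domain family
#'
#' For each (family, member gene) pair computes the gene profile: `n_i`
#' eligible mutations with a known protein position, the family span union
#' `S`, hit probability `p_i = S / L`, and `k_i` mutations falling inside
#' the span. Family-level statistics aggregate the profiles: `N_obs = sum
#' k_i`, distinct `genomes_hit`, and the normalized Shannon entropy of the
#' in-domain counts across member genes (see [normalized_entropy()]).
#'
#' Boundary convention: positions are 1-based and spans inclusive, so a
#' mutation at `start` or `end` is in-domain; at `end + 1` it is not.
#'
#' @param mutations Canonical mutation tibble.
#' @param domains Domain instance tibble (already E-value filtered).
#' @param eligible_classes Variant classes entering the tally (default
#'   missense only, since only amino-acid-changing point mutations are
#'   modelled by the uniform-placement null).
#' @param entropy_axis What the entropy is computed over: in-domain
#'   mutation counts per member `"gene"` (default), per `"patient"`, or per
#'   residue `"position"`.
#' @param entropy_norm Entropy normalization base: `"hit"` uses the number
#'   of categories carrying mass; `"all"` uses all member genes (only
#'   meaningful for the gene axis).
#' @return A tibble with one row per family: counts, `genomes_hit`,
#'   `entropy`, and a list-column `profiles` of per-gene
#'   `(gene, L, S, p, n, k)` tibbles.
#' @export
tally_families <- function(mutations, domains,
                           eligible_classes = "missense",
                           entropy_axis = c("gene", "patient", "position"),
                           entropy_norm = c("hit", "all")) {
  entropy_axis <- match.arg(entropy_axis)
  entropy_norm <- match.arg(entropy_norm)
  stopifnot(length(eligible_classes) >= 1)

  elig <- mutations[mutations$variant_class %in% eligible_classes &
                      !is.na(mutations$protein_pos), , drop = FALSE]
  elig$.mut_id <- seq_len(nrow(elig))

  # per (family, gene): span union and protein length, in one IRanges pass
  key <- paste(domains$family_acc, domains$gene, sep = "\r")
  spans <- IRanges::reduce(S4Vectors::splitAsList(
    IRanges::IRanges(domains$start, domains$end), key))
  S_by_key <- sum(IRanges::width(spans))
  first <- !duplicated(key)
  prof <- tibble::tibble(family_acc = domains$family_acc[first],
                         family_name = domains$family_name[first],
                         gene = domains$gene[first],
                         L = domains$protein_length[first],
                         S = unname(S_by_key[key[first]]))
  prof$p <- prof$S / prof$L

  # n_i: eligible mutations per gene
  n_by_gene <- elig |> dplyr::count(.data$gene, name = "n")
  prof <- dplyr::left_join(prof, n_by_gene, by = "gene")
  prof$n[is.na(prof$n)] <- 0L

  # in-domain hits: join eligible mutations to instances, dedupe overlaps
  hits <- dplyr::inner_join(
    elig[, c(".mut_id", "patient_id", "gene", "protein_pos")],
    domains[, c("gene", "family_acc", "start", "end")],
    by = "gene", relationship = "many-to-many")
  hits <- hits[hits$protein_pos >= hits$start &
                 hits$protein_pos <= hits$end, , drop = FALSE]
  hits <- dplyr::distinct(hits, .data$family_acc, .data$.mut_id,
                          .keep_all = TRUE)

  k_by <- hits |> dplyr::count(.data$family_acc, .data$gene, name = "k")
  prof <- dplyr::left_join(prof, k_by, by = c("family_acc", "gene"))
  prof$k[is.na(prof$k)] <- 0L

  fam_genomes <- hits |>
    dplyr::distinct(.data$family_acc, .data$patient_id) |>
    dplyr::count(.data$family_acc, name = "genomes_hit")

  axis_col <- switch(entropy_axis, gene = "gene", patient = "patient_id",
                     position = "protein_pos")
  fam_entropy <- hits |>
    dplyr::count(.data$family_acc, .data[[axis_col]]) |>
    dplyr::group_by(.data$family_acc) |>
    dplyr::summarise(entropy_raw = list(.data$n), .groups = "drop")

  fam <- prof |>
    dplyr::group_by(.data$family_acc, .data$family_name) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_trials = sum(.data$n),
      N_obs = sum(.data$k),
      profiles = list(dplyr::pick(dplyr::all_of(
        c("gene", "L", "S", "p", "n", "k")))),
      .groups = "drop")
  fam <- dplyr::left_join(fam, fam_genomes, by = "family_acc")
  fam$genomes_hit[is.na(fam$genomes_hit)] <- 0L
  fam <- dplyr::left_join(fam, fam_entropy, by = "family_acc")

  m_all <- if (entropy_axis == "gene" && entropy_norm == "all") {
    fam$n_genes
  } else {
    NA_integer_
  }
  fam$entropy <- mapply(function(cnt, m_override) {
    if (is.null(cnt) || length(cnt) == 0L || sum(cnt) == 0) return(NA_real_)
    m <- if (!is.na(m_override)) m_override else length(cnt)
    normalized_entropy(cnt, m)
  }, fam$entropy_raw, m_all)
  fam$entropy_raw <- NULL
  attr(fam, "entropy_axis") <- entropy_axis
  attr(fam, "entropy_norm") <- entropy_norm
  fam
}

#' Tally a single domain family
#'
#' @inheritParams tally_families
#' @param family_acc Family accession to tally.
#' @return One-row family tibble as from [tally_families()].
#' @export
tally_family <- function(mutations, domains, family_acc,
                         eligible_classes = "missense", ...) {
  sub <- domains[domains$family_acc == family_acc, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("Family '", family_acc, "' absent from the domain table.",
         call. = FALSE)
  }
  tally_families(mutations, sub, eligible_classes = eligible_classes, ...)
}

#' Exact Poisson-binomial test for one tallied family
#'
#' Assembles the trial list — each of the `n_i` eligible mutations of member
#' gene *i* contributes one Bernoulli trial with probability `p_i` — and
#' computes the exact tail p-value at the observed in-domain count `N_obs`
#' with [poisson_binomial_tail()]. A family with zero trials gets p = 1
#' with a message.
#'
#' @param family_row One-row tibble from [tally_families()].
#' @param inclusive Tail convention passed to [poisson_binomial_tail()];
#'   the default `TRUE` is the standard exact one-sided p-value
#'   `P(N >= N_obs)`.
#' @return The row with a `p_value` column set.
#' @export
family_test <- function(family_row, inclusive = TRUE) {
  prof <- family_row$profiles[[1]]
  trials <- rep.int(prof$p, prof$n)
  if (length(trials) == 0L) {
    message("family_test: ", family_row$family_acc,
            " has zero eligible trials; p = 1.")
    family_row$p_value <- 1
    return(family_row)
  }
  family_row$p_value <- poisson_binomial_tail(trials, family_row$N_obs,
                                              inclusive = inclusive)
  family_row
}

#' Domain-burden analysis across all families
#'
#' End-to-end per-family computation: tally ([tally_families()]), exact
#' Poisson-binomial p-value per family ([family_test()]),
#' Benjamini-Hochberg q-values, and the genome fraction
#' `genomes_hit / cohort_size`.
#'
#' @inheritParams tally_families
#' @param cohort_size Number of patients in the cohort (for
#'   `genome_fraction`). Defaults to the number of distinct patients in
#'   `mutations`.
#' @param inclusive Tail convention, see [family_test()].
#' @return A tibble with one row per family, sorted by ascending p-value
#'   (ties broken by accession).
#' @export
domain_burden <- function(mutations, domains,
                          eligible_classes = "missense",
                          cohort_size = NULL,
                          inclusive = TRUE,
                          entropy_axis = "gene",
                          entropy_norm = "hit") {
  if (is.null(cohort_size)) {
    cohort_size <- dplyr::n_distinct(mutations$patient_id)
  }
  fam <- tally_families(mutations, domains,
                        eligible_classes = eligible_classes,
                        entropy_axis = entropy_axis,
                        entropy_norm = entropy_norm)
  fam$p_value <- vapply(seq_len(nrow(fam)), function(i) {
    prof <- fam$profiles[[i]]
    trials <- rep.int(prof$p, prof$n)
    if (length(trials) == 0L) return(1)
    poisson_binomial_tail(trials, fam$N_obs[i], inclusive = inclusive)
  }, numeric(1))
  fam$q_value <- bh_fdr(fam$p_value)
  fam$genome_fraction <- fam$genomes_hit / cohort_size
  fam <- fam[order(fam$p_value, fam$family_acc), , drop = FALSE]
  attr(fam, "cohort_size") <- cohort_size
  attr(fam, "tail") <- if (inclusive) "inclusive" else "exclusive"
  fam
}
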