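#' Normalized Shannon entropy of a count vector
#'
#' \eqn{H = -\sum f_i \log f_i / \log m} over categories with positive
#' mass, where `f_i` are the count fractions and `m` the axis cardinality.
#' `H = 1` for counts uniform over `m` categories, `H = 0` when all mass
#' sits in one category (or `m = 1`). Used to require that a domain
#' family's in-domain mutations are spread across several member genes
#' rather than driven by a single recurrently mutated gene.
#'
#' @param counts Non-negative integer vector with positive sum.
#' @param m Axis cardinality (number of categories the distribution could
#'   occupy); defaults to `length(counts)`.
#' @return A value in \[0, 1\].
#' @examples
#' normalized_entropy(c(5, 5, 5, 5))      # 1
#' normalized_entropy(c(7, 0, 0))         # 0
#' normalized_entropy(c(3, 1))            # 0.8113
#' @export
normalized_entropy <- function(counts, m = length(counts)) {
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be non-negative.", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("`counts` must have a positive sum.", call. = FALSE)
  stopifnot(m >= 1)
  if (m == 1) return(0)
  f <- counts[counts > 0] / total
  h <- -sum(f * log(f)) / log(m)
  min(max(h, 0), 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`, kept as the
#' package's single FDR entry point.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Recurrence-screen thresholds
#'
#' The three-part screen a domain family must pass: mutations spread over
#' enough genomes (an absolute count, or a cohort fraction whose cutoff is
#' `ceiling(fraction * cohort_size)`), an exact p-value strictly below
#' `p_max`, and a normalized Shannon entropy of at least `entropy_min`.
#' Defaults: fraction 0.064, p < 0.05, entropy >= 0.71 — with a 468-patient
#' cohort the fraction cutoff is `ceiling(29.95) = 30` genomes.
#'
#' @param min_genomes Absolute genome cutoff; overrides the fraction when
#'   given.
#' @param min_genome_fraction Cohort fraction defining the genome cutoff.
#' @param p_max Strict upper bound on the exact p-value.
#' @param entropy_min Inclusive lower bound on normalized entropy.
#' @param fdr_q Optional additional bound on the BH q-value.
#' @return A `screen_thresholds` list.
#' @export
screen_thresholds <- function(min_genomes = NULL,
                              min_genome_fraction = 0.064,
                              p_max = 0.05,
                              entropy_min = 0.71,
                              fdr_q = NULL) {
  if (!is.null(min_genomes)) {
    stopifnot(min_genomes >= 1, min_genomes == trunc(min_genomes))
  }
  stopifnot(min_genome_fraction > 0, min_genome_fraction < 1,
            p_max > 0, p_max <= 1, entropy_min >= 0, entropy_min <= 1)
  if (!is.null(fdr_q)) stopifnot(fdr_q > 0, fdr_q <= 1)
  structure(list(min_genomes = min_genomes,
                 min_genome_fraction = min_genome_fraction,
                 p_max = p_max, entropy_min = entropy_min, fdr_q = fdr_q),
            class = "screen_thresholds")
}

#' Genome cutoff implied by thresholds and cohort size
#'
#' @param thresholds A [screen_thresholds()].
#' @param cohort_size Number of patients.
#' @return Integer cutoff: minimum `genomes_hit` required.
#' @export
genome_cutoff <- function(thresholds, cohort_size) {
  if (!is.null(thresholds$min_genomes)) {
    as.integer(thresholds$min_genomes)
  } else {
    as.integer(ceiling(thresholds$min_genome_fraction * cohort_size))
  }
}

#' Apply the three-part recurrence screen to family statistics
#'
#' A family passes iff `genomes_hit >= genome_cutoff` (non-strict),
#' `p_value < p_max` (strict), and `entropy >= entropy_min` (non-strict);
#' optionally also `q_value <= fdr_q`. The result is sorted by ascending
#' p-value with a deterministic accession tie-break.
#'
#' @param stats Family tibble from [domain_burden()].
#' @param thresholds A [screen_thresholds()].
#' @param cohort_size Number of patients (defaults to the attribute stored
#'   by [domain_burden()]).
#' @return The passing subset, p-sorted; the applied cutoffs are attached
#'   as attribute `"screen"`.
#' @export
screen_families <- function(stats, thresholds = screen_thresholds(),
                            cohort_size = attr(stats, "cohort_size")) {
  if (is.null(cohort_size)) {
    stop("`cohort_size` is required (not found on `stats`).", call. = FALSE)
  }
  cutoff <- genome_cutoff(thresholds, cohort_size)
  keep <- stats$genomes_hit >= cutoff &
    stats$p_value < thresholds$p_max &
    !is.na(stats$entropy) & stats$entropy >= thresholds$entropy_min
  if (!is.null(thresholds$fdr_q)) {
    keep <- keep & stats$q_value <= thresholds$fdr_q
  }
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$p_value, out$family_acc), , drop = FALSE]
  attr(out, "screen") <- list(genome_cutoff = cutoff,
                              p_max = thresholds$p_max,
                              entropy_min = thresholds$entropy_min,
                              fdr_q = thresholds$fdr_q,
                              cohort_size = cohort_size)
  out
}
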