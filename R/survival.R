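#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate via `survival::survfit`. The returned step
#' function is non-increasing with S(0) = 1.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) death indicators.
#' @return Tibble with `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) > 0)
  if (any(times < 0)) stop("Negative survival time.", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv)
}

#' Log-rank test between two survival groups
#'
#' Standard one-degree-of-freedom log-rank chi-square via
#' `survival::survdiff`; symmetric in the two groups.
#'
#' @param times_a,events_a Follow-up and event indicator, group A.
#' @param times_b,events_b Follow-up and event indicator, group B.
#' @return List with `statistic` (chi-square) and `p_value`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("Both groups must be non-empty.", call. = FALSE)
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("No events in either group.", call. = FALSE)
  }
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio between two survival groups
#'
#' Single-binary-covariate Cox proportional-hazards fit (partial
#' likelihood, Efron tie handling by default) returning the hazard of
#' group B relative to group A, its Wald p-value and confidence interval.
#'
#' @inheritParams logrank_test
#' @param conf_level Confidence level for the interval.
#' @param ties Tie-handling method for `survival::coxph`.
#' @return List with `hr`, `ci` (length-2), `wald_p`, `log_hr`, `se`.
#' @export
hazard_ratio <- function(times_a, events_a, times_b, events_b,
                         conf_level = 0.95, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(events_a) < 1 || sum(events_b) < 1) {
    stop("Each group needs at least one event.", call. = FALSE)
  }
  time <- c(times_a, times_b)
  event <- as.integer(c(events_a, events_b))
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  fit <- survival::coxph(survival::Surv(time, event) ~ grp, ties = ties)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 1e3) {
    stop("Cox fit did not converge (possible complete separation): beta = ",
         signif(beta, 3), ", se = ", signif(se, 3), call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * z * se),
       wald_p = 2 * stats::pnorm(-abs(beta / se)),
       log_hr = beta, se = se)
}

#' Stratify a cohort by domain-family (or gene) mutation status
#'
#' Splits patients into carriers of at least one eligible mutation inside
#' the family's domain spans (or anywhere in `gene` when `family_acc` is
#' `NULL`) versus non-carriers, and runs the Kaplan-Meier, log-rank and
#' Cox-PH analyses.
#'
#' @param mutations Canonical mutation tibble.
#' @param clinical Clinical tibble with `patient_id`, `survival_time`,
#'   `event`.
#' @param domains Domain instance tibble (needed when `family_acc` given).
#' @param family_acc Domain family accession defining carrier status.
#' @param gene Gene symbol defining carrier status (alternative).
#' @param eligible_classes Variant classes counted (default missense).
#' @return List with `carriers`, `km` (per-group curves), `logrank`, `hr`.
#' @export
survival_by_mutation <- function(mutations, clinical, domains = NULL,
                                 family_acc = NULL, gene = NULL,
                                 eligible_classes = "missense") {
  if (is.null(family_acc) == is.null(gene)) {
    stop("Give exactly one of `family_acc` or `gene`.", call. = FALSE)
  }
  if (!is.null(family_acc)) {
    inst <- domains[domains$family_acc == family_acc, , drop = FALSE]
    if (nrow(inst) == 0L) {
      stop("Family '", family_acc, "' absent from the domain table.",
           call. = FALSE)
    }
    m <- mutations[mutations$variant_class %in% eligible_classes &
                     !is.na(mutations$protein_pos), , drop = FALSE]
    hit <- dplyr::inner_join(m, inst[, c("gene", "start", "end")],
                             by = "gene", relationship = "many-to-many")
    hit <- hit[hit$protein_pos >= hit$start & hit$protein_pos <= hit$end, ]
    carriers <- unique(hit$patient_id)
  } else {
    carriers <- gene_carriers(mutations, gene, eligible_classes)
  }
  is_carrier <- clinical$patient_id %in% carriers
  a <- clinical[!is_carrier, ]  # reference group: non-carriers
  b <- clinical[is_carrier, ]
  list(carriers = carriers,
       km = list(
         non_carrier = km_curve(a$survival_time, a$event),
         carrier = km_curve(b$survival_time, b$event)),
       logrank = logrank_test(a$survival_time, a$event,
                              b$survival_time, b$event),
       hr = hazard_ratio(a$survival_time, a$event,
                         b$survival_time, b$event))
}
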