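#' Configuration for the synthetic tumor-cohort generator
#'
#' Collects the sizes, rates and planted effects that define a simulated
#' cohort. The defaults emulate a breast-tumor exome cohort: 468 patients
#' with stage frequencies 89/287/92 (I/II/III, stage IV pre-merged into
#' III), exponential survival with independent uniform censoring, and
#' domain families whose member genes carry enough missense burden that
#' family-level aggregation has tens of Bernoulli trials.
#'
#' Under the null (no `enriched_families`), each mutation's within-domain
#' indicator is Bernoulli with probability exactly (domain span)/(protein
#' length) — mutations are placed uniformly and independently along the
#' protein, which is precisely the null model of the domain-burden test.
#' For planted families the within-domain *odds* are multiplied by
#' `enrichment_lambda` (applied to missense mutations), so `lambda = 1`
#' reproduces the null exactly.
#'
#' @param n_patients Cohort size.
#' @param n_genes Number of genes; the first
#'   `n_families * genes_per_family` carry one domain instance each.
#' @param protein_length_range Integer interval for protein lengths (aa).
#' @param n_families Number of domain families.
#' @param genes_per_family Member genes per family.
#' @param domain_span_fraction Expected domain length / protein length,
#'   in (0, 1).
#' @param background_mutation_rate Expected mutations per gene per patient.
#' @param enriched_families Character vector of family accessions (e.g.
#'   `"FAM0001"`) with planted within-domain enrichment.
#' @param enrichment_lambda Odds multiplier (>= 1) applied to the
#'   within-domain hit probability of missense mutations in enriched
#'   families.
#' @param variant_class_probs Named probabilities over generated variant
#'   classes.
#' @param stage_probs Probabilities for stages I/II/III; must sum to 1.
#' @param ilbc_fraction Fraction of patients labelled ILBC (the rest IDBC).
#' @param baseline_hazard Exponential death hazard per day for
#'   non-carriers.
#' @param hazard_ratio_domain_mut Hazard multiplier for patients carrying
#'   at least one missense mutation inside an enriched family's domain.
#' @param censor_max Upper bound of the uniform censoring time (days).
#' @param seed Master seed; per-stage child seeds are derived from it so
#'   stages are individually reproducible.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 468,
                          n_genes = 3600,
                          protein_length_range = c(200L, 1200L),
                          n_families = 200,
                          genes_per_family = 15,
                          domain_span_fraction = 0.3,
                          background_mutation_rate = 0.012,
                          enriched_families = character(0),
                          enrichment_lambda = 8,
                          variant_class_probs = c(missense = 0.75,
                                                  silent = 0.15,
                                                  nonsense = 0.10),
                          stage_probs = c(I = 89, II = 287, III = 92) / 468,
                          ilbc_fraction = 0,
                          baseline_hazard = 1 / 1000,
                          hazard_ratio_domain_mut = 1,
                          censor_max = 3000,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              protein_length_range = as.integer(protein_length_range),
              n_families = as.integer(n_families),
              genes_per_family = as.integer(genes_per_family),
              domain_span_fraction = domain_span_fraction,
              background_mutation_rate = background_mutation_rate,
              enriched_families = as.character(enriched_families),
              enrichment_lambda = enrichment_lambda,
              variant_class_probs = variant_class_probs,
              stage_probs = stage_probs,
              ilbc_fraction = ilbc_fraction,
              baseline_hazard = baseline_hazard,
              hazard_ratio_domain_mut = hazard_ratio_domain_mut,
              censor_max = censor_max,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_patients >= 1, n_genes >= 1, n_families >= 0,
              genes_per_family >= 1,
              length(protein_length_range) == 2,
              protein_length_range[1] >= 10,
              protein_length_range[2] >= protein_length_range[1])
    if (n_families * genes_per_family > n_genes) {
      stop("Infeasible config: n_families * genes_per_family exceeds n_genes.",
           call. = FALSE)
    }
    if (domain_span_fraction <= 0 || domain_span_fraction >= 1) {
      stop("domain_span_fraction must lie in (0, 1).", call. = FALSE)
    }
    if (round(domain_span_fraction * protein_length_range[1]) >
        protein_length_range[1]) {
      stop("Infeasible config: domain span exceeds protein length.",
           call. = FALSE)
    }
    stopifnot(background_mutation_rate > 0, enrichment_lambda >= 1,
              baseline_hazard > 0, hazard_ratio_domain_mut > 0,
              censor_max > 0, ilbc_fraction >= 0, ilbc_fraction <= 1)
    if (abs(sum(stage_probs) - 1) > 1e-12) {
      stop("stage_probs must sum to 1 (within 1e-12).", call. = FALSE)
    }
    if (abs(sum(variant_class_probs) - 1) > 1e-12 ||
        !all(names(variant_class_probs) %in% variant_class_levels)) {
      stop("variant_class_probs must be named by valid classes and sum to 1.",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

# deterministic per-stage child seeds, kept inside 32-bit integer range
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435761 + stage * 40503) %% 2147483647)
}

#' Generate a synthetic tumor cohort
#'
#' Produces the three tables the pipeline consumes — mutations, domain
#' instances, clinical records — with the statistical structure described
#' in [cohort_config()]. Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `domain_cohort` with elements `mutations`,
#'   `domains`, `clinical` (tibbles) and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config

  # --- genes and proteins -------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  lens <- seq.int(cfg$protein_length_range[1], cfg$protein_length_range[2])
  L <- lens[sample.int(length(lens), cfg$n_genes, replace = TRUE)]

  # --- domain instances ---------------------------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  n_member <- cfg$n_families * cfg$genes_per_family
  fam_idx <- rep(seq_len(cfg$n_families), each = cfg$genes_per_family)
  mem <- seq_len(n_member)                # member genes are the first block
  span <- pmax(1L, as.integer(round(cfg$domain_span_fraction * L[mem])))
  start <- 1L + as.integer(floor(stats::runif(n_member) * (L[mem] - span + 1L)))
  domains <- tibble::tibble(
    gene = gene_ids[mem],
    protein_length = L[mem],
    family_acc = sprintf("FAM%04d", fam_idx),
    family_name = sprintf("fam_%04d", fam_idx),
    start = start,
    end = start + span - 1L,
    e_value = 10^-stats::runif(n_member, 6, 30))
  bad_fam <- setdiff(cfg$enriched_families, domains$family_acc)
  if (length(bad_fam)) {
    stop("enriched_families not generated: ",
         paste(bad_fam, collapse = ", "), call. = FALSE)
  }

  # per-gene domain lookup (one instance per member gene by construction)
  dom_start <- rep(NA_integer_, cfg$n_genes); dom_start[mem] <- start
  dom_span <- rep(0L, cfg$n_genes);           dom_span[mem] <- span
  gene_fam <- rep(NA_character_, cfg$n_genes)
  gene_fam[mem] <- domains$family_acc

  # --- patients -----------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  patient_ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  histology <- ifelse(stats::runif(cfg$n_patients) < cfg$ilbc_fraction,
                      "ILBC", "IDBC")
  stage <- sample(stage_levels, cfg$n_patients, replace = TRUE,
                  prob = cfg$stage_probs)

  # --- mutations ----------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  counts <- stats::rpois(cfg$n_genes,
                         cfg$background_mutation_rate * cfg$n_patients)
  gidx <- rep.int(seq_len(cfg$n_genes), counts)
  M <- length(gidx)
  pat <- sample(patient_ids, M, replace = TRUE)
  vclass <- sample(names(cfg$variant_class_probs), M, replace = TRUE,
                   prob = cfg$variant_class_probs)
  vtype <- sample(c("SNP", "DNP"), M, replace = TRUE, prob = c(0.97, 0.03))

  p0 <- dom_span[gidx] / L[gidx]
  enr <- !is.na(gene_fam[gidx]) & gene_fam[gidx] %in% cfg$enriched_families &
    vclass == "missense"
  lam <- ifelse(enr, cfg$enrichment_lambda, 1)
  p_hit <- lam * p0 / (lam * p0 + (1 - p0))   # odds-scaled hit probability
  in_dom <- stats::runif(M) < p_hit
  s <- dom_start[gidx]; w <- dom_span[gidx]; Lg <- L[gidx]
  pos <- integer(M)
  pos[in_dom] <- s[in_dom] +
    as.integer(floor(stats::runif(sum(in_dom)) * w[in_dom]))
  out <- !in_dom
  r <- 1L + as.integer(floor(stats::runif(sum(out)) * (Lg[out] - w[out])))
  # complement draw: shift indices at/after the span past it
  no_dom <- is.na(s[out])
  s_out <- ifelse(no_dom, Lg[out] + 1L, s[out])
  pos[out] <- ifelse(r >= s_out, r + w[out], r)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  mutations <- tibble::tibble(
    patient_id = pat,
    gene = gene_ids[gidx],
    variant_class = vclass,
    variant_type = vtype,
    protein_pos = pos,
    aa_change = paste0("p.", sample(aa, M, TRUE), pos, sample(aa, M, TRUE)))

  # --- clinical / survival ------------------------------------------------
  set.seed(derive_seed(cfg$seed, 5L))
  carrier_pats <- unique(mutations$patient_id[enr & in_dom])
  carrier <- patient_ids %in% carrier_pats
  hazard <- cfg$baseline_hazard *
    ifelse(carrier, cfg$hazard_ratio_domain_mut, 1)
  t_death <- stats::rexp(cfg$n_patients, rate = hazard)
  t_cens <- stats::runif(cfg$n_patients, 0, cfg$censor_max)
  clinical <- tibble::tibble(
    patient_id = patient_ids,
    histology = histology,
    stage = factor(stage, levels = stage_levels),
    survival_time = pmin(t_death, t_cens),
    event = t_death <= t_cens)

  structure(list(mutations = mutations, domains = domains,
                 clinical = clinical, config = cfg),
            class = "domain_cohort")
}

#' Generate a null cohort (no planted enrichment, hazard ratio 1)
#'
#' Convenience wrapper for type-I-error studies: disables all planted
#' effects so every family satisfies the burden test's null model and the
#' two survival groups share one hazard. The returned config records
#' `enrichment_lambda = 1`.
#'
#' @inheritParams generate_cohort
#' @return A `domain_cohort`, as [generate_cohort()].
#' @export
null_cohort <- function(config) {
  config$enriched_families <- character(0)
  config$enrichment_lambda <- 1
  config$hazard_ratio_domain_mut <- 1
  generate_cohort(config)
}

#' Write a cohort bundle to disk
#'
#' Writes `mutations.tsv`, `domains.tsv`, `clinical.tsv` and a
#' `manifest.yaml` recording the full generating configuration.
#'
#' @param cohort A `domain_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results_table(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_results_table(cohort$domains, file.path(dir, "domains.tsv"))
  cl <- cohort$clinical
  cl$stage <- as.character(cl$stage)
  write_results_table(cl, file.path(dir, "clinical.tsv"))
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.domain_cohort <- function(x, ...) {
  cat("domain_cohort:", nrow(x$mutations), "mutations,",
      nrow(x$domains), "domain instances,",
      nrow(x$clinical), "patients\n")
  invisible(x)
}
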