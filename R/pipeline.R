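#' Pipeline run configuration
#'
#' One object holding everything a full run needs: either the three input
#' paths (mutations, domains, clinical) or a synthetic [cohort_config()],
#' plus thresholds and conventions. Exactly one input source must be
#' given.
#'
#' @param mutations_path,domains_path,clinical_path Input TSV paths.
#' @param synthetic A [cohort_config()] for a simulated run.
#' @param thresholds A [screen_thresholds()].
#' @param eligible_classes Variant classes entering the burden tally.
#' @param e_value_max Domain-instance E-value cutoff.
#' @param inclusive_tail Tail convention for the exact test.
#' @param entropy_axis,entropy_norm Entropy conventions, see
#'   [tally_families()].
#' @param out_dir Output directory.
#' @param seed Seed for any randomness (synthetic generation).
#' @return A `run_config` list (not yet validated).
#' @export
run_config <- function(mutations_path = NULL, domains_path = NULL,
                       clinical_path = NULL, synthetic = NULL,
                       thresholds = screen_thresholds(),
                       eligible_classes = "missense",
                       e_value_max = 1e-5,
                       inclusive_tail = TRUE,
                       entropy_axis = "gene",
                       entropy_norm = "hit",
                       out_dir = "domainburden_out",
                       seed = 1L) {
  structure(list(mutations_path = mutations_path,
                 domains_path = domains_path,
                 clinical_path = clinical_path,
                 synthetic = synthetic,
                 thresholds = thresholds,
                 eligible_classes = eligible_classes,
                 e_value_max = e_value_max,
                 inclusive_tail = inclusive_tail,
                 entropy_axis = entropy_axis,
                 entropy_norm = entropy_norm,
                 out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Collects every violation rather than stopping at the first.
#'
#' @param config A [run_config()].
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  has_paths <- !is.null(config$mutations_path) ||
    !is.null(config$domains_path) || !is.null(config$clinical_path)
  has_syn <- !is.null(config$synthetic)
  if (has_paths && has_syn) {
    v <- c(v, "Give real input paths OR a synthetic config, not both.")
  }
  if (!has_paths && !has_syn) {
    v <- c(v, "No input source: set the three input paths or `synthetic`.")
  }
  if (has_paths) {
    for (p in c("mutations_path", "domains_path", "clinical_path")) {
      if (is.null(config[[p]])) {
        v <- c(v, paste0("Missing ", p, "."))
      } else if (!file.exists(config[[p]])) {
        v <- c(v, paste0(p, " does not exist: ", config[[p]]))
      }
    }
  }
  if (has_syn && !inherits(config$synthetic, "cohort_config")) {
    v <- c(v, "`synthetic` must be a cohort_config.")
  }
  th <- config$thresholds
  if (!inherits(th, "screen_thresholds")) {
    v <- c(v, "`thresholds` must come from screen_thresholds().")
  } else {
    if (th$entropy_min < 0 || th$entropy_min > 1) {
      v <- c(v, "entropy_min must lie in [0, 1].")
    }
    if (th$p_max <= 0 || th$p_max > 1) v <- c(v, "p_max must lie in (0, 1].")
  }
  if (config$e_value_max <= 0) v <- c(v, "e_value_max must be > 0.")
  if (!length(config$eligible_classes)) {
    v <- c(v, "eligible_classes must be non-empty.")
  }
  v
}

#' Run the full domain-burden pipeline
#'
#' Loads (or simulates) the cohort, runs the domain-burden test over all
#' families, applies the recurrence screen, computes per-gene coverage and
#' per-stage enrichment for the most-covered genes, and writes every table
#' plus a manifest of all thresholds and conventions to `out_dir`.
#' Deterministic given the config seed.
#'
#' @param config A validated [run_config()].
#' @param top_genes How many top-coverage genes get stage-enrichment tests.
#' @return Invisibly, a list with the in-memory tables (`burden`,
#'   `screened`, `coverage`, `stage`, `manifest`).
#' @export
run_pipeline <- function(config, top_genes = 20L) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("Invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
    message("run_pipeline: created output directory ", config$out_dir)
  }

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    cohort <- generate_cohort(syn)
    mutations <- cohort$mutations
    domains <- filter_domains(cohort$domains, config$e_value_max)
    clinical <- cohort$clinical
  } else {
    mutations <- read_mutation_table(config$mutations_path)
    domains <- read_domain_table(config$domains_path, config$e_value_max)
    clinical <- read_clinical_table(config$clinical_path)
  }
  cohort_size <- nrow(clinical)

  burden <- domain_burden(mutations, domains,
                          eligible_classes = config$eligible_classes,
                          cohort_size = cohort_size,
                          inclusive = config$inclusive_tail,
                          entropy_axis = config$entropy_axis,
                          entropy_norm = config$entropy_norm)
  screened <- screen_families(burden, config$thresholds, cohort_size)

  flat <- function(x) x[, setdiff(names(x), "profiles"), drop = FALSE]
  write_results_table(flat(burden),
                      file.path(config$out_dir, "domain_burden.tsv"))
  write_results_table(flat(screened),
                      file.path(config$out_dir, "screened_families.tsv"))

  coverage <- gene_coverage(mutations, clinical)
  coverage <- coverage[order(-coverage$mc_overall, coverage$gene), ]
  write_results_table(coverage,
                      file.path(config$out_dir, "gene_coverage.tsv"))

  top <- utils::head(coverage$gene, top_genes)
  stage_tbl <- dplyr::bind_rows(lapply(top, function(g) {
    dplyr::bind_rows(lapply(stage_levels, function(s) {
      stage_enrichment(mutations, clinical, g, s)
    }))
  }))
  write_results_table(stage_tbl,
                      file.path(config$out_dir, "stage_enrichment.tsv"))

  manifest <- list(
    seed = config$seed,
    inputs = if (is.null(config$synthetic)) {
      list(mutations = config$mutations_path,
           domains = config$domains_path,
           clinical = config$clinical_path)
    } else {
      list(synthetic = unclass(config$synthetic))
    },
    cohort_size = cohort_size,
    eligible_classes = config$eligible_classes,
    e_value_max = config$e_value_max,
    tail = if (config$inclusive_tail) "inclusive" else "exclusive",
    entropy_axis = config$entropy_axis,
    entropy_norm = config$entropy_norm,
    screen = attr(screened, "screen"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(burden = burden, screened = screened, coverage = coverage,
                 stage = stage_tbl, manifest = manifest))
}
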