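# Small in-code fixtures shared across test files.

toy_mutations <- function() {
  tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P4"),
    gene = c("GA", "GA", "GA", "GB", "GC", "GC"),
    variant_class = c("missense", "missense", "missense", "missense",
                      "missense", "silent"),
    variant_type = "SNP",
    protein_pos = c(15L, 25L, 80L, 50L, 10L, 12L),
    aa_change = NA_character_)
}

# spans chosen so the missense tallies for FAMX are k = (GA 2, GB 0, GC 1)
toy_domains <- function() {
  tibble::tibble(
    gene = c("GA", "GB", "GC"),
    protein_length = c(100L, 200L, 50L),
    family_acc = "FAMX",
    family_name = "toy",
    start = c(10L, 100L, 5L),
    end = c(30L, 150L, 20L),
    e_value = 1e-10)
}

toy_clinical <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:10),
    histology = "IDBC",
    stage = factor(rep(c("I", "II", "III"), c(3, 4, 3)),
                   levels = c("I", "II", "III")),
    survival_time = seq(100, 1000, by = 100),
    event = rep(c(TRUE, FALSE), 5))
}

write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

small_config <- function(seed = 42L, ...) {
  cohort_config(n_patients = 120, n_genes = 300, n_families = 15,
                genes_per_family = 6, seed = seed, ...)
}
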