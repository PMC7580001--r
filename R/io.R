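#' @importFrom rlang %||%
NULL

variant_class_levels <- c("missense", "nonsense", "frameshift_indel",
                          "inframe_indel", "splice", "silent", "other")
variant_type_levels <- c("SNP", "DNP", "INS", "DEL")
stage_levels <- c("I", "II", "III")
histology_levels <- c("IDBC", "ILBC")

#' Default MAF-style column map for mutation tables
#'
#' Maps the package's canonical mutation fields to the column names found in
#' MAF-subset exports. Override individual entries to ingest differently
#' named tables.
#'
#' @param ... Named overrides, e.g. `gene = "symbol"`.
#' @return Named character vector: canonical field -> input column name.
#' @export
maf_column_map <- function(...) {
  map <- c(patient_id    = "Tumor_Sample_Barcode",
           gene          = "Hugo_Symbol",
           variant_class = "Variant_Classification",
           variant_type  = "Variant_Type",
           protein_pos   = "Protein_position",
           aa_change     = "HGVSp_Short")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) stop("Unknown column-map fields: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    map[names(over)] <- over
  }
  map
}

# MAF Variant_Classification -> canonical class; anything unmapped -> "other"
maf_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Nonstop_Mutation  = "other",
  Frame_Shift_Del   = "frameshift_indel",
  Frame_Shift_Ins   = "frameshift_indel",
  In_Frame_Del      = "inframe_indel",
  In_Frame_Ins      = "inframe_indel",
  Splice_Site       = "splice",
  Splice_Region     = "splice",
  Silent            = "silent"
)

normalize_variant_class <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% variant_class_levels, x,
                unname(maf_class_map[x]))
  out[is.na(out)] <- "other"
  out
}

#' Read a somatic mutation table
#'
#' Ingests a tab-delimited mutation table (a MAF subset by default) into the
#' canonical mutation tibble with columns `patient_id`, `gene`,
#' `variant_class`, `variant_type`, `protein_pos`, `aa_change`. Variant
#' classes are normalized through an explicit MAF mapping; unmapped labels
#' become `"other"`. Protein positions are parsed from plain integers or
#' VEP-style `"pos/len"` strings.
#'
#' Rows with an empty patient or gene are skipped with a message (lenient
#' mode) or raise an error (`strict = TRUE`); the same applies to
#' unparseable protein positions, which in lenient mode are retained with
#' `NA` position. `parsed + skipped` always equals the input row count; the
#' skip count is attached as attribute `"skipped"`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param col_map Named character vector from [maf_column_map()].
#' @param strict If `TRUE`, malformed rows are an error instead of a logged
#'   skip.
#' @return A tibble of mutations, one row per record.
#' @export
read_mutation_table <- function(path, col_map = maf_column_map(),
                                strict = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("patient_id", "gene", "variant_class")
  for (field in required) {
    if (!col_map[[field]] %in% names(raw)) {
      stop("Mutation table is missing required column '", col_map[[field]],
           "' (", field, ").", call. = FALSE)
    }
  }
  get_col <- function(field) {
    nm <- col_map[[field]]
    if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }
  out <- tibble::tibble(
    patient_id    = get_col("patient_id"),
    gene          = get_col("gene"),
    variant_class = normalize_variant_class(get_col("variant_class")),
    variant_type  = toupper(trimws(get_col("variant_type") %||% NA_character_)),
    protein_pos   = parse_protein_pos(get_col("protein_pos")),
    aa_change     = get_col("aa_change")
  )
  out$variant_type[!out$variant_type %in% variant_type_levels] <- NA_character_

  bad_id <- is.na(out$patient_id) | out$patient_id == "" |
    is.na(out$gene) | out$gene == ""
  pos_raw <- get_col("protein_pos")
  bad_pos <- !is.na(pos_raw) & pos_raw != "" & is.na(out$protein_pos)
  if (strict && any(bad_id | bad_pos)) {
    stop("Malformed mutation rows at: ",
         paste(utils::head(which(bad_id | bad_pos), 5), collapse = ", "),
         call. = FALSE)
  }
  skipped <- sum(bad_id)
  if (skipped > 0) {
    message("read_mutation_table: skipped ", skipped,
            " row(s) with empty patient or gene.")
  }
  if (any(bad_pos & !bad_id)) {
    message("read_mutation_table: ", sum(bad_pos & !bad_id),
            " row(s) with unparseable protein position kept with NA position.")
  }
  out <- out[!bad_id, , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

parse_protein_pos <- function(x) {
  x <- as.character(x)
  x[x %in% c("", ".", "-", "NA")] <- NA_character_
  # VEP writes "123/456" (position/protein length); take the position part
  first <- sub("/.*$", "", x)
  pos <- suppressWarnings(as.numeric(first))
  pos[!is.na(pos) & (pos < 1 | pos != trunc(pos))] <- NA_real_
  as.integer(pos)
}

#' Read a protein-domain annotation table
#'
#' Reads Pfam-scan style domain instances (`gene`, `protein_length`,
#' `family_acc`, `family_name`, `start`, `end`, `e_value`; 1-based inclusive
#' amino-acid coordinates) and retains only instances with
#' `e_value < e_value_max` (default 1e-5, the conventional Pfam match
#' threshold for this analysis).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param e_value_max Strict upper bound on the match E-value; must be > 0.
#' @return A tibble of domain instances.
#' @export
read_domain_table <- function(path, e_value_max = 1e-5) {
  stopifnot(is.numeric(e_value_max), length(e_value_max) == 1L,
            e_value_max > 0)
  d <- readr::read_tsv(path, col_types = readr::cols(
    gene = "c", protein_length = "i", family_acc = "c", family_name = "c",
    start = "i", end = "i", e_value = "d"), progress = FALSE)
  validate_domain_table(d)
  filter_domains(d, e_value_max)
}

validate_domain_table <- function(d) {
  required <- c("gene", "protein_length", "family_acc", "family_name",
                "start", "end", "e_value")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("Domain table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(d$start) | is.na(d$end) | is.na(d$protein_length) |
                 d$start < 1 | d$start > d$end | d$end > d$protein_length |
                 is.na(d$e_value) | d$e_value < 0)
  if (length(bad)) {
    stop("Invalid domain instance at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": need 1 <= start <= end <= protein_length and e_value >= 0.",
         call. = FALSE)
  }
  invisible(d)
}

#' Filter domain instances by match E-value
#'
#' @param domains Domain instance tibble.
#' @param e_value_max Strict upper bound; instances with
#'   `e_value < e_value_max` are kept.
#' @return The filtered tibble. Idempotent.
#' @export
filter_domains <- function(domains, e_value_max = 1e-5) {
  domains[domains$e_value < e_value_max, , drop = FALSE]
}

#' Read a clinical table
#'
#' Expects columns `patient_id`, `histology` (IDBC/ILBC), `stage`,
#' `survival_time` (days, >= 0) and `event` (0/1 or TRUE/FALSE death
#' indicator); an optional `subtype` column is carried through. Stage labels
#' outside I/II/III are resolved through `stage_merge` (by default stage IV
#' is merged into III, following the convention for sparsely populated late
#' stages); any label still unresolved is an error.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param stage_merge Named character vector mapping raw labels to merged
#'   stages.
#' @return A tibble of clinical records.
#' @export
read_clinical_table <- function(path, stage_merge = c(IV = "III")) {
  cl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("patient_id", "histology", "stage", "survival_time", "event")
  missing <- setdiff(required, names(cl))
  if (length(missing)) {
    stop("Clinical table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stage <- as.character(cl$stage)
  hit <- stage %in% names(stage_merge)
  stage[hit] <- unname(stage_merge[stage[hit]])
  bad_stage <- which(!stage %in% stage_levels)
  if (length(bad_stage)) {
    stop("Unknown stage label(s) at row(s) ",
         paste(utils::head(bad_stage, 5), collapse = ", "), ": ",
         paste(unique(cl$stage[bad_stage]), collapse = ", "), call. = FALSE)
  }
  if (any(!cl$histology %in% histology_levels)) {
    stop("Histology must be one of: ",
         paste(histology_levels, collapse = ", "), call. = FALSE)
  }
  time <- as.numeric(cl$survival_time)
  if (anyNA(time) || any(time < 0)) {
    stop("survival_time must be numeric and >= 0.", call. = FALSE)
  }
  event <- cl$event %in% c("1", "TRUE", "true", "T", "yes")
  out <- tibble::tibble(patient_id = cl$patient_id,
                        histology = cl$histology,
                        stage = factor(stage, levels = stage_levels),
                        survival_time = time,
                        event = event)
  if ("subtype" %in% names(cl)) out$subtype <- cl$subtype
  out
}

#' Write a results table as TSV
#'
#' Plain `write_tsv` wrapper so every pipeline output goes through one
#' code path; writing then re-reading reproduces the values exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_results_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Read an aligned-FASTA domain alignment
#'
#' Reads a multiple alignment of domain instances (gapped FASTA). All
#' sequences must have the same gapped length; a ragged alignment is an
#' error.
#'
#' @param path Path to an aligned FASTA file.
#' @return A named character vector of gapped sequences with attribute
#'   `"n_columns"`; names are the sequence IDs.
#' @export
read_domain_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  widths <- Biostrings::width(aln)
  if (length(unique(widths)) > 1L) {
    stop("Ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "),
         " differ.", call. = FALSE)
  }
  seqs <- as.character(aln)
  attr(seqs, "n_columns") <- if (length(widths)) widths[1] else 0L
  seqs
}

#' Ungapped lengths of an alignment's sequences
#'
#' @param alignment Named character vector from [read_domain_alignment()].
#' @return Integer vector of residue counts (gaps `-` and `.` excluded).
#' @export
ungapped_lengths <- function(alignment) {
  vapply(strsplit(unname(alignment), ""),
         function(ch) sum(!ch %in% c("-", ".")), integer(1))
}
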