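#' Build an aligned domain instance
#'
#' Pairs one domain occurrence in a protein with its gapped row in the
#' family multiple alignment, precomputing the map from ungapped residue
#' index to alignment column.
#'
#' @param gene Gene symbol.
#' @param start 1-based protein position of the instance's first residue.
#' @param gapped_seq Gapped sequence string (gaps `-` or `.`).
#' @return An `aligned_instance` list with the strictly increasing column
#'   map.
#' @export
aligned_instance <- function(gene, start, gapped_seq) {
  stopifnot(is.character(gapped_seq), length(gapped_seq) == 1L,
            start >= 1, start == trunc(start))
  chars <- strsplit(gapped_seq, "")[[1]]
  residue <- !chars %in% c("-", ".")
  col_map <- which(residue)
  structure(list(gene = gene, start = as.integer(start),
                 gapped_seq = gapped_seq, col_map = col_map,
                 ungapped_length = length(col_map),
                 n_columns = length(chars)),
            class = "aligned_instance")
}

#' Map a protein position to its alignment column
#'
#' Returns the alignment column holding residue `protein_pos - start + 1`
#' of the instance, or `NA` if the position falls outside the instance.
#' Gap columns are never returned.
#'
#' @param instance An [aligned_instance()].
#' @param protein_pos 1-based protein position.
#' @return Integer alignment column, or `NA_integer_`.
#' @export
map_to_column <- function(instance, protein_pos) {
  stopifnot(inherits(instance, "aligned_instance"), protein_pos >= 1)
  if (is.unsorted(instance$col_map, strictly = TRUE)) {
    stop("Malformed column map: not strictly increasing.", call. = FALSE)
  }
  idx <- protein_pos - instance$start + 1L
  if (idx < 1L || idx > instance$ungapped_length) return(NA_integer_)
  instance$col_map[idx]
}

#' Invert an alignment column back to a protein position
#'
#' @param instance An [aligned_instance()].
#' @param column Alignment column index.
#' @return The protein position whose residue occupies `column`, or `NA`
#'   if `column` is a gap in (or outside) this row.
#' @export
column_to_pos <- function(instance, column) {
  idx <- match(column, instance$col_map)
  if (is.na(idx)) return(NA_integer_)
  instance$start + idx - 1L
}

#' Tally mutations per alignment column across a domain family
#'
#' Projects each candidate mutation through its gene's aligned instance(s)
#' and counts, per alignment column, the mutations and the distinct
#' contributing genes. Mutations that fall outside every instance are
#' conserved in the `unmapped` count, so
#' `sum(counts) + unmapped = candidate mutations`.
#'
#' @param mutations Canonical mutation tibble (pre-filtered to the classes
#'   of interest); only genes present among the instances are candidates.
#' @param instances List of [aligned_instance()] objects.
#' @return List with `columns` (tibble: column, n_mutations, n_genes,
#'   genes), `unmapped`, and `n_candidates`.
#' @export
column_tally <- function(mutations, instances) {
  genes <- vapply(instances, `[[`, character(1), "gene")
  cand <- mutations[mutations$gene %in% genes &
                      !is.na(mutations$protein_pos), , drop = FALSE]
  mapped_col <- rep(NA_integer_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (inst in instances[genes == cand$gene[i]]) {
      col <- map_to_column(inst, cand$protein_pos[i])
      if (!is.na(col)) { mapped_col[i] <- col; break }
    }
  }
  ok <- !is.na(mapped_col)
  cols <- tibble::tibble(column = mapped_col[ok], gene = cand$gene[ok]) |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(n_mutations = dplyr::n(),
                     n_genes = dplyr::n_distinct(.data$gene),
                     genes = paste(sort(unique(.data$gene)),
                                   collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$column)
  list(columns = cols, unmapped = sum(!ok), n_candidates = nrow(cand))
}

#' Per-column binomial recurrence test (optional extension)
#'
#' Tests each column's mutation count against a uniform expectation over
#' the alignment's non-gap columns. This goes beyond the plain positional
#' tally and is provided as a labelled extension, not part of the default
#' screen.
#'
#' @param tally Result of [column_tally()].
#' @param n_columns Total alignment columns.
#' @return The `columns` tibble with `p_uniform` added.
#' @export
column_uniform_test <- function(tally, n_columns) {
  total <- sum(tally$columns$n_mutations)
  tally$columns$p_uniform <- stats::pbinom(
    tally$columns$n_mutations - 1, total, 1 / n_columns,
    lower.tail = FALSE)
  tally$columns
}
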