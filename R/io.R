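#' Read a samples-by-metabolites peak-area CSV
#'
#' Expected layout: header row of metabolite ids, first column `sample_id`,
#' one row per sample. Empty cells are missing values (never zero). Values
#' must be non-negative; duplicate ids or negative entries raise an error
#' naming the offending row/column.
#'
#' @param path CSV file path.
#' @return wide peak-area tibble.
#' @export
read_peak_matrix <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE, name_repair = "minimal")
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed peak-area CSV `%s`: %s (row %d, col %d).",
                  path, probs$expected[1], probs$row[1], probs$col[1]))
  }
  assert_peak_tbl(x)
  m <- pa_matrix(x)
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("Negative peak area at sample `%s`, metabolite `%s`.",
                  rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  }
  x
}

#' @rdname read_peak_matrix
#' @param matrix wide peak-area tibble.
#' @export
write_peak_matrix <- function(matrix, path) {
  assert_peak_tbl(matrix)
  readr::write_csv(matrix, path, na = "")
  invisible(path)
}

#' Read / write the sample annotation table
#'
#' Columns: `sample_id`, `subject_id`, `age_group`, `intervention`,
#' `timepoint` (character, `"RO"` or hours), `batch`.
#'
#' @param path CSV file path.
#' @export
read_sample_annotation <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @rdname read_sample_annotation
#' @param samples sample annotation tibble.
#' @export
write_sample_annotation <- function(samples, path) {
  readr::write_csv(samples, path, na = "")
  invisible(path)
}

#' Read / write the metabolite annotation table
#'
#' Columns: `metabolite_id`, `display_name`, `superfamily`, `kegg_id`,
#' `hmdb_id`; a metabolite counts as annotated iff it carries a KEGG or HMDB
#' identifier.
#'
#' @param path CSV file path.
#' @export
read_metabolite_annotation <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @rdname read_metabolite_annotation
#' @param annotation metabolite annotation tibble.
#' @export
write_metabolite_annotation <- function(annotation, path) {
  readr::write_csv(annotation, path, na = "")
  invisible(path)
}

#' Read / write a pathway library in GMT format
#'
#' One pathway per line: `pathway_id<TAB>description<TAB>member1<TAB>...`.
#'
#' @param path GMT file path.
#' @return tibble with `pathway_id`, `description`, and list-column `members`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1]))
  }
  tibble(
    pathway_id = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(x) x[-(1:2)]))
}

#' @rdname read_gmt
#' @param pathways pathway tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$description[i],
            pathways$members[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Restrict a peak-area table to annotated metabolites
#'
#' Keeps exactly the metabolites with a KEGG or HMDB identifier (column order
#' preserved), the role played by the 566-of-834 annotated subset in a typical
#' commercial panel.
#'
#' @param matrix wide peak-area tibble.
#' @param annotation metabolite annotation tibble covering every matrix
#'   metabolite.
#' @return filtered peak-area tibble.
#' @export
filter_annotated <- function(matrix, annotation) {
  assert_peak_tbl(matrix)
  ids <- metabolite_ids(matrix)
  missing <- setdiff(ids, annotation$metabolite_id)
  if (length(missing)) {
    abort(sprintf("Metabolites missing from annotation: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  ann <- annotation[match(ids, annotation$metabolite_id), ]
  has_id <- function(v) !is.na(v) & nzchar(v)
  keep <- has_id(ann$kegg_id) | has_id(ann$hmdb_id)
  if (!any(keep)) warn("No annotated metabolites; returning an empty matrix.")
  out <- matrix[, c(TRUE, keep), drop = FALSE]
  add_provenance(out, sprintf("filter_annotated: %d -> %d metabolites",
                              length(ids), sum(keep)))
}
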