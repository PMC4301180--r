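#' Write a simulated experiment to TSV files
#'
#' Writes `matrix.tsv` (gene_id + one column per sample, linear
#' intensities), `design.tsv` (sample_id, time_point_h, replicate),
#' `annotation.tsv` (gene_id, tap_family, orphan 0/1, process_class,
#' go_terms semicolon-separated), `truth.tsv` and `effects.tsv`.
#'
#' @param sim a `cryomoss_sim` object.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(sim$expr, file.path(dir, "matrix.tsv"))
  readr::write_tsv(rename(sim$design, time_point_h = "time_point"),
                   file.path(dir, "design.tsv"))
  readr::write_tsv(mutate(sim$annotation, orphan = as.integer(.data$orphan)),
                   file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$effects, file.path(dir, "effects.tsv"))
  invisible(dir)
}

#' Read an expression matrix TSV
#'
#' @param path TSV with a `gene_id` column and one numeric column per sample.
#' @return wide expression tibble.
#' @export
read_expression_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(out)) abort("matrix file must have a `gene_id` column.")
  out
}

#' Read a sample design TSV
#'
#' @param path TSV with columns `sample_id`, `time_point_h` (or
#'   `time_point`) and `replicate`.
#' @return design tibble with columns `sample_id`, `time_point`, `replicate`.
#' @export
read_design <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if ("time_point_h" %in% names(out)) {
    out <- rename(out, time_point = "time_point_h")
  }
  check_design(out)
  out
}

#' Read a gene annotation TSV
#'
#' @param path TSV with columns `gene_id`, `tap_family`, `orphan` (0/1 or
#'   logical) and optionally `process_class`, `go_terms`.
#' @return annotation tibble with logical `orphan`.
#' @export
read_annotation <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "orphan") %in% names(out))) {
    abort("annotation file needs `gene_id` and `orphan` columns.")
  }
  mutate(out, orphan = as.logical(as.integer(.data$orphan)))
}

#' Write a DEG table to TSV
#'
#' One row per gene with the ANOVA block (`gene_id`, `f`, `p`, `p_bh`)
#' followed by one block per time-point pair (`tukey_p`, `tukey_p_bonf`,
#' `fold_change`, `direction`).
#'
#' @param deg a `cryomoss_deg` result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  wide <- deg$pairs |>
    mutate(pair = gsub("[ /]+", "_", .data$pair)) |>
    select("gene_id", "pair", "tukey_p", "tukey_p_bonf", "fold_change",
           "direction") |>
    tidyr::pivot_wider(names_from = "pair",
                       values_from = c("tukey_p", "tukey_p_bonf",
                                       "fold_change", "direction"),
                       names_vary = "slowest")
  out <- left_join(deg$genes, wide, by = "gene_id") |> select(-"gate")
  readr::write_tsv(out, path)
  invisible(path)
}
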