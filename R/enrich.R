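#' Fisher's-exact term over/under-representation
#'
#' For every annotation term present in the universe, builds the 2x2 table
#' (in-set with term, in-set without, out-of-set with, out-of-set without),
#' computes two-sided and one-tailed exact p-values via [fisher_2x2()], and
#' applies Benjamini-Hochberg correction across terms. Significant terms are
#' labelled over- or under-represented by their smaller one-tail.
#'
#' @param genes character vector, the gene set of interest (must be contained
#'   in `universe`).
#' @param universe character vector of all genes considered.
#' @param annotation long mapping tibble with columns `gene_id`, `term`
#'   (one row per association); genes with no terms are allowed.
#' @param alpha BH significance threshold used for the direction label.
#' @return tibble sorted by `p_bh`: `term`, `a`, `b`, `c`, `d`,
#'   `p_two_sided`, `p_over`, `p_under`, `p_bh`, `direction`.
#' @export
enrich_terms <- function(genes, universe, annotation, alpha = 0.05) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (length(setdiff(genes, universe))) {
    abort("`genes` must be a subset of `universe`.")
  }
  if (!all(c("gene_id", "term") %in% names(annotation))) {
    abort("`annotation` needs columns `gene_id` and `term`.")
  }
  ann <- annotation |>
    filter(.data$gene_id %in% universe) |>
    distinct(.data$gene_id, .data$term)
  n_set <- length(genes)
  n_uni <- length(universe)
  counts <- ann |>
    group_by(.data$term) |>
    summarise(a = sum(.data$gene_id %in% genes), m = dplyr::n(),
              .groups = "drop") |>
    mutate(b = n_set - .data$a, c = .data$m - .data$a,
           d = n_uni - n_set - .data$c)
  if (nrow(counts) == 0) {
    return(tibble(term = character(), a = integer(), b = integer(),
                  c = integer(), d = integer(), p_two_sided = numeric(),
                  p_over = numeric(), p_under = numeric(), p_bh = numeric(),
                  direction = character()))
  }
  ps <- pmap(list(counts$a, counts$b, counts$c, counts$d), fisher_2x2) |>
    list_rbind()
  counts |>
    select(-"m") |>
    dplyr::bind_cols(ps) |>
    mutate(p_bh = bh_adjust(.data$p_two_sided),
           direction = dplyr::case_when(
             .data$p_bh >= alpha ~ "none",
             .data$p_over <= .data$p_under ~ "over",
             TRUE ~ "under")) |>
    arrange(.data$p_bh, .data$p_two_sided)
}

#' Partition the time course into response stages
#'
#' Assigns every non-control time point to a response stage (early,
#' intermediate, late by default) and collects, per stage, the union of
#' genes called DEG in the control-versus-t comparison for any member time
#' point. Stage gene sets may overlap: a gene significant at 3 h and 24 h
#' belongs to both the early and late sets.
#'
#' @param deg a `cryomoss_deg` result.
#' @param stage_map named character vector mapping every non-control time
#'   point (as `"1"`, `"3"`, ...) to a stage label.
#' @param control control time-point label; defaults to the result's.
#' @return object of class `stage_partition`: tibble `stage`, `time_point`,
#'   `gene_id`, `direction` (relative to the control), one row per
#'   (stage-member time point, DEG).
#' @export
partition_stages <- function(deg,
                             stage_map = c(`1` = "early", `3` = "early",
                                           `8` = "intermediate", `24` = "late"),
                             control = deg$control) {
  later <- setdiff(deg$time_points, control)
  miss <- setdiff(as.character(later), names(stage_map))
  if (length(miss)) {
    abort(paste0("stage map does not cover time point(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- deg$pairs |>
    filter(.data$t_earlier == control, .data$deg) |>
    mutate(stage = unname(stage_map[as.character(.data$t_later)])) |>
    select("stage", time_point = "t_later", "gene_id", "direction") |>
    arrange(.data$time_point, .data$gene_id)
  structure(out, class = c("stage_partition", class(out)))
}

#' Genes per stage from a stage partition
#'
#' @param partition a [partition_stages()] result.
#' @return tibble `stage`, `gene_id`, `induced`, `repressed` with one row per
#'   distinct (stage, gene): `induced`/`repressed` flag whether the gene is
#'   induced/repressed at any member time point of the stage.
#' @export
stage_gene_sets <- function(partition) {
  partition |>
    as_tibble() |>
    group_by(.data$stage, .data$gene_id) |>
    summarise(induced = any(.data$direction == "induced"),
              repressed = any(.data$direction == "repressed"),
              .groups = "drop")
}
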