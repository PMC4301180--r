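#' Orphan-gene fraction of a gene set
#'
#' Counts orphan (species-specific) genes in a set and reports the
#' percentage, rounded half away from zero to the requested precision.
#'
#' @param genes character vector of gene ids (may be empty).
#' @param annotation tibble with `gene_id` and logical `orphan`; must cover
#'   the set.
#' @param digits decimal places of the reported percentage (default 0,
#'   whole-percent convention for count-derived percentages).
#' @return one-row tibble `n_orphan`, `n_total`, `percent`; an empty set
#'   yields zero counts and `NA` percent.
#' @export
#' @examples
#' ann <- tibble::tibble(gene_id = paste0("g", 1:44),
#'                       orphan = c(rep(TRUE, 9), rep(FALSE, 35)))
#' orphan_fraction(ann$gene_id, ann)  # 9/44 -> 20%
orphan_fraction <- function(genes, annotation, digits = 0) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    return(tibble(n_orphan = 0L, n_total = 0L, percent = NA_real_))
  }
  miss <- setdiff(genes, annotation$gene_id)
  if (length(miss)) {
    abort(paste0("annotation does not cover gene(s): ",
                 paste(utils::head(miss, 3), collapse = ", ")))
  }
  orphan <- annotation$orphan[match(genes, annotation$gene_id)]
  tibble(n_orphan = sum(orphan), n_total = length(genes),
         percent = round_half_up(100 * sum(orphan) / length(genes), digits))
}

# assign every DEG to its earliest significant control comparison
earliest_deg_assignment <- function(deg, control = deg$control) {
  deg$pairs |>
    filter(.data$t_earlier == control, .data$deg) |>
    group_by(.data$gene_id) |>
    summarise(first_time_point = min(.data$t_later),
              direction = .data$direction[which.min(.data$t_later)],
              .groups = "drop")
}

#' Test orphan enrichment in the early response
#'
#' Each DEG is assigned to its earliest significant control comparison so
#' that the early and later sets are disjoint; the early set (1 and 3 h by
#' default) is then tested for a higher orphan proportion than the
#' intermediate-plus-late set with a one-sided Fisher's exact test
#' (identical to [fisher_2x2()] on the same table).
#'
#' @param deg a `cryomoss_deg` result.
#' @param annotation tibble with `gene_id` and logical `orphan`.
#' @param early_time_points time points counted as the early response.
#' @param control control time-point label.
#' @return one-row tibble: per-set orphan and total counts, the 2x2 cell
#'   counts `a`/`b`/`c`/`d` (orphan-and-early, non-orphan-and-early,
#'   orphan-and-later, non-orphan-and-later) and the one-sided `p_value`.
#' @export
orphan_stage_test <- function(deg, annotation, early_time_points = c(1, 3),
                              control = deg$control) {
  assign <- earliest_deg_assignment(deg, control)
  if (nrow(assign) == 0) abort("no DEGs to test.")
  miss <- setdiff(assign$gene_id, annotation$gene_id)
  if (length(miss)) abort("annotation does not cover all DEGs.")
  orphan <- annotation$orphan[match(assign$gene_id, annotation$gene_id)]
  early <- assign$first_time_point %in% early_time_points
  a <- sum(orphan & early); b <- sum(!orphan & early)
  cc <- sum(orphan & !early); d <- sum(!orphan & !early)
  p <- fisher_2x2(a, b, cc, d)
  tibble(n_early = a + b, n_early_orphan = a,
         n_later = cc + d, n_later_orphan = cc,
         a = a, b = b, c = cc, d = d,
         p_value = p$p_over)
}

#' Test orphan composition of induced versus repressed DEGs
#'
#' Compares the orphan proportion between induced and repressed DEGs with a
#' two-sided Fisher's exact test. By default a gene's direction is taken at
#' its earliest significant control comparison; restrict to a single
#' comparison with `time_point`.
#'
#' @param deg a `cryomoss_deg` result.
#' @param annotation tibble with `gene_id` and logical `orphan`.
#' @param time_point optional single time point: use the control-vs-t DEG
#'   calls only.
#' @param control control time-point label.
#' @return one-row tibble with the 2x2 counts (orphan-and-induced,
#'   non-orphan-and-induced, orphan-and-repressed, non-orphan-and-repressed)
#'   and the two-sided `p_value`.
#' @export
orphan_direction_test <- function(deg, annotation, time_point = NULL,
                                  control = deg$control) {
  if (is.null(time_point)) {
    assign <- earliest_deg_assignment(deg, control)
  } else {
    assign <- deg$pairs |>
      filter(.data$t_earlier == control, .data$t_later == time_point,
             .data$deg) |>
      select("gene_id", "direction")
  }
  if (nrow(assign) == 0) abort("no DEGs to test.")
  miss <- setdiff(assign$gene_id, annotation$gene_id)
  if (length(miss)) abort("annotation does not cover all DEGs.")
  orphan <- annotation$orphan[match(assign$gene_id, annotation$gene_id)]
  induced <- assign$direction == "induced"
  a <- sum(orphan & induced); b <- sum(!orphan & induced)
  cc <- sum(orphan & !induced); d <- sum(!orphan & !induced)
  p <- fisher_2x2(a, b, cc, d)
  tibble(n_induced = a + b, n_induced_orphan = a,
         n_repressed = cc + d, n_repressed_orphan = cc,
         a = a, b = b, c = cc, d = d,
         p_value = p$p_two_sided)
}

#' Per-time-point orphan summary of the DEG sets
#'
#' For every control-versus-t comparison: DEG, induced and repressed counts
#' with their orphan sub-counts and whole-percent orphan fractions, plus one
#' row for the persistently induced/repressed genes.
#'
#' @param deg a `cryomoss_deg` result.
#' @param annotation tibble with `gene_id` and logical `orphan`.
#' @param control control time-point label.
#' @return tibble with one row per time point (and a `persistent` row):
#'   counts and orphan percentages.
#' @export
orphan_summary <- function(deg, annotation, control = deg$control) {
  ctrl <- deg$pairs |> filter(.data$t_earlier == control, .data$deg)
  per_tp <- ctrl |>
    group_by(.data$t_later) |>
    summarise(
      n_deg = dplyr::n(),
      n_orphan = orphan_fraction(.data$gene_id, annotation)$n_orphan,
      pct_orphan = orphan_fraction(.data$gene_id, annotation)$percent,
      n_induced = sum(.data$direction == "induced"),
      n_induced_orphan =
        orphan_fraction(.data$gene_id[.data$direction == "induced"],
                        annotation)$n_orphan,
      pct_induced_orphan =
        orphan_fraction(.data$gene_id[.data$direction == "induced"],
                        annotation)$percent,
      n_repressed = sum(.data$direction == "repressed"),
      n_repressed_orphan =
        orphan_fraction(.data$gene_id[.data$direction == "repressed"],
                        annotation)$n_orphan,
      pct_repressed_orphan =
        orphan_fraction(.data$gene_id[.data$direction == "repressed"],
                        annotation)$percent,
      .groups = "drop") |>
    mutate(set = sprintf("0 h vs %g h", .data$t_later), .before = 1) |>
    select(-"t_later")
  pers <- classify_persistence(deg, control)
  pg <- pers$gene_id[pers$persistent_induced | pers$persistent_repressed]
  of <- orphan_fraction(pg, annotation, digits = 2)
  bind_rows(per_tp,
            tibble(set = "persistent", n_deg = of$n_total,
                   n_orphan = of$n_orphan, pct_orphan = of$percent))
}
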