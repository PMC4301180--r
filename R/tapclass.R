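#' Combine per-species TAP tables with GO process classes
#'
#' Pools the TAP-family membership tables of two species and derives every
#' gene's process class from its GO annotations: `developmental`
#' (developmental process, GO:0032502), `stimulus_stress` (response to
#' stimulus GO:0050896 or response to stress GO:0006950), `both` when
#' annotated to both sides, or `none` when unannotated. Unannotated genes
#' stay in the table (they count toward family totals but not class
#' tabulations).
#'
#' @param tap_a,tap_b per-species tibbles `gene_id`, `species`, `tap_family`.
#' @param classes tibble `gene_id`, `class` with `class` one of
#'   `developmental`, `stimulus`, `stress` (one row per annotation).
#' @return pooled tibble `gene_id`, `species`, `tap_family`, `process_class`.
#' @export
combine_tap_annotations <- function(tap_a, tap_b, classes) {
  pooled <- bind_rows(tap_a, tap_b)
  need <- c("gene_id", "species", "tap_family")
  miss <- setdiff(need, names(pooled))
  if (length(miss)) abort(paste0("TAP tables need columns: ", paste(miss, collapse = ", ")))
  dup <- pooled |>
    distinct(.data$species, .data$gene_id, .data$tap_family) |>
    dplyr::count(.data$species, .data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("gene(s) assigned to more than one family: ",
                 paste(utils::head(dup$gene_id, 3), collapse = ", ")))
  }
  if (!all(c("gene_id", "class") %in% names(classes))) {
    abort("`classes` needs columns `gene_id` and `class`.")
  }
  bad <- setdiff(unique(classes$class), c("developmental", "stimulus", "stress"))
  if (length(bad)) {
    abort(paste0("unknown process class value(s): ", paste(bad, collapse = ", ")))
  }
  side <- classes |>
    group_by(.data$gene_id) |>
    summarise(has_dev = any(.data$class == "developmental"),
              has_stim = any(.data$class %in% c("stimulus", "stress")),
              .groups = "drop")
  pooled |>
    distinct(.data$gene_id, .data$species, .data$tap_family) |>
    left_join(side, by = "gene_id") |>
    mutate(process_class = dplyr::case_when(
      is.na(.data$has_dev) ~ "none",
      .data$has_dev & .data$has_stim ~ "both",
      .data$has_dev ~ "developmental",
      .data$has_stim ~ "stimulus_stress",
      TRUE ~ "none")) |>
    select("gene_id", "species", "tap_family", "process_class")
}

# per family x candidate class one-sided Fisher enrichment against all other
# TAP-annotated genes; 'both' genes count toward each side's class total
tap_family_tests <- function(pooled) {
  fam <- pooled |>
    group_by(.data$tap_family) |>
    summarise(
      n_total = dplyr::n(),
      n_annotated = sum(.data$process_class != "none"),
      n_developmental = sum(.data$process_class %in% c("developmental", "both")),
      n_stimulus_stress = sum(.data$process_class %in% c("stimulus_stress", "both")),
      n_both = sum(.data$process_class == "both"),
      .groups = "drop")
  tot_ann <- sum(fam$n_annotated)
  tot_dev <- sum(fam$n_developmental)
  tot_stim <- sum(fam$n_stimulus_stress)
  tests <- bind_rows(
    fam |> mutate(class = "developmental", a = .data$n_developmental,
                  side_total = tot_dev),
    fam |> mutate(class = "stimulus_stress", a = .data$n_stimulus_stress,
                  side_total = tot_stim)) |>
    mutate(b = .data$n_annotated - .data$a,
           c = .data$side_total - .data$a,
           d = (tot_ann - .data$n_annotated) - .data$c)
  tests$p <- map_dbl(seq_len(nrow(tests)), function(i) {
    fisher_2x2(tests$a[i], tests$b[i], tests$c[i], tests$d[i])$p_over
  })
  list(families = fam, tests = tests)
}

#' Classify TAP families by process specialization
#'
#' For every TAP family and each candidate process class (developmental,
#' stimulus/stress), tests enrichment of the class among the family's
#' annotated members against all other TAP-annotated genes with a one-sided
#' Fisher's exact test; Benjamini-Hochberg correction is applied once across
#' all family x class tests of the run. Each family is then assigned:
#' \itemize{
#'   \item quality class 1 - the class with the smallest BH-adjusted p when
#'     that adjusted p is below `alpha`;
#'   \item quality class 2 - the class with the smallest raw p when only the
#'     raw p is below `alpha`;
#'   \item quality class 3 - otherwise, the class with the maximal number of
#'     annotated members; a tie (or a family with no annotated members)
#'     yields the `unspecialized` flag.
#' }
#'
#' @param pooled pooled gene table from [combine_tap_annotations()] (or the
#'   simulator's annotation restricted to TAP genes, with columns
#'   `gene_id`, `tap_family`, `process_class`).
#' @param alpha significance level for both quality gates.
#' @return a `tap_classification` tibble: per family the member counts,
#'   `assigned_class`, `quality_class`, `p`, `p_bh` (of the assigned class)
#'   and the `flag` (`developmental`, `stimulus_stress`, `unspecialized`).
#' @export
#' @examples
#' tabs <- simulate_tap_tables(n_stress = 5, n_dev = 3, n_neutral = 1,
#'                             family_size = 12, seed = 2)
#' pooled <- combine_tap_annotations(tabs$tap[tabs$tap$species == "Ppatens", ],
#'                                   tabs$tap[tabs$tap$species != "Ppatens", ],
#'                                   tabs$classes)
#' classify_tap_families(pooled)
classify_tap_families <- function(pooled, alpha = 0.05) {
  pooled <- pooled |> filter(!is.na(.data$tap_family))
  if (length(unique(pooled$tap_family)) < 2) {
    abort("need at least 2 TAP families to classify.")
  }
  res <- tap_family_tests(pooled)
  tests <- res$tests |> mutate(p_bh = bh_adjust(.data$p))

  one_family <- function(sub) {
    counts <- setNames(c(sub$n_developmental[1], sub$n_stimulus_stress[1]),
                       c("developmental", "stimulus_stress"))
    counts <- counts[match(sub$class, names(counts))]
    if (any(sub$p_bh < alpha)) {
      i <- order(sub$p_bh, sub$p, -counts)[1]
      quality <- 1L
    } else if (any(sub$p < alpha)) {
      i <- order(sub$p, -counts)[1]
      quality <- 2L
    } else {
      quality <- 3L
      if (sub$n_annotated[1] == 0 || counts[1] == counts[2]) {
        return(tibble(assigned_class = NA_character_, quality_class = quality,
                      p = NA_real_, p_bh = NA_real_, flag = "unspecialized"))
      }
      i <- which.max(counts)
    }
    tibble(assigned_class = sub$class[i], quality_class = quality,
           p = sub$p[i], p_bh = sub$p_bh[i], flag = sub$class[i])
  }
  assigned <- tests |>
    arrange(.data$tap_family, .data$class) |>
    group_by(.data$tap_family) |>
    dplyr::group_modify(~ one_family(.x)) |>
    ungroup()
  out <- res$families |>
    left_join(assigned, by = "tap_family") |>
    arrange(.data$tap_family)
  structure(out, class = c("tap_classification", class(out)), alpha = alpha)
}

#' Classify a single TAP family against the remaining TAP complement
#'
#' Convenience wrapper around [classify_tap_families()] returning the row of
#' one family; the BH correction still spans all family x class tests of the
#' pooled table.
#'
#' @param pooled pooled gene table (see [classify_tap_families()]).
#' @param family family id to report; must be present and non-empty.
#' @param alpha significance level.
#' @return one-row `tap_classification` tibble.
#' @export
classify_family <- function(pooled, family, alpha = 0.05) {
  if (!family %in% pooled$tap_family) {
    abort(sprintf("family `%s` is empty or absent from the pooled table.", family))
  }
  out <- classify_tap_families(pooled, alpha = alpha)
  out[out$tap_family == family, ]
}

#' @exportS3Method generics::glance
glance.tap_classification <- function(x, ...) {
  tibble(n_families = nrow(x),
         n_stimulus_stress = sum(x$flag == "stimulus_stress"),
         n_developmental = sum(x$flag == "developmental"),
         n_unspecialized = sum(x$flag == "unspecialized"),
         n_quality1 = sum(x$quality_class == 1),
         n_quality2 = sum(x$quality_class == 2),
         n_quality3 = sum(x$quality_class == 3),
         alpha = attr(x, "alpha"))
}

#' @exportS3Method generics::tidy
tidy.tap_classification <- function(x, ...) as_tibble(x)

#' @exportS3Method ggplot2::autoplot
autoplot.tap_classification <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(quality = factor(.data$quality_class))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$flag, fill = .data$quality)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "process specialization", y = "TAP families",
                  fill = "quality class",
                  title = "TAP family process specialization") +
    ggplot2::theme_minimal()
}
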