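#' Default stage profile for the cold time course
#'
#' One row per sampled stress time point (hours of cold), giving the fraction
#' of differentially expressed genes that first respond at that time point,
#' the log2 effect-size distribution of those genes, and the response stage
#' the time point belongs to. Fractions must sum to 1. The defaults mirror
#' the observed accumulation of cold DEGs over a 1/3/8/24 h course: few
#' early responders, the bulk arriving at 8 and 24 h, with later responders
#' carrying somewhat larger effects.
#'
#' @param time_points stress time points in hours (control excluded).
#' @param fraction fraction of DE genes first responding at each time point.
#' @param effect_mean,effect_sd mean and sd of the absolute log2 effect drawn
#'   for genes first responding at each time point.
#' @param stage response-stage label of each time point.
#' @return a tibble with columns `time_point`, `fraction`, `effect_mean`,
#'   `effect_sd`, `stage`.
#' @export
stage_profile <- function(time_points = c(1, 3, 8, 24),
                          fraction = c(0.03, 0.07, 0.45, 0.45),
                          effect_mean = c(1.2, 1.2, 1.5, 1.8),
                          effect_sd = c(0.5, 0.5, 0.5, 0.5),
                          stage = c("early", "early", "intermediate", "late")) {
  tibble(time_point = time_points, fraction = fraction,
         effect_mean = effect_mean, effect_sd = effect_sd, stage = stage)
}

default_tap_family_sizes <- function(n = 40) {
  pmax(2L, as.integer(round(27 * exp(-0.12 * seq(0, n - 1)))))
}

# family-size spectrum scaled to the genome size: the canonical decaying
# spectrum (largest family 27 members) at >= 5000 genes, shrunk below that
# so TAP genes stay a small fraction of the array
scaled_tap_family_sizes <- function(n_genes, orphan_fraction) {
  base <- default_tap_family_sizes(40)
  sizes <- pmax(1L, as.integer(round(base * min(1, n_genes / 5000))))
  cap <- floor(0.25 * n_genes * (1 - orphan_fraction))
  while (length(sizes) > 2 && sum(sizes) > cap) {
    sizes <- sizes[-length(sizes)]
  }
  if (sum(sizes) > cap) sizes <- integer(0)
  sizes
}

#' Configuration for the synthetic cold time-course generator
#'
#' Parameterizes a genes x samples intensity matrix with the structure the
#' downstream pipeline assumes: log-normal intensities (baseline + planted
#' effect + replicate noise on log2 scale, then exponentiated), a 5 time
#' point x 3 replicate design by default, planted step-function effects with
#' stage-dependent onset, TAP families with process-class-biased GO labels,
#' and an orphan fraction optionally enriched among early responders.
#'
#' @param n_genes number of genes on the simulated array.
#' @param time_points sampled time points in hours; the first is the control.
#' @param n_replicates biological replicates per time point (>= 2).
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline log2
#'   intensity distribution.
#' @param noise_log2_sd replicate noise sd on the log2 scale.
#' @param de_fraction fraction of genes carrying a planted effect.
#' @param profile stage profile tibble, see [stage_profile()]; its
#'   `time_point` set must equal the non-control time points and its
#'   `fraction` column must sum to 1.
#' @param induced_fraction probability a planted effect is positive
#'   (induction) rather than negative.
#' @param min_log2_effect floor on the absolute planted log2 effect.
#' @param transient_fraction fraction of DE genes whose effect is present
#'   only at the first responding time point instead of persisting.
#' @param tap_family_sizes integer vector of TAP family sizes; by default a
#'   decaying spectrum (largest family 27 members, as the dominant AP2/EREBP
#'   family) scaled down for small gene universes.
#' @param class_bias probability a TAP family member carries exactly its
#'   family's process-class label; the remainder is split evenly between the
#'   opposite class, both classes, and no class annotation.
#' @param stress_family_fraction fraction of TAP families whose planted
#'   process class is stimulus/stress (the rest are developmental).
#' @param n_go_terms size of the generic GO-term pool.
#' @param go_terms_per_gene generic GO terms drawn per gene.
#' @param orphan_fraction overall fraction of orphan (species-specific) genes.
#' @param orphan_early_enrichment multiplicative enrichment of the orphan
#'   rate among genes whose planted first response is at an early time point;
#'   the rate of the remaining genes is renormalized so the marginal orphan
#'   fraction stays at `orphan_fraction` (rates are capped at \[0, 1\]).
#' @param class_direction optional named vector giving, per TAP family
#'   process class, the probability that a planted effect on a member gene
#'   is an induction. The default emulates the antagonistic regulatory
#'   pattern of the cold response: stimulus/stress regulators accumulate,
#'   developmental regulators decline. `NULL` leaves TAP genes at the global
#'   `induced_fraction`.
#' @param seed default seed used by [simulate_experiment()].
#' @return an object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' sim <- simulate_experiment(cfg)
#' dim(sim$expr)
sim_config <- function(n_genes = 10000,
                       time_points = c(0, 1, 3, 8, 24),
                       n_replicates = 3,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.25,
                       de_fraction = 0.10,
                       profile = stage_profile(time_points[-1]),
                       induced_fraction = 0.6,
                       min_log2_effect = 0.25,
                       transient_fraction = 0,
                       tap_family_sizes = NULL,
                       class_bias = 0.8,
                       stress_family_fraction = 0.6,
                       n_go_terms = 150,
                       go_terms_per_gene = 3,
                       orphan_fraction = 0.12,
                       orphan_early_enrichment = 2,
                       class_direction = c(stimulus_stress = 0.9,
                                           developmental = 0.2),
                       seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  if (length(time_points) < 2) abort("need at least two time points (control + one).")
  if (anyDuplicated(time_points)) abort("`time_points` must be distinct.")
  check_fraction(de_fraction, "de_fraction")
  check_fraction(induced_fraction, "induced_fraction")
  check_fraction(transient_fraction, "transient_fraction")
  check_fraction(class_bias, "class_bias")
  check_fraction(stress_family_fraction, "stress_family_fraction")
  check_fraction(orphan_fraction, "orphan_fraction")
  if (orphan_early_enrichment < 0) abort("`orphan_early_enrichment` must be >= 0.")
  if (noise_log2_sd < 0) abort("`noise_log2_sd` must be >= 0.")
  if (!setequal(profile$time_point, time_points[-1])) {
    abort("`profile$time_point` must cover exactly the non-control time points.")
  }
  check_probabilities(profile$fraction, "profile$fraction")
  if (abs(sum(profile$fraction) - 1) > 1e-8) {
    abort("`profile$fraction` must sum to 1 over stages.")
  }
  if (is.null(tap_family_sizes)) {
    tap_family_sizes <- scaled_tap_family_sizes(n_genes, orphan_fraction)
  }
  if (any(tap_family_sizes < 1)) abort("`tap_family_sizes` must be positive.")
  if (!is.null(class_direction)) {
    check_probabilities(unname(class_direction), "class_direction")
    bad <- setdiff(names(class_direction),
                   c("stimulus_stress", "developmental"))
    if (length(bad)) {
      abort(paste0("unknown class_direction name(s): ", paste(bad, collapse = ", ")))
    }
  }

  structure(
    list(n_genes = n_genes, time_points = time_points,
         n_replicates = n_replicates,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         noise_log2_sd = noise_log2_sd, de_fraction = de_fraction,
         profile = profile, induced_fraction = induced_fraction,
         min_log2_effect = min_log2_effect,
         transient_fraction = transient_fraction,
         tap_family_sizes = as.integer(tap_family_sizes),
         class_bias = class_bias,
         stress_family_fraction = stress_family_fraction,
         n_go_terms = check_count(n_go_terms, "n_go_terms"),
         go_terms_per_gene = check_count(go_terms_per_gene, "go_terms_per_gene", 0L),
         orphan_fraction = orphan_fraction,
         orphan_early_enrichment = orphan_early_enrichment,
         class_direction = class_direction,
         seed = seed),
    class = "sim_config")
}

#' Simulate a cold time-course expression experiment
#'
#' Draws per-gene baseline log2 intensities, plants step-function log2
#' effects on the genes and time points dictated by the stage profile, adds
#' replicate noise, exponentiates to the linear intensity scale, and draws
#' TAP-family / GO / orphan annotations. Identical `config` and `seed` give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `cryomoss_sim`: a list with
#' \describe{
#'   \item{expr}{tibble, `gene_id` plus one linear-intensity column per sample.}
#'   \item{design}{tibble `sample_id`, `time_point`, `replicate`.}
#'   \item{annotation}{tibble `gene_id`, `tap_family`, `orphan`,
#'     `process_class`, `go_terms` (semicolon separated).}
#'   \item{truth}{tibble of planted effects per gene: `de`, `first_time_point`,
#'     `stage`, `direction`, `log2_effect`, `transient`, plus the annotation
#'     flags.}
#'   \item{effects}{long tibble `gene_id`, `time_point`, `log2_effect` of
#'     every planted (gene, time point) effect.}
#' }
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  if (is.null(seed)) abort("a `seed` is required (in the config or as argument).")
  withr::with_seed(as.integer(seed), {
    n <- config$n_genes
    gene_ids <- sprintf("gene%05d", seq_len(n))
    tps <- config$time_points

    design <- tidyr::expand_grid(time_point = tps,
                                 replicate = seq_len(config$n_replicates)) |>
      mutate(sample_id = sprintf("t%g_r%d", .data$time_point, .data$replicate)) |>
      select("sample_id", "time_point", "replicate")

    baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

    # planted effects: choose DE genes, first-responding time point, effect
    n_de <- round(config$de_fraction * n)
    de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
    prof <- config$profile[order(config$profile$time_point), ]
    truth <- tibble(gene_id = gene_ids, de = FALSE,
                    first_time_point = NA_real_, stage = NA_character_,
                    direction = NA_character_, log2_effect = NA_real_,
                    transient = NA)
    if (n_de > 0) {
      first_tp <- sample(prof$time_point, n_de, replace = TRUE, prob = prof$fraction)
      row <- match(first_tp, prof$time_point)
      mag <- pmax(rnorm(n_de, prof$effect_mean[row], prof$effect_sd[row]),
                  config$min_log2_effect)
      sgn <- ifelse(stats::runif(n_de) < config$induced_fraction, 1, -1)
      transient <- stats::runif(n_de) < config$transient_fraction
      truth$de[de_idx] <- TRUE
      truth$first_time_point[de_idx] <- first_tp
      truth$stage[de_idx] <- prof$stage[row]
      truth$direction[de_idx] <- ifelse(sgn > 0, "induced", "repressed")
      truth$log2_effect[de_idx] <- sgn * mag
      truth$transient[de_idx] <- transient
    }
    annotation <- assign_annotations(config, gene_ids, truth)
    families <- attr(annotation, "families")
    attr(annotation, "families") <- NULL

    # tie planted-effect direction to the TAP family's process class
    if (!is.null(config$class_direction)) {
      fam_class <- families$planted_class[match(annotation$tap_family,
                                                families$tap_family)]
      adj <- which(truth$de & !is.na(fam_class) &
                     fam_class %in% names(config$class_direction))
      if (length(adj)) {
        p_ind <- config$class_direction[fam_class[adj]]
        sgn <- ifelse(stats::runif(length(adj)) < p_ind, 1, -1)
        truth$log2_effect[adj] <- sgn * abs(truth$log2_effect[adj])
        truth$direction[adj] <- ifelse(sgn > 0, "induced", "repressed")
      }
    }
    effects <- planted_effects(truth, tps)

    log2_mat <- matrix(baseline, nrow = n, ncol = nrow(design),
                       dimnames = list(gene_ids, design$sample_id))
    log2_mat <- log2_mat +
      matrix(rnorm(n * nrow(design), 0, config$noise_log2_sd), nrow = n)
    log2_mat <- inject_effects(log2_mat, effects, design)

    expr <- as_tibble(2^log2_mat) |> mutate(gene_id = gene_ids, .before = 1)

    truth <- left_join(truth,
                       select(annotation, "gene_id", "tap_family", "orphan",
                              "process_class"),
                       by = "gene_id")

    structure(list(expr = expr, design = design, annotation = annotation,
                   truth = truth, effects = effects, families = families,
                   config = config, seed = as.integer(seed)),
              class = "cryomoss_sim")
  })
}

# expand per-gene truth rows into (gene, time_point) planted log2 effects:
# a persistent effect covers the first responding time point and all later
# sampled ones, a transient effect only the first
planted_effects <- function(truth, time_points) {
  de <- truth[which(truth$de), ]
  if (nrow(de) == 0) {
    return(tibble(gene_id = character(), time_point = numeric(),
                  log2_effect = numeric()))
  }
  pmap(list(de$gene_id, de$first_time_point, de$log2_effect, de$transient),
       function(g, t0, eff, tr) {
         tp <- if (isTRUE(tr)) t0 else time_points[time_points >= t0]
         tibble(gene_id = g, time_point = tp, log2_effect = eff)
       }) |> list_rbind()
}

#' Add planted log2 effects to a baseline log2 matrix
#'
#' @param log2_matrix genes x samples matrix on the log2 scale, gene ids as
#'   rownames.
#' @param effects long tibble `gene_id`, `time_point`, `log2_effect`; every
#'   gene id must exist in the matrix. An empty table returns the matrix
#'   unchanged.
#' @param design sample design tibble (`sample_id`, `time_point`, `replicate`).
#' @return the matrix with each effect added to all replicate columns of its
#'   time point.
#' @export
inject_effects <- function(log2_matrix, effects, design) {
  check_design(design, colnames(log2_matrix))
  if (nrow(effects) == 0) return(log2_matrix)
  unknown <- setdiff(effects$gene_id, rownames(log2_matrix))
  if (length(unknown)) {
    abort(paste0("effects reference unknown gene ids: ",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  }
  bad_tp <- setdiff(effects$time_point, design$time_point)
  if (length(bad_tp)) {
    abort(paste0("effects reference time points absent from the design: ",
                 paste(bad_tp, collapse = ", ")))
  }
  for (tp in unique(effects$time_point)) {
    rows <- effects$time_point == tp
    cols <- design$sample_id[design$time_point == tp]
    idx <- match(effects$gene_id[rows], rownames(log2_matrix))
    log2_matrix[idx, cols] <- log2_matrix[idx, cols] + effects$log2_effect[rows]
  }
  log2_matrix
}

#' Draw gene annotations for a simulated experiment
#'
#' Orphan flags are drawn at base rate `orphan_fraction`, multiplied by
#' `orphan_early_enrichment` (capped at 1) for genes whose planted first
#' response falls in an early-stage time point; the rate of all other genes
#' is renormalized so the marginal rate stays at `orphan_fraction`. TAP
#' families of the configured sizes are placed on non-orphan genes and their
#' members receive process-class GO labels with the configured bias; every
#' gene additionally draws generic GO terms from a common pool.
#'
#' @param config a [sim_config()].
#' @param gene_ids unique gene identifiers.
#' @param truth truth tibble as produced inside [simulate_experiment()]
#'   (needs `stage`).
#' @return annotation tibble: `gene_id`, `tap_family`, `orphan`,
#'   `process_class` (`developmental`, `stimulus_stress`, `both`, `none`),
#'   `go_terms` (semicolon-separated); the per-family planted classes are
#'   attached as the `families` attribute.
#' @export
assign_annotations <- function(config, gene_ids, truth) {
  if (anyDuplicated(gene_ids)) abort("`gene_ids` must be unique.")
  n <- length(gene_ids)
  stage <- truth$stage[match(gene_ids, truth$gene_id)]

  # orphan rates: enrich early responders, renormalize the rest
  p0 <- config$orphan_fraction
  early <- !is.na(stage) & stage == "early"
  f_early <- mean(early)
  p_early <- min(1, p0 * config$orphan_early_enrichment)
  p_rest <- if (f_early < 1) (p0 - f_early * p_early) / (1 - f_early) else p_early
  p_rest <- min(1, max(0, p_rest))
  orphan <- stats::runif(n) < ifelse(early, p_early, p_rest)

  # TAP families live on non-orphan genes (orphans have no ortholog cluster)
  sizes <- config$tap_family_sizes
  fam_ids <- sprintf("TAP_f%02d", seq_along(sizes))
  planted_class <- ifelse(
    stats::runif(length(sizes)) < config$stress_family_fraction,
    "stimulus_stress", "developmental")
  candidates <- which(!orphan)
  if (sum(sizes) > length(candidates)) {
    abort("tap_family_sizes exceed the number of non-orphan genes.")
  }
  members <- sample(candidates, sum(sizes))
  tap_family <- rep(NA_character_, n)
  tap_family[members] <- rep(fam_ids, sizes)
  fam_class_of_gene <- rep(NA_character_, n)
  fam_class_of_gene[members] <- rep(planted_class, sizes)

  # member process class: matches the family side with prob class_bias,
  # otherwise evenly: opposite side / both sides / unannotated
  process_class <- rep("none", n)
  is_member <- !is.na(tap_family)
  u <- stats::runif(sum(is_member))
  b <- config$class_bias
  other <- ifelse(fam_class_of_gene[is_member] == "stimulus_stress",
                  "developmental", "stimulus_stress")
  pc <- fam_class_of_gene[is_member]
  pc[u >= b & u < b + (1 - b) / 3] <- other[u >= b & u < b + (1 - b) / 3]
  pc[u >= b + (1 - b) / 3 & u < b + 2 * (1 - b) / 3] <- "both"
  pc[u >= b + 2 * (1 - b) / 3] <- "none"
  process_class[is_member] <- pc

  # GO terms: process-class terms plus a generic pool
  pool <- sprintf("GO:9%06d", seq_len(config$n_go_terms))
  k <- min(config$go_terms_per_gene, config$n_go_terms)
  generic <- replicate(n, sort(sample(pool, k)), simplify = FALSE)
  class_terms <- lapply(process_class, function(cl) {
    switch(cl,
           developmental = "GO:0032502",
           stimulus_stress = c("GO:0050896", "GO:0006950"),
           both = c("GO:0032502", "GO:0050896", "GO:0006950"),
           none = character(0))
  })
  go_terms <- map2(class_terms, generic, ~ paste(c(.x, .y), collapse = ";")) |>
    unlist()

  out <- tibble(gene_id = gene_ids, tap_family = tap_family, orphan = orphan,
                process_class = process_class, go_terms = go_terms)
  attr(out, "families") <- tibble(tap_family = fam_ids,
                                  planted_class = planted_class)
  out
}

#' Expand semicolon-separated GO annotations to a long gene-term mapping
#'
#' @param annotation tibble with `gene_id` and `go_terms` columns.
#' @return tibble `gene_id`, `term` with one row per association.
#' @export
annotation_go_long <- function(annotation) {
  annotation |>
    select("gene_id", "go_terms") |>
    mutate(term = strsplit(.data$go_terms, ";", fixed = TRUE)) |>
    select(-"go_terms") |>
    tidyr::unnest("term") |>
    filter(.data$term != "")
}

#' Simulate two-species TAP membership and process-class tables
#'
#' Builds the inputs of the comparative TAP-family classifier: a planted set
#' of stimulus/stress-specialized, developmental, and unbiased families whose
#' members are split across two species, together with per-gene GO process
#' classes drawn with the configured bias.
#'
#' @param n_stress,n_dev,n_neutral numbers of families planted as
#'   stimulus/stress-specialized, developmental, and unbiased (50/50).
#' @param family_size members per family (split across the two species).
#' @param class_bias probability a member of a biased family is annotated to
#'   its family's side.
#' @param species two species labels.
#' @param seed integer seed.
#' @return list of tibbles: `tap` (`gene_id`, `species`, `tap_family`),
#'   `classes` (`gene_id`, `class` in developmental/stimulus/stress), and
#'   `truth` (`tap_family`, `planted_class`).
#' @export
simulate_tap_tables <- function(n_stress = 30, n_dev = 15, n_neutral = 5,
                                family_size = 20, class_bias = 0.9,
                                species = c("Ppatens", "Athaliana"),
                                seed = NULL) {
  if (is.null(seed)) abort("`seed` is required.")
  withr::with_seed(as.integer(seed), {
    fams <- tibble(
      tap_family = sprintf("fam%02d", seq_len(n_stress + n_dev + n_neutral)),
      planted_class = rep(c("stimulus_stress", "developmental", "none"),
                          c(n_stress, n_dev, n_neutral)))
    genes <- tidyr::expand_grid(tap_family = fams$tap_family,
                                member = seq_len(family_size)) |>
      left_join(fams, by = "tap_family") |>
      mutate(gene_id = sprintf("%s_g%02d", .data$tap_family, .data$member),
             species = rep_len(species, dplyr::n()))
    p_stress <- dplyr::case_when(genes$planted_class == "stimulus_stress" ~ class_bias,
                                 genes$planted_class == "developmental" ~ 1 - class_bias,
                                 TRUE ~ 0.5)
    stress_side <- stats::runif(nrow(genes)) < p_stress
    classes <- tibble(
      gene_id = genes$gene_id,
      class = ifelse(stress_side,
                     sample(c("stimulus", "stress"), nrow(genes), replace = TRUE),
                     "developmental"))
    list(tap = select(genes, "gene_id", "species", "tap_family"),
         classes = classes,
         truth = fams)
  })
}

#' @export
print.cryomoss_sim <- function(x, ...) {
  cat(sprintf(
    "<cryomoss_sim> %d genes x %d samples (%d time points x %d replicates)\n",
    nrow(x$expr), nrow(x$design), length(x$config$time_points),
    x$config$n_replicates))
  cat(sprintf("  planted DE genes: %d (%.1f%%), orphans: %d, TAP genes: %d\n",
              sum(x$truth$de), 100 * mean(x$truth$de),
              sum(x$annotation$orphan), sum(!is.na(x$annotation$tap_family))))
  invisible(x)
}
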