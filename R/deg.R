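#' Call differentially expressed genes across a time course
#'
#' Runs the full DEG pipeline: median normalization, per-gene one-way
#' K-groups ANOVA on log2 intensities, Benjamini-Hochberg FDR across genes,
#' Tukey HSD post-hoc p-values for every time-point pair for genes passing
#' the FDR gate, Bonferroni correction across the pairs within each gene,
#' and linear fold changes with direction calls. A gene is a DEG for a pair
#' iff it passed the BH gate (`p_bh < alpha`) and its Bonferroni-corrected
#' Tukey p-value for that pair is below `alpha_pair`.
#'
#' Genes failing the BH gate are carried with their fold changes but their
#' post-hoc fields are marked not tested (`NA`), not p = 1.
#'
#' @param x a `cryomoss_sim` object, or a wide expression tibble / matrix
#'   (linear-scale non-negative intensities).
#' @param design sample design tibble (`sample_id`, `time_point`,
#'   `replicate`); taken from the simulation object when `x` is one.
#' @param alpha gene-level BH FDR threshold.
#' @param alpha_pair per-pair threshold on the Bonferroni-corrected Tukey p.
#' @param normalize median-normalize before testing (default TRUE).
#' @param ... passed between methods.
#' @return an object of class `cryomoss_deg`: list with `genes` (per-gene
#'   `gene_id`, `f`, `p`, `p_bh`, `gate`), `pairs` (long per gene x pair:
#'   `tukey_p`, `tukey_p_bonf`, `fold_change`, `direction`, `deg`, `tested`),
#'   and the thresholds/time points used.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 300, seed = 7))
#' deg <- call_degs(sim)
#' glance(deg)
call_degs <- function(x, ...) UseMethod("call_degs")

#' @rdname call_degs
#' @export
call_degs.cryomoss_sim <- function(x, alpha = 0.05, alpha_pair = 0.05,
                                   normalize = TRUE, ...) {
  call_degs(x$expr, x$design, alpha = alpha, alpha_pair = alpha_pair,
            normalize = normalize)
}

#' @rdname call_degs
#' @export
call_degs.default <- function(x, design, alpha = 0.05, alpha_pair = 0.05,
                              normalize = TRUE, ...) {
  mat <- as_expr_matrix(x)
  check_design(design, colnames(mat))
  mat <- mat[, design$sample_id, drop = FALSE]
  tps <- sort(unique(design$time_point))
  if (length(tps) < 2) abort("need at least 2 time points.")
  reps <- table(design$time_point)
  if (any(reps < 2)) abort("every time point needs at least 2 replicates.")

  if (normalize) mat <- median_normalize(mat)
  if (any(mat <= 0)) abort("normalized intensities must be positive for log2.")
  group <- factor(design$time_point, levels = tps)
  lmat <- log2(mat)

  an <- row_anova(lmat, group)
  p_bh <- bh_adjust(an$p)
  gate <- p_bh < alpha

  genes <- tibble(gene_id = rownames(mat), f = an$f, p = an$p, p_bh = p_bh,
                  gate = gate)

  # linear group means for fold changes
  k <- length(tps)
  nvec <- as.vector(table(group))
  Z <- stats::model.matrix(~ group - 1)
  lin_means <- (mat %*% Z) %*% diag(1 / nvec, k)
  colnames(lin_means) <- as.character(tps)

  idx <- utils::combn(k, 2)
  n_pairs <- ncol(idx)
  pair_tabs <- vector("list", n_pairs)
  df2 <- an$df2
  gidx <- which(gate)  # post-hoc testing only behind the BH gate

  # studentized-range q per gated gene and pair
  qmat <- matrix(NA_real_, length(gidx), n_pairs)
  dmat <- matrix(NA_real_, length(gidx), n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- idx[1, j]; b <- idx[2, j]
    dmat[, j] <- an$means[gidx, b] - an$means[gidx, a]
    se <- sqrt(an$msw[gidx] / 2 * (1 / nvec[a] + 1 / nvec[b]))
    qmat[, j] <- abs(dmat[, j]) / se
  }
  pmat <- matrix(tukey_tail(as.vector(qmat), k, df2), nrow = nrow(qmat),
                 ncol = n_pairs)
  # zero residual variance: decide by whether the log2 means differ
  degen <- an$msw[gidx] <= 0
  if (any(degen)) pmat[degen, ] <- ifelse(abs(dmat[degen, ]) > 0, 0, 1)

  for (j in seq_len(n_pairs)) {
    a <- idx[1, j]; b <- idx[2, j]
    tk <- rep(NA_real_, nrow(mat))
    tk[gidx] <- pmat[, j]
    fc <- fold_change(lin_means[, a], lin_means[, b])
    pair_tabs[[j]] <- tibble(
      gene_id = rownames(mat),
      pair = pair_label(tps[a], tps[b]),
      t_earlier = tps[a], t_later = tps[b],
      tukey_p = tk,
      tukey_p_bonf = pmin(1, tk * n_pairs),
      fold_change = fc)
  }
  pairs <- list_rbind(pair_tabs) |>
    mutate(tested = !is.na(.data$tukey_p),
           deg = .data$tested & .data$tukey_p_bonf < alpha_pair,
           direction = dplyr::case_when(
             .data$deg & .data$fold_change > 1 ~ "induced",
             .data$deg & .data$fold_change < 1 ~ "repressed",
             TRUE ~ "none"))

  structure(list(genes = genes, pairs = pairs, time_points = tps,
                 control = tps[1], alpha = alpha, alpha_pair = alpha_pair,
                 n_pairs = n_pairs),
            class = "cryomoss_deg")
}

# upper tail of the studentized range. For large batches the tail is
# evaluated on a dense grid and monotone-interpolated (error well below
# 1e-6, negligible against any significance threshold); small batches go to
# ptukey directly.
tukey_tail <- function(q, k, df) {
  fin <- which(is.finite(q))
  out <- rep(NA_real_, length(q))
  if (!length(fin)) return(out)
  if (length(fin) <= 2048) {
    out[fin] <- ptukey(q[fin], nmeans = k, df = df, lower.tail = FALSE)
    return(out)
  }
  hi <- max(q[fin])
  grid <- seq(0, hi, length.out = 4096)
  pg <- ptukey(grid, nmeans = k, df = df, lower.tail = FALSE)
  f <- stats::splinefun(grid, pg, method = "monoH.FC")
  out[fin] <- pmin(1, pmax(0, f(q[fin])))
  out
}

#' @export
print.cryomoss_deg <- function(x, ...) {
  n_deg <- length(unique(x$pairs$gene_id[x$pairs$deg]))
  cat(sprintf(
    "<cryomoss_deg> %d genes, %d time points; %d pass BH gate (alpha = %g), %d DEG in >= 1 pair\n",
    nrow(x$genes), length(x$time_points), sum(x$genes$gate), x$alpha, n_deg))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cryomoss_deg <- function(x, ...) {
  left_join(x$pairs, select(x$genes, "gene_id", "f", "p", "p_bh"),
            by = "gene_id")
}

#' @exportS3Method generics::glance
glance.cryomoss_deg <- function(x, ...) {
  ctrl <- x$pairs |> filter(.data$t_earlier == x$control)
  tibble(n_genes = nrow(x$genes),
         n_gate = sum(x$genes$gate),
         n_deg = length(unique(ctrl$gene_id[ctrl$deg])),
         n_deg_any_pair = length(unique(x$pairs$gene_id[x$pairs$deg])),
         alpha = x$alpha, alpha_pair = x$alpha_pair)
}

#' Flag persistently induced / repressed genes
#'
#' A gene is persistently induced iff it is called an induced DEG in the
#' control-versus-t comparison for every later time point t, and
#' persistently repressed analogously.
#'
#' @param deg a `cryomoss_deg` result.
#' @param control control time-point label; defaults to the earliest.
#' @return tibble `gene_id`, `persistent_induced`, `persistent_repressed`.
#' @export
classify_persistence <- function(deg, control = deg$control) {
  if (!control %in% deg$time_points) abort("`control` is not a sampled time point.")
  later <- setdiff(deg$time_points, control)
  ctrl <- deg$pairs |>
    filter(.data$t_earlier == control | .data$t_later == control)
  have <- unique(ifelse(ctrl$t_earlier == control, ctrl$t_later, ctrl$t_earlier))
  miss <- setdiff(later, have)
  if (length(miss)) {
    abort(paste0("missing control comparisons for time points: ",
                 paste(miss, collapse = ", ")))
  }
  # orient direction relative to the control as the earlier condition
  ctrl <- ctrl |>
    mutate(dir = dplyr::case_when(
      .data$t_earlier == control ~ .data$direction,
      .data$direction == "induced" ~ "repressed",
      .data$direction == "repressed" ~ "induced",
      TRUE ~ "none"))
  ctrl |>
    group_by(.data$gene_id) |>
    summarise(persistent_induced = all(.data$dir == "induced"),
              persistent_repressed = all(.data$dir == "repressed"),
              .groups = "drop")
}

#' Per-pair DEG summary table
#'
#' Mirrors the classic time-series summary: per time-point pair the DEG
#' count with its induced/repressed split, the counts changing at least
#' `two_fold_threshold`-fold in either direction, and the fold-change range
#' and mean among the pair's DEGs.
#'
#' @param deg a `cryomoss_deg` result.
#' @param two_fold_threshold linear fold-change cutoff (>= threshold or
#'   <= 1/threshold counts as a two-fold change at the default 2).
#' @return tibble with one row per pair: `pair`, `n_deg`, `n_induced`,
#'   `n_repressed`, `n_deg_2fold` (+ splits), `fc_min`, `fc_max`, `fc_mean`.
#' @export
summarize_comparisons <- function(deg, two_fold_threshold = 2) {
  thr <- two_fold_threshold
  deg$pairs |>
    group_by(.data$pair, .data$t_earlier, .data$t_later) |>
    summarise(
      n_deg = sum(.data$deg),
      n_induced = sum(.data$direction == "induced"),
      n_repressed = sum(.data$direction == "repressed"),
      n_deg_2fold = sum(.data$deg &
                          (.data$fold_change >= thr | .data$fold_change <= 1 / thr)),
      n_induced_2fold = sum(.data$direction == "induced" & .data$fold_change >= thr),
      n_repressed_2fold = sum(.data$direction == "repressed" &
                                .data$fold_change <= 1 / thr),
      fc_min = if (any(.data$deg)) min(.data$fold_change[.data$deg]) else NA_real_,
      fc_max = if (any(.data$deg)) max(.data$fold_change[.data$deg]) else NA_real_,
      fc_mean = if (any(.data$deg)) mean(.data$fold_change[.data$deg]) else NA_real_,
      .groups = "drop") |>
    arrange(.data$t_earlier, .data$t_later)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cryomoss_deg <- function(object, ...) {
  sm <- summarize_comparisons(object) |>
    filter(.data$t_earlier == object$control) |>
    tidyr::pivot_longer(c("n_induced", "n_repressed"),
                        names_to = "direction", values_to = "count") |>
    mutate(direction = sub("n_", "", .data$direction),
           time_point = factor(.data$t_later))
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$time_point, y = .data$count,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(induced = "#2166ac",
                                          repressed = "#1b7837")) +
    ggplot2::labs(x = "hours of cold vs control", y = "number of DEGs",
                  fill = NULL,
                  title = "Differentially expressed genes over the time course") +
    ggplot2::theme_minimal()
}
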