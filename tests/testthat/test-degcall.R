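test_that("median normalization equalizes sample medians", {
  # forced arithmetic: medians 10 and 20, grand median 15
  m <- matrix(c(5, 10, 20, 10, 20, 40), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  out <- median_normalize(m)
  expect_equal(out[, "s1"], c(g1 = 7.5, g2 = 15, g3 = 30))
  expect_equal(out[, "s2"], c(g1 = 7.5, g2 = 15, g3 = 30))
  # identity when all medians already agree
  m2 <- matrix(c(1, 2, 3, 3, 2, 1), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(median_normalize(m2), m2)
  # random log-normal: medians equal afterwards, ranks preserved
  set.seed(1)
  m3 <- matrix(2^rnorm(600, 8, 1.5), ncol = 6,
               dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  out3 <- median_normalize(m3)
  meds <- apply(out3, 2, median)
  expect_equal(unname(meds), rep(meds[[1]], 6))
  for (j in 1:6) expect_equal(order(out3[, j]), order(m3[, j]))
  # degenerate sample
  m4 <- matrix(c(0, 0, 0, 1, 2, 3), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_error(median_normalize(m4), "median 0")
})

test_that("K-groups ANOVA matches an independent least-squares fit", {
  # forced: identical group means with within-group variance
  res0 <- anova_k_groups(c(1, 2, 3, 3, 2, 1), rep(c("a", "b"), each = 3))
  expect_equal(res0$f, 0)
  expect_equal(res0$p, 1)
  # two groups, hand-checkable sums of squares
  vals <- c(1.0, 1.2, 1.1, 2.0, 2.2, 2.1)
  grp <- rep(c("a", "b"), each = 3)
  res <- anova_k_groups(vals, grp)
  oracle <- stats::anova(stats::lm(vals ~ grp))
  expect_equal(res$f, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(res$df1, oracle$Df[1])
  expect_equal(res$df2, oracle$Df[2])
  # five unbalanced groups against the same oracle
  set.seed(2)
  grp5 <- rep(letters[1:5], times = c(3, 4, 2, 5, 3))
  vals5 <- rnorm(length(grp5)) + as.integer(factor(grp5)) * 0.3
  res5 <- anova_k_groups(vals5, grp5)
  or5 <- stats::anova(stats::lm(vals5 ~ grp5))
  expect_equal(res5$f, or5$`F value`[1], tolerance = 1e-12)
  expect_equal(res5$p, or5$`Pr(>F)`[1], tolerance = 1e-12)
  expect_error(anova_k_groups(1:3, c("a", "a", "b")), "at least 2")
})

test_that("ANOVA p-values are calibrated under the null", {
  set.seed(11)
  mat <- matrix(rnorm(10000 * 15), nrow = 10000)
  res <- cryomoss:::row_anova(mat, rep(1:5, each = 3))
  frac <- mean(res$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))  # monotone in sorted order
    expect_true(all(q >= p - 1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Tukey pairwise p behaves like the studentized range", {
  # equal means: q = 0, p = 1
  res <- tukey_pairwise_p(c(a = 1, b = 1, c = 2), n = 3, msw = 0.5, df = 6)
  expect_equal(res$p[res$group_a == "a" & res$group_b == "b"], 1)
  # k = 2 reduces to the two-sided pooled t-test
  x <- c(1.0, 1.4, 1.1); y <- c(2.0, 1.7, 2.3)
  msw <- (stats::var(x) + stats::var(y)) / 2
  res2 <- tukey_pairwise_p(c(x = mean(x), y = mean(y)), n = 3, msw = msw,
                           df = 4)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-4)
  expect_equal(res2$q, sqrt(2) * abs(tt$statistic[[1]]), tolerance = 1e-10)
  # p decreases monotonically in q
  qs <- seq(0.5, 6, by = 0.5)
  ps <- ptukey(qs, nmeans = 5, df = 10, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))
  expect_error(tukey_pairwise_p(c(1, 2), n = 3, msw = 0, df = 4), "msw")
})

test_that("fold change is the later/earlier ratio of group means", {
  expect_equal(fold_change(3, 3), 1)
  expect_equal(fold_change(3, 6), 2)
  expect_error(fold_change(0, 3), "positive")
})

test_that("a gene responding only at 8 and 24 h is a DEG exactly for the separating pairs", {
  set.seed(21)
  design <- tidyr::expand_grid(time_point = c(0, 1, 3, 8, 24),
                               replicate = 1:3) |>
    dplyr::mutate(sample_id = sprintf("t%g_r%d", time_point, replicate))
  n <- 40
  base <- matrix(8 + rnorm(n * 15, 0, 0.01), n, 15,
                 dimnames = list(sprintf("g%02d", 1:n), design$sample_id))
  eff <- tidyr::expand_grid(gene_id = "g01", time_point = c(8, 24)) |>
    dplyr::mutate(log2_effect = 5)
  lin <- 2^inject_effects(base, eff, design)
  deg <- call_degs(lin, design)
  hits <- deg$pairs[deg$pairs$gene_id == "g01" & deg$pairs$deg, ]
  sep <- c("0 h/8 h", "0 h/24 h", "1 h/8 h", "1 h/24 h", "3 h/8 h",
           "3 h/24 h")
  expect_setequal(hits$pair, sep)
  expect_true(all(hits$direction == "induced"))
})

test_that("a noiseless planted effect gives an exact two-fold change end to end", {
  design <- tidyr::expand_grid(time_point = c(0, 1, 3, 8, 24),
                               replicate = 1:3) |>
    dplyr::mutate(sample_id = sprintf("t%g_r%d", time_point, replicate))
  base <- matrix(rep(seq(6, 9, length.out = 20), 15), 20, 15,
                 dimnames = list(sprintf("g%02d", 1:20), design$sample_id))
  # the planted gene stays below the column median, so normalization is
  # unaffected and the ratio is exact
  eff <- tibble::tibble(gene_id = "g01", time_point = 24, log2_effect = 1)
  lin <- 2^inject_effects(base, eff, design)
  deg <- call_degs(lin, design)
  fc <- deg$pairs$fold_change[deg$pairs$gene_id == "g01" &
                                deg$pairs$pair == "0 h/24 h"]
  expect_equal(unname(fc), 2, tolerance = 1e-12)
})

test_that("batched post-hoc p-values match the exact studentized-range tail", {
  set.seed(31)
  q <- c(runif(3000, 0, 12), runif(100, 12, 40))
  batched <- cryomoss:::tukey_tail(q, k = 5, df = 10)
  exact <- ptukey(q, nmeans = 5, df = 10, lower.tail = FALSE)
  expect_lt(max(abs(batched - exact)), 1e-6)
})

test_that("non-gated genes carry no post-hoc calls", {
  deg <- small_deg()
  untested <- deg$pairs[deg$pairs$gene_id %in%
                          deg$genes$gene_id[!deg$genes$gate], ]
  expect_true(all(is.na(untested$tukey_p)))
  expect_true(all(!untested$deg))
  tested <- deg$pairs[deg$pairs$tested, ]
  expect_true(all(tested$tukey_p_bonf >= tested$tukey_p - 1e-15))
  expect_true(all(deg$genes$p_bh >= deg$genes$p - 1e-15))
})

test_that("the pipeline detects strong planted effects with controlled FDR", {
  hits <- 0; called <- 0; false <- 0; planted <- 0
  prof <- stage_profile(effect_mean = rep(2, 4), effect_sd = rep(0, 4))
  for (seed in 1:3) {
    sim <- simulate_experiment(sim_config(n_genes = 2000, profile = prof,
                                          seed = 200 + seed))
    deg <- call_degs(sim)
    ctrl <- deg$pairs[deg$pairs$t_earlier == 0 & deg$pairs$deg, ]
    found <- unique(ctrl$gene_id)
    truth_de <- sim$truth$gene_id[sim$truth$de]
    hits <- hits + length(intersect(found, truth_de))
    planted <- planted + length(truth_de)
    called <- called + length(found)
    false <- false + length(setdiff(found, truth_de))
  }
  expect_gte(hits / planted, 0.95)
  expect_lte(false / max(called, 1), 0.10)
})

test_that("persistence flags follow the all-comparisons definition", {
  calls <- dplyr::bind_rows(
    tidyr::expand_grid(gene_id = "always_up", t_later = c(1, 3, 8, 24)) |>
      dplyr::mutate(deg = TRUE, fold_change = 2),
    tidyr::expand_grid(gene_id = "fades", t_later = c(1, 3, 8)) |>
      dplyr::mutate(deg = TRUE, fold_change = 2),
    tidyr::expand_grid(gene_id = "always_down", t_later = c(1, 3, 8, 24)) |>
      dplyr::mutate(deg = TRUE, fold_change = 0.4))
  deg <- fake_deg(calls)
  pers <- classify_persistence(deg)
  expect_true(pers$persistent_induced[pers$gene_id == "always_up"])
  expect_false(pers$persistent_induced[pers$gene_id == "fades"])
  expect_true(pers$persistent_repressed[pers$gene_id == "always_down"])
  expect_false(pers$persistent_induced[pers$gene_id == "always_down"])
  expect_error(classify_persistence(deg, control = 99), "not a sampled")
})

test_that("comparison summaries count directions consistently", {
  calls <- dplyr::bind_rows(
    tibble::tibble(gene_id = sprintf("up%d", 1:3), t_later = 8, deg = TRUE,
                   fold_change = c(2.5, 3, 1.5)),
    tibble::tibble(gene_id = sprintf("dn%d", 1:2), t_later = 8, deg = TRUE,
                   fold_change = c(0.3, 0.6)))
  sm <- summarize_comparisons(fake_deg(calls))
  row8 <- sm[sm$pair == "0 h/8 h", ]
  expect_equal(row8$n_deg, 5L)
  expect_equal(row8$n_induced, 3L)
  expect_equal(row8$n_repressed, 2L)
  expect_equal(row8$n_deg_2fold, 3L)  # 2.5, 3 induced; 0.3 repressed
  expect_equal(row8$fc_min, 0.3)
  expect_equal(row8$fc_max, 3)
  # structural invariant on a full pipeline result
  sm2 <- summarize_comparisons(small_deg())
  expect_true(all(sm2$n_induced + sm2$n_repressed == sm2$n_deg))
  expect_true(all(sm2$n_deg_2fold <= sm2$n_deg))
  # empty DEG set: zero counts, empty ranges
  empty <- fake_deg(tibble::tibble(gene_id = "g1", t_later = 8, deg = FALSE,
                                   fold_change = 1.2))
  sm3 <- summarize_comparisons(empty)
  expect_true(all(sm3$n_deg == 0))
  expect_true(all(is.na(sm3$fc_min)))
})

test_that("result objects build their diagnostic plots", {
  expect_s3_class(autoplot(small_deg()), "ggplot")
  sim <- small_sim()
  cls <- classify_tap_families(dplyr::filter(sim$annotation,
                                             !is.na(tap_family)))
  expect_s3_class(autoplot(cls), "ggplot")
  trends <- suppressWarnings(
    test_timepoint_class_effect(small_deg(), cls, sim$annotation))
  if (nrow(trends) > 0) {
    expect_s3_class(plot_class_trends(trends), "ggplot")
  }
})

test_that("tidy and glance expose the DEG result as tables", {
  deg <- small_deg()
  td <- tidy(deg)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gene_id", "pair", "fold_change", "p_bh") %in% names(td)))
  expect_equal(nrow(td), nrow(deg$pairs))
  gl <- glance(deg)
  expect_equal(nrow(gl), 1)
  expect_lte(gl$n_deg, gl$n_deg_any_pair)
})
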