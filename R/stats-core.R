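#' Median-normalize an intensity matrix
#'
#' Rescales each sample column multiplicatively so that its median equals the
#' grand median of all per-sample medians. Rank order within a column is
#' preserved; columns that already share one median are returned unchanged.
#'
#' @param expr wide expression tibble (`gene_id` + sample columns) or a
#'   numeric matrix with gene rownames; values must be non-negative.
#' @return the same container type with normalized intensities.
#' @export
#' @examples
#' m <- matrix(c(5, 10, 20, 10, 20, 40), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' apply(median_normalize(m), 2, median)
median_normalize <- function(expr) {
  mat <- as_expr_matrix(expr)
  if (nrow(mat) < 1) abort("need at least one gene.")
  if (anyNA(mat)) abort("missing intensities are not supported.")
  if (any(mat < 0)) abort("intensities must be non-negative.")
  meds <- apply(mat, 2, median)
  if (any(meds == 0)) {
    abort(paste0("degenerate array: sample(s) with median 0: ",
                 paste(colnames(mat)[meds == 0], collapse = ", ")))
  }
  grand <- median(meds)
  out <- sweep(mat, 2, grand / meds, `*`)
  if (is.matrix(expr)) return(out)
  as_tibble(out) |> mutate(gene_id = rownames(mat), .before = 1)
}

# vectorized one-way fixed-effects ANOVA over matrix rows.
# returns list(f, p, df1, df2, msw, means) with group means as a rows x k
# matrix. Zero within- and between-variance rows get F = 0, p = 1; zero
# within-variance with differing means gets F = Inf, p = 0.
row_anova <- function(mat, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  nvec <- as.vector(table(group))
  if (k < 2) abort("need at least 2 groups.")
  if (any(nvec < 2)) abort("every group needs at least 2 observations.")
  N <- ncol(mat)
  Z <- stats::model.matrix(~ group - 1)
  M <- (mat %*% Z) %*% diag(1 / nvec, k)
  colnames(M) <- levels(group)
  grand <- rowMeans(mat)
  ssb <- as.vector((M - grand)^2 %*% nvec)
  ssw <- pmax(rowSums(mat^2) - as.vector(M^2 %*% nvec), 0)
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  # degenerate rows: no variance at all -> null by definition
  zero_all <- ssw <= 0 & ssb <= 1e-12 * pmax(rowMeans(mat^2), 1)
  f[zero_all] <- 0
  p <- pf(f, df1, df2, lower.tail = FALSE)
  p[zero_all] <- 1
  list(f = f, p = p, df1 = df1, df2 = df2, msw = ssw / df2, means = M,
       n = nvec)
}

#' One-way K-groups ANOVA
#'
#' Fixed-effects one-way analysis of variance: F statistic and upper-tail
#' p-value from the F distribution with (k - 1, N - k) degrees of freedom.
#' A response with zero within- and between-group variance is reported with
#' F = 0 and p = 1 rather than dropped.
#'
#' @param values numeric response vector.
#' @param group group labels, same length as `values`; at least 2 groups with
#'   at least 2 observations each.
#' @return one-row tibble: `f`, `p`, `df1`, `df2`.
#' @export
#' @examples
#' anova_k_groups(c(1, 1.2, 1.1, 2, 2.2, 2.1), rep(c("a", "b"), each = 3))
anova_k_groups <- function(values, group) {
  if (length(values) != length(group)) abort("`values` and `group` lengths differ.")
  if (anyNA(values)) abort("`values` must not contain missing values.")
  res <- row_anova(matrix(values, nrow = 1), group)
  tibble(f = res$f, p = res$p, df1 = res$df1, df2 = res$df2)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted p-values: with p sorted ascending,
#' q_i = min over j >= i of p_j * m / j, capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  check_probabilities(p, "p")
  p.adjust(p, method = "BH")
}

#' Tukey HSD pairwise p-values
#'
#' For every ordered pair of groups, computes the studentized-range statistic
#' q = |mean difference| / sqrt(MSW/2 * (1/n_a + 1/n_b)) and its upper-tail
#' p-value from the studentized-range distribution with `k` means and `df`
#' error degrees of freedom (Tukey-Kramer for unequal group sizes).
#'
#' @param means named vector of group means (names are group labels, in time
#'   order).
#' @param n group sizes (scalar or one per group).
#' @param msw pooled within-group mean square (> 0).
#' @param df error degrees of freedom.
#' @return tibble with one row per pair: `group_a`, `group_b`, `q`, `p`.
#' @export
tukey_pairwise_p <- function(means, n, msw, df) {
  k <- length(means)
  if (k < 2) abort("need at least 2 groups.")
  if (msw <= 0) abort("`msw` must be > 0.")
  if (df < 1) abort("`df` must be >= 1.")
  n <- rep_len(n, k)
  idx <- utils::combn(k, 2)
  a <- idx[1, ]; b <- idx[2, ]
  se <- sqrt(msw / 2 * (1 / n[a] + 1 / n[b]))
  q <- abs(means[a] - means[b]) / se
  tibble(group_a = names(means)[a] %||% as.character(a),
         group_b = names(means)[b] %||% as.character(b),
         q = unname(q),
         p = ptukey(unname(q), nmeans = k, df = df, lower.tail = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Linear fold change between two group means
#'
#' @param mean_earlier,mean_later positive normalized group means.
#' @return `mean_later / mean_earlier`; values > 1 indicate induction in the
#'   later group, values < 1 repression.
#' @export
fold_change <- function(mean_earlier, mean_later) {
  if (any(mean_earlier <= 0) || any(mean_later <= 0)) {
    abort("group means must be positive to form a fold change.")
  }
  mean_later / mean_earlier
}

#' Two-by-two Fisher's exact test
#'
#' Exact hypergeometric test on the table \code{rbind(c(a, b), c(c, d))}
#' where rows are in-set / out-of-set and columns are has-term / lacks-term.
#' `p_over` is the upper tail (observed or larger `a`), `p_under` the lower
#' tail; the two-sided p sums the probabilities of all tables with the same
#' margins whose point probability does not exceed the observed one (with a
#' 1e-7 relative tolerance on the comparison).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return one-row tibble: `p_two_sided`, `p_over`, `p_under`.
#' @export
#' @examples
#' fisher_2x2(3, 1, 1, 3)
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts)) || anyNA(counts)) {
    abort("cell counts must be non-negative integers.")
  }
  m <- a + c          # genes carrying the term
  n_ <- b + d         # genes lacking it
  kk <- a + b         # set size
  lo <- max(0, kk - n_)
  hi <- min(kk, m)
  if (lo == hi) {
    return(tibble(p_two_sided = 1, p_over = 1, p_under = 1))
  }
  support <- lo:hi
  dens <- dhyper(support, m, n_, kk)
  d_obs <- dens[support == a]
  tibble(
    p_two_sided = min(1, sum(dens[dens <= d_obs * (1 + 1e-7)])),
    p_over = min(1, sum(dens[support >= a])),
    p_under = min(1, sum(dens[support <= a])))
}
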