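#' Fit a Gaussian-identity GLM
#'
#' Least-squares fit of a Gaussian generalized linear model with identity
#' link: coefficient estimates, standard errors from the residual variance,
#' and two-sided Wald p-values from the t distribution with the residual
#' degrees of freedom. A rank-deficient design is an error naming the
#' collinear columns. A perfect fit (zero residual variance) is flagged and
#' its p-values are reported at the machine floor rather than 0.
#'
#' @param data data frame holding the response and covariates.
#' @param formula model formula.
#' @return an object of class `cryomoss_glm` with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 5, 6, 7), grp = rep(c("a", "b"), each = 3))
#' tidy(fit_glm_gaussian(d, y ~ grp))
fit_glm_gaussian <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(collinear, collapse = ", ")))
  }
  if (nrow(X) <= ncol(X)) abort("need more observations than parameters.")
  fit <- stats::glm(formula, data = data, family = gaussian())
  rss <- sum(fit$residuals^2)
  df_res <- fit$df.residual
  scale <- max(mean(fit$fitted.values^2), 1)
  perfect <- rss <= 1e-24 * scale * length(fit$residuals)
  est <- stats::coef(fit)
  if (perfect) {
    se <- rep(0, length(est))
    stat <- ifelse(est == 0, 0, sign(est) * Inf)
    pval <- ifelse(est == 0, 1, .Machine$double.xmin)
  } else {
    s <- summary(fit)
    se <- s$coefficients[, "Std. Error"]
    stat <- s$coefficients[, "t value"]
    pval <- 2 * pt(-abs(stat), df_res)
  }
  structure(
    list(coefficients = tibble(term = names(est), estimate = unname(est),
                               std.error = unname(se),
                               statistic = unname(stat),
                               p.value = unname(pval)),
         sigma = sqrt(rss / df_res), df_residual = df_res,
         n = length(fit$residuals), deviance = rss,
         perfect_fit = perfect, formula = formula),
    class = "cryomoss_glm")
}

#' @exportS3Method generics::tidy
tidy.cryomoss_glm <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- x$coefficients
  if (conf.int) {
    tq <- qt(1 - (1 - conf.level) / 2, x$df_residual)
    out <- out |>
      mutate(conf.low = .data$estimate - tq * .data$std.error,
             conf.high = .data$estimate + tq * .data$std.error)
  }
  out
}

#' @exportS3Method generics::glance
glance.cryomoss_glm <- function(x, ...) {
  tibble(n = x$n, df.residual = x$df_residual, sigma = x$sigma,
         deviance = x$deviance, perfect_fit = x$perfect_fit)
}

#' @export
print.cryomoss_glm <- function(x, ...) {
  cat(sprintf("<cryomoss_glm> n = %d, residual df = %d, sigma = %.4g%s\n",
              x$n, x$df_residual, x$sigma,
              if (x$perfect_fit) " (perfect fit)" else ""))
  print(x$coefficients)
  invisible(x)
}

# log2 fold-change responses of TAP-coding DEGs for the control comparisons,
# one observation per gene x comparison, joined with the family's
# specialization flag when a classification is supplied
tap_glm_responses <- function(deg, annotation, classification = NULL,
                              control = deg$control) {
  resp <- deg$pairs |>
    filter(.data$t_earlier == control, .data$deg) |>
    inner_join(annotation |>
                 filter(!is.na(.data$tap_family)) |>
                 select("gene_id", "tap_family"),
               by = "gene_id") |>
    mutate(log2_fc = log2(.data$fold_change)) |>
    select("gene_id", "tap_family", time_point = "t_later", "log2_fc")
  if (!is.null(classification)) {
    resp <- resp |>
      left_join(as_tibble(classification)[c("tap_family", "flag")],
                by = "tap_family")
  }
  resp
}

one_sample_fit <- function(lfc) {
  fit <- fit_glm_gaussian(data.frame(lfc = lfc), lfc ~ 1)
  co <- fit$coefficients
  tibble(n = length(lfc), estimate = co$estimate, se = co$std.error,
         statistic = co$statistic, p_value = co$p.value,
         direction = dplyr::case_when(co$estimate > 0 ~ "induced",
                                      co$estimate < 0 ~ "repressed",
                                      TRUE ~ "none"))
}

#' Global GLM test of class-level regulatory trends
#'
#' Pools the log2 fold changes of TAP-coding DEGs over all control
#' comparisons and, per process class, tests whether the mean log2 fold
#' change differs from zero (intercept-only Gaussian GLM; equivalent to a
#' one-sample t-test). A positive estimate is reported as induction, a
#' negative one as repression. Classes with fewer than 3 responses are
#' skipped with a warning.
#'
#' @param deg a `cryomoss_deg` result.
#' @param classification a `tap_classification` (family -> flag).
#' @param annotation tibble with `gene_id`, `tap_family`.
#' @param control control time-point label.
#' @return tibble per class: `class`, `n`, `estimate`, `se`, `statistic`,
#'   `p_value`, `direction`.
#' @export
test_global_class_effect <- function(deg, classification, annotation,
                                     control = deg$control) {
  resp <- tap_glm_responses(deg, annotation, classification, control)
  out <- list()
  for (cl in c("stimulus_stress", "developmental")) {
    lfc <- resp$log2_fc[!is.na(resp$flag) & resp$flag == cl]
    if (length(lfc) < 3) {
      warn(sprintf("class `%s` has %d response(s); skipped.", cl, length(lfc)))
      next
    }
    out[[cl]] <- mutate(one_sample_fit(lfc), class = cl, .before = 1)
  }
  list_rbind(out)
}

#' Per-time-point GLM test of class-level regulatory trends
#'
#' As [test_global_class_effect()] but restricted to the control-versus-t
#' responses of each time point separately.
#'
#' @inheritParams test_global_class_effect
#' @param time_points time points to test; defaults to all non-control ones.
#' @return tibble per (time point, class) with the same columns plus
#'   `time_point`. Empty class/time-point combinations are skipped with a
#'   warning.
#' @export
test_timepoint_class_effect <- function(deg, classification, annotation,
                                        time_points = NULL,
                                        control = deg$control) {
  resp <- tap_glm_responses(deg, annotation, classification, control)
  if (is.null(time_points)) time_points <- setdiff(deg$time_points, control)
  out <- list()
  for (tp in time_points) {
    for (cl in c("stimulus_stress", "developmental")) {
      lfc <- resp$log2_fc[!is.na(resp$flag) & resp$flag == cl &
                            resp$time_point == tp]
      if (length(lfc) < 3) {
        warn(sprintf("class `%s` at %g h has %d response(s); skipped.",
                     cl, tp, length(lfc)))
        next
      }
      out[[paste(tp, cl)]] <-
        mutate(one_sample_fit(lfc), time_point = tp, class = cl, .before = 1)
    }
  }
  list_rbind(out)
}

#' GLM trend test for individual TAP families
#'
#' Tests, per TAP family, whether the mean log2 fold change of the family's
#' DEG responses differs from zero, either pooled over the whole time course
#' (`time_point = NULL`) or restricted to one control comparison. Families
#' with fewer than 3 responses in scope are skipped with a warning.
#'
#' @param deg a `cryomoss_deg` result.
#' @param annotation tibble with `gene_id`, `tap_family`.
#' @param families families to test; defaults to every family with enough
#'   responses.
#' @param time_point optional single time point restricting the scope.
#' @param control control time-point label.
#' @return tibble per family: `tap_family`, `scope`, `n`, `estimate`, `se`,
#'   `statistic`, `p_value`, `direction`.
#' @export
test_family_trend <- function(deg, annotation, families = NULL,
                              time_point = NULL, control = deg$control) {
  resp <- tap_glm_responses(deg, annotation, NULL, control)
  if (!is.null(time_point)) {
    resp <- resp |> filter(.data$time_point %in% .env$time_point)
  }
  scope <- if (is.null(time_point)) "global" else sprintf("%g h", time_point)
  explicit <- !is.null(families)
  if (is.null(families)) families <- sort(unique(resp$tap_family))
  out <- list()
  for (fam in families) {
    lfc <- resp$log2_fc[resp$tap_family == fam]
    if (length(lfc) < 3) {
      if (explicit) {
        warn(sprintf("family `%s` has %d response(s) in scope; skipped.",
                     fam, length(lfc)))
      }
      next
    }
    out[[fam]] <- mutate(one_sample_fit(lfc), tap_family = fam, scope = scope,
                         .before = 1)
  }
  list_rbind(out)
}

#' Plot per-time-point class trends
#'
#' Point-and-interval plot of the estimated mean log2 fold change per
#' process class and time point from [test_timepoint_class_effect()].
#'
#' @param trends tibble returned by [test_timepoint_class_effect()].
#' @param conf.level confidence level of the plotted normal intervals.
#' @return a ggplot object.
#' @export
plot_class_trends <- function(trends, conf.level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ggplot2::ggplot(trends,
                  ggplot2::aes(x = factor(.data$time_point),
                               y = .data$estimate, colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - z * .data$se,
                   ymax = .data$estimate + z * .data$se),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "hours of cold vs control",
                  y = "mean log2 fold change",
                  colour = "TAP class") +
    ggplot2::theme_minimal()
}
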