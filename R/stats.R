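#' Compare a morphometry metric between conditions
#'
#' One-way ANOVA with Tukey's HSD post-hoc over all condition pairs
#' (Tukey-Kramer under unequal group sizes), or an unpaired two-sided
#' t-test for exactly two conditions. Per-condition n, mean and SD are
#' always reported. Significance stars follow the four-level convention
#' (0.05, 0.01, 0.001, 0.0001).
#'
#' @param table a feature tibble (one row per sample).
#' @param metric name of the numeric column to compare.
#' @param group name of the grouping column (default `"condition"`).
#' @param method `"anova_tukey"` or `"ttest"`.
#' @param var_equal for the t-test: equal-variance (default `TRUE`, the
#'   classical unpaired test) or Welch (`FALSE`).
#' @return An object of class `group_comparison`; see [tidy.group_comparison()]
#'   and [glance.group_comparison()].
#' @export
compare_groups <- function(table, metric, group = "condition",
                           method = c("anova_tukey", "ttest"),
                           var_equal = TRUE) {
  method <- match.arg(method)
  if (!metric %in% names(table)) abort(sprintf("No column '%s' in the table.", metric))
  vals <- table[[metric]]
  if (!is.numeric(vals)) abort(sprintf("Metric '%s' is not numeric.", metric))
  g <- factor(table[[group]])
  keep <- !is.na(vals) & !is.na(g)
  vals <- vals[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("At least 2 conditions are required.")
  ns <- table(g)
  if (any(ns < 2)) {
    abort(sprintf("Condition(s) with fewer than 2 samples: %s.",
                  paste(names(ns)[ns < 2], collapse = ", ")))
  }
  summary_tbl <- tibble(condition = levels(g),
                        n = as.integer(ns),
                        mean = as.numeric(tapply(vals, g, mean)),
                        sd = as.numeric(tapply(vals, g, sd)))
  res <- list(metric = metric, method = method, summary = summary_tbl)
  if (method == "ttest") {
    if (nlevels(g) != 2) abort("ttest requires exactly 2 conditions.")
    tt <- t.test(vals ~ g, var.equal = var_equal)
    res$ttest <- tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                        p = tt$p.value,
                        stars = signif_stars(tt$p.value))
  } else {
    df <- data.frame(value = vals, condition = g)
    fit <- aov(value ~ condition, data = df)
    an <- summary(fit)[[1]]
    res$anova <- tibble(F = an[["F value"]][1],
                        df_between = an[["Df"]][1],
                        df_within = an[["Df"]][2],
                        p = an[["Pr(>F)"]][1])
    tk <- TukeyHSD(fit)$condition
    res$tukey <- tibble(contrast = rownames(tk),
                        diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"],
                        stars = signif_stars(tk[, "p adj"]))
  }
  structure(res, class = "group_comparison")
}

#' Significance stars
#'
#' Four-level convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001; `ns` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Character vector of star labels.
#' @export
signif_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> metric '%s', method %s\n", x$metric, x$method))
  print(x$summary)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
                x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
    print(x$tukey)
  }
  if (!is.null(x$ttest)) {
    cat(sprintf("t-test: t(%.4g) = %.4g, p = %.4g %s\n",
                x$ttest$df, x$ttest$t, x$ttest$p, x$ttest$stars))
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' One row per pairwise contrast (Tukey) or the single t-test row.
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$tukey)) {
    dplyr::mutate(x$tukey, metric = x$metric, .before = 1)
  } else {
    dplyr::mutate(x$ttest, metric = x$metric, .before = 1)
  }
}

#' Glance at a group comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return A one-row tibble with the omnibus statistic and p-value.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  if (!is.null(x$anova)) {
    tibble(metric = x$metric, method = x$method, statistic = x$anova$F,
           p_value = x$anova$p, n_groups = nrow(x$summary),
           n_total = sum(x$summary$n))
  } else {
    tibble(metric = x$metric, method = x$method, statistic = x$ttest$t,
           p_value = x$ttest$p, n_groups = 2L, n_total = sum(x$summary$n))
  }
}

#' Per-condition summary of a metric
#'
#' @param table a feature tibble.
#' @param metric numeric column name.
#' @param group grouping column (default `"condition"`).
#' @param dispersion `"sd"` (default, the reporting convention) or `"sem"`
#'   (sd / sqrt(n)).
#' @return Tibble with `condition`, `n`, `mean`, and `sd` or `sem` (NA for
#'   n = 1).
#' @export
summarize_features <- function(table, metric, group = "condition",
                               dispersion = c("sd", "sem")) {
  dispersion <- match.arg(dispersion)
  if (!metric %in% names(table)) abort(sprintf("No column '%s' in the table.", metric))
  vals <- table[[metric]]
  if (!is.numeric(vals)) abort(sprintf("Metric '%s' is not numeric.", metric))
  out <- tibble(condition = as.character(table[[group]]), value = vals) |>
    filter(!is.na(.data$value)) |>
    group_by(.data$condition) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = if (dplyr::n() >= 2) sd(.data$value) else NA_real_,
              .groups = "drop")
  if (dispersion == "sem") {
    out$sem <- out$sd / sqrt(out$n)
    out$sd <- NULL
  }
  out
}
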