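#' Spearman rank correlation with midrank ties
#'
#' Spearman's coefficient computed as the Pearson correlation of midranks,
#' with a two-sided p-value from the t approximation on n - 2 degrees of
#' freedom — the convention of standard statistical packages for
#' moderate-size cohorts. Pairs with missing values are dropped.
#'
#' @param x,y Paired numeric vectors (at least 4 complete pairs).
#' @return A `correlation_result` list: `rs`, `p`, `n`, and `flags`
#'   (contains `"zero_variance"` with `rs = NA` when either rank vector is
#'   constant).
#' @export
spearman_cor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(structure(list(rs = NA_real_, p = NA_real_, n = n,
                          flags = "zero_variance"),
                     class = "correlation_result"))
  rs <- cor(rx, ry)
  tval <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  structure(list(rs = rs, p = min(p, 1), n = n, flags = character(0)),
            class = "correlation_result")
}

check_predictors <- function(X, cols) {
  for (j in seq_along(cols)) {
    if (length(unique(X[, j + 1])) < 2)
      stop("constant predictor: ", cols[j], call. = FALSE)
  }
  if (qr(X)$rank < ncol(X))
    stop("collinear predictors: ", paste(cols, collapse = ", "),
         call. = FALSE)
}

group_effect_fit <- function(y, dm, fib = NULL) {
  X <- if (is.null(fib)) cbind(1, dm) else cbind(1, dm, fib)
  fit <- lm(y ~ X - 1)
  # summary.lm warns on exact fits (legitimate for degenerate inputs)
  sm <- suppressWarnings(summary(fit)$coefficients)
  b <- sm[2, 1]; se <- sm[2, 2]
  df <- fit$df.residual
  ci <- b + c(-1, 1) * qt(0.975, df) * se
  cf <- as.numeric(coef(fit))
  names(cf) <- c("intercept", "group", if (!is.null(fib)) "fibrinogen")
  list(B = b, ci95 = ci, p = sm[2, 4], n_used = length(y), coefs = cf)
}

#' Group effect on a clot property, adjusted for fibrinogen
#'
#' Ordinary least squares of a clot property on group membership (DM vs
#' control) with and without adjustment for fibrinogen concentration:
#' `outcome ~ group + fibrinogen`. Reports the group coefficient B with
#' its 95% confidence interval (t distribution) and two-sided p-value,
#' mirroring the B [95% CI] presentation of adjusted cohort analyses.
#' Outcomes flagged for log transformation (natural log) are modeled on
#' the log scale, in which case B is in log units. Rows with missing
#' values are deleted listwise.
#'
#' @param table A `cohort_table` (see [simulate_cohort()]) or data frame
#'   with columns `group` and `fibrinogen`. `group` should be a two-level
#'   factor whose first level is the reference (B is the effect of the
#'   second level); character columns are leveled in locale-independent
#'   (C radix) sort order.
#' @param outcome Name of the outcome column.
#' @param log_transform Model the outcome on the natural-log scale;
#'   defaults to the table's per-outcome flag when present.
#' @return A `regression_result` list with `adjusted` and `unadjusted`
#'   components, each holding `B`, `ci95`, `p`, `n_used`; plus `outcome`
#'   and `log_transform`.
#' @export
adjusted_group_effect <- function(table, outcome, log_transform = NULL) {
  if (!outcome %in% names(table))
    stop("no such outcome column: ", outcome, call. = FALSE)
  if (is.null(log_transform))
    log_transform <- isTRUE(attr(table, "log_transform")[outcome])
  keep <- complete.cases(table[[outcome]], table$group, table$fibrinogen)
  y <- table[[outcome]][keep]
  if (length(y) < 10) stop("fewer than 10 complete rows", call. = FALSE)
  if (log_transform) {
    if (any(y <= 0))
      stop("log transform requested but `", outcome,
           "` has non-positive values", call. = FALSE)
    y <- log(y)
  }
  g <- table$group
  if (!is.factor(g))   # locale-independent level order for character input
    g <- factor(g, levels = sort(unique(as.character(g)), method = "radix"))
  if (nlevels(g) != 2) stop("`group` must have exactly 2 levels",
                            call. = FALSE)
  dm <- as.numeric(g[keep] == levels(g)[2])
  fib <- table$fibrinogen[keep]
  check_predictors(cbind(1, dm, fib), c("group", "fibrinogen"))
  structure(list(adjusted = group_effect_fit(y, dm, fib),
                 unadjusted = group_effect_fit(y, dm),
                 outcome = outcome, log_transform = log_transform),
            class = "regression_result")
}

normality_ok <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
  n <- length(x)
  if (n > 5000) x <- sample(x, 5000)
  shapiro.test(x)$p.value > 0.05
}

fmt_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), sd(x))
fmt_med_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.1f [%.1f-%.1f]", q[2], q[1], q[3])
}

#' Compare a clot property between two groups
#'
#' Two-sample comparison following the conventional decision rule: an
#' independent two-sample t-test when both groups pass a Shapiro-Wilk
#' normality screen at alpha = 0.05, otherwise a Mann-Whitney U test; the
#' method can also be forced. The effect summary mirrors cohort-table
#' formatting: mean +/- SD per group for the t-test, median [IQR] for
#' Mann-Whitney.
#'
#' @param x_dm,x_ctrl Numeric vectors (each n >= 3), e.g. the DM and
#'   control groups.
#' @param method `"auto"` (default), `"t"` or `"mannwhitney"`.
#' @return A list: `p`, `method_used`, `effect` (difference of means or of
#'   medians, DM minus control), `summary_dm`, `summary_ctrl`, `flags`
#'   (contains `"constant_data"` with `p = NA` when both groups are
#'   constant).
#' @export
group_compare <- function(x_dm, x_ctrl,
                          method = c("auto", "t", "mannwhitney")) {
  method <- match.arg(method)
  x_dm <- x_dm[is.finite(x_dm)]; x_ctrl <- x_ctrl[is.finite(x_ctrl)]
  if (length(x_dm) < 3 || length(x_ctrl) < 3)
    stop("each group needs at least 3 values", call. = FALSE)
  if (var(x_dm) == 0 && var(x_ctrl) == 0) {
    eq <- isTRUE(all.equal(mean(x_dm), mean(x_ctrl)))
    return(list(p = if (eq) 1 else NA_real_, method_used = "none",
                effect = mean(x_dm) - mean(x_ctrl),
                summary_dm = fmt_mean_sd(x_dm),
                summary_ctrl = fmt_mean_sd(x_ctrl),
                flags = "constant_data"))
  }
  use_t <- switch(method,
                  auto = normality_ok(x_dm) && normality_ok(x_ctrl),
                  t = TRUE, mannwhitney = FALSE)
  if (use_t) {
    p <- t.test(x_dm, x_ctrl, var.equal = TRUE)$p.value
    list(p = p, method_used = "t",
         effect = mean(x_dm) - mean(x_ctrl),
         summary_dm = fmt_mean_sd(x_dm), summary_ctrl = fmt_mean_sd(x_ctrl),
         flags = character(0))
  } else {
    p <- suppressWarnings(wilcox.test(x_dm, x_ctrl, exact = FALSE)$p.value)
    list(p = p, method_used = "mannwhitney",
         effect = median(x_dm) - median(x_ctrl),
         summary_dm = fmt_med_iqr(x_dm), summary_ctrl = fmt_med_iqr(x_ctrl),
         flags = character(0))
  }
}

#' Per-timepoint group comparison of lysis time courses
#'
#' Compares two sets of fibrinolysis time courses (one series per subject)
#' at every shared timepoint with [group_compare()], then applies a
#' Bonferroni correction over timepoints:
#' `p_adj = min(1, p * n_timepoints)`.
#'
#' @param series_dm,series_ctrl Lists of [lysis_series()] objects on a
#'   common time grid (or numeric matrices, subjects in columns, with the
#'   grid as `time`).
#' @param time Time grid (required for matrix input).
#' @param method Passed to [group_compare()].
#' @return Data frame with columns `time`, `p`, `p_adj`, `effect`,
#'   `method_used`.
#' @export
timecourse_compare <- function(series_dm, series_ctrl, time = NULL,
                               method = "auto") {
  to_mat <- function(s) {
    if (is.matrix(s)) return(s)
    stopifnot(is.list(s), length(s) >= 1)
    grids <- lapply(s, function(x) x$time)
    if (!all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1))))
      stop("all series must share a common time grid", call. = FALSE)
    time <<- grids[[1]]
    vapply(s, function(x) x$fluorescence, numeric(length(grids[[1]])))
  }
  m_ctrl <- to_mat(series_ctrl)
  m_dm <- to_mat(series_dm)
  if (is.null(time)) stop("`time` required for matrix input", call. = FALSE)
  if (nrow(m_dm) != nrow(m_ctrl) || nrow(m_dm) != length(time))
    stop("mismatched time grids between groups", call. = FALSE)
  res <- lapply(seq_along(time), function(i)
    group_compare(m_dm[i, ], m_ctrl[i, ], method = method))
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(time = time, p = p,
             p_adj = pmin(1, p * length(time)),
             effect = vapply(res, `[[`, numeric(1), "effect"),
             method_used = vapply(res, `[[`, character(1), "method_used"))
}

#' Cohort descriptives table
#'
#' Per-variable summaries in the style of a clinical characteristics
#' table: `n (%)` with a chi-square test for categorical variables,
#' mean +/- SD with a t-test for normally distributed numerics, and
#' median [IQR] with a Mann-Whitney U test otherwise (Shapiro-Wilk screen
#' at alpha = 0.05 per group). With a single group the comparison columns
#' are absent-flagged.
#'
#' @param table Data frame including a `group` column.
#' @param variables Columns to summarize (default: all except
#'   `subject_id` and `group`).
#' @param group_col Name of the grouping column.
#' @return Data frame with one row per variable (categorical variables get
#'   one row per level): `variable`, `level`, `summary_total`,
#'   `summary_g1`, `summary_g2`, `test`, `p`.
#' @export
cohort_descriptives <- function(table, variables = NULL,
                                group_col = "group") {
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  g <- factor(table[[group_col]])
  two_groups <- nlevels(g) == 2
  if (is.null(variables))
    variables <- setdiff(names(table), c("subject_id", group_col))
  rows <- list()
  pct <- function(k, n) sprintf("%d (%.0f%%)", k, round(100 * k / n))
  for (v in variables) {
    x <- table[[v]]
    if (is.numeric(x)) {
      normal <- if (two_groups)
        all(tapply(x, g, normality_ok)) else normality_ok(x)
      s_tot <- if (normal) fmt_mean_sd(x) else fmt_med_iqr(x)
      if (two_groups) {
        cmp <- group_compare(x[g == levels(g)[2]], x[g == levels(g)[1]],
                             method = if (normal) "t" else "mannwhitney")
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = NA, summary_total = s_tot,
          summary_g1 = cmp$summary_ctrl, summary_g2 = cmp$summary_dm,
          test = cmp$method_used, p = cmp$p)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = NA, summary_total = s_tot,
          summary_g1 = NA, summary_g2 = NA, test = "absent", p = NA)
      }
    } else {
      x <- factor(x)
      n <- length(x)
      p_chi <- NA_real_
      if (two_groups) {
        tab <- base::table(x, g)
        p_chi <- tryCatch(
          suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
          error = function(e) NA_real_)
      }
      for (lev in levels(x)) {
        k <- sum(x == lev)
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lev, summary_total = pct(k, n),
          summary_g1 = if (two_groups)
            pct(sum(x == lev & g == levels(g)[1]), sum(g == levels(g)[1]))
            else NA,
          summary_g2 = if (two_groups)
            pct(sum(x == lev & g == levels(g)[2]), sum(g == levels(g)[2]))
            else NA,
          test = if (two_groups) "chisq" else "absent", p = p_chi)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
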