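#' Build the longitudinal cohort table
#'
#' Merges per-session parameter records into one tidy table with one row per
#' (subject, group, week, parameter). Duplicate (subject, week, parameter)
#' records are an error; missing sessions simply stay absent (never imputed).
#'
#' @param per_session_outputs a data.frame or list of data.frames, each with
#'   columns `subject`, `group`, `week`, `parameter`, `value`.
#' @return a tibble of class `cohort_table`.
#' @export
build_cohort_table <- function(per_session_outputs) {
  if (is.data.frame(per_session_outputs))
    per_session_outputs <- list(per_session_outputs)
  need <- c("subject", "group", "week", "parameter", "value")
  tabs <- lapply(per_session_outputs, function(x) {
    x <- tibble::as_tibble(x)
    if (!all(need %in% names(x)))
      stop("each session table needs columns: ", paste(need, collapse = ", "))
    x[need]
  })
  tab <- dplyr::bind_rows(tabs)
  if (!nrow(tab))
    return(structure(tibble::tibble(subject = character(), group = character(),
                                    week = numeric(), parameter = character(),
                                    value = numeric()),
                     class = c("cohort_table", class(tibble::tibble()))))
  dup <- dplyr::count(tab, .data$subject, .data$week, .data$parameter)
  if (any(dup$n > 1))
    stop("duplicate (subject, week, parameter) records in cohort table")
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Normalize a parameter to its baseline (week 0) value per subject
#'
#' `value(week) / value(baseline)`; the baseline week maps to 1. Subjects
#' with a missing or zero baseline are excluded from the result with a
#' warning.
#'
#' @param table a [build_cohort_table()] table.
#' @param parameter parameter name to normalize.
#' @param baseline_week the baseline week (default 0).
#' @return tibble with `subject`, `group`, `week`, `value` (normalized).
#' @export
normalize_to_baseline <- function(table, parameter, baseline_week = 0) {
  x <- dplyr::filter(table, .data$parameter == !!parameter)
  base <- dplyr::filter(x, .data$week == baseline_week)
  bad <- unique(c(
    setdiff(unique(x$subject), base$subject),
    base$subject[is.na(base$value) | base$value == 0]
  ))
  if (length(bad))
    warning("excluded subjects with missing/zero baseline: ",
            paste(bad, collapse = ", "))
  x <- dplyr::filter(x, !(.data$subject %in% bad))
  base <- dplyr::filter(base, !(.data$subject %in% bad))
  x <- dplyr::left_join(x,
                        dplyr::select(base, "subject", baseline = "value"),
                        by = "subject")
  x$value <- x$value / x$baseline
  dplyr::select(x, "subject", "group", "week", "value")
}

#' Correlation heatmap of early changes against endpoint values
#'
#' For every parameter pair (i, j), the squared Pearson correlation across
#' subjects between the early change `param_i(W1) - param_i(W0)` and the
#' endpoint value `param_j(W6)`. Complete-case per cell; cells with fewer
#' than `min_n` complete subjects or a zero-variance series are NA and
#' flagged undefined.
#'
#' @param table a [build_cohort_table()] table.
#' @param early_week week of the early change (default 1).
#' @param endpoint_week endpoint week (default 6).
#' @param baseline_week baseline week (default 0).
#' @param min_n minimum complete pairs per cell (default 3).
#' @return object of class `correlation_heatmap`: `r2`, `n`, `undefined`
#'   matrices (rows = delta parameters, cols = endpoint parameters).
#' @export
delta_endpoint_correlation <- function(table, early_week = 1,
                                       endpoint_week = 6, baseline_week = 0,
                                       min_n = 3) {
  pars <- sort(unique(table$parameter))
  wide <- function(wk) {
    x <- dplyr::filter(table, .data$week == wk)
    tidyr::pivot_wider(x[c("subject", "parameter", "value")],
                       names_from = "parameter", values_from = "value")
  }
  w0 <- wide(baseline_week); w1 <- wide(early_week); w6 <- wide(endpoint_week)
  subj <- sort(unique(table$subject))
  getcol <- function(w, p) {
    v <- rep(NA_real_, length(subj))
    if (p %in% names(w)) v[match(w$subject, subj)] <- w[[p]]
    v
  }
  k <- length(pars)
  r2 <- nmat <- matrix(NA_real_, k, k, dimnames = list(delta = pars,
                                                       endpoint = pars))
  undef <- matrix(FALSE, k, k, dimnames = dimnames(r2))
  for (i in seq_len(k)) {
    dx <- getcol(w1, pars[i]) - getcol(w0, pars[i])
    for (j in seq_len(k)) {
      y <- getcol(w6, pars[j])
      ok <- stats::complete.cases(dx, y)
      nmat[i, j] <- sum(ok)
      if (sum(ok) < min_n || stats::sd(dx[ok]) == 0 || stats::sd(y[ok]) == 0) {
        undef[i, j] <- TRUE
        next
      }
      r2[i, j] <- stats::cor(dx[ok], y[ok])^2
    }
  }
  structure(list(r2 = r2, n = nmat, undefined = undef,
                 early_week = early_week, endpoint_week = endpoint_week),
            class = "correlation_heatmap")
}

#' Critical R-squared for a two-sided Pearson test
#'
#' `r2_crit = t^2 / (t^2 + n - 2)` with `t = qt(1 - alpha/2, n - 2)`.
#'
#' @param n number of pairs (>= 3).
#' @param alpha two-sided significance level.
#' @export
critical_r2 <- function(n, alpha = 0.01) {
  if (any(n < 3)) stop("need n >= 3")
  tc <- stats::qt(1 - alpha / 2, n - 2)
  tc^2 / (tc^2 + n - 2)
}

#' Significance masks for a correlation heatmap
#'
#' Two modes, both always reported and never merged: the fixed-threshold
#' rule (R^2 at or above `r2_fixed`, default 0.61) and the analytic rule
#' (R^2 at or above the critical value of the two-sided Pearson test at
#' `alpha` with the per-cell n). Undefined cells are FALSE in both masks.
#'
#' @param heatmap a [delta_endpoint_correlation()] result.
#' @param alpha two-sided level for the analytic mask (default 0.01).
#' @param r2_fixed fixed threshold (default 0.61).
#' @return list with logical matrices `fixed` and `analytic`, plus
#'   `r2_critical` (per-cell analytic thresholds) and `r2_fixed`.
#' @export
significance_mask <- function(heatmap, alpha = 0.01, r2_fixed = 0.61) {
  stopifnot(inherits(heatmap, "correlation_heatmap"))
  n <- heatmap$n
  if (any(n[!heatmap$undefined] < 3)) stop("need n >= 3 in defined cells")
  r2c <- matrix(NA_real_, nrow(n), ncol(n), dimnames = dimnames(n))
  ok <- !heatmap$undefined & n >= 3
  r2c[ok] <- critical_r2(n[ok], alpha)
  fixed <- !is.na(heatmap$r2) & heatmap$r2 >= r2_fixed
  analytic <- !is.na(heatmap$r2) & !is.na(r2c) & heatmap$r2 >= r2c
  list(fixed = fixed, analytic = analytic, r2_critical = r2c,
       r2_fixed = r2_fixed, alpha = alpha)
}

#' Groupwise longitudinal comparison of one parameter
#'
#' Two-way analysis of variance (group x week, both factors) plus per-week
#' two-group contrasts with Bonferroni adjustment
#' (`p_adj = min(1, m * p_raw)` over the m weeks tested). A Wilcoxon
#' rank-sum alternative is available for non-normal data.
#'
#' @param table a [build_cohort_table()] table.
#' @param parameter parameter to compare.
#' @param test `"ttest"` (default) or `"wilcoxon"` for the per-week contrasts.
#' @return list with `anova` (the aov summary table) and `per_week`
#'   (data.frame week, p_raw, p_adj).
#' @export
group_compare <- function(table, parameter, test = c("ttest", "wilcoxon")) {
  test <- match.arg(test)
  x <- dplyr::filter(table, .data$parameter == !!parameter)
  if (length(unique(x$group)) < 2)
    stop("need both groups to compare")
  x$group <- factor(x$group)
  x$weekf <- factor(x$week)
  fit <- stats::aov(value ~ group * weekf, data = x)
  weeks <- sort(unique(x$week))
  weeks <- weeks[vapply(weeks, function(w) {
    g <- x$group[x$week == w]
    length(unique(g)) == 2
  }, logical(1))]
  m <- length(weeks)
  praw <- vapply(weeks, function(w) {
    xa <- x$value[x$week == w & x$group == levels(x$group)[1]]
    xb <- x$value[x$week == w & x$group == levels(x$group)[2]]
    if (test == "ttest") {
      if (stats::sd(c(xa, xb)) == 0) return(1)
      stats::t.test(xa, xb)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    }
  }, numeric(1))
  data.frame(week = weeks, p_raw = praw,
             p_adj = pmin(1, m * praw)) -> per_week
  list(anova = summary(fit), per_week = per_week)
}

#' Simulate a null cohort (independent standard-normal parameters)
#'
#' Every (subject, week, parameter) value is an independent N(0, 1) draw —
#' the null world for calibrating the correlation heatmap's significance
#' masks.
#'
#' @param seed RNG seed.
#' @param n_subjects number of subjects (default 12).
#' @param parameters parameter names.
#' @param weeks weeks recorded (default `c(0, 1, 6)`).
#' @param group group label applied to all subjects.
#' @return a `cohort_table`.
#' @export
simulate_null_cohort <- function(seed = 1, n_subjects = 12,
                                 parameters = c("mean_suv", "mrglu",
                                                "vessel_volume"),
                                 weeks = c(0, 1, 6), group = "SUNI") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- expand.grid(subject = paste0("m", seq_len(n_subjects)),
                   week = weeks, parameter = parameters,
                   stringsAsFactors = FALSE)
  g$group <- group
  g$value <- stats::rnorm(nrow(g))
  build_cohort_table(g[c("subject", "group", "week", "parameter", "value")])
}
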