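#' Normality-gated matched-samples omnibus test
#'
#' Applies the testing battery used for comparing a morphometric measure
#' across ROM levels: each level (column) is screened with a Shapiro-Wilk
#' test; if every level passes at `alpha`, a one-way repeated-measures ANOVA
#' is run, otherwise a Friedman test. The normality gate uses the
#' all-levels-must-pass rule with no multiplicity correction (configurable
#' via `gate`). Degenerate tables in which every subject is constant across
#' levels have no within-subject variance and are routed to the (rank-based)
#' Friedman test, which returns statistic 0 and p = 1.
#'
#' @param mat Numeric matrix or data frame, subjects x ROM levels; at least
#'   3 subjects and 3 levels, no missing cells.
#' @param alpha Significance level (default 0.05), used both for the
#'   normality gate and the reported decision.
#' @param gate `"all"` (every level must pass Shapiro-Wilk) or `"none"`
#'   (skip the gate and always use the ANOVA).
#' @return An object of class `test_report`: test name, statistic, degrees of
#'   freedom, p value, n, the normality screen per level, and the decision at
#'   `alpha`.
#' @export
choose_and_run_omnibus <- function(mat, alpha = 0.05, gate = c("all", "none")) {
  gate <- match.arg(gate)
  mat <- as.matrix(mat)
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)
    stop("missing cells: ", paste(sprintf("[%d,%d]", miss[, 1], miss[, 2]),
                                  collapse = " "), call. = FALSE)
  }
  n_sub <- nrow(mat); n_lev <- ncol(mat)
  if (n_lev < 3 || n_sub < 3)
    stop("need at least 3 subjects and 3 levels", call. = FALSE)
  sw <- lapply(seq_len(n_lev), function(j) {
    tryCatch(stats::shapiro.test(mat[, j]),
             error = function(e) list(statistic = NA_real_, p.value = 0))
  })
  normality <- data.frame(level = seq_len(n_lev),
                          W = vapply(sw, function(s) unname(s$statistic), numeric(1)),
                          p = vapply(sw, function(s) s$p.value, numeric(1)))
  all_normal <- all(normality$p > alpha)
  degenerate <- all(apply(mat, 1, function(r) max(r) - min(r) < 1e-12))
  if (gate == "none" || (all_normal && !degenerate)) {
    d <- data.frame(y = as.vector(mat),
                    level = factor(rep(seq_len(n_lev), each = n_sub)),
                    subject = factor(rep(seq_len(n_sub), n_lev)))
    fit <- stats::aov(y ~ level + Error(subject), data = d)
    s <- summary(fit)[["Error: Within"]][[1]]
    report <- list(test = "repeated-measures ANOVA",
                   statistic = s["level", "F value"],
                   df = c(s["level", "Df"], s["Residuals", "Df"]),
                   p_value = s["level", "Pr(>F)"])
  } else if (degenerate) {
    # every subject fully tied across levels: the tie-corrected Friedman
    # statistic is 0/0; the table carries no evidence against the null, so
    # report the defined limit (statistic 0, p = 1)
    report <- list(test = "Friedman", statistic = 0,
                   df = n_lev - 1, p_value = 1)
  } else {
    fr <- stats::friedman.test(mat)
    report <- list(test = "Friedman",
                   statistic = unname(fr$statistic),
                   df = unname(fr$parameter),
                   p_value = fr$p.value)
  }
  structure(c(report,
              list(n = n_sub, groups = n_lev, normality = normality,
                   all_normal = all_normal, alpha = alpha,
                   significant = report$p_value < alpha)),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s\n", x$test))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g (%ssignificant at alpha = %g)\n",
              x$statistic, paste(x$df, collapse = ", "), x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  if (!is.null(x$normality))
    cat(sprintf("  normality screen: %d/%d levels pass Shapiro-Wilk\n",
                sum(x$normality$p > x$alpha), nrow(x$normality)))
  if (!is.null(x$pairwise)) {
    cat("  pairwise slope contrasts:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' ANCOVA comparison of regression slopes between conditions
#'
#' Tests homogeneity of the maximum-CSA-versus-length regression slopes
#' across conditions via the length x condition interaction in an analysis of
#' covariance, and reports pairwise slope contrasts between conditions.
#'
#' @param data Data frame with one row per observation.
#' @param x,y,condition Column names of the covariate, response and grouping
#'   factor (defaults `length_pct_L0`, `max_csa_mm2`, `condition`).
#' @param alpha Significance level (default 0.05).
#' @return A `test_report` with the interaction F test and a `pairwise` data
#'   frame of slope differences.
#' @export
compare_slopes <- function(data, x = "length_pct_L0", y = "max_csa_mm2",
                           condition = "condition", alpha = 0.05) {
  stopifnot(is.data.frame(data), all(c(x, y, condition) %in% names(data)))
  d <- data.frame(x = data[[x]], y = data[[y]], g = factor(data[[condition]]))
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$g)) < 2)
    stop("need at least 2 conditions to compare slopes", call. = FALSE)
  counts <- table(d$g)
  if (any(counts < 3)) stop("need at least 3 points per condition", call. = FALSE)
  for (lv in levels(d$g)) {
    if (stats::sd(d$x[d$g == lv]) < 1e-12)
      stop("rank-deficient covariate for condition ", lv, call. = FALSE)
  }
  full <- stats::lm(y ~ x * g, data = d)
  add <- stats::lm(y ~ x + g, data = d)
  an <- stats::anova(add, full)
  trends <- emmeans::emtrends(full, ~ g, var = "x")
  pw <- as.data.frame(emmeans::contrast(trends, method = "pairwise"))
  structure(list(test = "ANCOVA slope homogeneity (interaction)",
                 statistic = an$F[2],
                 df = c(an$Df[2], an$Res.Df[2]),
                 p_value = an$`Pr(>F)`[2],
                 n = nrow(d), groups = nlevels(d$g),
                 pairwise = pw, alpha = alpha,
                 significant = an$`Pr(>F)`[2] < alpha),
            class = "test_report")
}
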