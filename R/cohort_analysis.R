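#' Compare every metric between the two groups
#'
#' Runs a two-sided two-sample test per metric between the with-syrinx and
#' without-syrinx groups. The default is the Mann-Whitney (Wilcoxon
#' rank-sum) test, exact when the smaller group has at most 20 subjects
#' and the metric is tie-free, with the normal approximation and tie
#' correction otherwise; Student's t (Welch) is available as an
#' alternative. Metrics present in only one group (the syrinx stroke
#' volume) are skipped.
#'
#' @param cohort Cohort data.frame as produced by [make_cohort()] (columns
#'   `group` plus metrics).
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @param alpha Significance threshold recorded in the report (default
#'   0.05).
#' @return A data.frame with one row per metric: group means and SDs, the
#'   p-value, the test used and a significance flag.
#' @export
compare_groups <- function(cohort, method = c("mann_whitney", "t_test"),
                           alpha = 0.05) {
  method <- match.arg(method)
  metrics <- intersect(names(metric_labels()), names(cohort))
  g1 <- cohort$group == "CS_with_syrinx"
  g2 <- cohort$group == "CS_without_syrinx"
  if (!any(g1) || !any(g2)) stop("both groups must be non-empty")
  rows <- lapply(metrics, function(m) {
    x <- cohort[[m]][g1]; y <- cohort[[m]][g2]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) && !length(y))
      stop("metric ", m, " is missing in both groups")
    if (!length(x) || !length(y))
      return(data.frame(metric = m,
                        mean_with_syrinx = if (length(x)) mean(x) else NA,
                        sd_with_syrinx = if (length(x)) stats::sd(x) else NA,
                        mean_without_syrinx = if (length(y)) mean(y) else NA,
                        sd_without_syrinx = if (length(y)) stats::sd(y) else NA,
                        p_value = NA_real_, test = "none (one group only)",
                        significant = NA))
    if (method == "mann_whitney") {
      exact <- min(length(x), length(y)) <= 20 &&
        !any(duplicated(c(x, y)))
      tst <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
      tname <- paste0("Mann-Whitney (",
                      if (exact) "exact" else "normal approx.", ")")
    } else {
      tst <- stats::t.test(x, y)
      tname <- "Welch t-test"
    }
    data.frame(metric = m,
               mean_with_syrinx = mean(x), sd_with_syrinx = stats::sd(x),
               mean_without_syrinx = mean(y),
               sd_without_syrinx = stats::sd(y),
               p_value = unname(tst$p.value), test = tname,
               significant = unname(tst$p.value) < alpha)
  })
  do.call(rbind, rows)
}

#' Pearson correlation and linear regression between two metrics
#'
#' Signed Pearson correlation with its two-sided p-value and the ordinary
#' least-squares regression of `y` on `x`, within one group or overall.
#'
#' @param cohort Cohort data.frame (columns `group` plus metrics).
#' @param x,y Metric column names.
#' @param scope `"with_syrinx"`, `"without_syrinx"` or `"overall"`.
#' @return One-row data.frame: `metric_x`, `metric_y`, `scope`, `n`, `r`,
#'   `p_value`, `slope`, `intercept`.
#' @export
correlate <- function(cohort, x, y,
                      scope = c("overall", "with_syrinx",
                                "without_syrinx")) {
  scope <- match.arg(scope)
  keep <- switch(scope,
                 overall = rep(TRUE, nrow(cohort)),
                 with_syrinx = cohort$group == "CS_with_syrinx",
                 without_syrinx = cohort$group == "CS_without_syrinx")
  xv <- cohort[[x]][keep]; yv <- cohort[[y]][keep]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L)
    stop("need at least 3 paired observations in scope '", scope, "'")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in ", if (stats::sd(xv) == 0) x else y)
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- stats::lm(yv ~ xv)
  data.frame(metric_x = x, metric_y = y, scope = scope, n = length(xv),
             r = unname(ct$estimate), p_value = unname(ct$p.value),
             slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]))
}

.fmt_num <- function(v, digits) formatC(v, format = "f", digits = digits)

.fmt_mean_sd <- function(m, s, digits) {
  if (is.na(m)) "/" else paste0(.fmt_num(m, digits), " ± ",
                                .fmt_num(s, digits))
}

.fmt_p <- function(p) {
  if (is.na(p)) "/" else if (p < 0.01) "<0.01" else .fmt_num(p, 2)
}

.fmt_r_p <- function(row) {
  paste0(.fmt_num(row$r, 2), " (", .fmt_p(row$p_value), ")")
}

#' Publication-style summary tables of a cohort
#'
#' Renders the three study tables from a cohort: the group comparison of
#' all nine metrics (mean ± SD per group with the comparison p-value, `/`
#' where a metric does not exist in a group), the correlations of the
#' vascular stroke volume with the CSF/tonsil metrics, and the
#' correlations of the alpha factor with the arterial flow and the
#' CSF/tonsil metrics — each correlation as an `r (p)` cell per group and
#' overall.
#'
#' @param cohort Cohort data.frame.
#' @param method Group-comparison test, as in [compare_groups()].
#' @return A list of three data.frames: `group_comparison`,
#'   `sv_blood_correlations`, `alpha_correlations`.
#' @export
build_tables <- function(cohort, method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  labels <- metric_labels()
  cmp <- compare_groups(cohort, method = method)
  digits <- c(sv_csf_aqu = 0, sv_csf_fm = 0, sv_tonsils = 0,
              sv_csf_ppc = 0, sv_csf_cerv = 0, sv_syrinx = 0, cbfa = 0,
              sv_blood = 2, alpha = 2)
  t3 <- data.frame(
    `Flow Parameters` = unname(labels[cmp$metric]),
    `CS with a Syrinx` = mapply(.fmt_mean_sd, cmp$mean_with_syrinx,
                                cmp$sd_with_syrinx, digits[cmp$metric]),
    `CS without a Syrinx` = mapply(.fmt_mean_sd, cmp$mean_without_syrinx,
                                   cmp$sd_without_syrinx,
                                   digits[cmp$metric]),
    `p Value` = vapply(cmp$p_value, .fmt_p, character(1)),
    check.names = FALSE)
  rownames(t3) <- NULL

  cor_table <- function(xmetric, ymetrics) {
    rows <- lapply(ymetrics, function(m) {
      cells <- vapply(c("with_syrinx", "without_syrinx", "overall"),
                      function(sc) .fmt_r_p(correlate(cohort, xmetric, m,
                                                      scope = sc)),
                      character(1))
      data.frame(Pair = paste0(sub(" \\(.*", "", labels[xmetric]), " vs. ",
                               sub(" \\(.*", "", labels[m])),
                 `CS with a Syrinx` = cells[1],
                 `CS without a Syrinx` = cells[2],
                 `Overall CS` = cells[3], check.names = FALSE)
    })
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  }
  list(group_comparison = t3,
       sv_blood_correlations = cor_table(
         "sv_blood", c("sv_csf_fm", "sv_csf_ppc", "sv_tonsils",
                       "sv_csf_cerv")),
       alpha_correlations = cor_table(
         "alpha", c("cbfa", "sv_csf_fm", "sv_tonsils", "sv_csf_ppc",
                    "sv_csf_cerv")))
}

#' Write the summary tables as CSV and Markdown
#'
#' @param tables List from [build_tables()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    csv <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], csv, row.names = FALSE)
    md <- file.path(dir, paste0(nm, ".md"))
    tb <- tables[[nm]]
    lines <- c(paste0("| ", paste(names(tb), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(tb)), collapse = "|"),
                      "|"),
               apply(tb, 1L, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, md)
    paths <- c(paths, csv, md)
  }
  invisible(paths)
}
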