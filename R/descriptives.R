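# ---- Descriptive group comparisons ---------------------------------------

#' Compare a variable across groups
#'
#' Categorical variables get the chi-square test of independence without
#' continuity correction (a warning recommends the Fisher exact test when
#' any expected cell count falls below 1, or it can be requested
#' directly); ordinal/continuous variables get the tie-corrected
#' Kruskal-Wallis test. Rows with a missing value or group are excluded
#' per variable.
#'
#' @param data Data frame.
#' @param variable Column name to compare.
#' @param grouping Column name of the grouping factor.
#' @param test `"auto"`, `"chi_square"`, `"fisher"` or `"kruskal_wallis"`.
#' @return Object of class `group_comparison`: list with `variable`,
#'   `test`, `statistic`, `p`, `n`, and `summary` (per-group counts and
#'   percentages, or medians and IQRs).
#' @export
compare_groups <- function(data, variable, grouping,
                           test = c("auto", "chi_square", "fisher",
                                    "kruskal_wallis")) {
  test <- match.arg(test)
  x <- data[[variable]]
  g <- data[[grouping]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(factor(g[ok]))
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  categorical <- is.character(x) || is.factor(x) || is.logical(x)
  if (test == "auto") {
    test <- if (categorical) "chi_square" else "kruskal_wallis"
  }
  if (test %in% c("chi_square", "fisher")) {
    tab <- table(factor(x), g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (test == "chi_square" && any(expected < 1)) {
      warning("expected cell count below 1 for '", variable,
              "'; consider test = \"fisher\"")
    }
    res <- if (test == "fisher") {
      ft <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 8,
                               B = 10000)
      list(statistic = NA_real_, p = ft$p.value)
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      list(statistic = unname(ct$statistic), p = ct$p.value)
    }
    pct <- prop.table(tab, 2) * 100
    summ <- data.frame(level = rep(rownames(tab), ncol(tab)),
                       group = rep(colnames(tab), each = nrow(tab)),
                       n = as.vector(tab), pct = as.vector(pct))
  } else {
    kt <- kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic), p = kt$p.value)
    summ <- do.call(rbind, lapply(levels(g), function(lv) {
      xi <- x[g == lv]
      q <- quantile(xi, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(group = lv, median = q[2], q1 = q[1], q3 = q[3],
                 n = length(xi))
    }))
  }
  structure(list(variable = variable, grouping = grouping, test = test,
                 statistic = res$statistic, p = res$p, n = length(x),
                 summary = summ),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$variable, " by ", x$grouping, ": ", x$test,
      if (!is.na(x$statistic)) paste0(" statistic = ",
                                      format(x$statistic, digits = 4)),
      ", p = ", format.pval(x$p, digits = 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

fmt_n_pct <- function(n, pct) sprintf("%d (%.0f%%)", n, pct)

#' Descriptive table by group
#'
#' Builds a publication-style descriptive table: one row per variable (or
#' variable level), columns for the overall sample and each group showing
#' `n (%)` for categorical variables or `median (Q1, Q3)` for continuous
#' ones, with the group-comparison p-value on the variable's first row.
#'
#' @param data Data frame containing the variables and grouping column.
#' @param variables Character vector of column names to summarise.
#' @param grouping Grouping column name.
#' @return Data frame (class `descriptive_table`) with columns `variable`,
#'   `level`, `overall`, one column per group level, `test` and `p`.
#' @export
describe_by_group <- function(data, variables, grouping) {
  g_all <- factor(data[[grouping]])
  groups <- levels(droplevels(g_all[!is.na(g_all)]))
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    cmp <- compare_groups(data, v, grouping)
    categorical <- is.character(x) || is.factor(x) || is.logical(x)
    if (categorical) {
      lv <- levels(factor(x))
      first <- TRUE
      for (l in lv) {
        n_all <- sum(x == l, na.rm = TRUE)
        pct_all <- 100 * n_all / sum(!is.na(x))
        cells <- vapply(groups, function(gr) {
          sel <- g_all == gr & !is.na(g_all) & !is.na(x)
          fmt_n_pct(sum(x[sel] == l), 100 * mean(x[sel] == l))
        }, character(1))
        rows[[length(rows) + 1]] <- c(
          variable = v, level = l, overall = fmt_n_pct(n_all, pct_all),
          setNames(cells, groups),
          test = if (first) cmp$test else "",
          p = if (first) format.pval(cmp$p, digits = 3, eps = 1e-3) else "")
        first <- FALSE
      }
    } else {
      fmt_med <- function(xi) {
        q <- quantile(xi[!is.na(xi)], c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.3g (%.3g, %.3g)", q[2], q[1], q[3])
      }
      cells <- vapply(groups, function(gr)
        fmt_med(x[g_all == gr & !is.na(g_all)]), character(1))
      rows[[length(rows) + 1]] <- c(
        variable = v, level = "", overall = fmt_med(x),
        setNames(cells, groups), test = cmp$test,
        p = format.pval(cmp$p, digits = 3, eps = 1e-3))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' Printed-count prevalence recomputation
#'
#' Recomputes percentage prevalences from a table of published counts: for
#' each row the share is `100 * numerator / (cohort_n - n_missing)`, the
#' convention used when a table footnotes per-variable missing counts.
#'
#' @param counts Data frame with columns `measure`, `numerator`,
#'   `n_missing` and optionally `denominator` (overrides
#'   `cohort_n - n_missing` for shares of a subgroup).
#' @param cohort_n Total cohort size.
#' @return The input with columns `denominator` and `percent` filled in.
#' @export
prevalence_from_counts <- function(counts, cohort_n) {
  den <- ifelse(is.na(counts$denominator) | counts$denominator <= 0,
                cohort_n - counts$n_missing, counts$denominator)
  counts$denominator <- den
  counts$percent <- 100 * counts$numerator / den
  counts
}
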