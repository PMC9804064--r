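#' Shapiro-Wilk normality annotation
#'
#' Thin wrapper around [stats::shapiro.test()]; used to annotate, never to
#' gate, the nonparametric pipeline.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3) stop("Shapiro-Wilk needs n >= 3")
  if (stats::sd(values) == 0) stop("zero variance: Shapiro-Wilk undefined")
  r <- stats::shapiro.test(values)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples are at most `exact_threshold` and
#' tie-free; otherwise the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact_threshold largest per-group size for the exact test.
#' @return two-sided p-value.
#' @export
wilcoxon_ranksum <- function(a, b, exact_threshold = 10) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= exact_threshold &&
    length(b) <= exact_threshold
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg FDR adjustment with family bookkeeping
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1,
#' computed independently within each family (e.g. the seven class-wise tests
#' of one indicator, or the k(k-1) syntax cells).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param family optional factor/vector of family ids; `NULL` treats all p as
#'   one family.
#' @return adjusted p-values in the input order.
#' @export
fdr_bh <- function(p, family = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  out <- p
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

group_summary_row <- function(x) {
  c(median = stats::median(x), mean = mean(x), sd = stats::sd(x))
}

#' Two-group comparison of microstate indicators and syntax cells
#'
#' For each of the three indicators (duration, coverage, occurrence) a
#' Wilcoxon rank-sum test per class, Benjamini-Hochberg adjusted within that
#' indicator's k-test family; optionally a Wilcoxon per syntax cell,
#' BH-adjusted across the k(k-1) off-diagonal cells.  Both raw and adjusted
#' p-values are always reported.
#'
#' @param stats_table data frame with columns `scan_id`, `group`, `class`,
#'   `duration_ms`, `coverage`, `occurrence` (one row per scan and class, as
#'   produced by [cohort_stats_table()]).
#' @param syntax optional list of per-scan `"syntax_matrix"` objects aligned
#'   with a `syntax_group` vector of group labels.
#' @param syntax_group group label per element of `syntax`.
#' @param alpha significance level for the `flag` column.
#' @return data frame of class `"cohort_comparison"`: `family`, `indicator`,
#'   `class` (or `"i->j"` cell), per-group median/mean/sd, `p_raw`, `p_fdr`,
#'   `flag_raw`, `flag_fdr`.
#' @export
compare_cohorts <- function(stats_table, syntax = NULL, syntax_group = NULL,
                            alpha = 0.05) {
  groups <- sort(unique(stats_table$group))
  if (length(groups) != 2) stop("need exactly 2 groups, got ",
                                length(groups))
  n_scans <- vapply(groups, function(g)
    length(unique(stats_table$scan_id[stats_table$group == g])), 0L)
  if (any(n_scans < 2)) stop("each group needs >= 2 scans")
  rows <- list()
  for (ind in c("duration_ms", "coverage", "occurrence")) {
    for (cl in sort(unique(stats_table$class))) {
      sub <- stats_table[stats_table$class == cl, ]
      a <- sub[[ind]][sub$group == groups[1]]
      b <- sub[[ind]][sub$group == groups[2]]
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      p <- if (length(a) >= 2 && length(b) >= 2)
        wilcoxon_ranksum(a, b) else NA_real_
      sa <- group_summary_row(a)
      sb <- group_summary_row(b)
      rows[[length(rows) + 1L]] <- data.frame(
        family = ind, indicator = ind, class = as.character(cl),
        median_1 = sa[["median"]], mean_1 = sa[["mean"]], sd_1 = sa[["sd"]],
        median_2 = sb[["median"]], mean_2 = sb[["mean"]], sd_2 = sb[["sd"]],
        p_raw = p)
    }
  }
  if (!is.null(syntax)) {
    stopifnot(length(syntax) == length(syntax_group))
    k <- nrow(syntax[[1]]$probs)
    probs <- lapply(syntax, `[[`, "probs")
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      v <- vapply(probs, function(m) m[i, j], 0)
      a <- v[syntax_group == groups[1]]
      b <- v[syntax_group == groups[2]]
      sa <- group_summary_row(a)
      sb <- group_summary_row(b)
      rows[[length(rows) + 1L]] <- data.frame(
        family = "syntax", indicator = "transition_prob",
        class = sprintf("%d->%d", i, j),
        median_1 = sa[["median"]], mean_1 = sa[["mean"]], sd_1 = sa[["sd"]],
        median_2 = sb[["median"]], mean_2 = sb[["mean"]], sd_2 = sb[["sd"]],
        p_raw = wilcoxon_ranksum(a, b))
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p_raw, out$family)
  out$flag_raw <- !is.na(out$p_raw) & out$p_raw < alpha
  out$flag_fdr <- !is.na(out$p_fdr) & out$p_fdr < alpha
  names(out)[names(out) == "median_1"] <- paste0("median_", groups[1])
  names(out)[names(out) == "median_2"] <- paste0("median_", groups[2])
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  names(out)[names(out) == "sd_1"] <- paste0("sd_", groups[1])
  names(out)[names(out) == "sd_2"] <- paste0("sd_", groups[2])
  class(out) <- c("cohort_comparison", "data.frame")
  rownames(out) <- NULL
  out
}

#' Tidy per-scan, per-class statistics table for a cohort
#'
#' Stacks [class_stats()] results from many scans into the long table
#' consumed by [compare_cohorts()].
#'
#' @param sequences list of `"state_sequence"` objects.
#' @param groups group label per sequence.
#' @param scan_ids optional scan identifiers.
#' @param k number of classes.
#' @param ... passed to [class_stats()].
#' @return data frame: `scan_id`, `group`, `class`, `duration_ms`,
#'   `coverage`, `occurrence`.
#' @export
cohort_stats_table <- function(sequences, groups, scan_ids = NULL, k = NULL,
                               ...) {
  stopifnot(length(sequences) == length(groups))
  if (is.null(scan_ids)) scan_ids <- sprintf("scan%03d", seq_along(sequences))
  do.call(rbind, lapply(seq_along(sequences), function(i) {
    st <- class_stats(sequences[[i]], k = k, ...)
    cbind(data.frame(scan_id = scan_ids[i], group = groups[i]),
          st$per_class[, c("class", "duration_ms", "coverage", "occurrence")])
  }))
}

#' Demographic summary table with between-group tests
#'
#' Mirrors the usual clinical "Table 1": for categorical variables, counts
#' with percentages (1 decimal) overall and per group with a chi-square test
#' (Fisher's exact test when any expected cell is below 5); for continuous
#' variables, mean (SD, 1 decimal) with a Welch t-test (or Wilcoxon).
#' Columns other than `scan_id` and `group` are summarized by type:
#' character/factor as categorical, numeric as continuous.
#'
#' @param demographics data frame with `scan_id`, `group`, and covariate
#'   columns.
#' @param continuous_test `"t"` (Welch, default) or `"wilcoxon"`.
#' @return an object of class `"cohort_summary"`: data frame with columns
#'   `variable`, `level`, `all`, one column per group, `p`.
#' @export
summarize_cohort <- function(demographics, continuous_test = c("t",
                                                               "wilcoxon")) {
  continuous_test <- match.arg(continuous_test)
  stopifnot(all(c("scan_id", "group") %in% names(demographics)))
  if (anyNA(demographics$group)) stop("unknown (NA) group label")
  groups <- sort(unique(as.character(demographics$group)))
  vars <- setdiff(names(demographics), c("scan_id", "group"))
  fmt_n <- function(n, tot) sprintf("%d (%.1f%%)", n, 100 * n / tot)
  rows <- list()
  for (v in vars) {
    x <- demographics[[v]]
    if (is.numeric(x)) {
      p <- if (continuous_test == "t")
        stats::t.test(x ~ demographics$group)$p.value
      else wilcoxon_ranksum(x[demographics$group == groups[1]],
                            x[demographics$group == groups[2]])
      row <- data.frame(variable = v, level = "mean (SD)",
                        all = sprintf("%.1f (%.1f)", mean(x), stats::sd(x)))
      for (g in groups) {
        xg <- x[demographics$group == g]
        row[[g]] <- sprintf("%.1f (%.1f)", mean(xg), stats::sd(xg))
      }
      row$p <- sprintf("%.3f", p)
      rows[[length(rows) + 1L]] <- row
    } else {
      lv <- if (is.factor(x)) levels(x) else sort(unique(x))
      tab <- table(factor(x, levels = lv), demographics$group)
      ttab <- tab[rowSums(tab) > 0, , drop = FALSE]  # test on observed levels
      expected <- outer(rowSums(ttab), colSums(ttab)) / sum(ttab)
      p <- if (any(expected < 5)) stats::fisher.test(ttab)$p.value
           else stats::chisq.test(ttab, correct = FALSE)$p.value
      head_row <- data.frame(variable = v, level = "", all = "")
      for (g in groups) head_row[[g]] <- ""
      head_row$p <- sprintf("%.3f", p)
      rows[[length(rows) + 1L]] <- head_row
      for (lv in rownames(tab)) {
        n_all <- sum(tab[lv, ])
        row <- data.frame(variable = "", level = lv,
                          all = fmt_n(n_all, nrow(demographics)))
        for (g in groups)
          row[[g]] <- fmt_n(tab[lv, g], sum(demographics$group == g))
        row$p <- ""
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, right = FALSE)
  invisible(x)
}
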