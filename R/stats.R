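#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA assuming equal variances, as used for the
#' per-metric group comparisons. Thin wrapper around
#' [stats::oneway.test()] (`var.equal = TRUE`) returning a tidy one-row
#' tibble.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor), >= 2 levels with >= 2
#'   observations each.
#' @return Tibble with `F`, `df_between`, `df_within`, `p`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # F = 13.5
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (!all(is.finite(values))) {
    abort("values must be finite", class = "tremorkit_data_error")
  }
  sizes <- table(groups)
  if (length(sizes) < 2) {
    abort("need at least two groups", class = "tremorkit_usage_error")
  }
  if (any(sizes < 2)) {
    abort(sprintf("every group needs n >= 2 (got: %s)",
                  paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")),
          class = "tremorkit_usage_error")
  }
  wvar <- tapply(values, groups, var)
  if (all(wvar == 0)) {
    if (var(values) == 0) {
      abort("all values identical across groups: ANOVA undefined",
            class = "tremorkit_degenerate_error")
    }
    # zero within-group variance but distinct means: report a clean infinite F
    return(tibble(F = Inf, df_between = length(sizes) - 1,
                  df_within = length(values) - length(sizes), p = 0))
  }
  ow <- oneway.test(values ~ groups, var.equal = TRUE)
  tibble(F = unname(ow$statistic),
         df_between = unname(ow$parameter[1]),
         df_within = unname(ow$parameter[2]),
         p = unname(ow$p.value))
}

group_comparison <- function(data, value, group_col, alpha) {
  lv <- levels(factor(data[[group_col]]))
  st <- data %>%
    group_by(.data[[group_col]]) %>%
    summarise(n = dplyr::n(), mean = mean(.data[[value]]),
              sd = sd(.data[[value]]), .groups = "drop")
  aov_row <- one_way_anova(data[[value]], data[[group_col]])
  tibble(
    n1 = st$n[st[[group_col]] == lv[1]], mean1 = st$mean[st[[group_col]] == lv[1]],
    sd1 = st$sd[st[[group_col]] == lv[1]],
    n2 = st$n[st[[group_col]] == lv[2]], mean2 = st$mean[st[[group_col]] == lv[2]],
    sd2 = st$sd[st[[group_col]] == lv[2]],
    F = aov_row$F, df_between = aov_row$df_between,
    df_within = aov_row$df_within, p = aov_row$p
  )
}

comparison_result <- function(tbl, alpha, labels) {
  tbl <- tbl %>%
    mutate(p_bh = p.adjust(.data$p, method = "BH"),  # extension; headline
           # significance uses the raw per-test p at alpha
           significant = .data$p < alpha)
  structure(tbl, alpha = alpha, group_labels = labels,
            class = c("tremor_comparison", class(tibble())))
}

#' Compare tremor metrics between patients and controls
#'
#' Runs, for every combination of the twelve tremor metrics, body side and
#' arm segment present in the feature table, a one-way ANOVA of PD versus
#' CO. With the full design this yields 12 metrics x 2 sides x 3 segments =
#' 72 tests, mirroring the per-segment cohort comparison tables of a
#' clinical tremor study. Sides are analysed separately (left vs left,
#' right vs right). Raw per-test p-values drive the significance flag; a
#' Benjamini-Hochberg column (`p_bh`) is reported alongside as an extension
#' and never used for the flags.
#'
#' @param features per-subject feature table from [extract_features()],
#'   with a `group` column containing both `"PD"` and `"CO"`.
#' @param alpha significance level (default 0.05).
#' @return A `tremor_comparison` tibble: one row per (metric, side,
#'   segment) with group sizes, means, SDs, `F`, `p`, `p_bh` and
#'   `significant`. Group 1 is CO, group 2 is PD.
#' @export
compare_pd_vs_co <- function(features, alpha = 0.05) {
  features <- as_tibble(features)
  if (!"group" %in% names(features) ||
      !all(c("PD", "CO") %in% features$group)) {
    abort("feature table must contain both PD and CO groups",
          class = "tremorkit_usage_error")
  }
  metrics <- intersect(feature_metrics(), names(features))
  cells <- features %>% distinct(.data$side, .data$segment)
  out <- purrr::pmap_dfr(cells, function(side, segment) {
    sub <- features[features$side == side & features$segment == segment, ]
    purrr::map_dfr(metrics, function(mname) {
      bind_cols(tibble(metric = mname, side = side, segment = segment),
                group_comparison(sub, mname, "group", alpha))
    })
  })
  comparison_result(out, alpha, labels = c("CO", "PD"))
}

#' Compare tremor metrics between clinical-score strata within patients
#'
#' Within the PD group, compares sides scored 0 versus 1 on the per-side
#' clinical tremor item (UPDRS item 21) for one body side: left-0 versus
#' left-1 or right-0 versus right-1, per metric and segment. Sides scored
#' above 1 are excluded with a warning (the stratified comparison is
#' defined for scores 0 and 1 only).
#'
#' @param features per-subject feature table restricted to (or containing)
#'   PD subjects, with an `updrs21` column.
#' @param side `"left"` or `"right"`.
#' @param alpha significance level.
#' @return A `tremor_comparison` tibble, one row per (metric, segment).
#'   Group 1 is score 0, group 2 is score 1.
#' @export
compare_updrs <- function(features, side = c("right", "left"), alpha = 0.05) {
  side <- match.arg(side)
  features <- as_tibble(features)
  if ("group" %in% names(features)) {
    features <- features %>% filter(.data$group == "PD")
  }
  sub <- features %>% filter(.data$side == !!side, !is.na(.data$updrs21))
  if (any(sub$updrs21 > 1)) {
    dropped <- unique(sub$subject_id[sub$updrs21 > 1])
    warn(sprintf("excluding %d side(s) with updrs21 > 1 (%s): stratified comparison uses scores 0 and 1 only",
                 length(dropped), paste(dropped, collapse = ", ")))
    sub <- sub %>% filter(.data$updrs21 <= 1)
  }
  present <- sort(unique(sub$updrs21))
  if (!all(c(0, 1) %in% present)) {
    abort(sprintf("%s side: need both score levels 0 and 1 (present: %s)",
                  side, paste(present, collapse = ", ")),
          class = "tremorkit_stratification_error")
  }
  n_strata <- table(factor(sub$updrs21[!duplicated(sub$subject_id)],
                           levels = c(0, 1)))
  if (any(n_strata < 2)) {
    abort(sprintf("%s side: need n >= 2 subjects per score level (got 0: %d, 1: %d)",
                  side, n_strata[1], n_strata[2]),
          class = "tremorkit_usage_error")
  }
  metrics <- intersect(feature_metrics(), names(sub))
  segments <- unique(sub$segment)
  out <- purrr::map_dfr(segments, function(seg) {
    cell <- sub[sub$segment == seg, ]
    purrr::map_dfr(metrics, function(mname) {
      bind_cols(tibble(metric = mname, side = side, segment = seg),
                group_comparison(cell, mname, "updrs21", alpha))
    })
  })
  side_lab <- paste0(toupper(substring(side, 1, 1)), substring(side, 2))
  comparison_result(out, alpha, labels = sprintf("%s %d", side_lab, 0:1))
}

#' @export
print.tremor_comparison <- function(x, ...) {
  lab <- attr(x, "group_labels")
  cat(sprintf("<tremor_comparison: %s vs %s, %d tests, alpha = %g, %d significant>\n",
              lab[1], lab[2], nrow(x), attr(x, "alpha"), sum(x$significant)))
  NextMethod()
}

#' Tidy and summarise comparison results
#'
#' `tidy()` returns the comparison table as a plain tibble (one row per
#' test); `glance()` returns a one-row summary with the number of tests,
#' the number significant, and the significance level.
#'
#' @param x a `tremor_comparison`.
#' @param ... unused.
#' @export
tidy.tremor_comparison <- function(x, ...) {
  as_tibble(unclass_comparison(x))
}

#' @rdname tidy.tremor_comparison
#' @export
glance.tremor_comparison <- function(x, ...) {
  lab <- attr(x, "group_labels")
  tibble(groups = paste(lab, collapse = " vs "), n_tests = nrow(x),
         n_significant = sum(x$significant),
         prop_significant = mean(x$significant), alpha = attr(x, "alpha"))
}

unclass_comparison <- function(x) {
  class(x) <- setdiff(class(x), "tremor_comparison")
  attr(x, "alpha") <- NULL
  attr(x, "group_labels") <- NULL
  x
}

#' Render comparison tables for reporting
#'
#' Formats a comparison as a publication-style summary: `mean +/- SD` per
#' group to three decimals, with significant rows marked `*`. Use
#' [readr::write_csv()] on the result, or `format = "text"` for an aligned
#' plain-text table.
#'
#' @param comparisons a `tremor_comparison`.
#' @param format `"tibble"` (default) or `"text"` (single character string).
#' @return A tibble (or character scalar) with columns `metric`, `side`,
#'   `segment`, one formatted column per group, `F`, `p`, `sig`.
#' @export
render_summary_tables <- function(comparisons, format = c("tibble", "text")) {
  format <- match.arg(format)
  if (is.null(comparisons) || nrow(comparisons) == 0) {
    abort("no comparisons to render", class = "tremorkit_usage_error")
  }
  lab <- attr(comparisons, "group_labels") %||% c("group1", "group2")
  fmt <- function(m, s) sprintf("%.3f ± %.3f", m, s)
  out <- tibble(
    metric = comparisons$metric, side = comparisons$side,
    segment = comparisons$segment,
    g1 = paste0(fmt(comparisons$mean1, comparisons$sd1),
                sprintf(" (n=%d)", comparisons$n1)),
    g2 = paste0(fmt(comparisons$mean2, comparisons$sd2),
                sprintf(" (n=%d)", comparisons$n2)),
    F = round(comparisons$F, 3), p = signif(comparisons$p, 3),
    sig = ifelse(comparisons$significant, "*", "")
  )
  names(out)[names(out) == "g1"] <- lab[1]
  names(out)[names(out) == "g2"] <- lab[2]
  if (format == "text") {
    mat <- rbind(names(out), as.matrix(format(as.data.frame(out))))
    widths <- apply(nchar(mat), 2, max)
    lines <- apply(mat, 1, function(row)
      paste(mapply(formatC, row, width = widths), collapse = "  "))
    return(paste(lines, collapse = "\n"))
  }
  out
}
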