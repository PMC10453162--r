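#' Pearson correlation with t-based p-value
#'
#' Correlates a predictor (e.g. E-cadherin gray levels per cell line) with a
#' response (CIC rates). The p-value is the standard two-sided t test on
#' `r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return A list of class `cic_correlation`: `r`, `p`, `n`, and a `note`
#'   when the correlation is undefined (zero variance in x or y), in which
#'   case `r` and `p` are `NA` rather than NaN.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          note = "undefined: zero variance"),
                     class = "cic_correlation"))
  r <- stats::cor(x, y)
  p <- if (1 - r^2 < .Machine$double.eps) 0
       else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  structure(list(r = r, p = p, n = n, note = NULL), class = "cic_correlation")
}

#' @export
print.cic_correlation <- function(x, ...) {
  if (!is.null(x$note)) cat("correlation", x$note, sprintf("(n = %d)\n", x$n))
  else cat(sprintf("Pearson r = %.3f, %s, n = %d\n", x$r, format_p(x$p), x$n))
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) "p not calculated"
  else if (p < 0.001) "p < 0.001"
  else sprintf("p = %.3f", p)
}

#' Compare CIC rates between two culture conditions, paired by cell line
#'
#' Paired two-sided test of per-line CIC rates (e.g. adherent vs
#' suspension). Pairing by line is the natural design when each line was
#' measured under both conditions. Lines missing one condition (e.g. a line
#' that could not be adherently cultured) are dropped with a message. The
#' default is the paired t test; a Wilcoxon signed-rank alternative is
#' available.
#'
#' @param a,b per-line rates under the two conditions, same order.
#' @param lines optional line labels (used in the dropped-pairs message).
#' @param method `"t"` (paired t test) or `"wilcoxon"` (signed rank).
#' @return A list of class `cic_comparison`: `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `p`, `statistic`, `test_name`, `paired = TRUE`, `n_pairs`,
#'   `dropped`.
#' @export
compare_conditions <- function(a, b, lines = NULL, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b lengths differ", call. = FALSE)
  if (is.null(lines)) lines <- as.character(seq_along(a))
  keep <- is.finite(a) & is.finite(b)
  dropped <- lines[!keep]
  if (length(dropped))
    message("dropping line(s) missing one condition: ",
            paste(dropped, collapse = ", "))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L)
    stop("need at least 2 complete pairs for a paired comparison", call. = FALSE)
  d <- a - b
  if (method == "t") {
    test_name <- "paired t-test"
    if (stats::sd(d) == 0) {
      # degenerate: identical differences; no variance for the t statistic
      p <- if (all(d == 0)) 1 else 0
      statistic <- if (all(d == 0)) 0 else Inf * sign(mean(d))
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      p <- tt$p.value; statistic <- unname(tt$statistic)
    }
  } else {
    test_name <- "Wilcoxon signed-rank test"
    if (all(d == 0)) { p <- 1; statistic <- 0 }
    else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
      p <- wt$p.value; statistic <- unname(wt$statistic)
    }
  }
  structure(list(mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b),
                 p = p, statistic = statistic, test_name = test_name,
                 paired = TRUE, n_pairs = length(a), dropped = dropped),
            class = "cic_comparison")
}

#' @export
print.cic_comparison <- function(x, ...) {
  cat(sprintf("%s on %d pairs: %.1f +/- %.1f vs %.1f +/- %.1f, %s\n",
              x$test_name, x$n_pairs, x$mean_a, x$sd_a, x$mean_b, x$sd_b,
              format_p(x$p)))
  invisible(x)
}

#' Pairwise group comparisons with the minimum-n significance gate
#'
#' Computes two-sided Welch t tests of CIC/mm^2 between every pair of groups
#' in which both groups have at least 5 samples; for smaller groups the
#' p-value is marked "not calculated" rather than computed. Empty groups are
#' excluded entirely.
#'
#' @param summaries per-sample summaries (tissue mode).
#' @param group_key grouping column, as in [aggregate_groups()].
#' @return A data frame of group pairs: `group1`, `group2`, `n1`, `n2`, `p`
#'   (`NA` when gated), `calculated` flag, `test_name`.
#' @export
gate_significance <- function(summaries, group_key) {
  g <- as.character(summaries[[group_key]])
  g[is.na(g)] <- "unknown"
  groups <- sort(unique(g))
  groups <- groups[vapply(groups, function(gr) sum(g == gr) > 0, logical(1))]
  if (length(groups) < 2L)
    return(data.frame(group1 = character(0), group2 = character(0),
                      n1 = integer(0), n2 = integer(0), p = numeric(0),
                      calculated = logical(0), test_name = character(0)))
  rows <- list()
  for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
    x <- summaries$cic_per_mm2[g == groups[i]]
    y <- summaries$cic_per_mm2[g == groups[j]]
    eligible <- length(x) >= MIN_GROUP_FOR_SIGNIFICANCE &&
      length(y) >= MIN_GROUP_FOR_SIGNIFICANCE
    p <- NA_real_
    if (eligible) {
      p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        if (mean(x) == mean(y)) 1 else 0
      } else stats::t.test(x, y)$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = groups[i], group2 = groups[j],
      n1 = length(x), n2 = length(y), p = p, calculated = eligible,
      test_name = if (eligible) "Welch t-test" else "not calculated",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a self-contained analysis report
#'
#' Writes a markdown report plus a CSV bundle: per-line rates and the
#' condition comparison (fluorescence part), and stage/score group tables
#' with gated significance (tissue part). Either part may be absent. Output
#' is deterministic - identical inputs give byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param cell_lines optional data frame (`line`, `n_viable`, `n_dead`,
#'   `n_cic`, `condition`).
#' @param condition_comparison optional `cic_comparison`.
#' @param correlation optional `cic_correlation`.
#' @param group_tables optional named list of [aggregate_groups()] outputs.
#' @param significance_tables optional named list of [gate_significance()]
#'   outputs.
#' @param score_table optional [score_distribution()] output.
#' @return Invisibly, the path of the markdown report.
#' @export
build_report <- function(out_dir, cell_lines = NULL,
                         condition_comparison = NULL, correlation = NULL,
                         group_tables = NULL, significance_tables = NULL,
                         score_table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lines_md <- c("# Cell-in-cell quantification report", "")
  n_tests <- 0L
  if (!is.null(cell_lines)) {
    cl <- cell_lines[order(cell_lines$condition, cell_lines$line), ]
    cl$cic_rate_percent <- round(cic_rate(cl$n_cic, cl$n_viable), 4)
    utils::write.csv(cl, file.path(out_dir, "cell_lines.csv"),
                     row.names = FALSE, quote = FALSE)
    lines_md <- c(lines_md, "## Per-line CIC rates", "",
                  sprintf("- %s (%s): %d CIC / %d viable = %.1f%%",
                          cl$line, cl$condition, cl$n_cic, cl$n_viable,
                          cl$cic_rate_percent), "")
  }
  if (!is.null(condition_comparison)) {
    x <- condition_comparison
    n_tests <- n_tests + 1L
    lines_md <- c(lines_md, "## Condition comparison", "",
                  sprintf("%s on %d pairs: %.1f +/- %.1f%% vs %.1f +/- %.1f%%, %s",
                          x$test_name, x$n_pairs, x$mean_a, x$sd_a,
                          x$mean_b, x$sd_b, format_p(x$p)), "")
  }
  if (!is.null(correlation)) {
    n_tests <- n_tests + 1L
    lines_md <- c(lines_md, "## Intensity-rate correlation", "",
                  if (is.null(correlation$note))
                    sprintf("Pearson r = %.2f, %s, n = %d", correlation$r,
                            format_p(correlation$p), correlation$n)
                  else paste("correlation", correlation$note), "")
  }
  for (nm in names(group_tables)) {
    tab <- group_tables[[nm]]
    utils::write.csv(tab, file.path(out_dir, paste0("groups_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    lines_md <- c(lines_md, sprintf("## Groups by %s", nm), "",
                  sprintf("- %s: n=%d, %.2f CIC/mm2 (SD %s), %.0f%% with CIC%s",
                          tab$group, tab$n_samples, tab$mean_cic_per_mm2,
                          ifelse(is.na(tab$sd_cic_per_mm2), "NA",
                                 sprintf("%.2f", tab$sd_cic_per_mm2)),
                          100 * tab$fraction_with_cic,
                          ifelse(tab$significance_eligible, "",
                                 " [n < 5: no significance calculated]")), "")
  }
  for (nm in names(significance_tables)) {
    tab <- significance_tables[[nm]]
    n_tests <- n_tests + sum(tab$calculated)
    utils::write.csv(tab, file.path(out_dir, paste0("significance_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    lines_md <- c(lines_md, sprintf("## Significance by %s", nm), "",
                  sprintf("- %s vs %s: %s", tab$group1, tab$group2,
                          ifelse(tab$calculated,
                                 vapply(tab$p, format_p, character(1)),
                                 "not calculated (n < 5)")), "")
  }
  if (!is.null(score_table)) {
    utils::write.csv(score_table, file.path(out_dir, "score_distribution.csv"),
                     row.names = FALSE, quote = FALSE)
    lines_md <- c(lines_md, "## E-cadherin score distribution", "",
                  sprintf("- score %d: %d (%.1f%%)", score_table$score,
                          score_table$n, score_table$percent), "")
  }
  lines_md <- c(lines_md,
                sprintf("Comparisons made: %d (no multiple-testing correction applied).",
                        n_tests))
  path <- file.path(out_dir, "report.md")
  writeLines(lines_md, path)
  invisible(path)
}
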