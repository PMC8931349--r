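#' Aggregate per-curve fit results to one row per cell
#'
#' Batch AFM studies acquire several (typically three) curves per cell;
#' the per-cell value of each parameter is the median across that cell's
#' curves, so single outlier curves do not dominate and cells — not curves
#' — are the statistical unit.
#'
#' @param df A data frame of per-curve results (e.g. [fit_results_df()])
#'   with a cell identifier column.
#' @param value_cols Columns to aggregate (default: the five reported
#'   parameters).
#' @param cell_col,group_col Identifier column names.
#' @return A data frame with one row per cell: group, cell, n_curves, and
#'   the per-cell medians.
#' @export
aggregate_per_cell <- function(df,
                               value_cols = c("E0_Pa", "E1_Pa", "eta_Pa_s",
                                              "Eu_Pa", "Eapp_Pa"),
                               cell_col = "cell", group_col = "group") {
  stopifnot(is.data.frame(df), cell_col %in% names(df),
            all(value_cols %in% names(df)))
  cells <- unique(df[[cell_col]])
  rows <- lapply(cells, function(cl) {
    sub <- df[df[[cell_col]] == cl, , drop = FALSE]
    out <- data.frame(cell = cl, n_curves = nrow(sub),
                      stringsAsFactors = FALSE)
    if (group_col %in% names(df)) out$group <- sub[[group_col]][1]
    for (vc in value_cols) out[[vc]] <- stats::median(sub[[vc]])
    out
  })
  do.call(rbind, rows)
}

#' Percentile and moment summary of a parameter by group
#'
#' The box/whisker quantities used to report fitted parameters: median,
#' 25th/75th percentiles (box), 10th/90th percentiles (whiskers), plus
#' mean and standard error.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector, same length.
#' @return A data frame, one row per group: `group`, `n`, `median`, `q25`,
#'   `q75`, `q10`, `q90`, `mean`, `sem`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(is.numeric(values), length(values) == length(groups))
  gs <- unique(as.character(groups))
  rows <- lapply(gs, function(g) {
    x <- values[groups == g]
    q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    data.frame(group = g, n = length(x), median = q[3],
               q25 = q[2], q75 = q[4], q10 = q[1], q90 = q[5],
               mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.sig_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p > 0.05) "n.s." else "significant"
}

#' Compare a fitted parameter across groups
#'
#' Kruskal-Wallis rank test across all groups, followed by pairwise
#' post-hoc Welch t-tests. Significance labels follow the reporting
#' convention `***` for p < 0.001 and `n.s.` for p > 0.05. By default the
#' pairwise p values are uncorrected; set `p_adjust = "holm"` (or any
#' [stats::p.adjust()] method) to correct for multiplicity.
#'
#' @param values Numeric vector of per-cell (or per-curve) parameter
#'   values.
#' @param groups Grouping vector, same length; at least 2 groups with
#'   n >= 3 each.
#' @param p_adjust Multiplicity correction for the pairwise tests
#'   (default `"none"`).
#' @return A list of class `"group_comparison"`: `kruskal` (list with `H`,
#'   `df`, `p`, `label`), `pairwise` (data frame `group1`, `group2`, `p`,
#'   `label`), `summary` (the [group_summary()] table).
#' @export
compare_groups <- function(values, groups, p_adjust = "none") {
  groups <- as.character(groups)
  stopifnot(is.numeric(values), length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 3L)) stop("each group needs n >= 3", call. = FALSE)

  if (length(unique(values)) == 1L) {
    kr <- list(H = 0, df = length(tab) - 1L, p = 1, label = "n.s.")
    pw <- t(utils::combn(names(tab), 2L))
    pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2],
                           p = 1, label = "n.s.",
                           stringsAsFactors = FALSE)
  } else {
    kt <- stats::kruskal.test(values, factor(groups))
    kr <- list(H = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value, label = .sig_label(kt$p.value))
    pw <- t(utils::combn(names(tab), 2L))
    pvals <- apply(pw, 1L, function(gg) {
      x <- values[groups == gg[1]]
      y <- values[groups == gg[2]]
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y)$p.value
    })
    pvals <- stats::p.adjust(pvals, method = p_adjust)
    pairwise <- data.frame(group1 = pw[, 1], group2 = pw[, 2], p = pvals,
                           label = vapply(pvals, .sig_label, ""),
                           stringsAsFactors = FALSE)
  }
  structure(list(kruskal = kr, pairwise = pairwise,
                 summary = group_summary(values, groups)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g (%s)\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p, x$kruskal$label))
  cat("pairwise Welch t-tests:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
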