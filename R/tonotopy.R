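## Tonotopic aggregation and gradient testing along the cochlear axis.

#' Aggregate per-cell measurements by cochlear position
#'
#' Snaps each cell's position to the nearest canonical location (D05, D20,
#' D40, D60, D80) within a tolerance and computes group mean +/- SEM per
#' position and condition. Off-grid cells keep their own position with
#' `canonical = NA`; they are excluded from canonical-group statistics but
#' retained for regression use. Empty condition groups are dropped with a
#' warning.
#'
#' @param cells data.frame with columns `position`, `value` and optionally
#'   `condition` (e.g. genotype x Ca2+ label).
#' @param snap_tol snapping tolerance in D units (default 0.05).
#' @return An object of class `hc_tonotable` (a data.frame): `position`
#'   (canonical D), `condition`, `n`, `mean`, `sem`, `single_n`.
#' @export
aggregate_by_position <- function(cells, snap_tol = 0.05) {
  stopifnot(all(c("position", "value") %in% names(cells)))
  if (is.null(cells$condition)) cells$condition <- "all"
  d <- CANONICAL_D[apply(abs(outer(cells$position, CANONICAL_D, "-")), 1,
                         which.min)]
  off <- abs(cells$position - d) > snap_tol
  cells$canonical <- ifelse(off, NA_real_, d)
  if (any(off))
    warning(sum(off), " cell(s) lie off the canonical position grid ",
            "and are excluded from group statistics")
  grp <- cells[!is.na(cells$canonical), , drop = FALSE]
  if (!nrow(grp)) stop("no cells on the canonical position grid")
  key <- interaction(grp$canonical, grp$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(grp, key), function(g)
    data.frame(position = g$canonical[1], condition = g$condition[1],
               n = nrow(g), mean = mean(g$value),
               sem = if (nrow(g) > 1) stats::sd(g$value) / sqrt(nrow(g))
                 else 0,
               single_n = nrow(g) == 1L)))
  rownames(out) <- NULL
  out <- out[order(out$condition, out$position), , drop = FALSE]
  class(out) <- c("hc_tonotable", class(out))
  attr(out, "cells") <- cells
  out
}

#' Test for a tonotopic gradient
#'
#' Two complementary tests on per-cell values across cochlear positions:
#' a one-way ANOVA over canonical position groups (the group-difference
#' test) and a linear trend test -- a regression of the per-cell values on
#' position D, whose slope (pA per unit D for current measures), standard
#' error and t-test p-value quantify the gradient. Needs at least 3
#' positions with n >= 3 each for the ANOVA.
#'
#' @param table an `hc_tonotable` from [aggregate_by_position()], or a
#'   per-cell data.frame with `position` and `value` columns.
#' @param condition when the table holds several conditions, which one to
#'   test (default: the first).
#' @return list: `slope`, `slope_se`, `p_trend` (trend regression),
#'   `p_anova` (group ANOVA), `n_groups`.
#' @export
gradient_test <- function(table, condition = NULL) {
  cells <- if (inherits(table, "hc_tonotable")) attr(table, "cells")
    else {
      stopifnot(all(c("position", "value") %in% names(table)))
      tb <- table
      if (is.null(tb$condition)) tb$condition <- "all"
      d <- CANONICAL_D[apply(abs(outer(tb$position, CANONICAL_D, "-")), 1,
                             which.min)]
      tb$canonical <- ifelse(abs(tb$position - d) > 0.05, NA_real_, d)
      tb
    }
  if (is.null(condition)) condition <- cells$condition[1]
  cells <- cells[cells$condition == condition, , drop = FALSE]
  grp <- cells[!is.na(cells$canonical), , drop = FALSE]
  tab <- vapply(split(grp$value, grp$canonical), length, 1L)
  ok_groups <- names(tab)[tab >= 3]
  if (length(ok_groups) < 3)
    stop("gradient test needs >= 3 canonical positions with n >= 3")
  ga <- grp[grp$canonical %in% as.numeric(ok_groups), , drop = FALSE]
  p_anova <- summary(stats::aov(value ~ factor(canonical),
                                data = ga))[[1]][["Pr(>F)"]][1]
  fit <- stats::lm(value ~ position, data = cells)
  sm <- summary(fit)$coefficients
  list(slope = sm["position", "Estimate"],
       slope_se = sm["position", "Std. Error"],
       p_trend = sm["position", "Pr(>|t|)"],
       p_anova = p_anova,
       n_groups = length(ok_groups))
}
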