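.diet_palette <- c(HOK = "#1f3a93", NEH = "#7d3c98", CCH = "#7f8c8d",
                   ICH = "#000000", SWJ = "#e67e22")

#' Scatter plot of canonical variates scores
#'
#' CV1 x CV2 (or CV1 against jitter when only one axis exists), coloured by
#' group with the conventional diet-group palette where codes match.
#'
#' @param x a `cva_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cva_result <- function(x, ...) {
  lab <- x$labels
  cols <- .diet_palette[as.character(lab)]
  cols[is.na(cols)] <- grDevices::hcl.colors(nlevels(lab), "Dark 3")[as.integer(lab)][is.na(cols)]
  if (x$n_axes >= 2) {
    graphics::plot(x$cv_scores[, 1], x$cv_scores[, 2], col = cols, pch = 19,
                   xlab = sprintf("CV1 (%.1f%%)", x$pct_differentiation[1]),
                   ylab = sprintf("CV2 (%.1f%%)", x$pct_differentiation[2]),
                   ...)
  } else {
    graphics::stripchart(x$cv_scores[, 1] ~ lab, vertical = TRUE,
                         method = "jitter", pch = 19, col = .diet_palette,
                         ylab = "CV1", ...)
  }
  graphics::legend("topright", legend = levels(lab),
                   col = .diet_palette[levels(lab)], pch = 19, bty = "n")
  invisible(x)
}

#' Correlogram biplot: Moran's I against class mean distance
#'
#' Filled points mark classes significant at p < 0.05; open points are
#' non-significant; crossed points are classes with undefined p.
#'
#' @param x a `correlogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.correlogram <- function(x, ...) {
  pch <- ifelse(!x$defined, 4, ifelse(!is.na(x$p_perm) & x$p_perm < 0.05, 19, 1))
  graphics::plot(x$mean_distance_km, x$morans_i, type = "b", pch = pch,
                 xlab = "mean distance (km)", ylab = "Moran's I",
                 main = attr(x, "variable"), ...)
  graphics::abline(h = -1 / (attr(x, "n_sites") - 1), lty = 2, col = "grey50")
  invisible(x)
}

#' Box-plot with jitter of bite force by group
#'
#' @param bf data frame from [biteforce_table()].
#' @param by grouping column (`"diet_group"` or `"sex"`).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_biteforce <- function(bf, by = "diet_group", ...) {
  grp <- factor(bf[[by]])
  graphics::boxplot(bf$BF ~ grp, outline = FALSE, ylab = "relative bite force",
                    xlab = by, ...)
  graphics::points(jitter(as.integer(grp), 0.35), bf$BF, pch = 19,
                   col = grDevices::adjustcolor(
                     .diet_palette[as.character(grp)], 0.7))
  invisible(bf)
}
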