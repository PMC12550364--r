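#' Two-way group-by-day ANOVA of a study quantification table
#'
#' Tests whether a longitudinal measurement (wall thickness, per-layer
#' attenuation coefficient, or percent change from baseline) differs
#' between challenged and unchallenged mice across imaging days, with the
#' group x day interaction carrying the colitis signal (an effect present
#' only in challenged mice at peak inflammation).
#'
#' By default measurements are averaged to one value per mouse-day before
#' the ANOVA (`unit = "mouse_mean"`): the 10 pullback locations of one
#' mouse are not independent replicates, and treating them as such
#' inflates power. `unit = "location"` uses each location as an
#' observation and is provided for comparison.
#'
#' Sums of squares are Type II (via `car::Anova`), which handles
#' unbalanced tables and reduces to the classical decomposition when the
#' design is balanced.
#'
#' @param tab Long table from [quantify_study()] (columns `mouse`,
#'   `group`, `day`, `location` and the response).
#' @param response One of `"thickness_um"`, `"mu_A"`, `"pct_change"`.
#' @param unit `"mouse_mean"` (default) or `"location"`.
#' @param layer Optional layer name to filter on (e.g. `"wall"` for
#'   thickness rows, a layer name for attenuation rows).
#' @return An `AnovaTable` data.frame with one row per term (`group`,
#'   `day`, `group:day`, `Residuals`) and columns `sum_sq`, `df`,
#'   `statistic`, `p_value`, plus a `signif` significance annotation
#'   (`***` for p <= 0.001).
#' @export
two_way_anova <- function(tab, response = c("thickness_um", "mu_A",
                                            "pct_change"),
                          unit = c("mouse_mean", "location"),
                          layer = NULL) {
  response <- match.arg(response)
  unit <- match.arg(unit)
  if (!is.null(layer)) tab <- tab[tab$layer == layer, ]
  tab <- tab[!is.na(tab[[response]]), ]
  if (!nrow(tab)) stop("no observations for response ", response, call. = FALSE)
  if (length(unique(tab$group)) < 2 || length(unique(tab$day)) < 2)
    stop("need at least 2 levels of both group and day", call. = FALSE)

  if (unit == "mouse_mean") {
    agg <- stats::aggregate(tab[[response]],
                            by = list(mouse = tab$mouse, group = tab$group,
                                      day = tab$day),
                            FUN = mean, na.rm = TRUE)
    names(agg)[4] <- "y"
  } else {
    agg <- data.frame(mouse = tab$mouse, group = tab$group, day = tab$day,
                      y = tab[[response]])
  }
  cells <- table(agg$group, agg$day)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell: group '", rownames(cells)[bad[1, 1]],
         "', day ", colnames(cells)[bad[1, 2]], call. = FALSE)
  }
  agg$group <- factor(agg$group)
  agg$day <- factor(agg$day)
  fit <- stats::lm(y ~ group * day, data = agg)
  a2 <- car::Anova(fit, type = 2)
  out <- data.frame(term = rownames(a2),
                    sum_sq = a2[["Sum Sq"]],
                    df = a2[["Df"]],
                    statistic = a2[["F value"]],
                    p_value = a2[["Pr(>F)"]])
  rownames(out) <- NULL
  out$signif <- ifelse(is.na(out$p_value), "",
                       ifelse(out$p_value <= 0.001, "***",
                              ifelse(out$p_value <= 0.01, "**",
                                     ifelse(out$p_value <= 0.05, "*", ""))))
  class(out) <- c("AnovaTable", class(out))
  out
}

#' Group x day x layer summary statistics
#'
#' Box-plot-ready summaries of a quantification table: mean, standard
#' deviation and observation count per group, day and layer. Cells with a
#' single observation report `NA` standard deviation; empty cells are
#' absent from the output.
#'
#' @param tab Long table from [quantify_study()].
#' @param response Response column to summarise.
#' @return Data.frame with `group`, `day`, `layer`, `mean`, `sd`, `n`.
#' @export
summarize_quant <- function(tab, response = "thickness_um") {
  stopifnot(response %in% names(tab))
  tab <- tab[!is.na(tab[[response]]), ]
  if (!nrow(tab)) stop("empty quantification table", call. = FALSE)
  agg <- stats::aggregate(tab[[response]],
                          by = list(group = tab$group, day = tab$day,
                                    layer = tab$layer),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group = agg$group, day = agg$day, layer = agg$layer,
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = as.integer(agg$x[, "n"]))
  out[order(out$layer, out$group, out$day), , drop = FALSE]
}

#' Box plot of a quantification summary
#'
#' Convenience ggplot2 figure mirroring the usual presentation of
#' longitudinal colitis measurements: per-day boxes split by group, one
#' panel per layer. Requires ggplot2 (suggested dependency).
#'
#' @param tab Long table from [quantify_study()].
#' @param response Response column.
#' @return A ggplot object.
#' @export
plot_quant <- function(tab, response = "thickness_um") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_quant requires the ggplot2 package", call. = FALSE)
  tab <- tab[!is.na(tab[[response]]), ]
  tab$.resp <- tab[[response]]
  tab$.day <- factor(tab$day)
  ggplot2::ggplot(tab, ggplot2::aes(x = .day, y = .resp, fill = group)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = "day", y = response) +
    ggplot2::theme_minimal()
}
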